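Package: cthabitat
Title: CT Radiomic Tumour Habitat Mapping and CT/US Fusion Accuracy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps intra-tumoural habitats on contrast-enhanced CT by computing
    sliding-window grey-level co-occurrence (Haralick) texture maps over a
    tumour volume of interest, reducing them with principal component
    analysis, and clustering the per-voxel principal components together with
    Hounsfield units using a Gaussian mixture model whose component count is
    selected by the minimum Akaike information criterion (at most three
    habitats, with a minimum habitat volume rule). Also provides
    landmark-based rigid CT-to-ultrasound registration, reslicing of the CT
    tumour silhouette into the ultrasound plane, and Dice-coefficient
    quantification of fusion accuracy, together with a seeded synthetic
    phantom generator (CT-like lesions with ground-truth habitats and
    simulated ultrasound frames) so that every stage is testable end to end.
    Habitat maps are exported as DICOM segmentation objects and NIfTI.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
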