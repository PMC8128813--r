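#' Published per-patient characteristics of the development cohort
#'
#' The six-patient table from the technique-development study this package
#' reimplements computationally: age, FIGO stage, days between the CT scan
#' and the biopsy, lesion site (pelvis/omentum), number of biopsies, number
#' of habitats, targeted lesion volume in cm^3, biopsy adequacy, weight,
#' and the per-lesion CT/US fusion DSC. The DSC is `NA` for patient 1,
#' whose tumour edges were not visible on B-mode US (an undefined overlap,
#' not a zero); the assignment of the within-site DSC values to individual
#' patients is arbitrary since they were reported per site.
#'
#' @return A data frame with one row per patient.
#' @export
study_patients <- function() {
  path <- system.file("extdata", "study_patients.csv",
                      package = "cthabitat", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(dsc = "numeric"))
}
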