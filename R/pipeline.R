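# One-shot pipeline orchestration with a reproducible run manifest.

stage_log <- function(verbose, stage, msg) {
  if (verbose)
    message(sprintf("[%s] %s", stage, msg))
}

run_stage <- function(stage, verbose, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full habitat (and optional fusion) pipeline
#'
#' Executes, in order: CT and VOI reading, omental fat sub-segmentation
#' (when `site = "omentum"`), sliding-window texture maps, PCA (fitted on
#' this lesion's maps, or loaded from a serialised model), Gaussian-mixture
#' habitat clustering with AIC selection, the minimum-habitat-volume rule,
#' DICOM-SEG + NIfTI export, and — when landmarks, a US frame and a US
#' segmentation are supplied — rigid CT/US registration, reslicing and DSC
#' computation. A JSON run manifest recording the configuration, stages and
#' output content hashes is written alongside the outputs; seeded reruns
#' reproduce the output hashes.
#'
#' @param config a named list or path to a JSON file with entries: `ct`
#'   (CT path), `mask` (VOI path), `out_dir`, optional `site`
#'   (`"pelvis"`/`"omentum"`), `pca_model` (serialised model JSON),
#'   `landmarks` (CSV), `us_frame` (pose JSON), `us_seg` (mask image),
#'   and any [pipeline_config()] field.
#' @param verbose log stage progress to stderr.
#' @return The run manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$ct) || is.null(config$mask) || is.null(config$out_dir))
    stop("config must name 'ct', 'mask' and 'out_dir'")
  pcfg_fields <- names(formals(pipeline_config))
  pcfg <- do.call(pipeline_config, config[intersect(names(config), pcfg_fields)])
  site <- if (is.null(config$site)) "pelvis" else config$site
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  outputs <- character(0)

  stage_log(verbose, "read", sprintf("reading CT from %s", config$ct))
  volume <- run_stage("read_ct", verbose, read_ct_series(config$ct))
  mask <- run_stage("read_mask", verbose, read_mask(config$mask, volume))
  stages <- c(stages, "read_ct", "read_mask")

  if (identical(site, "omentum")) {
    stage_log(verbose, "sub_segmentation",
              sprintf("removing fat below %g HU", pcfg$fat_hu_max))
    mask <- run_stage("sub_segmentation", verbose,
                      sub_segment_solid(volume, mask,
                                        fat_hu_max = pcfg$fat_hu_max))
    stages <- c(stages, "sub_segmentation")
  }

  stage_log(verbose, "textures", sprintf(
    "texture maps over %d voxels (window %d, %d levels)",
    sum(mask$voxels), pcfg$window, pcfg$n_levels))
  tcfg <- texture_config(pcfg$window, pcfg$n_levels,
                         window_masking = pcfg$window_masking)
  stack <- run_stage("textures", verbose,
                     texture_map_stack(volume, mask, tcfg))
  stages <- c(stages, "textures")

  if (!is.null(config$pca_model)) {
    stage_log(verbose, "pca", sprintf("loading PCA model %s",
                                      config$pca_model))
    pca <- run_stage("pca", verbose, read_pca_model(config$pca_model))
  } else {
    stage_log(verbose, "pca", "fitting PCA on this lesion's texture maps")
    pca <- run_stage("pca", verbose,
                     fit_pca(stack, m_cap = pcfg$m_cap,
                             variance_target = pcfg$variance_target))
  }
  stages <- c(stages, "pca")

  stage_log(verbose, "cluster", sprintf("GMM over %d PCs + HU, k <= %d",
                                        pca$m, pcfg$k_max))
  pc <- run_stage("cluster", verbose, project_pca(stack, pca))
  hu <- stack$hu[stack$valid]
  model <- run_stage("cluster", verbose, fit_habitats(pc, hu, pcfg))
  vm <- array(FALSE, stack$dim)
  vm[stack$idx[stack$valid]] <- TRUE
  valid_mask <- voi_mask(vm)
  map <- run_stage("cluster", verbose,
                   label_habitats(model, pc, hu, valid_mask,
                                  spacing = volume$spacing))
  map <- run_stage("min_volume", verbose,
                   enforce_min_volume(map, model, pcfg$min_habitat_cm3))
  stages <- c(stages, "cluster", "min_volume")

  seg_path <- file.path(out_dir, "habitats.dcm")
  nii_path <- file.path(out_dir, "habitats.nii.gz")
  run_stage("export", verbose, write_habitat_dicom(map, volume, seg_path))
  run_stage("export", verbose, write_nifti(map, nii_path, reference = volume))
  pca_path <- file.path(out_dir, "pca_model.json")
  write_pca_model(pca, pca_path)
  outputs <- c(outputs, seg_path, nii_path, pca_path)
  stages <- c(stages, "export")

  report <- list(site = site, k = map$k,
                 habitat_volumes_cm3 = as.list(map$volumes_cm3),
                 voi_volume_cm3 = mask_volume_cm3(mask, volume$spacing),
                 aic_by_k = model$aic_by_k,
                 pca_components = pca$m,
                 pca_explained = sum(pca$explained[seq_len(pca$m)]))

  if (!is.null(config$landmarks) && !is.null(config$us_frame)) {
    stage_log(verbose, "fusion", "rigid CT/US registration and DSC")
    lm <- run_stage("fusion", verbose, read_landmarks(config$landmarks))
    frame <- run_stage("fusion", verbose, read_us_frame(config$us_frame))
    transform <- run_stage("fusion", verbose, fit_rigid(lm))
    resliced <- run_stage("fusion", verbose,
                          reslice_mask(mask, volume, frame, transform))
    report$fre_mm <- fre(lm, transform)
    if (!is.null(config$us_seg)) {
      us_seg <- run_stage("fusion", verbose, {
        s <- RNifti::readNifti(config$us_seg)
        s <- array(as.vector(s), dim(s))
        if (length(dim(s)) == 3L) s <- s[, , 1]
        s != 0
      })
      report$dsc <- dice(resliced, us_seg)
    }
    stages <- c(stages, "fusion")
  }

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  outputs <- c(outputs, report_path)

  manifest <- list(
    tool = "cthabitat",
    version = as.character(packageVersion("cthabitat")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = pcfg$seed,
    config = c(list(ct = config$ct, mask = config$mask, site = site),
               unclass(pcfg)),
    input_hashes = as.list(tools::md5sum(c(config$ct, config$mask)[
      file.exists(c(config$ct, config$mask))])),
    stages = stages,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p)))),
    report = report)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, na = "null")
  invisible(manifest)
}
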