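# Habitat definition: Gaussian mixture over (principal components, HU),
# component count selected by minimum AIC with a hard cap, labels ordered
# by mean HU, and a minimum-habitat-volume rule.

#' Pipeline configuration
#'
#' Holds the fixed analysis constants: sliding-window size 5, 32 grey
#' levels, up to 6 principal components retaining >= 90% of variance, at
#' most 3 habitats, a 3 cm^3 minimum habitat volume, and a -30 HU fat
#' threshold for omental sub-segmentation.
#'
#' @param window sliding-window size in voxels.
#' @param n_levels grey levels for GLCM quantisation.
#' @param m_cap maximum retained principal components.
#' @param variance_target cumulative explained-variance target.
#' @param k_max maximum number of habitats.
#' @param min_habitat_cm3 minimum habitat volume in cm^3; smaller habitats
#'   are dissolved into the remaining ones.
#' @param fat_hu_max HU threshold for fat removal in omental lesions.
#' @param window_masking see [texture_config()].
#' @param max_fit_voxels cap on the number of voxels used to fit the
#'   mixture (a seeded random subsample when the VOI is larger); every
#'   voxel is still labelled from the fitted model.
#' @param seed random seed for the mixture fitting.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(window = 5L, n_levels = 32L, m_cap = 6L,
                            variance_target = 0.90, k_max = 3L,
                            min_habitat_cm3 = 3.0, fat_hu_max = -30,
                            window_masking = "volume",
                            max_fit_voxels = 4000L, seed = 1L) {
  stopifnot(variance_target > 0, k_max >= 1L, min_habitat_cm3 > 0,
            m_cap >= 1L, max_fit_voxels >= 50L)
  structure(list(window = as.integer(window), n_levels = as.integer(n_levels),
                 m_cap = as.integer(m_cap),
                 variance_target = variance_target,
                 k_max = as.integer(k_max),
                 min_habitat_cm3 = min_habitat_cm3,
                 fat_hu_max = fat_hu_max,
                 window_masking = window_masking,
                 max_fit_voxels = as.integer(max_fit_voxels),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Fit the habitat mixture model over (principal components, HU)
#'
#' The per-voxel feature vector joins the m principal component scores with
#' the standardised HU value. For each candidate component count
#' k = 1..`k_max`, a full-covariance Gaussian mixture is fitted by EM
#' (k-means++ initialisation, 5 restarts, log-likelihood tolerance 1e-4,
#' covariance ridge 1e-6) under the configured seed. The habitat count is
#' the k minimising AIC = 2q - 2 lnL with
#' q = (k - 1) + k d + k d(d+1)/2 free parameters (d = m + 1); ties break
#' toward smaller k. Candidates whose EM fails are excluded with a warning.
#'
#' @param pc_maps matrix (n x m) of per-voxel PC scores from
#'   [project_pca()].
#' @param hu numeric vector of per-voxel HU values (length n).
#' @param config a [pipeline_config()].
#' @return Object of class `habitat_model` with the selected mixture
#'   (`k`, `weights`, `means`, `covariances`), `aic_by_k`, the seed, and
#'   the HU standardisation used.
#' @export
fit_habitats <- function(pc_maps, hu, config = pipeline_config()) {
  pc_maps <- as.matrix(pc_maps)
  n <- nrow(pc_maps)
  if (length(hu) != n) stop("pc_maps and hu disagree in length")
  if (n < 50) stop("too few voxels for habitat clustering (need >= 50)")
  hu_center <- mean(hu)
  hu_scale <- sd(hu)
  if (!is.finite(hu_scale) || hu_scale <= 0) hu_scale <- 1
  X <- cbind(pc_maps, (hu - hu_center) / hu_scale)
  d <- ncol(X)
  fits <- vector("list", config$k_max)
  aic <- rep(NA_real_, config$k_max)
  with_seed(config$seed, {
    Xfit <- if (n > config$max_fit_voxels)
      X[sample.int(n, config$max_fit_voxels), , drop = FALSE]
    else X
    for (k in seq_len(config$k_max)) {
      fit <- tryCatch(gmm_em(Xfit, k), error = function(e) NULL)
      if (is.null(fit)) {
        warning(sprintf("EM failed for k = %d; candidate excluded", k))
        next
      }
      q <- (k - 1) + k * d + k * d * (d + 1) / 2
      fits[[k]] <- fit
      aic[k] <- 2 * q - 2 * fit$loglik
    }
  })
  if (all(is.na(aic)))
    stop("clustering failed for every candidate component count")
  k_sel <- which.min(aic)  # NA candidates never win; ties -> smaller k
  fit <- fits[[k_sel]]
  structure(list(k = as.integer(k_sel), weights = fit$weights,
                 means = fit$means, covariances = fit$covs,
                 loglik = fit$loglik, aic_by_k = aic,
                 seed = config$seed, d = d,
                 hu_center = hu_center, hu_scale = hu_scale),
            class = "habitat_model")
}

#' @export
print.habitat_model <- function(x, ...) {
  cat(sprintf("<habitat_model> k = %d (AIC by k: %s)\n", x$k,
              paste(format(x$aic_by_k, digits = 6), collapse = ", ")))
  invisible(x)
}

# feature matrix in the model's space
habitat_feature_matrix <- function(model, pc_maps, hu) {
  cbind(as.matrix(pc_maps), (hu - model$hu_center) / model$hu_scale)
}

#' Assign habitat labels to VOI voxels
#'
#' Each voxel gets the maximum-posterior mixture component; components are
#' renumbered 1..k in increasing order of their mean HU so labels are
#' deterministic and comparable across runs.
#'
#' @param model a fitted [habitat_model].
#' @param pc_maps matrix of PC scores, rows matching the foreground voxels
#'   of `mask` in column-major grid order.
#' @param hu per-voxel HU values.
#' @param mask the [voi_mask()] the rows refer to.
#' @param spacing voxel spacing in mm (for habitat volumes).
#' @return A [habitat_map()]; the per-voxel posterior matrix (columns in
#'   label order) and voxel indices are attached as attributes for the
#'   volume rule.
#' @export
label_habitats <- function(model, pc_maps, hu, mask, spacing) {
  idx <- which(mask$voxels)
  X <- habitat_feature_matrix(model, pc_maps, hu)
  if (nrow(X) != length(idx))
    stop("pc_maps rows must match mask foreground voxels")
  post <- gmm_log_resp(model$weights, model$means, model$covariances, X)
  ord <- order(model$means[, model$d])  # ascending mean (standardised) HU
  post <- post[, ord, drop = FALSE]
  lab_vox <- max.col(post, ties.method = "first")
  labels <- array(0L, dim(mask$voxels))
  labels[idx] <- lab_vox
  map <- habitat_map(labels, spacing = spacing, k_max = model$k)
  attr(map, "posterior") <- post
  attr(map, "voxel_idx") <- idx
  map
}

#' Dissolve habitats smaller than a minimum volume
#'
#' Any habitat below `min_habitat_cm3` (smallest first) is dissolved: its
#' voxels are reassigned to the remaining component with the highest
#' posterior, labels are renumbered (preserving the mean-HU order), and the
#' rule repeats until every habitat reaches the threshold or a single
#' habitat remains. Total labelled volume is conserved exactly.
#'
#' @param map a [habitat_map()] from [label_habitats()].
#' @param model the [habitat_model] that produced it.
#' @param min_habitat_cm3 minimum habitat volume (default 3 cm^3).
#' @return A [habitat_map()].
#' @export
enforce_min_volume <- function(map, model, min_habitat_cm3 = 3.0) {
  post <- attr(map, "posterior")
  idx <- attr(map, "voxel_idx")
  if (is.null(post) || is.null(idx))
    stop("map lacks posterior attributes; use label_habitats() first")
  labels <- map$labels
  lab_vox <- labels[idx]
  active <- seq_len(map$k)  # columns of post still alive, in label order
  repeat {
    vox_cm3 <- prod(map$spacing) / 1000
    vols <- vapply(seq_along(active), function(l)
      sum(lab_vox == l) * vox_cm3, numeric(1))
    if (length(active) <= 1L) break
    under <- which(vols < min_habitat_cm3)
    if (length(under) == 0L) break
    drop_l <- under[which.min(vols[under])]
    keep <- setdiff(seq_along(active), drop_l)
    sub <- post[, active[keep], drop = FALSE]
    moved <- lab_vox == drop_l
    lab_vox[moved] <- max.col(sub[moved, , drop = FALSE],
                              ties.method = "first")
    # renumber survivors compactly, preserving order
    remap <- integer(length(active))
    remap[keep] <- seq_along(keep)
    lab_vox[!moved] <- remap[lab_vox[!moved]]
    active <- active[keep]
  }
  labels[idx] <- lab_vox
  out <- habitat_map(labels, spacing = map$spacing, k_max = length(active))
  attr(out, "posterior") <- post[, active, drop = FALSE]
  attr(out, "voxel_idx") <- idx
  out
}
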