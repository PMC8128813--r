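# Sliding-window GLCM (Haralick) texture maps over a tumour VOI.

default_offsets <- function() {
  # the four unit-distance in-plane directions: 0, 45, 90, 135 degrees
  rbind(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))
}

#' Texture-map configuration
#'
#' @param window odd in-plane sliding-window size in voxels (default 5).
#' @param n_levels number of grey levels for quantisation (default 32).
#' @param offsets integer matrix of in-plane displacement vectors (di, dj);
#'   each offset is accumulated together with its negation (symmetric GLCM).
#'   Default: the four unit offsets at 0/45/90/135 degrees.
#' @param window_masking `"volume"` (default): windows are clipped at the
#'   volume edge only, so tissue surrounding the VOI contributes context;
#'   `"voi"`: voxels outside the VOI are excluded from co-occurrence pairs.
#' @return A `texture_config` list.
#' @export
texture_config <- function(window = 5L, n_levels = 32L,
                           offsets = default_offsets(),
                           window_masking = c("volume", "voi")) {
  window <- as.integer(window)
  n_levels <- as.integer(n_levels)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be odd and >= 3")
  if (n_levels < 2L)
    stop("n_levels must be >= 2")
  offsets <- matrix(as.integer(offsets), ncol = 2L)
  if (nrow(offsets) == 0L)
    stop("offsets must be non-empty")
  structure(list(window = window, n_levels = n_levels, offsets = offsets,
                 window_masking = match.arg(window_masking)),
            class = "texture_config")
}

feature_names <- c("energy", "entropy", "sum_average", "correlation",
                   "idmn", "contrast", "cluster_shade",
                   "cluster_prominence", "haralick_correlation")

#' Quantise HU values inside a mask into equal-width grey levels
#'
#' Linear min-max binning of the HU values inside the mask into levels
#' 1..`n_levels`; the maximum maps to `n_levels`, voxels outside the mask
#' get level 0. A constant VOI maps every masked voxel to level 1. Because
#' binning is min-max, any positive affine rescale of the HU leaves the
#' level grid unchanged.
#'
#' @param volume an [image_volume()] or 3D array.
#' @param mask a [voi_mask()] or logical array; defines both the binning
#'   range and (unless `clamp_outside`) the quantised support.
#' @param n_levels number of grey levels.
#' @param clamp_outside if `TRUE`, apply the mask-derived bin edges to every
#'   voxel in the grid, clamping to `[1, n_levels]` (used when surrounding
#'   tissue should contribute to boundary windows).
#' @return Integer array of levels, same shape as the volume.
#' @export
quantize_hu <- function(volume, mask, n_levels = 32L, clamp_outside = FALSE) {
  vox <- if (inherits(volume, "image_volume")) volume$voxels else as.array(volume)
  m <- if (inherits(mask, "voi_mask")) mask$voxels else as.array(mask) != 0
  if (!identical(dim(vox), dim(m)))
    stop("mask/volume geometry mismatch")
  if (!any(m))
    stop("empty VOI")
  n_levels <- as.integer(n_levels)
  lo <- min(vox[m]); hi <- max(vox[m])
  lev <- array(0L, dim(vox))
  if (hi == lo) {
    if (clamp_outside) lev[] <- 1L else lev[m] <- 1L
    return(lev)
  }
  scale_to <- function(v) {
    l <- as.integer(floor((v - lo) / (hi - lo) * n_levels)) + 1L
    pmax(1L, pmin(l, n_levels))
  }
  if (clamp_outside) lev[] <- scale_to(vox) else lev[m] <- scale_to(vox[m])
  lev
}

#' Grey-level co-occurrence matrix of a 2D window
#'
#' Counts co-occurrences of level pairs for each offset and its negation
#' (symmetric accumulation), pooled over all offsets into a single
#' `n_levels` x `n_levels` matrix normalised to sum to one. Pairs are
#' counted only when both voxels lie inside the window and have level > 0.
#'
#' This is the plain reference implementation; [texture_map_stack()] uses a
#' compiled engine that must agree with the composition of this function and
#' [haralick_features()] at every voxel.
#'
#' @param levels 2D integer matrix of quantised levels (0 = excluded).
#' @param offsets integer matrix of (di, dj) displacements.
#' @param n_levels number of grey levels.
#' @return Normalised symmetric co-occurrence matrix.
#' @export
glcm <- function(levels, offsets = default_offsets(), n_levels = 32L) {
  levels <- as.matrix(levels)
  offsets <- matrix(as.integer(offsets), ncol = 2L)
  ng <- as.integer(n_levels)
  counts <- matrix(0, ng, ng)
  nr <- nrow(levels); nc <- ncol(levels)
  for (o in seq_len(nrow(offsets))) {
    di <- offsets[o, 1]; dj <- offsets[o, 2]
    for (j in seq_len(nc)) {
      j2 <- j + dj
      if (j2 < 1 || j2 > nc) next
      for (i in seq_len(nr)) {
        i2 <- i + di
        if (i2 < 1 || i2 > nr) next
        la <- levels[i, j]; lb <- levels[i2, j2]
        if (la > 0L && lb > 0L) {
          counts[la, lb] <- counts[la, lb] + 1
          counts[lb, la] <- counts[lb, la] + 1
        }
      }
    }
  }
  total <- sum(counts)
  if (total == 0)
    stop("degenerate window: no valid co-occurrence pairs")
  counts / total
}

#' Nine Haralick features of a normalised GLCM
#'
#' Computes, in order: energy, entropy (base-2 log), sum average,
#' correlation, inverse difference moment normalised (IDMN), contrast,
#' cluster shade, cluster prominence, and Haralick correlation. Correlation
#' terms are defined as 0 when a marginal standard deviation vanishes.
#'
#' @param p square matrix of co-occurrence probabilities, symmetric,
#'   summing to one.
#' @return Named numeric vector of length 9.
#' @export
haralick_features <- function(p) {
  p <- as.matrix(p)
  if (nrow(p) != ncol(p) || abs(sum(p) - 1) > 1e-8 ||
      max(abs(p - t(p))) > 1e-8)
    stop("invalid GLCM: must be square, symmetric, and sum to 1")
  ng <- nrow(p)
  lv <- seq_len(ng)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(lv * px); muy <- sum(lv * py)
  sx <- sqrt(sum((lv - mux)^2 * px)); sy <- sqrt(sum((lv - muy)^2 * py))
  ii <- matrix(lv, ng, ng); jj <- t(ii)
  energy <- sum(p^2)
  pe <- p[p > 0]
  entropy <- -sum(pe * log2(pe))
  sum_average <- sum((ii + jj) * p)
  sxsy <- sx * sy
  correlation <- if (sxsy > 1e-12) sum((ii - mux) * (jj - muy) * p) / sxsy else 0
  idmn <- sum(p / (1 + ((ii - jj) / ng)^2))
  contrast <- sum((ii - jj)^2 * p)
  cc <- ii + jj - mux - muy
  cluster_shade <- sum(cc^3 * p)
  cluster_prominence <- sum(cc^4 * p)
  haralick_correlation <- if (sxsy > 1e-12) (sum(ii * jj * p) - mux * muy) / sxsy else 0
  out <- c(energy, entropy, sum_average, correlation, idmn, contrast,
           cluster_shade, cluster_prominence, haralick_correlation)
  names(out) <- feature_names
  out
}

#' Per-voxel sliding-window texture maps over a VOI
#'
#' For every VOI voxel, extracts the in-plane window (clipped at the volume
#' edge), computes the pooled symmetric GLCM over quantised levels, and
#' evaluates the nine Haralick features; the HU channel is copied from the
#' volume. Voxels whose window yields no valid co-occurrence pair are marked
#' invalid.
#'
#' @param volume an [image_volume()].
#' @param mask a [voi_mask()] (after any sub-segmentation).
#' @param config a [texture_config()].
#' @return Object of class `texture_map_stack` with fields `features`
#'   (n x 9 matrix over VOI voxels in column-major grid order), `hu`,
#'   `valid`, `idx` (linear voxel indices), `dim`, `spacing`.
#' @export
texture_map_stack <- function(volume, mask, config = texture_config()) {
  if (!inherits(volume, "image_volume")) stop("volume must be an image_volume")
  if (!inherits(mask, "voi_mask")) stop("mask must be a voi_mask")
  if (!identical(dim(mask$voxels), dim(volume$voxels)))
    stop("mask/volume geometry mismatch")
  if (!any(mask$voxels))
    stop("lesion too small for texture analysis")
  lev <- quantize_hu(volume, mask, config$n_levels,
                     clamp_outside = identical(config$window_masking, "volume"))
  res <- cpp_texture_maps(array(as.integer(lev), dim(lev)),
                          array(mask$voxels, dim(lev)),
                          config$window, config$offsets, config$n_levels)
  if (!any(res$valid))
    stop("lesion too small for texture analysis")
  colnames(res$features) <- feature_names
  structure(list(features = res$features,
                 hu = volume$voxels[res$idx],
                 valid = as.logical(res$valid),
                 idx = as.integer(res$idx),
                 dim = dim(volume$voxels),
                 spacing = volume$spacing,
                 config = config),
            class = "texture_map_stack")
}

#' @export
print.texture_map_stack <- function(x, ...) {
  cat(sprintf("<texture_map_stack> %d VOI voxels (%d valid), window %d, %d levels\n",
              length(x$idx), sum(x$valid), x$config$window,
              x$config$n_levels))
  invisible(x)
}

#' Write a texture map stack as a multi-channel NIfTI
#'
#' Channels: the nine texture maps followed by HU; voxels outside the valid
#' set are NA.
#'
#' @param stack a [texture_map_stack()].
#' @param path output .nii/.nii.gz path.
#' @param reference [image_volume()] supplying geometry.
#' @return Invisibly, `path`.
#' @export
write_texture_nifti <- function(stack, path, reference) {
  arr <- array(NA_real_, c(stack$dim, 10L))
  plane <- prod(stack$dim)
  for (f in 1:9)
    arr[stack$idx + (f - 1L) * plane] <- stack$features[, f]
  arr[stack$idx + 9L * plane] <- stack$hu
  aff <- ras_lps %*% volume_affine_lps(reference)
  img <- RNifti::asNifti(arr)
  full <- rbind(cbind(aff[, 1:3], aff[, 4]), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(full, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
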