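#' CT image volume in patient space
#'
#' Container for a 3D scalar grid of Hounsfield units together with its
#' geometry: voxel spacing in mm, the patient-space position of voxel
#' (1,1,1), and a direction-cosine matrix. The patient coordinate
#' convention is LPS (the DICOM standard); voxel index `(i, j, k)` maps to
#' `origin + orientation %*% (spacing * (c(i, j, k) - 1))`.
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing numeric length-3, voxel spacing (dx, dy, dz) in mm, all
#'   strictly positive.
#' @param origin numeric length-3, patient-space position of voxel (1,1,1)
#'   in mm.
#' @param orientation 3x3 direction-cosine matrix; must be orthonormal with
#'   determinant +1.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                         orientation = diag(3)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L || any(dim(voxels) < 1L))
    stop("voxels must be a non-empty 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be a finite length-3 vector (mm)")
  orientation <- matrix(as.numeric(orientation), 3L, 3L)
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("orientation must be orthonormal")
  if (det(orientation) < 0)
    stop("orientation must have determinant +1 (right-handed)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 orientation = orientation),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x ")))
  cat(sprintf("  HU range [%.1f, %.1f], origin (%s) mm\n",
              min(x$voxels), max(x$voxels),
              paste(format(x$origin, digits = 4), collapse = ", ")))
  invisible(x)
}

# patient-space position (mm) of 1-based voxel indices (n x 3 matrix)
voxel_to_patient <- function(volume, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  t(volume$orientation %*% (t(idx) - 1) * volume$spacing) +
    rep(volume$origin, each = nrow(idx))
}

# inverse mapping: patient-space mm (n x 3) to continuous 1-based indices
patient_to_voxel <- function(volume, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  rel <- t(pts) - volume$origin
  t((crossprod(volume$orientation, rel)) / volume$spacing) + 1
}

#' Tumour volume-of-interest mask
#'
#' Binary mask congruent with a reference [image_volume()]. Any nonzero
#' voxel is treated as foreground (8-bit mask dialects with values such as
#' 255 are tolerated).
#'
#' @param voxels 3D array, coerced to logical by `!= 0`.
#' @param reference an [image_volume()] the mask refers to, or `NULL`.
#' @param allow_empty keep an all-background mask instead of erroring.
#' @return An object of class `voi_mask` with logical `voxels`.
#' @export
voi_mask <- function(voxels, reference = NULL, allow_empty = FALSE) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("mask must be a 3D array")
  if (!is.null(reference)) {
    if (!inherits(reference, "image_volume"))
      stop("reference must be an image_volume")
    if (!identical(dim(voxels), dim(reference$voxels)))
      stop("mask/volume geometry mismatch")
  }
  m <- array(voxels != 0, dim = dim(voxels))
  if (!allow_empty && !any(m))
    stop("empty VOI")
  structure(list(voxels = m, reference_shape = dim(m)), class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %s grid, %d foreground voxels\n",
              paste(x$reference_shape, collapse = " x "),
              sum(x$voxels)))
  invisible(x)
}

#' Physical volume of a mask in cubic centimetres
#'
#' @param mask a [voi_mask()] or 3D logical/numeric array.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @return Foreground voxel count times voxel volume, in cm^3.
#' @export
mask_volume_cm3 <- function(mask, spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive numbers (mm)")
  vox <- if (inherits(mask, "voi_mask")) mask$voxels else mask
  sum(vox != 0) * prod(spacing) / 1000
}

#' Habitat label map
#'
#' Integer label grid over a VOI: 0 outside the VOI, labels 1..k inside.
#' Labels must be contiguous (every value 1..k present) and k may not
#' exceed `k_max` (three, matching the cap on targetable habitats).
#'
#' @param labels 3D integer array.
#' @param spacing voxel spacing in mm, used for the per-habitat volumes.
#' @param k_max maximum admissible habitat count.
#' @return Object of class `habitat_map` with fields `labels`, `k`,
#'   `volumes_cm3` (named by label).
#' @export
habitat_map <- function(labels, spacing, k_max = 3L) {
  labels <- array(as.integer(labels), dim = dim(labels))
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  if (any(labels < 0L))
    stop("labels must be non-negative")
  k <- max(labels)
  if (k == 0L)
    stop("empty habitat map")
  present <- sort(unique(labels[labels > 0L]))
  if (!identical(present, seq_len(k)))
    stop("non-contiguous labels")
  if (k > k_max)
    stop(sprintf("habitat count %d exceeds k_max = %d", k, k_max))
  vox_cm3 <- prod(as.numeric(spacing)) / 1000
  volumes <- vapply(seq_len(k), function(l) sum(labels == l) * vox_cm3,
                    numeric(1))
  names(volumes) <- seq_len(k)
  structure(list(labels = labels, k = k, volumes_cm3 = volumes,
                 spacing = as.numeric(spacing)),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  cat(sprintf("<habitat_map> k = %d habitats over %s grid\n", x$k,
              paste(dim(x$labels), collapse = " x ")))
  for (l in seq_len(x$k))
    cat(sprintf("  habitat %d: %.2f cm^3\n", l, x$volumes_cm3[[l]]))
  invisible(x)
}
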