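# Volume and mask I/O. NIfTI via RNifti; DICOM via the codec in dicom.R.
# Patient coordinates are LPS throughout; NIfTI xforms (RAS) are converted
# on read/write by negating the first two axes.

ras_lps <- diag(c(-1, -1, 1))

# plain numeric array from a niftiImage (drops RNifti attributes)
nifti_array <- function(img) {
  array(as.vector(img), dim = dim(img))
}

volume_affine_lps <- function(volume) {
  cbind(volume$orientation %*% diag(volume$spacing), volume$origin)
}

#' Write an image volume (or mask) to NIfTI-1
#'
#' @param volume an [image_volume()], [voi_mask()] (needs `reference` for
#'   geometry) or 3D array.
#' @param path output file (.nii or .nii.gz).
#' @param reference an [image_volume()] supplying geometry when `volume`
#'   has none.
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(volume, path, reference = NULL) {
  if (inherits(volume, "voi_mask")) {
    geom <- reference
    vox <- array(as.integer(volume$voxels), dim = dim(volume$voxels))
  } else if (inherits(volume, "habitat_map")) {
    geom <- reference
    vox <- volume$labels
  } else if (inherits(volume, "image_volume")) {
    geom <- volume
    vox <- volume$voxels
  } else {
    geom <- reference
    vox <- as.array(volume)
  }
  if (is.null(geom))
    geom <- image_volume(array(0, dim(vox)[1:3]), spacing = c(1, 1, 1))
  aff <- ras_lps %*% volume_affine_lps(geom)  # LPS -> RAS for NIfTI
  img <- RNifti::asNifti(vox)
  full <- rbind(cbind(aff[, 1:3], aff[, 4]), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(full, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- nifti_array(img)
  if (length(dim(vox)) == 4L && dim(vox)[4] == 1L)
    vox <- array(vox, dim = dim(vox)[1:3])
  if (length(dim(vox)) != 3L)
    stop("expected a 3D NIfTI volume")
  aff <- RNifti::xform(img)
  aff <- ras_lps %*% aff[1:3, , drop = FALSE]  # back to LPS
  dircos <- aff[, 1:3]
  spacing <- sqrt(colSums(dircos^2))
  if (any(spacing <= 0)) stop("invalid geometry: non-positive spacing")
  orientation <- sweep(dircos, 2, spacing, "/")
  if (det(orientation) < 0) {
    # flip the slice axis to keep a right-handed direction matrix
    orientation[, 3] <- -orientation[, 3]
    vox <- vox[, , rev(seq_len(dim(vox)[3])), drop = FALSE]
    origin <- aff[, 4] + dircos[, 3] * (dim(vox)[3] - 1)
  } else {
    origin <- aff[, 4]
  }
  image_volume(vox, spacing = spacing, origin = origin,
               orientation = orientation)
}

#' Read a CT volume from a DICOM series directory or a NIfTI file
#'
#' DICOM slices are sorted by their position along the slice normal, so the
#' on-disk file order does not matter. A directory containing more than one
#' series UID is rejected.
#'
#' @param path directory of DICOM files, a single .nii/.nii.gz file, or a
#'   single .dcm file.
#' @return An [image_volume()] in LPS patient coordinates.
#' @export
read_ct_series <- function(path) {
  if (dir.exists(path))
    return(read_ct_dicom_dir(path))
  if (!file.exists(path))
    stop(sprintf("no such file or directory: %s", path))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    return(read_nifti_volume(path))
  if (grepl("\\.dcm$", path, ignore.case = TRUE))
    return(read_ct_dicom_dir(dirname(path)))
  stop("unrecognised CT input (expect DICOM directory or NIfTI file)")
}

#' Read a VOI mask congruent with a reference volume
#'
#' Accepts NIfTI label/mask images or DICOM segmentation files; any nonzero
#' voxel becomes foreground.
#'
#' @param path mask file.
#' @param reference the [image_volume()] the mask belongs to.
#' @return A [voi_mask()].
#' @export
read_mask <- function(path, reference) {
  if (!inherits(reference, "image_volume"))
    stop("reference must be an image_volume")
  if (grepl("\\.dcm$", path, ignore.case = TRUE)) {
    m <- read_habitat_dicom(path)
    vox <- m$labels
  } else {
    vox <- nifti_array(RNifti::readNifti(path))
    if (length(dim(vox)) == 4L && dim(vox)[4] == 1L)
      vox <- array(vox, dim = dim(vox)[1:3])
  }
  if (!identical(dim(vox), dim(reference$voxels)))
    stop("mask/volume geometry mismatch")
  voi_mask(vox, reference)
}

# ---- omental fat sub-segmentation ------------------------------------------

# binary opening with a 3x3x1 (in-plane) structuring element
open_3x3x1 <- function(m) {
  er <- m
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    er <- er & shift_array2d(m, dx, dy, fill = FALSE)
  }
  di <- er
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    di <- di | shift_array2d(er, dx, dy, fill = FALSE)
  }
  di
}

# shift a 3D array in-plane by (dx, dy) voxels, padding with `fill`
shift_array2d <- function(m, dx, dy, fill = FALSE) {
  d <- dim(m)
  out <- array(fill, d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2])
  src_x <- xs - dx; src_y <- ys - dy
  okx <- src_x >= 1 & src_x <= d[1]
  oky <- src_y >= 1 & src_y <= d[2]
  out[xs[okx], ys[oky], ] <- m[src_x[okx], src_y[oky], , drop = FALSE]
  out
}

#' Restrict an omental VOI to solid (non-fat) tissue
#'
#' Omental deposits contain interspersed fat which should not enter texture
#' analysis. Voxels at or below `fat_hu_max` are removed, the result is
#' cleaned by a morphological opening with a 3x3x1 structuring element, and
#' connected components smaller than `min_component_cm3` are dropped.
#' Pelvic lesions do not contain interspersed fat and do not need this step.
#'
#' @param volume an [image_volume()].
#' @param mask the [voi_mask()] to restrict.
#' @param fat_hu_max HU threshold; voxels with HU <= this are treated as fat
#'   (default -30; fat is roughly -190..-30 HU).
#' @param min_component_cm3 connected components below this size are removed.
#' @return A [voi_mask()], always a subset of `mask`.
#' @export
sub_segment_solid <- function(volume, mask, fat_hu_max = -30,
                              min_component_cm3 = 0.1) {
  if (!inherits(volume, "image_volume")) stop("volume must be an image_volume")
  if (!inherits(mask, "voi_mask")) stop("mask must be a voi_mask")
  if (!identical(dim(mask$voxels), dim(volume$voxels)))
    stop("mask/volume geometry mismatch")
  solid <- mask$voxels & (volume$voxels > fat_hu_max)
  solid <- open_3x3x1(solid)
  if (any(solid)) {
    lab <- cpp_label_components(array(as.integer(solid), dim(solid)))
    vox_cm3 <- prod(volume$spacing) / 1000
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes * vox_cm3 >= min_component_cm3)
    solid <- array(lab %in% keep & lab > 0L, dim(solid))
  }
  if (!any(solid))
    stop("no solid tissue in VOI")
  voi_mask(solid, volume)
}
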