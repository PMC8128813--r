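# US frame geometry, CT-silhouette reslicing, and Dice-based fusion
# accuracy.

#' 2D ultrasound frame with patient-space pose
#'
#' @param pixels 2D numeric matrix; `pixels[r, c]` is row r, column c.
#' @param spacing in-plane pixel spacing (row, column) in mm.
#' @param origin patient-space position of pixel (1,1) in mm.
#' @param dir_row,dir_col unit direction vectors of increasing row /
#'   column index; must be orthonormal.
#' @return A `us_frame`.
#' @export
us_frame <- function(pixels, spacing, origin, dir_row, dir_col) {
  pixels <- as.matrix(pixels)
  spacing <- as.numeric(spacing)
  dir_row <- as.numeric(dir_row); dir_col <- as.numeric(dir_col)
  if (length(spacing) != 2L || any(spacing <= 0))
    stop("spacing must be two positive numbers (mm)")
  if (abs(sum(dir_row^2) - 1) > 1e-8 || abs(sum(dir_col^2) - 1) > 1e-8 ||
      abs(sum(dir_row * dir_col)) > 1e-8)
    stop("frame direction vectors must be orthonormal")
  structure(list(pixels = pixels, spacing = spacing,
                 origin = as.numeric(origin),
                 dir_row = dir_row, dir_col = dir_col),
            class = "us_frame")
}

# patient-space positions of all frame pixels (nr*nc x 3, column-major)
frame_pixel_positions <- function(frame) {
  nr <- nrow(frame$pixels); nc <- ncol(frame$pixels)
  r <- rep(seq_len(nr), times = nc) - 1
  c <- rep(seq_len(nc), each = nr) - 1
  outer(r, frame$dir_row) * frame$spacing[1] +
    outer(c, frame$dir_col) * frame$spacing[2] +
    rep(frame$origin, each = nr * nc)
}

#' Reslice a CT VOI mask into the US image plane
#'
#' Maps every US pixel position through the inverse of the CT->US transform
#' into CT patient space and samples the VOI mask by nearest neighbour
#' (keeping the silhouette binary). This reproduces offline the geometric
#' core of live CT/US fusion: the CT tumour silhouette as seen in the US
#' plane.
#'
#' @param mask a [voi_mask()].
#' @param ct the [image_volume()] the mask belongs to.
#' @param frame a [us_frame()].
#' @param transform the CT -> US [rigid_transform()].
#' @return Logical matrix with the frame's shape.
#' @export
reslice_mask <- function(mask, ct, frame, transform) {
  if (!identical(dim(mask$voxels), dim(ct$voxels)))
    stop("mask/volume geometry mismatch")
  pos_us <- frame_pixel_positions(frame)
  pos_ct <- apply_rigid(invert_rigid(transform), pos_us)
  idx <- round(patient_to_voxel(ct, pos_ct))
  d <- dim(ct$voxels)
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
    idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  if (!any(inside))
    stop("no overlap between frame and CT")
  out <- logical(nrow(idx))
  lin <- (idx[inside, 3] - 1) * d[1] * d[2] + (idx[inside, 2] - 1) * d[1] +
    idx[inside, 1]
  out[inside] <- mask$voxels[lin]
  matrix(out, nrow(frame$pixels), ncol(frame$pixels))
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`. When both masks are empty the overlap is
#' undefined and `NA` is returned (mirroring a tumour whose edge is not
#' visible on B-mode US); an undefined DSC is excluded from summaries
#' rather than counted as zero.
#'
#' @param a,b binary masks (arrays/matrices of equal shape).
#' @return DSC in `[0, 1]`, or `NA` if both masks are empty.
#' @export
dice <- function(a, b) {
  a <- as.array(a) != 0; b <- as.array(b) != 0
  if (!identical(dim(a), dim(b)))
    stop("masks must have identical shape")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(NA_real_)
  2 * sum(a & b) / (sa + sb)
}

#' Axial slice with the largest tumour area
#'
#' @param mask a [voi_mask()].
#' @return 1-based slice index; ties break toward the lowest index
#'   (inferior-most slice).
#' @export
select_largest_slice <- function(mask) {
  vox <- if (inherits(mask, "voi_mask")) mask$voxels else as.array(mask) != 0
  counts <- apply(vox, 3, sum)
  if (sum(counts) == 0) stop("empty VOI")
  which.max(counts)
}

#' Median / min / max summary of defined values
#'
#' Uses the sample median (mean of the middle two for even n); `NA` entries
#' (undefined measurements) are excluded.
#'
#' @param values numeric vector, possibly containing `NA`.
#' @return List with `median`, `min`, `max`, `n` (defined values),
#'   `n_total`.
#' @export
summarize_values <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0)
    stop("no defined values to summarise")
  list(median = median(v), min = min(v), max = max(v),
       n = length(v), n_total = length(values))
}

#' Per-lesion DSC report with summary statistics
#'
#' @param lesion_id character/integer ids.
#' @param site per-lesion site, e.g. "pelvis"/"omentum".
#' @param dsc per-lesion DSC, `NA` where undefined.
#' @return `dsc_report` with the per-lesion table and the median/min/max
#'   over the defined values.
#' @export
dsc_report <- function(lesion_id, site, dsc) {
  per <- data.frame(lesion_id = lesion_id, site = site, dsc = dsc,
                    stringsAsFactors = FALSE)
  s <- summarize_values(dsc)
  structure(list(per_lesion = per, median = s$median, min = s$min,
                 max = s$max, n_defined = s$n),
            class = "dsc_report")
}

#' @export
print.dsc_report <- function(x, ...) {
  cat(sprintf("<dsc_report> median DSC %.2f (range %.2f to %.2f), %d/%d defined\n",
              x$median, x$max, x$min, x$n_defined, nrow(x$per_lesion)))
  invisible(x)
}

#' Write a US frame to disk (image + JSON pose sidecar)
#'
#' @param frame a [us_frame()].
#' @param image_path .nii/.nii.gz for the pixel data.
#' @param pose_path .json sidecar (origin, direction vectors, spacing).
#' @return Invisibly, `pose_path`.
#' @export
write_us_frame <- function(frame, image_path, pose_path) {
  img <- RNifti::asNifti(array(frame$pixels, c(dim(frame$pixels), 1L)))
  RNifti::writeNifti(img, image_path)
  jsonlite::write_json(list(origin = frame$origin, dir_row = frame$dir_row,
                            dir_col = frame$dir_col,
                            spacing = frame$spacing,
                            image = basename(image_path)),
                       pose_path, digits = NA, auto_unbox = TRUE)
  invisible(pose_path)
}

#' Read a US frame from an image + JSON pose sidecar
#'
#' @param pose_path .json written by [write_us_frame()].
#' @param image_path image file; defaults to the sidecar's `image` entry
#'   resolved next to the sidecar. PNG (via the png package) and NIfTI are
#'   supported.
#' @return A [us_frame()].
#' @export
read_us_frame <- function(pose_path, image_path = NULL) {
  pose <- jsonlite::read_json(pose_path, simplifyVector = TRUE)
  if (is.null(image_path))
    image_path <- file.path(dirname(pose_path), pose$image)
  if (grepl("\\.png$", image_path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required to read PNG frames")
    px <- png::readPNG(image_path)
    if (length(dim(px)) == 3L) px <- px[, , 1]
  } else {
    px <- RNifti::readNifti(image_path)
    px <- array(as.vector(px), dim(px))
    if (length(dim(px)) == 3L) px <- px[, , 1]
  }
  us_frame(px, spacing = pose$spacing, origin = pose$origin,
           dir_row = pose$dir_row, dir_col = pose$dir_col)
}
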