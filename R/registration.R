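# Landmark-based rigid CT -> US registration.
#
# The clinical protocol aligns the axial plane first (US acquired strictly
# axially), then registers 1-3 fusion points (pubic symphysis, umbilicus,
# anterior superior iliac spine). The fit hierarchy mirrors that: one pair
# gives a pure translation, two pairs add a rotation about the craniocaudal
# (z) axis, three non-collinear pairs give the full least-squares rigid fit.

#' Paired CT/US fiducial landmarks
#'
#' @param names character vector of landmark names (unique), conventionally
#'   from pubic_symphysis, umbilicus, asis, custom.
#' @param ct numeric matrix (n x 3) of CT patient-space positions in mm.
#' @param us numeric matrix (n x 3) of US patient-space positions in mm.
#' @return A `landmark_set` with 1-3 pairs.
#' @export
landmark_set <- function(names, ct, us) {
  ct <- matrix(as.numeric(ct), ncol = 3L)
  us <- matrix(as.numeric(us), ncol = 3L)
  n <- nrow(ct)
  if (n < 1L || n > 3L)
    stop("between one and three landmark pairs are supported")
  if (nrow(us) != n || length(names) != n)
    stop("names, ct and us must all have the same number of entries")
  if (anyDuplicated(names))
    stop("duplicate landmark names")
  if (any(!is.finite(ct)) || any(!is.finite(us)))
    stop("landmark coordinates must be finite")
  structure(list(names = as.character(names), ct = ct, us = us),
            class = "landmark_set")
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 vector in mm.
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 || det(rotation) < 0)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Rotation about the craniocaudal (z) axis
#' @param theta angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta),  cos(theta), 0),
        c(0, 0, 1))
}

#' Apply a rigid transform to points
#' @param transform a [rigid_transform()].
#' @param pts n x 3 matrix (or length-3 vector) of mm coordinates.
#' @return Transformed points, same shape.
#' @export
apply_rigid <- function(transform, pts) {
  v <- is.null(dim(pts))
  pts <- matrix(as.numeric(pts), ncol = 3L)
  out <- t(transform$rotation %*% t(pts) + transform$translation)
  if (v) out[1, ] else out
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_rigid <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

# closed-form in-plane (z-axis) rotation + translation between paired sets
fit_z_rotation <- function(ct, us) {
  cc <- colMeans(ct); uc <- colMeans(us)
  a <- sweep(ct, 2, cc); b <- sweep(us, 2, uc)
  num <- sum(a[, 1] * b[, 2] - a[, 2] * b[, 1])
  den <- sum(a[, 1] * b[, 1] + a[, 2] * b[, 2])
  theta <- if (num == 0 && den == 0) 0 else atan2(num, den)
  R <- rotation_z(theta)
  rigid_transform(R, uc - as.numeric(R %*% cc))
}

#' Fit a rigid CT -> US transform from 1-3 landmark pairs
#'
#' One pair: pure translation. Two pairs: centroid translation plus the
#' rotation about the z axis minimising the residual (the axial orientation
#' is assumed pre-aligned). Three pairs: full least-squares orthogonal
#' Procrustes fit (SVD with determinant correction); a collinear triple
#' falls back to the z-rotation solution with a warning.
#'
#' @param landmarks a [landmark_set()].
#' @return A [rigid_transform()] mapping CT patient space to US patient
#'   space.
#' @export
fit_rigid <- function(landmarks) {
  if (!inherits(landmarks, "landmark_set"))
    stop("landmarks must be a landmark_set")
  ct <- landmarks$ct; us <- landmarks$us
  n <- nrow(ct)
  if (n == 1L)
    return(rigid_transform(diag(3), us[1, ] - ct[1, ]))
  if (n == 2L)
    return(fit_z_rotation(ct, us))
  cc <- colMeans(ct); uc <- colMeans(us)
  a <- sweep(ct, 2, cc); b <- sweep(us, 2, uc)
  sv <- svd(crossprod(a, b))  # H = A^T B
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    warning("collinear landmarks; falling back to in-plane rotation fit")
    return(fit_z_rotation(ct, us))
  }
  dsign <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  rigid_transform(R, uc - as.numeric(R %*% cc))
}

#' Fiducial registration error
#'
#' Root-mean-square distance between the transformed CT landmarks and the
#' US landmarks — the standard residual of a landmark registration,
#' reported in mm.
#'
#' @param landmarks a [landmark_set()].
#' @param transform the fitted [rigid_transform()].
#' @return FRE in mm.
#' @export
fre <- function(landmarks, transform) {
  pred <- apply_rigid(transform, landmarks$ct)
  sqrt(mean(rowSums((pred - landmarks$us)^2)))
}

#' Read landmark pairs from CSV
#'
#' Columns: name, ct_x, ct_y, ct_z, us_x, us_y, us_z (mm, LPS).
#'
#' @param path CSV file.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "ct_x", "ct_y", "ct_z", "us_x", "us_y", "us_z")
  if (!all(need %in% names(df)))
    stop(sprintf("landmark CSV must have columns: %s",
                 paste(need, collapse = ", ")))
  landmark_set(df$name, as.matrix(df[, c("ct_x", "ct_y", "ct_z")]),
               as.matrix(df[, c("us_x", "us_y", "us_z")]))
}

#' Write landmark pairs to CSV
#' @param landmarks a [landmark_set()].
#' @param path output CSV.
#' @return Invisibly, `path`.
#' @export
write_landmarks <- function(landmarks, path) {
  df <- data.frame(name = landmarks$names,
                   ct_x = landmarks$ct[, 1], ct_y = landmarks$ct[, 2],
                   ct_z = landmarks$ct[, 3],
                   us_x = landmarks$us[, 1], us_y = landmarks$us[, 2],
                   us_z = landmarks$us[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
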