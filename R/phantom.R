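# Seeded synthetic phantoms: CT-like lesions with ground-truth habitats and
# a simulated US frame related to the CT by a known rigid transform.
#
# Habitats differ in both mean HU and noise correlation length (texture),
# so that clustering cannot succeed on HU alone and the texture pathway is
# genuinely exercised. Omental lesions additionally scatter fat blobs
# (about -100 HU) through the VOI, emulating interspersed omental fat;
# pelvic lesions contain none.

#' Specification of a synthetic CT lesion phantom
#'
#' @param dim grid dimensions (nx, ny, nz).
#' @param spacing voxel spacing (mm); the default 1 x 1 x 5 mm matches a
#'   typical portal-venous abdominal CT reconstruction (sub-millimetre
#'   in-plane pixels, thick slices).
#' @param semi_axes_mm lesion ellipsoid semi-axes in mm.
#' @param centre_mm ellipsoid centre (defaults to the grid centre).
#' @param site `"pelvis"` (no interspersed fat) or `"omentum"`.
#' @param true_k number of ground-truth habitats (1-3), laid out as equal
#'   angular wedges.
#' @param habitat_hu per-habitat mean HU (soft-tissue range); defaults to
#'   20/60/100 HU, i.e. 40 HU between neighbours.
#' @param habitat_noise_sd per-habitat noise standard deviation (HU);
#'   defaults 26/10/16 HU differ strongly between habitats so that local
#'   grey-level spread (the dominant small-window texture signal) is
#'   habitat-specific.
#' @param habitat_smoothing_mm per-habitat noise correlation length (mm);
#'   defaults 0.4/1.2/3.6 differ by 3x between habitats.
#' @param fat_fraction fraction of VOI voxels replaced by fat blobs
#'   (omentum only; forced to 0 for pelvis).
#' @param background_hu surrounding soft tissue mean (default 40 HU).
#' @param us_transform ground-truth rigid CT -> US transform.
#' @param landmark_jitter_mm standard deviation of Gaussian jitter applied
#'   to the US-side landmarks.
#' @param seed random seed; all phantom content is bit-reproducible.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(72L, 72L, 14L), spacing = c(1, 1, 5),
                         semi_axes_mm = c(30, 30, 15), centre_mm = NULL,
                         site = c("pelvis", "omentum"), true_k = 3L,
                         habitat_hu = NULL, habitat_noise_sd = NULL,
                         habitat_smoothing_mm = NULL, fat_fraction = NULL,
                         background_hu = 40,
                         us_transform = rigid_transform(
                           rotation_z(10 * pi / 180), c(8, -6, 4)),
                         landmark_jitter_mm = 0, seed = 1L) {
  site <- match.arg(site)
  true_k <- as.integer(true_k)
  if (true_k < 1L || true_k > 3L)
    stop("true_k must be 1, 2 or 3")
  if (is.null(centre_mm)) centre_mm <- (dim - 1) * spacing / 2
  if (is.null(habitat_hu)) habitat_hu <- c(20, 60, 100)[seq_len(true_k)]
  if (is.null(habitat_noise_sd)) habitat_noise_sd <- c(26, 10, 16)[seq_len(true_k)]
  if (is.null(habitat_smoothing_mm))
    habitat_smoothing_mm <- c(0.4, 1.2, 3.6)[seq_len(true_k)]
  if (is.null(fat_fraction))
    fat_fraction <- if (site == "omentum") 0.3 else 0
  if (site == "pelvis" && fat_fraction > 0)
    stop("pelvic lesions do not contain interspersed fat (fat_fraction must be 0)")
  if (fat_fraction < 0 || fat_fraction >= 1)
    stop("fat_fraction must be in [0, 1)")
  stopifnot(length(habitat_hu) == true_k,
            length(habitat_noise_sd) == true_k,
            length(habitat_smoothing_mm) == true_k,
            landmark_jitter_mm >= 0)
  extent <- (dim - 1) * spacing
  if (any(centre_mm - semi_axes_mm < 0) || any(centre_mm + semi_axes_mm > extent))
    stop("lesion semi-axes do not fit inside the grid")
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 semi_axes_mm = as.numeric(semi_axes_mm),
                 centre_mm = as.numeric(centre_mm), site = site,
                 true_k = true_k, habitat_hu = habitat_hu,
                 habitat_noise_sd = habitat_noise_sd,
                 habitat_smoothing_mm = habitat_smoothing_mm,
                 fat_fraction = fat_fraction, background_hu = background_hu,
                 us_transform = us_transform,
                 landmark_jitter_mm = landmark_jitter_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# weight-normalised separable Gaussian smoothing of each axial slice
smooth_slices <- function(arr, sigma_px) {
  if (sigma_px < 0.3) return(arr)
  r <- ceiling(3 * sigma_px)
  band <- function(n) {
    K <- outer(seq_len(n), seq_len(n), function(i, j)
      exp(-((i - j)^2) / (2 * sigma_px^2)) * (abs(i - j) <= r))
    K
  }
  d <- dim(arr)
  Kx <- band(d[1]); Ky <- band(d[2])
  ones <- matrix(1, d[1], d[2])
  norm <- Kx %*% ones %*% t(Ky)
  for (k in seq_len(d[3]))
    arr[, , k] <- (Kx %*% arr[, , k] %*% t(Ky)) / norm
  arr
}

#' Generate a synthetic CT lesion with ground-truth habitats
#'
#' Builds an ellipsoidal lesion partitioned into `true_k` angular wedges;
#' each wedge is filled with its mean HU plus Gaussian noise smoothed at
#' its habitat-specific correlation length (distinct texture, not just a
#' distinct mean). The surrounding background is soft tissue around 40 HU
#' with fine noise. Omental phantoms scatter fat blobs (about -100 HU)
#' through the VOI until the requested fat fraction is reached.
#'
#' @param spec a [phantom_spec()].
#' @return List with `volume` ([image_volume()]), `mask` ([voi_mask()]),
#'   `truth` (ground-truth [habitat_map()]), `fat` (logical array of fat
#'   voxels) and `spec`.
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  d <- spec$dim; sp <- spec$spacing
  x <- (seq_len(d[1]) - 1) * sp[1]
  y <- (seq_len(d[2]) - 1) * sp[2]
  z <- (seq_len(d[3]) - 1) * sp[3]
  cx <- spec$centre_mm
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  inside <- ((X - cx[1]) / spec$semi_axes_mm[1])^2 +
    ((Y - cx[2]) / spec$semi_axes_mm[2])^2 +
    ((Z - cx[3]) / spec$semi_axes_mm[3])^2 <= 1
  if (!any(inside)) stop("degenerate geometry: empty lesion")
  k <- spec$true_k
  ang <- atan2(Y - cx[2], X - cx[1])  # (-pi, pi]
  wedge <- pmin(floor((ang + pi) / (2 * pi) * k) + 1L, k)
  labels <- array(0L, d)
  labels[inside] <- wedge[inside]
  vox <- with_seed(spec$seed, {
    v <- spec$background_hu + array(rnorm(prod(d), sd = 5), d)
    for (h in seq_len(k)) {
      field <- array(rnorm(prod(d)), d)
      field <- smooth_slices(field, spec$habitat_smoothing_mm[h] / sp[1])
      field <- field * (spec$habitat_noise_sd[h] / sd(field))
      sel <- labels == h
      v[sel] <- spec$habitat_hu[h] + field[sel]
    }
    v
  })
  fat <- array(FALSE, d)
  if (spec$fat_fraction > 0) {
    voi_idx <- which(inside)
    target <- round(spec$fat_fraction * length(voi_idx))
    fat_hu <- with_seed(spec$seed + 1L, {
      guard <- 0
      while (sum(fat) < target && guard < 10000) {
        centre_i <- arrayInd(sample(voi_idx, 1), d)
        r_mm <- runif(1, 1.5, 4)
        blob <- (X - x[centre_i[1]])^2 + (Y - y[centre_i[2]])^2 +
          ((Z - z[centre_i[3]]) / 2)^2 <= r_mm^2
        fat <- fat | (blob & inside)
        guard <- guard + 1
      }
      -100 + rnorm(sum(fat), sd = 4)
    })
    vox[fat] <- fat_hu
  }
  volume <- image_volume(vox, spacing = sp)
  mask <- voi_mask(inside, volume)
  truth <- habitat_map(labels, spacing = sp, k_max = k)
  list(volume = volume, mask = mask, truth = truth, fat = fat, spec = spec)
}

#' Simulate a US frame, its ground-truth silhouette, and fusion landmarks
#'
#' Takes the largest-area axial plane of the lesion, maps it through the
#' phantom's ground-truth rigid transform to define the US frame pose,
#' renders the lesion silhouette in that plane as the US ground truth, adds
#' multiplicative speckle-like noise to the image channel, and emits three
#' landmark pairs (pubic symphysis, umbilicus and anterior superior iliac
#' spine analogues) with Gaussian jitter on the US side.
#'
#' @param phantom result of [make_phantom()].
#' @param jitter_mm landmark jitter standard deviation; defaults to the
#'   spec's `landmark_jitter_mm`.
#' @param seed seed for speckle and jitter; defaults to the spec seed.
#' @return List with `frame` ([us_frame()]), `truth_mask` (logical matrix),
#'   `landmarks` ([landmark_set()]) and `slice_index`.
#' @export
make_us_frame <- function(phantom, jitter_mm = NULL, seed = NULL) {
  spec <- phantom$spec
  if (is.null(jitter_mm)) jitter_mm <- spec$landmark_jitter_mm
  if (is.null(seed)) seed <- spec$seed
  z0 <- select_largest_slice(phantom$mask)
  vol <- phantom$volume
  T_us <- spec$us_transform
  origin_us <- apply_rigid(T_us, voxel_to_patient(vol, c(1, 1, z0)))
  dir_row <- as.numeric(T_us$rotation %*% vol$orientation[, 1])
  dir_col <- as.numeric(T_us$rotation %*% vol$orientation[, 2])
  hu <- vol$voxels[, , z0]
  img <- (hu - min(hu)) / max(max(hu) - min(hu), 1e-9)
  ct_pts <- rbind(spec$centre_mm + c(0, 70, -40),
                  spec$centre_mm + c(0, -60, -10),
                  spec$centre_mm + c(60, 40, -25))
  out <- with_seed(seed + 77L, {
    speckle <- exp(matrix(rnorm(length(img), sd = 0.25), nrow(img)))
    us_pts <- apply_rigid(T_us, ct_pts) +
      matrix(rnorm(9, sd = jitter_mm), 3, 3)
    list(img = pmin(img * speckle, 1), us_pts = us_pts)
  })
  frame <- us_frame(out$img, spacing = vol$spacing[1:2],
                    origin = origin_us, dir_row = dir_row,
                    dir_col = dir_col)
  lm <- landmark_set(c("pubic_symphysis", "umbilicus", "asis"),
                     ct = ct_pts, us = out$us_pts)
  list(frame = frame, truth_mask = phantom$mask$voxels[, , z0],
       landmarks = lm, slice_index = z0)
}
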