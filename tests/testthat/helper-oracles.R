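# Shared fixtures and independent oracles for the suite.

# a small lesion phantom that keeps texture/clustering tests fast
small_phantom <- function(seed = 1, true_k = 3, site = "pelvis", ...) {
  make_phantom(phantom_spec(dim = c(36L, 36L, 7L), spacing = c(1, 1, 5),
                            semi_axes_mm = c(14, 14, 10), true_k = true_k,
                            site = site, seed = seed, ...))
}

# naive per-voxel texture oracle: composes the reference glcm() and
# haralick_features() functions voxel by voxel, independently of the
# compiled map engine
naive_texture_stack <- function(volume, mask, config = texture_config()) {
  lev <- quantize_hu(volume, mask, config$n_levels,
                     clamp_outside = identical(config$window_masking, "volume"))
  d <- dim(volume$voxels)
  hw <- config$window %/% 2
  idx <- which(mask$voxels)
  feats <- matrix(NA_real_, length(idx), 9)
  valid <- logical(length(idx))
  for (t in seq_along(idx)) {
    ijk <- arrayInd(idx[t], d)
    i0 <- max(1, ijk[1] - hw); i1 <- min(d[1], ijk[1] + hw)
    j0 <- max(1, ijk[2] - hw); j1 <- min(d[2], ijk[2] + hw)
    win <- lev[i0:i1, j0:j1, ijk[3]]
    p <- tryCatch(glcm(win, config$offsets, config$n_levels),
                  error = function(e) NULL)
    if (!is.null(p)) {
      feats[t, ] <- haralick_features(p)
      valid[t] <- TRUE
    }
  }
  list(features = feats, valid = valid, idx = idx)
}

# brute-force reference for sub_segment_solid (threshold + 3x3x1 opening),
# written as plain loops
naive_solid_mask <- function(volume, mask, fat_hu_max) {
  d <- dim(volume$voxels)
  thr <- mask$voxels & (volume$voxels > fat_hu_max)
  er <- array(FALSE, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!thr[i, j, k]) next
    ok <- TRUE
    for (dj in -1:1) for (di in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || !thr[ii, jj, k])
        ok <- FALSE
    }
    er[i, j, k] <- ok
  }
  di <- array(FALSE, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    hit <- FALSE
    for (dj in -1:1) for (ddi in -1:1) {
      ii <- i + ddi; jj <- j + dj
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && er[ii, jj, k])
        hit <- TRUE
    }
    di[i, j, k] <- hit
  }
  di
}

expect_same_labels <- function(a, b) {
  expect_identical(array(as.integer(a), dim(a)), array(as.integer(b), dim(b)))
}
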