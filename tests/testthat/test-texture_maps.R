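# Quantisation, GLCM, Haralick features, and the sliding-window map engine.

test_that("quantisation maps a full-range ramp to consecutive levels", {
  vox <- array(rep(0:31, each = 4), c(4, 8, 4))
  vol <- image_volume(vox, c(1, 1, 1))
  m <- array(TRUE, dim(vox))
  lev <- quantize_hu(vol, m, 32)
  expect_identical(lev, array(as.integer(vox) + 1L, dim(vox)))
})

test_that("constant VOIs quantise to level 1 and outside voxels to 0", {
  vox <- array(7, c(5, 5, 2))
  m <- array(FALSE, c(5, 5, 2)); m[2:4, 2:4, ] <- TRUE
  lev <- quantize_hu(vox, m, 32)
  expect_true(all(lev[m] == 1L))
  expect_true(all(lev[!m] == 0L))
})

test_that("quantisation is invariant under positive affine HU rescaling", {
  set.seed(5)
  vox <- array(rnorm(6 * 6 * 3, 50, 20), c(6, 6, 3))
  m <- array(runif(length(vox)) < 0.8, dim(vox))
  expect_identical(quantize_hu(vox, m, 16),
                   quantize_hu(2.5 * vox + 100, m, 16))
})

test_that("GLCM of a constant window concentrates at (1,1)", {
  p <- glcm(matrix(1L, 5, 5), n_levels = 32)
  expect_equal(p[1, 1], 1)
  expect_equal(sum(p), 1)
})

test_that("GLCM of the 2x2 checker column pattern splits evenly", {
  win <- rbind(c(1L, 2L), c(1L, 2L))
  p <- glcm(win, offsets = matrix(c(0L, 1L), 1), n_levels = 2)
  expect_equal(p[1, 2], 0.5)
  expect_equal(p[2, 1], 0.5)
  expect_equal(p[1, 1] + p[2, 2], 0)
})

test_that("GLCMs are symmetric probability matrices for random windows", {
  set.seed(9)
  for (i in 1:10) {
    win <- matrix(sample.int(8, 25, replace = TRUE), 5, 5)
    p <- glcm(win, n_levels = 8)
    expect_equal(sum(p), 1)
    expect_equal(p, t(p))
  }
  expect_error(glcm(matrix(0L, 3, 3), n_levels = 4), "degenerate window")
})

test_that("Haralick features match closed forms on degenerate GLCMs", {
  p1 <- matrix(0, 4, 4); p1[1, 1] <- 1
  f <- haralick_features(p1)
  expect_equal(unname(f["energy"]), 1)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["idmn"]), 1)
  expect_equal(unname(f["sum_average"]), 2)
  expect_equal(unname(f["cluster_shade"]), 0)
  expect_equal(unname(f["correlation"]), 0)  # zero marginal sd convention
})

test_that("Haralick features match hand-computed sums on the uniform 2x2 GLCM", {
  p <- matrix(0.25, 2, 2)
  f <- haralick_features(p)
  expect_equal(unname(f["energy"]), 0.25)
  expect_equal(unname(f["entropy"]), 2)
  expect_equal(unname(f["contrast"]), 0.5)
  expect_equal(unname(f["sum_average"]), 3)
  expect_equal(unname(f["idmn"]), 0.9)          # 0.5 + 2 * 0.25/1.25
  expect_equal(unname(f["correlation"]), 0)     # independent marginals
  expect_equal(unname(f["cluster_prominence"]), 0.5)
  expect_error(haralick_features(matrix(0.3, 2, 2)), "invalid GLCM")
})

test_that("symmetric GLCMs have equal row and column marginals", {
  set.seed(31)
  for (i in 1:5) {
    win <- matrix(sample.int(6, 36, replace = TRUE), 6, 6)
    p <- glcm(win, n_levels = 6)
    expect_equal(rowSums(p), colSums(p))
  }
})

test_that("constant lesions give energy 1, entropy 0, contrast 0 everywhere", {
  ph <- small_phantom(seed = 2, true_k = 1, habitat_noise_sd = 0,
                      habitat_hu = 60)
  vol <- ph$volume
  vol$voxels[] <- 60  # remove background noise too
  stack <- texture_map_stack(vol, ph$mask)
  expect_true(all(stack$valid))
  expect_true(all(stack$features[, "energy"] == 1))
  expect_true(all(stack$features[, "entropy"] == 0))
  expect_true(all(stack$features[, "contrast"] == 0))
})

test_that("the compiled map engine equals the per-voxel oracle exactly", {
  for (masking in c("volume", "voi")) {
    ph <- make_phantom(phantom_spec(dim = c(24L, 24L, 5L), spacing = c(1, 1, 5),
                                    semi_axes_mm = c(9, 9, 8), true_k = 2,
                                    seed = 13))
    cfg <- texture_config(window_masking = masking)
    stack <- texture_map_stack(ph$volume, ph$mask, cfg)
    oracle <- naive_texture_stack(ph$volume, ph$mask, cfg)
    expect_identical(stack$idx, oracle$idx)
    expect_identical(stack$valid, oracle$valid)
    expect_equal(unname(stack$features[oracle$valid, ]),
                 oracle$features[oracle$valid, ], tolerance = 1e-12)
  }
})

test_that("texture maps are invariant to affine HU rescaling of the lesion", {
  ph <- small_phantom(seed = 14, true_k = 2)
  s1 <- texture_map_stack(ph$volume, ph$mask)
  vol2 <- ph$volume
  vol2$voxels <- 3 * vol2$voxels + 250
  s2 <- texture_map_stack(vol2, ph$mask)
  expect_equal(s1$features, s2$features, tolerance = 1e-12)
})

test_that("texture maps shift with the lesion (translation equivariance)", {
  base <- phantom_spec(dim = c(30L, 30L, 5L), spacing = c(1, 1, 5),
                       semi_axes_mm = c(8, 8, 8), true_k = 1, seed = 15)
  ph <- make_phantom(base)
  shift <- c(4L, 3L, 0L)
  d <- dim(ph$volume$voxels)
  vox2 <- array(ph$volume$voxels[1, 1, 1], d)
  m2 <- array(FALSE, d)
  src <- list(1:(d[1] - shift[1]), 1:(d[2] - shift[2]), 1:d[3])
  dst <- list(src[[1]] + shift[1], src[[2]] + shift[2], src[[3]])
  vox2[dst[[1]], dst[[2]], dst[[3]]] <- ph$volume$voxels[src[[1]], src[[2]], src[[3]]]
  m2[dst[[1]], dst[[2]], dst[[3]]] <- ph$mask$voxels[src[[1]], src[[2]], src[[3]]]
  s1 <- texture_map_stack(ph$volume, ph$mask)
  s2 <- texture_map_stack(image_volume(vox2, ph$volume$spacing),
                          voi_mask(m2))
  expect_equal(s2$features, s1$features, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(texture_config(window = 4), "odd")
  expect_error(texture_config(n_levels = 1), "n_levels")
  ph <- small_phantom(seed = 16)
  empty <- ph$mask; empty$voxels[] <- FALSE
  expect_error(texture_map_stack(ph$volume, empty), "too small")
})
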