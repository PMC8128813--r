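# Landmark rigid registration, reslicing, Dice, and summary statistics.

test_that("identical landmark sets give the identity transform", {
  pts <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 5))
  lm <- landmark_set(c("pubic_symphysis", "umbilicus", "asis"), pts, pts)
  tf <- fit_rigid(lm)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tf$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fre(lm, tf), 0)
})

test_that("a single pair yields a pure translation", {
  lm <- landmark_set("pubic_symphysis", c(0, 0, 0), c(5, 5, 0))
  tf <- fit_rigid(lm)
  expect_equal(tf$rotation, diag(3))
  expect_equal(tf$translation, c(5, 5, 0))
})

test_that("three non-collinear pairs recover a known rigid transform", {
  set.seed(2)
  R <- rotation_z(30 * pi / 180)
  t <- c(10, -5, 2)
  truth <- rigid_transform(R, t)
  for (rep in 1:10) {
    ct <- matrix(runif(9, -100, 100), 3, 3)
    # reject nearly-collinear triples
    while (svd(scale(ct, scale = FALSE))$d[2] < 10) ct <- matrix(runif(9, -100, 100), 3, 3)
    us <- apply_rigid(truth, ct)
    tf <- fit_rigid(landmark_set(c("a", "b", "c"), ct, us))
    expect_lt(max(abs(apply_rigid(tf, ct) - us)), 1e-9)
    expect_lt(max(abs(tf$rotation - R)), 1e-9)
    expect_lt(max(abs(tf$translation - t)), 1e-9)
  }
})

test_that("general 3D rotations are also recovered from three pairs", {
  set.seed(7)
  ang <- runif(3, -0.5, 0.5)
  R <- rotation_z(ang[1]) %*%
    rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
          c(-sin(ang[2]), 0, cos(ang[2]))) %*%
    rbind(c(1, 0, 0), c(0, cos(ang[3]), -sin(ang[3])),
          c(0, sin(ang[3]), cos(ang[3])))
  truth <- rigid_transform(R, c(-3, 8, 12))
  ct <- rbind(c(0, 0, 0), c(50, 10, 0), c(5, 60, 20))
  us <- apply_rigid(truth, ct)
  tf <- fit_rigid(landmark_set(c("a", "b", "c"), ct, us))
  expect_lt(max(abs(tf$rotation - R)), 1e-9)
})

test_that("two pairs resolve an in-plane rotation about z", {
  R <- rotation_z(0.4)
  truth <- rigid_transform(R, c(3, -2, 7))
  ct <- rbind(c(0, 0, 0), c(40, 10, 0))
  us <- apply_rigid(truth, ct)
  tf <- fit_rigid(landmark_set(c("a", "b"), ct, us))
  expect_lt(max(abs(apply_rigid(tf, ct) - us)), 1e-9)
  expect_equal(tf$rotation[3, 3], 1)
})

test_that("collinear triples fall back to the in-plane fit with a warning", {
  ct <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0))
  us <- ct + rep(c(1, 2, 0), each = 3)
  expect_warning(tf <- fit_rigid(landmark_set(c("a", "b", "c"), ct, us)),
                 "collinear")
  expect_lt(fre(landmark_set(c("a", "b", "c"), ct, us), tf), 1e-9)
})

test_that("FRE is the RMS residual and is invariant under joint motion", {
  ct <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  us <- ct; us[1, ] <- us[1, ] + c(3, 0, 0)
  lm <- landmark_set(c("a", "b", "c"), ct, us)
  expect_equal(fre(lm, rigid_transform()), sqrt(3))
  mv <- rigid_transform(rotation_z(1.1), c(5, 6, 7))
  lm2 <- landmark_set(lm$names, apply_rigid(mv, ct), apply_rigid(mv, us))
  tf <- fit_rigid(lm); tf2 <- fit_rigid(lm2)
  expect_equal(fre(lm2, tf2), fre(lm, tf), tolerance = 1e-9)
})

test_that("landmark CSV round trip preserves the set", {
  lm <- landmark_set(c("pubic_symphysis", "umbilicus"),
                     rbind(c(1.5, 2, 3), c(4, 5, 6.25)),
                     rbind(c(7, 8, 9), c(10, 11.5, 12)))
  path <- tempfile(fileext = ".csv")
  write_landmarks(lm, path)
  back <- read_landmarks(path)
  expect_equal(back$ct, lm$ct)
  expect_equal(back$us, lm$us)
  expect_identical(back$names, lm$names)
})

test_that("dice matches closed forms and is symmetric and bounded", {
  a <- matrix(FALSE, 10, 10); a[1:5, 1:2] <- TRUE          # |A| = 10
  b <- matrix(FALSE, 10, 10); b[1:5, 1] <- TRUE; b[6:10, 2] <- TRUE  # overlap 5
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, a), 1)
  disj <- matrix(FALSE, 10, 10); disj[6:10, 5:6] <- TRUE
  expect_equal(dice(a, disj), 0)
  expect_true(is.na(dice(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3))))
  set.seed(8)
  for (i in 1:10) {
    x <- matrix(runif(64) < 0.4, 8, 8); y <- matrix(runif(64) < 0.4, 8, 8)
    expect_equal(dice(x, y), dice(y, x))
    dd <- dice(x, y)
    expect_true(is.na(dd) || (dd >= 0 && dd <= 1))
  }
  expect_error(dice(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "shape")
})

test_that("largest-slice selection follows counts with inferior tie-break", {
  m <- array(FALSE, c(6, 6, 4))
  m[1:3, 1, 1] <- TRUE          # 3
  m[1:5, 1:2, 2] <- TRUE        # 10
  m[1:5, 3:4, 3] <- TRUE        # 10
  m[1:2, 1, 4] <- TRUE          # 2
  expect_equal(select_largest_slice(voi_mask(m)), 2)
  ph <- small_phantom(seed = 18)
  counts <- apply(ph$mask$voxels, 3, sum)
  expect_equal(select_largest_slice(ph$mask), which.max(counts))
})

test_that("reslicing an axial frame at identity reproduces the mask slice", {
  ph <- small_phantom(seed = 19)
  z0 <- select_largest_slice(ph$mask)
  vol <- ph$volume
  frame <- us_frame(matrix(0, dim(vol$voxels)[1], dim(vol$voxels)[2]),
                    spacing = vol$spacing[1:2],
                    origin = c(0, 0, (z0 - 1) * vol$spacing[3]),
                    dir_row = c(1, 0, 0), dir_col = c(0, 1, 0))
  rs <- reslice_mask(ph$mask, vol, frame, rigid_transform())
  expect_identical(rs, ph$mask$voxels[, , z0])
})

test_that("reslicing through a known offset shifts the silhouette", {
  ph <- small_phantom(seed = 20)
  z0 <- select_largest_slice(ph$mask)
  vol <- ph$volume
  shift <- c(6, -4, 0)  # whole-voxel in-plane shift in mm
  tf <- rigid_transform(diag(3), shift)
  frame <- us_frame(matrix(0, dim(vol$voxels)[1], dim(vol$voxels)[2]),
                    spacing = vol$spacing[1:2],
                    origin = c(0, 0, (z0 - 1) * vol$spacing[3]) + shift,
                    dir_row = c(1, 0, 0), dir_col = c(0, 1, 0))
  rs <- reslice_mask(ph$mask, vol, frame, tf)
  expect_identical(rs, ph$mask$voxels[, , z0])
  far <- us_frame(matrix(0, 4, 4), spacing = c(1, 1),
                  origin = c(1e4, 1e4, 1e4),
                  dir_row = c(1, 0, 0), dir_col = c(0, 1, 0))
  expect_error(reslice_mask(ph$mask, vol, far, rigid_transform()),
               "no overlap")
})

test_that("summaries reproduce the published per-patient statistics", {
  pts <- study_patients()
  s_dsc <- summarize_values(pts$dsc)
  expect_equal(s_dsc$median, 0.53)
  expect_equal(s_dsc$min, 0.37)
  expect_equal(s_dsc$max, 0.79)
  expect_equal(s_dsc$n, 5)       # patient 1 undefined, excluded
  expect_equal(s_dsc$n_total, 6)

  s_days <- summarize_values(pts$days_biopsy_to_ct)
  expect_equal(s_days$median, 21)
  expect_equal(s_days$min, 7)
  expect_equal(s_days$max, 30)

  expect_equal(summarize_values(pts$volume_cm3[pts$site == "omentum"])$median,
               103.4)
  expect_equal(summarize_values(pts$volume_cm3[pts$site == "pelvis"])$median,
               520)
  expect_error(summarize_values(c(NA_real_, NA_real_)), "no defined values")
})
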