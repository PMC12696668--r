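zero_jitter_config <- function(...) {
  field_gen_config(placement_bias = c(0, 0, 0), placement_sd = c(0, 0, 0),
                   peak_insitu_sd = 0, ...)
}

test_that("pressure fields realise the configured geometry and intensity", {
  cfg <- zero_jitter_config(seed = 1)
  f <- generate_pressure_field(cfg)
  intens <- intensity_volume_from_pressure(f$pressure)
  pk <- in_brain_peak(intens, f$head$brain_mask)
  # zero jitter: peak voxel exactly at the omega target
  expect_equal(pk$world, cfg$target_point)
  # degenerate sd: in-brain intensity max equals the configured Isppa,
  # closing the plane-wave round trip through the stored pressure volume
  expect_equal(pk$value, 1.20, tolerance = 1e-9)
})

test_that("intensity conversion is voxel-wise plane-wave", {
  v0 <- vol3d(array(0, c(4, 4, 4)))
  expect_true(all(intensity_volume_from_pressure(v0)$values == 0))
  vu <- vol3d(array(pressure_from_isppa(1.2), c(4, 4, 4)))
  expect_equal(intensity_volume_from_pressure(vu)$values[1, 1, 1], 1.2,
               tolerance = 1e-12)
  # doubling pressure quadruples intensity
  v1 <- vol3d(array(runif(64, 1e4, 1e5), c(4, 4, 4)))
  v2 <- vol3d(2 * v1$values)
  expect_equal(intensity_volume_from_pressure(v2)$values,
               4 * intensity_volume_from_pressure(v1)$values,
               tolerance = 1e-12)
})

test_that("in-brain peak ignores hotter voxels outside the mask", {
  vals <- array(0, c(5, 5, 5))
  mask <- array(0, c(5, 5, 5))
  mask[2:4, 2:4, 2:4] <- 1
  vals[3, 3, 3] <- 5      # in-mask maximum
  vals[1, 1, 1] <- 50     # global maximum, outside mask
  v <- vol3d(vals); m <- vol3d(mask)
  pk <- in_brain_peak(v, m)
  expect_equal(pk$voxel, c(3, 3, 3))
  expect_equal(pk$value, 5)
  # uniform field: tie broken by lowest linear index inside the mask
  pku <- in_brain_peak(vol3d(array(1, c(5, 5, 5))), m)
  expect_equal(pku$voxel, c(2, 2, 2))
  expect_error(in_brain_peak(v, vol3d(array(0, c(5, 5, 5)))), "empty")
})

test_that("FWHM focus volume matches the analytic half-max ellipsoid", {
  # isotropic 6 mm focus on a half-millimetre grid
  cfg <- zero_jitter_config(focus_fwhm = c(6, 6, 6), spacing = 0.5,
                            origin = c(-24, -24, -24), seed = 1)
  f <- generate_pressure_field(cfg)
  intens <- intensity_volume_from_pressure(f$pressure)
  foc <- fwhm_focus(intens, f$head$brain_mask)
  expect_equal(foc$volume_mm3, pi / 6 * 6^3, tolerance = 0.05)

  # anisotropic case: half-max ellipsoid volume (pi/6) * wx * wy * wz
  cfg2 <- zero_jitter_config(seed = 1)   # 6 x 6 x 30 mm
  f2 <- generate_pressure_field(cfg2)
  foc2 <- fwhm_focus(intensity_volume_from_pressure(f2$pressure),
                     f2$head$brain_mask)
  expect_equal(foc2$volume_mm3, pi / 6 * 6 * 6 * 30, tolerance = 0.05)

  # the peak voxel is inside the focus and every focus voxel >= half max
  iv <- intensity_volume_from_pressure(f2$pressure)$values
  expect_equal(foc2$mask$values[foc2$peak$voxel[1], foc2$peak$voxel[2],
                                foc2$peak$voxel[3]], 1)
  expect_true(all(iv[foc2$mask$values > 0] >= foc2$peak$value / 2))
})

test_that("measured per-axis FWHM matches the configured widths", {
  cfg <- zero_jitter_config(seed = 1)
  f <- generate_pressure_field(cfg)
  intens <- intensity_volume_from_pressure(f$pressure)
  pk <- in_brain_peak(intens, f$head$brain_mask)
  v <- pk$voxel
  half <- pk$value / 2
  fwhm_axis <- function(line) sum(line >= half) # 1 mm spacing
  expect_equal(fwhm_axis(intens$values[, v[2], v[3]]), 6, tolerance = 1)
  expect_equal(fwhm_axis(intens$values[v[1], , v[3]]), 6, tolerance = 1)
  expect_equal(fwhm_axis(intens$values[v[1], v[2], ]), 30, tolerance = 1)
})

test_that("voxels at exactly half maximum are included in the focus", {
  vals <- array(0, c(3, 3, 3))
  vals[2, 2, 2] <- 1
  vals[1, 2, 2] <- 0.5     # exactly half max
  vals[3, 2, 2] <- 0.499
  foc <- fwhm_focus(vol3d(vals), vol3d(array(1, c(3, 3, 3))))
  expect_equal(foc$mask$values[1, 2, 2], 1)
  expect_equal(foc$mask$values[3, 2, 2], 0)
  # uniform field in brain: focus is the entire brain mask
  mask <- array(0, c(3, 3, 3)); mask[1:2, , ] <- 1
  focu <- fwhm_focus(vol3d(array(2, c(3, 3, 3))), vol3d(mask))
  expect_equal(focu$mask$values, mask)
})

test_that("ROI overlap is the focus fraction inside the ROI", {
  dimv <- c(20, 20, 20)
  base <- vol3d(array(0, dimv))
  focus <- array(0, dimv); focus[1:10, 1:10, 1:2] <- 1   # 200 voxels
  roi <- array(0, dimv);   roi[1:10, 1:4, 1] <- 1        # covers 40 of them
  intens <- array(1, dimv)
  ov <- roi_overlap(vol3d(focus), vol3d(roi), vol3d(intens))
  expect_equal(ov$overlap_pct, 20)

  roi_all <- array(1, dimv)
  expect_equal(roi_overlap(vol3d(focus), vol3d(roi_all),
                           vol3d(intens))$overlap_pct, 100)
  roi_off <- array(0, dimv); roi_off[15:20, 15:20, 15:20] <- 1
  expect_equal(roi_overlap(vol3d(focus), vol3d(roi_off),
                           vol3d(intens))$overlap_pct, 0)
  expect_error(roi_overlap(vol3d(array(0, dimv)), vol3d(roi), vol3d(intens)),
               "empty")
})

test_that("overlap is invariant under rigid translation of both volumes", {
  cfg <- field_gen_config(seed = 4)
  f <- generate_pressure_field(cfg)
  intens <- intensity_volume_from_pressure(f$pressure)
  foc <- fwhm_focus(intens, f$head$brain_mask)
  roi <- sphere_roi(intens, f$head$m1_roi$centre, f$head$m1_roi$radius)
  ov1 <- roi_overlap(foc$mask, roi, intens)
  shift <- c(7, -3, 11)
  tr_vol <- function(v) vol3d(v$values, v$spacing, v$origin + shift)
  ov2 <- roi_overlap(tr_vol(foc$mask), tr_vol(roi), tr_vol(intens))
  expect_equal(ov2$overlap_pct, ov1$overlap_pct)
})

test_that("landmark distances and axis signs follow the RAS/medial convention", {
  head <- synthetic_head_model(field_gen_config())
  ld0 <- landmark_distances(head$omega, head)
  expect_equal(ld0$dist_omega, 0)
  ld <- landmark_distances(head$omega + c(3, 4, 12), head)
  expect_equal(ld$dist_omega, 13)
  # left-hemisphere peak shifted toward the midline: positive medial
  ldm <- landmark_distances(head$omega + c(5, 0, 0), head)
  expect_gt(ldm$axis_shift[["medial"]], 0)
  expect_equal(landmark_distances(head$lip, head)$dist_lip, 0)
})

test_that("group axis tests reproduce closed-form one-sample t results", {
  z <- matrix(0, nrow = 5, ncol = 3)
  t0 <- group_axis_tests(z)
  expect_equal(t0$t, c(0, 0, 0))
  expect_equal(t0$p, c(1, 1, 1))

  sh <- cbind(c(1, 2, 3, 4, 5), rep(0, 5), rep(0, 5))
  tt <- group_axis_tests(sh)
  expect_equal(tt$t[1], 3 / (sd(1:5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(tt$t[1], 4.2426, tolerance = 1e-4)
  expect_equal(tt$p[1], 0.0132, tolerance = 5e-3)
  expect_equal(tt$df[1], 4)
  # zero variance with nonzero mean: flagged, p reported as 0
  dg <- group_axis_tests(cbind(rep(2, 4), rep(0, 4), rep(0, 4)))
  expect_true(dg$degenerate[1])
  expect_equal(dg$p[1], 0)
})

test_that("group focus maps sum voxel-wise", {
  m <- array(0, c(6, 6, 6)); m[1:3, , ] <- 1
  v <- vol3d(m)
  s3 <- group_focus_map(list(v, v, v))
  expect_equal(s3$values, 3 * m)
  m2 <- array(0, c(6, 6, 6)); m2[4:6, , ] <- 1
  expect_equal(max(group_focus_map(list(v, vol3d(m2)))$values), 1)
  m3 <- array(0, c(6, 6, 6)); m3[2:4, , ] <- 1   # half-overlapping
  sm <- group_focus_map(list(v, vol3d(m3)))
  expect_equal(unique(as.vector(sm$values[2:3, , ])), 2)
  expect_error(group_focus_map(list(v, vol3d(array(0, c(5, 5, 5))))), "grid")
})

test_that("cohort placement dispersion matches the configured targeting bias", {
  mc <- targeting_monte_carlo(30, field_gen_config(seed = 1))
  # mean peak-to-omega Euclidean distance in the observed calibration band
  expect_gte(mean(mc$mean_dist_omega), 15)
  expect_lte(mean(mc$mean_dist_omega), 27)
  # anterior shift detected in most replicates, superior shift not biased
  expect_gte(mean(mc$p_anterior < 0.05), 0.8)
  expect_gte(mean(mc$p_medial < 0.05), 0.8)
})

test_that("field generation is deterministic and validated", {
  f1 <- generate_pressure_field(field_gen_config(seed = 10))
  f2 <- generate_pressure_field(field_gen_config(seed = 10))
  expect_identical(f1$pressure$values, f2$pressure$values)
  expect_error(field_gen_config(target_point = c(500, 0, 0)), "outside")
  expect_error(field_gen_config(focus_fwhm = c(500, 6, 30)), "larger")
  expect_error(field_gen_config(spacing = 0), "positive")
})
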