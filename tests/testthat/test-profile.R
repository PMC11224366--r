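test_that("slice metrics decompose CSA by area fat fraction", {
  um <- uniform_muscle(dims = c(8, 5, 3), spacing = c(1, 1, 3), ff = 25)
  sm <- slice_metrics(um$water, um$fat, um$labelmap, 1L)
  expect_equal(nrow(sm), 3)
  expect_equal(sm$boundary_csa_mm2, rep(40, 3))
  expect_equal(sm$fat_csa_mm2, rep(10, 3))
  expect_equal(sm$lean_csa_mm2, rep(30, 3))
  expect_equal(sm$area_ff_pct, rep(25, 3))
  expect_equal(sm$z_mm, c(0, 3, 6))
})

test_that("profiles interpolate linearly onto the percent grid", {
  ## two slices, CSA 10 then 20 mm^2
  d <- c(10, 10, 2)
  labels <- array(0L, d)
  labels[1:10, 1, 1] <- 1L
  labels[1:10, 1:2, 2] <- 1L
  um <- uniform_muscle(dims = d, spacing = c(1, 1, 5), ff = 40)
  lm <- muscle_labelmap(labels, um$labelmap$dictionary, c(1, 1, 5))
  prof <- normalize_profile(slice_metrics(um$water, um$fat, lm, 1L))
  expect_equal(length(prof$percent), 101)
  expect_equal(prof$boundary_csa_mm2[1], 10)
  expect_equal(prof$boundary_csa_mm2[101], 20)
  expect_equal(prof$boundary_csa_mm2[51], 15)

  ## 11 equally spaced slices with CSA = slice index: profile(p) linear
  d2 <- c(12, 1, 11)
  labels2 <- array(0L, d2)
  for (k in 1:11) labels2[seq_len(k), 1, k] <- 1L
  um2 <- uniform_muscle(dims = d2, spacing = c(1, 1, 2), ff = 10)
  lm2 <- muscle_labelmap(labels2, um2$labelmap$dictionary, c(1, 1, 2))
  prof2 <- normalize_profile(slice_metrics(um2$water, um2$fat, lm2, 1L))
  expect_equal(prof2$boundary_csa_mm2, 1 + (0:100) / 10, tolerance = 1e-12)
})

test_that("single-slice muscles yield constant profiles with a warning", {
  um <- uniform_muscle(dims = c(5, 5, 1), ff = 30)
  sm <- slice_metrics(um$water, um$fat, um$labelmap, 1L)
  expect_equal(nrow(sm), 1)
  expect_warning(prof <- normalize_profile(sm), class = "mq_warning")
  expect_equal(unique(prof$boundary_csa_mm2), 25)
})

test_that("per-slice closure survives interpolation at every grid point", {
  ds <- get_minimal_noisy()
  for (code in 1:2) {
    prof <- normalize_profile(slice_metrics(ds$water, ds$fat, ds$labelmap, code))
    expect_lt(max(abs(prof$lean_csa_mm2 + prof$fat_csa_mm2 -
                        prof$boundary_csa_mm2)), 1e-9)
  }
})

test_that("summed slice CSA times slice spacing equals the boundary volume", {
  ds <- get_minimal()
  comp <- composition_table(ds$water, ds$fat, ds$labelmap)
  for (code in 1:2) {
    sm <- slice_metrics(ds$water, ds$fat, ds$labelmap, code)
    expect_equal(sum(sm$boundary_csa_mm2) * ds$water$spacing[3],
                 comp$boundary_volume_mm3[comp$code == code],
                 tolerance = 1e-12)
  }
})

test_that("normalization is invariant to axial storage direction", {
  ds <- get_minimal()
  prof <- normalize_profile(slice_metrics(ds$water, ds$fat, ds$labelmap, 2L))
  flip <- function(a) a[, , rev(seq_len(dim(a)[3])), drop = FALSE]
  water_f <- volumetric_image(flip(ds$water$data), ds$water$spacing,
                              superior_direction = -1L)
  fat_f <- volumetric_image(flip(ds$fat$data), ds$fat$spacing,
                            superior_direction = -1L)
  lm_f <- muscle_labelmap(flip(ds$labelmap$labels), ds$labelmap$dictionary,
                          ds$labelmap$spacing, superior_direction = -1L)
  prof_f <- normalize_profile(slice_metrics(water_f, fat_f, lm_f, 2L))
  expect_equal(prof_f$boundary_csa_mm2, prof$boundary_csa_mm2)
  expect_equal(prof_f$area_ff_pct, prof$area_ff_pct)
})

test_that("trimming restricts the grid and keeps the full profile", {
  ds <- get_minimal()
  prof <- normalize_profile(slice_metrics(ds$water, ds$fat, ds$labelmap, 2L))
  tr <- trim_profile(prof)
  expect_equal(length(tr$percent), 81)
  expect_equal(range(tr$percent), c(10, 90))
  expect_equal(tr$full$percent, 0:100)
  id <- trim_profile(prof, 0, 100)
  expect_equal(id$area_ff_pct, prof$area_ff_pct)
  expect_error(trim_profile(prof, 60, 40), class = "mq_parameter_error")
})

test_that("trimmed area-FF mean matches the analytic pattern mean", {
  ds <- get_minimal()
  spec <- ds$spec
  m <- spec$muscles[2, ]
  prof <- normalize_profile(slice_metrics(ds$water, ds$fat, ds$labelmap, 2L))
  tr <- trim_profile(prof)
  ## oracle: integral of the logistic pattern over the trimmed span of
  ## the occupied extent (u of first/last occupied slice centres)
  zpos <- (c(prof$inferior_slice, prof$superior_slice) - 1) * spec$spacing[3]
  u_lo <- (zpos[1] - m$z0_mm) / (m$z1_mm - m$z0_mm)
  u_hi <- (zpos[2] - m$z0_mm) / (m$z1_mm - m$z0_mm)
  uu <- function(p) u_lo + (u_hi - u_lo) * p / 100
  oracle <- integrate(function(p) ff_pattern_value(spec$patterns[["2"]], uu(p)),
                      10, 90)$value / 80
  ## area FF per slice is exact (uniform in-plane), so the only error is
  ## piecewise-linear interpolation of the smooth logistic on ~20 slices
  expect_lt(abs(mean(tr$area_ff_pct) - oracle), 0.5)
})

test_that("profile deltas are antisymmetric and localize programmed change", {
  ds <- get_minimal()
  prof <- normalize_profile(slice_metrics(ds$water, ds$fat, ds$labelmap, 1L))
  d0 <- profile_delta(prof, prof)
  expect_true(all(d0$d_area_ff_pct == 0))
  fu <- make_followup(ds, delta_ff = c("1" = 8, "2" = 5))
  prof_fu <- normalize_profile(slice_metrics(fu$water, fu$fat, fu$labelmap, 1L))
  dab <- profile_delta(prof, prof_fu)
  dba <- profile_delta(prof_fu, prof)
  expect_equal(dab$d_area_ff_pct, -dba$d_area_ff_pct)
  ## homogeneous muscle: uniform increment fallback
  expect_equal(dab$d_area_ff_pct, rep(8, 101), tolerance = 1e-9)
  short <- trim_profile(prof)
  expect_error(profile_delta(prof, short), class = "mq_alignment_error")
})
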