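test_that("generation is bit-reproducible for a fixed seed", {
  a <- generate_phantom(phantom_spec_minimal(seed = 4L, noise_sd_frac = 0.02))
  b <- generate_phantom(phantom_spec_minimal(seed = 4L, noise_sd_frac = 0.02))
  expect_identical(a$water$data, b$water$data)
  expect_identical(a$labelmap$labels, b$labelmap$labels)

  c2 <- generate_phantom(phantom_spec_minimal(seed = 5L, noise_sd_frac = 0.02))
  expect_identical(a$labelmap$labels, c2$labelmap$labels)  # same geometry
  expect_false(identical(a$water$data, c2$water$data))     # different noise
})

test_that("overlapping muscle geometry is rejected with the codes named", {
  sp <- phantom_spec_minimal()
  sp$muscles$cx_mm <- c(26, 27)   # same position -> overlap
  err <- tryCatch(generate_phantom(sp), error = identity)
  expect_s3_class(err, "mq_spec_error")
  expect_match(conditionMessage(err), "1, 2")
})

test_that("FF patterns follow their closed forms", {
  pat <- list(type = "high_distal", ff_hi = 70, ff_lo = 10,
              center = 0.5, width = 0.08)
  expect_equal(ff_pattern_value(pat, 0.5), 40)               # midpoint
  expect_equal(ff_pattern_value(pat, 0), 10 + 60 / (1 + exp(-0.5 / 0.08)))
  expect_lt(ff_pattern_value(pat, 1), 11)
  patc <- list(type = "high_center", ff_hi = 65, ff_lo = 15,
               center = 0.5, width = 0.18)
  expect_equal(ff_pattern_value(patc, 0.5), 65)
  pate <- list(type = "high_ends", ff_hi = 65, ff_lo = 15,
               center = 0.5, width = 0.18)
  expect_equal(ff_pattern_value(pate, 0.5), 15)
  expect_error(ff_pattern_value(list(type = "spiral", ff_hi = 1, ff_lo = 0), 0.5),
               class = "mq_spec_error")
})

test_that("noiseless generation closes the loop with the Dixon equations", {
  ds <- get_five_pattern()
  comp <- composition_table(ds$water, ds$fat, ds$labelmap)
  expect_equal(comp$fat_fraction_pct, ds$truth_composition$mean_ff,
               tolerance = 1e-12)
  ## voxelwise: Eq-style ratio reproduces the truth field inside muscles
  msk <- ds$labelmap$labels > 0
  ffmap <- voxel_ff(ds$water, ds$fat, msk)
  expect_lt(max(abs(ffmap$values[msk] - ds$truth_ff[msk])), 1e-9)
})

test_that("lesion intervals hit the programmed volume fraction", {
  m <- data.frame(taper = "none", taper_floor = 0.3)
  iv <- musclequant:::lesion_interval(m, 0.3)
  expect_equal(diff(iv), 0.3, tolerance = 1e-9)
  mc <- data.frame(taper = "cosine", taper_floor = 0.65)
  ivc <- musclequant:::lesion_interval(mc, 0.5)
  csa2 <- function(u) taper_value("cosine", u, 0.65)^2
  got <- integrate(csa2, ivc[1], ivc[2])$value / integrate(csa2, 0, 1)$value
  expect_equal(got, 0.5, tolerance = 1e-5)
})

test_that("follow-up generation concentrates progression in transition zones", {
  ds <- get_minimal()
  fu <- make_followup(ds, delta_ff = c("1" = 0, "2" = 5))
  ## zero-delta muscle unchanged (noiseless)
  m1 <- ds$labelmap$labels == 1L
  expect_equal(fu$truth_ff[m1], ds$truth_ff[m1])
  expect_equal(fu$water$data[m1], ds$water$data[m1])
  ## programmed mean change conserved
  m2 <- ds$labelmap$labels == 2L
  expect_equal(mean(fu$truth_ff[m2]) - mean(ds$truth_ff[m2]), 5,
               tolerance = 1e-9)
  ## increments grow with the axial FF gradient magnitude
  inc <- fu$truth_ff[m2] - ds$truth_ff[m2]
  spec <- ds$spec
  m <- spec$muscles[2, ]
  z <- musclequant:::grid_points(dim(ds$truth_ff), spec$spacing)[, 3][m2]
  u <- (z - m$z0_mm) / (m$z1_mm - m$z0_mm)
  near <- abs(u - 0.5) < 0.1; far <- abs(u - 0.5) > 0.3
  expect_gt(mean(inc[near]), mean(inc[far]))
  ## clipping warns and reports mass
  expect_warning(fu2 <- make_followup(ds, delta_ff = c("2" = 60)),
                 class = "mq_warning")
  expect_true(all(fu2$truth_ff[m2] <= 100))
  expect_gt(fu2$progression$clip_mass[fu2$progression$code == 2], 0)
})

test_that("truth ratings map truth fields through the ordinal scales", {
  ds <- get_stir_phantom()
  tr <- truth_ratings(ds)
  expect_equal(tr$fat_rating,
               fat_rating_from_ff(ds$truth_composition$mean_ff))
  fr <- ds$truth_stir_fraction
  expect_equal(tr$stir_grade,
               stir_grade_from_pct(fr$fraction_pct, fr$mild))
  ## the 72% muscle grades 4, the 0% muscle grades 0
  expect_equal(tr$stir_grade[fr$fraction_pct > 60], 4L)
  expect_equal(tr$stir_grade[fr$fraction_pct == 0], 0L)
})

test_that("truth STIR labels equal resampled Dixon labels under the known transform", {
  ds <- get_stir_phantom()
  labs <- resample_labels(ds$labelmap, ds$dixon_to_stir, ds$stir)
  agree <- mean(labs$labels == ds$truth_labels_stir$labels)
  expect_gt(agree, 0.985)   # only boundary voxels may differ
})

test_that("mild diffuse elevation scores near zero content", {
  sp <- phantom_spec_stir(seed = 5L,
                          fractions = c(0, 0, 0, 0))
  sp$stir$lesions$mild <- c(FALSE, TRUE, FALSE, FALSE)
  ds <- generate_phantom(sp)
  expect_equal(truth_ratings(ds)$stir_grade, c(0L, 1L, 0L, 0L))
  mask <- segment_stir(ds$stir, limb_mask(ds$stir))
  labs <- resample_labels(ds$labelmap, ds$dixon_to_stir, ds$stir)
  ct <- stir_content(mask, labs)
  ## the categorical grade-1 pattern has no discrete lesions: content
  ## stays far below even the grade-2 band (< 30%)
  expect_lt(max(ct$stir_pct), 10)
})
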