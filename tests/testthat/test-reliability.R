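test_that("overlap coefficients match brute-force voxel counting", {
  dict <- data.frame(code = 1L, name = "m", side = "left")
  mk <- function(m) muscle_labelmap(array(as.integer(m), dim(m)), dict,
                                    c(1, 1, 1))
  a <- array(FALSE, c(4, 4, 2)); a[1:2, 1:2, 1:2] <- TRUE       # 8 voxels
  b <- array(FALSE, c(4, 4, 2)); b[2:3, 1:2, 1:2] <- TRUE       # 8, overlap 4
  ov <- overlap(mk(a), mk(b), 1L)
  expect_equal(ov$jaccard, 4 / 12)
  expect_equal(ov$dice, 0.5)

  same <- overlap(mk(a), mk(a), 1L)
  expect_equal(c(same$dice, same$jaccard), c(1, 1))
  disj <- array(FALSE, c(4, 4, 2)); disj[4, 4, ] <- TRUE
  expect_equal(overlap(mk(a), mk(disj), 1L)$dice, 0)
  none <- array(FALSE, c(4, 4, 2))
  expect_error(overlap(mk(none), mk(none), 1L),
               class = "mq_undefined_overlap_error")

  set.seed(5)
  for (i in 1:25) {
    x <- array(runif(64) < 0.4, c(4, 4, 4))
    y <- array(runif(64) < 0.4, c(4, 4, 4))
    if (!any(x) && !any(y)) next
    ov <- overlap(mk(x), mk(y), 1L)
    bo <- brute_overlap(x, y)
    expect_equal(ov$dice, unname(bo["dice"]))
    expect_equal(ov$jaccard, unname(bo["jaccard"]))
    ## functional identity dice = 2j / (1 + j)
    expect_equal(ov$dice, 2 * ov$jaccard / (1 + ov$jaccard), tolerance = 1e-12)
  }
})

test_that("absolute volume error is the symmetric percent difference", {
  expect_equal(abs_volume_error(100, 100), 0)
  expect_equal(abs_volume_error(95, 105), 10)
  expect_equal(abs_volume_error(105, 95), abs_volume_error(95, 105))
  expect_error(abs_volume_error(0, 10), class = "mq_domain_error")
})

test_that("absolute FF differences obey the triangle inequality", {
  expect_equal(abs_ff_difference(20, 20), 0)
  expect_equal(abs_ff_difference(12.5, 15), 2.5)
  set.seed(8)
  for (i in 1:50) {
    t3 <- runif(3, 0, 100)
    expect_lte(abs_ff_difference(t3[1], t3[3]),
               abs_ff_difference(t3[1], t3[2]) + abs_ff_difference(t3[2], t3[3]))
  }
  expect_error(abs_ff_difference(-1, 50), class = "mq_domain_error")
})

test_that("Bland-Altman recovers constructed fixed and proportional biases", {
  a <- c(10, 20, 30, 40, 50, 60)

  same <- bland_altman(a, a)
  expect_equal(same$bias, 0)
  expect_equal(same$slope, 0)
  expect_true(same$degenerate)

  fixed <- bland_altman(a, a + 5)
  expect_equal(fixed$bias, 5)
  expect_equal(fixed$slope, 0, tolerance = 1e-12)
  expect_true(fixed$degenerate)   # zero variance of differences: no t-test
  expect_equal(fixed$loa, c(5, 5))

  set.seed(3)
  x <- a + rnorm(6, 0, 0.01)
  prop <- bland_altman(x, 1.1 * x)
  ## closed form: d = 0.1 x, m = 1.05 x -> slope = 0.1 / 1.05
  expect_equal(prop$slope, 0.1 / 1.05, tolerance = 1e-3)
  expect_equal(prop$fixed_df, 5)
  expect_equal(prop$slope_df, 4)
  ## cross-check the fixed-bias t against stats::t.test directly
  tt <- t.test(1.1 * x - x)
  expect_equal(prop$fixed_t, unname(tt$statistic))
  expect_equal(prop$fixed_p, tt$p.value)

  expect_error(bland_altman(1:2, 2:3), class = "mq_parameter_error")
})

test_that("Spearman matches exact permutation enumeration for small n", {
  expect_equal(spearman_cor(1:5, c(2, 4, 6, 7, 10))$rho, 1)
  expect_equal(spearman_cor(1:5, 5:1)$rho, -1)

  cases <- list(
    list(x = c(1, 1, 2, 2, 3, 3), y = c(0.3, 1.2, 0.9, 2.5, 2.4, 3.1)),
    list(x = c(1, 2, 2, 3, 3, 4), y = c(4, 4, 3, 3, 2, 2)),
    list(x = c(0, 1, 0, 1, 1), y = c(2, 3, 2, 5, 4)),
    list(x = 1:7, y = c(3, 1, 4, 1, 5, 9, 2))
  )
  for (cs in cases) {
    got <- spearman_cor(cs$x, cs$y)
    want <- brute_spearman(cs$x, cs$y)
    expect_equal(got$rho, want$rho, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_equal(got$method, "exact_permutation")
  }

  ## t-approximation agrees with stats::cor.test for larger n
  set.seed(12)
  x <- rnorm(30); y <- x + rnorm(30)
  got <- spearman_cor(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$method, "t_approximation")

  expect_warning(flat <- spearman_cor(rep(1, 5), 1:5), class = "mq_warning")
  expect_true(is.na(flat$rho))
})

test_that("rating-scale mappings are monotone with the published anchors", {
  expect_equal(fat_rating_from_ff(45), 4L)
  expect_equal(fat_rating_from_ff(30), 4L)   # 30-60% band is rating 4
  expect_equal(fat_rating_from_ff(60), 4L)
  expect_equal(fat_rating_from_ff(61), 5L)
  sweep <- fat_rating_from_ff(seq(0, 100, 0.5))
  expect_true(all(diff(sweep) >= 0))
  expect_equal(range(sweep), c(1L, 6L))

  expect_equal(stir_grade_from_pct(70), 4L)
  expect_equal(stir_grade_from_pct(45), 3L)
  expect_equal(stir_grade_from_pct(10), 2L)
  expect_equal(stir_grade_from_pct(0), 0L)
  expect_equal(stir_grade_from_pct(0, mild_diffuse = TRUE), 1L)
  gs <- stir_grade_from_pct(seq(0.5, 100, 0.5))
  expect_true(all(diff(gs) >= 0))
})

test_that("reliability reports summarize paired runs per muscle", {
  ds <- get_five_pattern()
  comp <- composition_table(ds$water, ds$fat, ds$labelmap)
  rep0 <- reliability_report(comp, comp, design = "intra_observer",
                             labels_a = ds$labelmap, labels_b = ds$labelmap)
  expect_equal(nrow(rep0$per_muscle), 5)
  expect_true(all(rep0$per_muscle$abs_volume_error_pct == 0))
  expect_true(all(rep0$per_muscle$dice == 1))
  expect_equal(rep0$volume_ba$bias, 0)
  expect_equal(rep0$volume_ba$slope, 0)

  ds2 <- generate_phantom(phantom_spec_five_pattern(seed = 9L,
                                                    noise_sd_frac = 0.02))
  comp2 <- composition_table(ds2$water, ds2$fat, ds2$labelmap)
  rep2 <- reliability_report(comp, comp2, design = "scan_rescan")
  expect_equal(rep2$per_muscle$code, 1:5)
  expect_true(all(rep2$per_muscle$abs_volume_error_pct < 10))

  one <- comp[1, , drop = FALSE]
  expect_error(reliability_report(one, one),
               class = "mq_insufficient_data_error")
})
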