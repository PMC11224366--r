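## Small synthetic STIR slices with a known lesion for segmentation
## oracle tests: a disc limb of muscle-like intensity containing a
## square lesion of programmed brightness.
make_stir_slice <- function(n = 48, muscle = 100, lesion = 300,
                            lesion_px = 6, noise_sd = 0, nslices = 3,
                            seed = 1) {
  set.seed(seed)
  xs <- seq_len(n) - (n + 1) / 2
  limb2d <- outer(xs^2, xs^2, "+") <= (n / 2 - 2)^2
  sl <- matrix(0, n, n)
  sl[limb2d] <- muscle
  les2d <- matrix(FALSE, n, n)
  idx <- seq(n / 2 - lesion_px / 2, length.out = lesion_px)
  les2d[idx, idx] <- TRUE
  sl[les2d] <- lesion
  arr <- array(rep(sl, nslices), c(n, n, nslices))
  if (noise_sd > 0) {
    msk <- array(rep(limb2d, nslices), dim(arr))
    arr[msk] <- pmax(0, arr[msk] + rnorm(sum(msk), 0, noise_sd))
  }
  list(stir = volumetric_image(arr, c(1, 1, 5), kind = "stir"),
       limb = array(rep(limb2d, nslices), dim(arr)),
       lesion = array(rep(les2d, nslices), dim(arr)))
}

test_that("limb masking recovers a cylinder against empty background", {
  ds <- get_stir_phantom()
  limb <- limb_mask(ds$stir)
  ## truth: limb disc evaluated on the STIR grid through the known transform
  pts <- musclequant:::grid_points(dim(ds$stir$data), ds$stir$spacing)
  pd <- transform_points(ds$dixon_to_stir, pts)
  sp <- ds$spec
  truth <- array((pd[, 1] - sp$limb_center_mm[1])^2 +
                   (pd[, 2] - sp$limb_center_mm[2])^2 <= sp$limb_radius_mm^2,
                 dim(ds$stir$data))
  disagree <- mean(limb != truth)
  expect_lt(disagree, 0.02)  # within a ~1-voxel boundary band

  flat <- volumetric_image(array(0, c(8, 8, 2)), c(1, 1, 1), kind = "stir")
  expect_true(all(!limb_mask(flat)))
})

test_that("a bright lesion is segmented exactly on a noiseless slice", {
  ms <- make_stir_slice()
  mask <- segment_stir(ms$stir, ms$limb, edge_margin_px = 2L)
  expect_identical(mask$mask, ms$lesion)
})

test_that("constant-intensity slices produce no detections", {
  ms <- make_stir_slice(lesion = 100)  # lesion intensity == muscle
  mask <- segment_stir(ms$stir, ms$limb)
  expect_equal(sum(mask$mask), 0)
  ## pure noise must also be rejected by the degenerate guard
  ms2 <- make_stir_slice(lesion = 100, noise_sd = 10, seed = 4)
  mask2 <- segment_stir(ms2$stir, ms2$limb)
  expect_lt(sum(mask2$mask) / sum(ms2$limb), 0.01)
})

test_that("segmentation survives noise with high overlap", {
  ms <- make_stir_slice(noise_sd = 10, seed = 9)
  mask <- segment_stir(ms$stir, ms$limb)
  ov <- brute_overlap(mask$mask, ms$lesion)
  expect_gte(ov["dice"], 0.95)
})

test_that("the Dixon fat veto removes fat-like candidates", {
  ms <- make_stir_slice()
  ff <- array(NA_real_, dim(ms$stir$data))
  ff[ms$lesion] <- 80  # pretend the bright voxels are fat on Dixon
  mask <- segment_stir(ms$stir, ms$limb, ff_on_stir = ff, ff_veto_pct = 50)
  expect_equal(sum(mask$mask), 0)
})

test_that("STIR content is the labelled STIR+ percentage", {
  labels <- array(0L, c(10, 10, 10))
  labels[, , ] <- 1L
  lm <- muscle_labelmap(labels, data.frame(code = 1L, name = "tibialis anterior",
                                           side = "left"), c(1, 1, 1))
  msk <- array(FALSE, c(10, 10, 10))
  msk[seq_len(720)] <- TRUE
  sm <- structure(list(mask = msk, provenance = "external",
                       spacing = c(1, 1, 1)), class = "stir_mask")
  ct <- stir_content(sm, lm, erode_first = FALSE)
  expect_equal(ct$stir_pct, 72)
  expect_equal(ct$stir_voxels, 720)

  ## empty mask -> 0% for all muscles
  sm0 <- structure(list(mask = array(FALSE, c(10, 10, 10)),
                        provenance = "external", spacing = c(1, 1, 1)),
                   class = "stir_mask")
  expect_equal(stir_content(sm0, lm, erode_first = FALSE)$stir_pct, 0)
})

test_that("one-layer erosion before counting flags emptied muscles", {
  labels <- array(0L, c(6, 6, 2))
  labels[3, 3, ] <- 1L     # single-pixel muscle disappears under erosion
  labels[1:6, 5, ] <- 2L
  lm <- muscle_labelmap(labels, data.frame(code = c(1L, 2L),
                                           name = c("a", "b"),
                                           side = "left"), c(1, 1, 5))
  sm <- structure(list(mask = array(FALSE, c(6, 6, 2)),
                       provenance = "external", spacing = c(1, 1, 5)),
                  class = "stir_mask")
  ct <- stir_content(sm, lm)
  expect_true(ct$flagged[ct$code == 1])
})

test_that("enlarging a lesion never decreases recovered content", {
  pcts <- vapply(c(4, 8, 12), function(px) {
    ms <- make_stir_slice(lesion_px = px)
    mask <- segment_stir(ms$stir, ms$limb)
    labels <- array(1L, dim(ms$stir$data))
    lm <- muscle_labelmap(labels, data.frame(code = 1L, name = "m",
                                             side = "left"),
                          ms$stir$spacing)
    stir_content(mask, lm, erode_first = FALSE)$stir_pct
  }, numeric(1))
  expect_true(all(diff(pcts) >= 0))
})
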