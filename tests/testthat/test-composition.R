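test_that("voxelwise fat fraction follows the signal ratio", {
  td <- tiny_dixon(fsi = c(10, 30, 60), wsi = c(90, 70, 40))
  ff <- voxel_ff(td$water, td$fat, td$mask)
  expect_equal(as.vector(ff$values), c(10, 30, 60))

  td2 <- tiny_dixon(fsi = c(50, 0), wsi = c(50, 120))
  ff2 <- voxel_ff(td2$water, td2$fat, td2$mask)
  expect_equal(as.vector(ff2$values), c(50, 0))

  ## zero-total-signal voxels are excluded, not propagated as NaN
  td3 <- tiny_dixon(fsi = c(0, 20), wsi = c(0, 80))
  ff3 <- voxel_ff(td3$water, td3$fat, td3$mask)
  expect_true(ff3$excluded[1, 1, 1])
  expect_true(is.na(ff3$values[1, 1, 1]))
  expect_equal(ff3$values[2, 1, 1], 20)

  expect_error(voxel_ff(td$water, td$fat, array(FALSE, c(3, 1, 1))),
               class = "mq_empty_muscle_error")
})

test_that("muscle composition splits boundary volume via the FF equations", {
  um <- uniform_muscle(dims = c(10, 10, 1), spacing = c(1, 1, 3), ff = 20)
  comp <- muscle_composition(um$water, um$fat, um$labelmap, 1L)
  expect_equal(comp$boundary_volume_mm3, 300)
  expect_equal(comp$fat_fraction_pct, 20)
  expect_equal(comp$fat_volume_mm3, 60)
  expect_equal(comp$lean_volume_mm3, 240)
  expect_equal(comp$tp, 100L)
  expect_error(muscle_composition(um$water, um$fat, um$labelmap, 9L),
               class = "mq_dictionary_error")
})

test_that("zero-signal muscles follow the configured degenerate policy", {
  um <- uniform_muscle(ff = 0, S0 = 0)
  expect_warning(comp <- muscle_composition(um$water, um$fat, um$labelmap, 1L),
                 class = "mq_warning")
  expect_true(is.na(comp$fat_fraction_pct))
  expect_equal(comp$boundary_volume_mm3, 300)  # volume keeps zero-signal voxels
  expect_equal(comp$excluded_voxels, 100L)
  expect_error(muscle_composition(um$water, um$fat, um$labelmap, 1L,
                                  on_zero_signal = "error"),
               class = "mq_validation_error")
})

test_that("FF is invariant to global intensity scaling and recovers phantom truth", {
  ds <- get_minimal()
  comp <- composition_table(ds$water, ds$fat, ds$labelmap)
  expect_equal(comp$fat_fraction_pct, ds$truth_composition$mean_ff,
               tolerance = 1e-12)
  for (c_scale in c(0.25, 3.7)) {
    ws <- volumetric_image(ds$water$data * c_scale, ds$water$spacing)
    fs <- volumetric_image(ds$fat$data * c_scale, ds$fat$spacing)
    comp2 <- composition_table(ws, fs, ds$labelmap)
    expect_equal(comp2$fat_fraction_pct, comp$fat_fraction_pct,
                 tolerance = 1e-12)
  }
})

test_that("fat + lean volume equals boundary volume on noisy phantoms", {
  ds <- get_minimal_noisy()
  comp <- composition_table(ds$water, ds$fat, ds$labelmap)
  expect_lt(max(abs(comp$fat_volume_mm3 + comp$lean_volume_mm3 -
                      comp$boundary_volume_mm3) / comp$boundary_volume_mm3),
            1e-9)
  expect_true(all(comp$fat_fraction_pct >= 0 & comp$fat_fraction_pct <= 100))
  expect_equal(comp$boundary_volume_mm3,
               (comp$tp + comp$excluded_voxels) * voxel_volume(ds$water))
})

test_that("dictionary codes absent from the grid yield flagged zero rows", {
  um <- uniform_muscle()
  dict <- rbind(um$labelmap$dictionary,
                data.frame(code = 5L, name = "m 5", side = "right"))
  lm <- muscle_labelmap(um$labelmap$labels, dict, um$labelmap$spacing)
  tab <- composition_table(um$water, um$fat, lm)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$code, c(1L, 5L))  # deterministic ascending order
  expect_false(tab$present[2])
  expect_equal(tab$boundary_volume_mm3[2], 0)
})

test_that("FF histograms bin correctly and conserve voxel counts", {
  td <- tiny_dixon(fsi = c(10, 30, 60), wsi = c(90, 70, 40))
  h <- ff_histogram(voxel_ff(td$water, td$fat, td$mask))
  expect_equal(length(h$bin_edges), 101)
  expect_equal(sum(h$counts), 3)
  expect_equal(which(h$counts == 1), c(11, 31, 61))

  um <- uniform_muscle(ff = 50)
  h2 <- ff_histogram(voxel_ff(um$water, um$fat, um$labelmap$labels == 1L))
  expect_equal(sum(h2$counts > 0), 1)
  expect_equal(h2$counts[51], 100)
  expect_equal(sum(h2$normalized), 1)

  ## FF = 100 falls in the last (closed) bin
  um3 <- uniform_muscle(ff = 100)
  h3 <- ff_histogram(voxel_ff(um3$water, um3$fat, um3$labelmap$labels == 1L))
  expect_equal(h3$counts[100], 100)

  ds <- get_minimal_noisy()
  ffm <- voxel_ff(ds$water, ds$fat, ds$labelmap$labels == 2L)
  hh <- ff_histogram(ffm, bin_width = 2)
  expect_equal(sum(hh$counts), hh$tp)
  expect_error(ff_histogram(ffm, bin_width = 3), class = "mq_parameter_error")
})
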