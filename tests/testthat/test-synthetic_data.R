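# Phantom generator: validation, determinism, geometry fidelity, manifest.

test_that("phantom_spec validation errors name the offending field", {
  expect_error(phantom_spec(image_size = 16), "image_size")
  expect_error(phantom_spec(benign_fraction = 1.2), "benign_fraction")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  expect_error(
    phantom_spec(nodule_diameter_range_benign = c(8, 22),
                 nodule_diameter_range_malignant = c(20, 34)),
    "nodule_diameter_range_malignant")
  expect_error(phantom_spec(nodule_diameter_range_benign = c(-2, 5)),
               "nodule_diameter_range_benign")
})

test_that("a noise-free benign nodule rasterizes to a disc of the right area", {
  # degenerate diameter range pins d exactly
  spec <- phantom_spec(n_slices = 1L, vessel_count = 0L, noise_sigma = 0,
                       benign_fraction = 1,
                       nodule_diameter_range_benign = c(20, 20),
                       nodule_diameter_range_malignant = c(24, 34),
                       seed = 5L)
  sl <- generate_slice(spec, 0L)
  area <- sum(sl$mask)
  expect_lt(abs(area - pi * 10^2), 4 * 20)  # Gauss-circle rasterization bound
  expect_setequal(unique(as.vector(sl$mask)), c(0L, 1L))
  # centroid lies inside the mask
  expect_equal(sl$mask[sl$nodules$centroid_row, sl$nodules$centroid_col], 1L)
  # image is three identical 8-bit channels
  expect_identical(sl$image[, , 1], sl$image[, , 2])
  expect_identical(sl$image[, , 1], sl$image[, , 3])
  expect_true(all(sl$image >= 0 & sl$image <= 255))
})

test_that("generation is deterministic and does not disturb the global RNG", {
  spec <- phantom_spec(n_slices = 2L, seed = 123L)
  set.seed(99); before <- .Random.seed
  a <- generate_slice(spec, 1L)
  expect_identical(.Random.seed, before)
  b <- generate_slice(spec, 1L)
  expect_identical(a, b)
  # different slice index gives a different slice
  expect_false(identical(a$image, generate_slice(spec, 0L)$image))
})

test_that("benign count over 152 one-nodule slices is in the binomial 95% interval", {
  spec <- phantom_spec(n_slices = 152L, benign_fraction = 103 / 152, seed = 7L)
  classes <- vapply(seq_len(152) - 1L, function(i)
    generate_slice(spec, i)$nodules$class, character(1))
  n_benign <- sum(classes == "benign")
  lo <- qbinom(0.025, 152, 103 / 152)
  hi <- qbinom(0.975, 152, 103 / 152)
  expect_gte(n_benign, lo)
  expect_lte(n_benign, hi)
})

test_that("class diameter geometry is separated and matches the mask caliper", {
  spec <- phantom_spec(n_slices = 12L, seed = 31L)
  d_by_class <- list(benign = c(), malignant = c())
  for (i in seq_len(12) - 1L) {
    sl <- generate_slice(spec, i)
    meas <- oracle_diameter(sl$mask)
    expect_lt(abs(meas - sl$nodules$diameter_px), 1.5)
    d_by_class[[sl$nodules$class]] <-
      c(d_by_class[[sl$nodules$class]], sl$nodules$diameter_px)
  }
  if (length(d_by_class$benign) && length(d_by_class$malignant))
    expect_gt(min(d_by_class$malignant), max(d_by_class$benign))
})

test_that("mask components match the manifest nodules per slice", {
  spec <- phantom_spec(n_slices = 6L, nodules_per_slice = 3L, seed = 13L,
                       image_size = 160L)
  for (i in seq_len(6) - 1L) {
    sl <- generate_slice(spec, i)
    lab <- focalseg:::label_components(sl$mask, connectivity = 8)
    expect_identical(max(lab), nrow(sl$nodules))
  }
})

test_that("generate_dataset writes files and a faithful manifest", {
  td <- withr::local_tempdir()
  spec <- phantom_spec(n_slices = 10L, seed = 21L)
  man <- generate_dataset(spec, td)
  expect_equal(length(list.files(td, pattern = "^slice_\\d+\\.png$")), 10L)
  expect_equal(length(list.files(td, pattern = "_mask\\.png$")), 10L)
  expect_equal(nrow(man), 10L)
  expect_named(man, c("slice_id", "nodule_id", "class", "diameter_px",
                      "centroid_row", "centroid_col"))
  # manifest diameter agrees with a brute-force measurement on the WRITTEN mask
  for (i in c(1L, 5L, 10L)) {
    msk <- load_mask(file.path(td, paste0(man$slice_id[i], "_mask.png")))
    expect_lt(abs(oracle_diameter(msk) - man$diameter_px[i]), 1.5)
  }
})

test_that("empty dataset writes an empty manifest and no image files", {
  td <- withr::local_tempdir()
  man <- generate_dataset(phantom_spec(n_slices = 0L), td)
  expect_equal(nrow(man), 0L)
  expect_equal(length(list.files(td, pattern = "\\.png$")), 0L)
})
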