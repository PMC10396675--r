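# Feature operators against brute-force oracles, plus their invariances.

test_that("gradients: flat field, linear ramp, and the double-loop oracle", {
  expect_true(all(unlist(gradients(matrix(7, 5, 5))) == 0))
  ramp <- matrix(rep(1:6, each = 5), 5, 6)  # I(r, c) = c
  g <- gradients(ramp)
  expect_true(all(g$gx[, 2:5] == 2))
  expect_true(all(g$gy == 0))
  set.seed(10)
  for (trial in 1:100) {
    m <- matrix(runif(25, 0, 255), 5, 5)
    o <- oracle_gradients(m)
    g <- gradients(m)
    expect_equal(g$gx, o$gx)
    expect_equal(g$gy, o$gy)
  }
  expect_error(gradients(matrix(1, 2, 2)), "3x3")
  expect_message(gradients(array(1, c(5, 5, 3))), "luminance")
})

test_that("magnitude and orientation behave on axis cases and satisfy the identity", {
  mo <- magnitude_orientation(matrix(3), matrix(4))
  expect_equal(mo$magnitude[1], 5)
  expect_equal(magnitude_orientation(matrix(1), matrix(0))$angle[1], 0)
  expect_equal(magnitude_orientation(matrix(0), matrix(1))$angle[1], 90)
  set.seed(11)
  gx <- matrix(rnorm(100), 10); gy <- matrix(rnorm(100), 10)
  mo <- magnitude_orientation(gx, gy)
  expect_equal(mo$magnitude^2, gx^2 + gy^2, tolerance = 1e-12)
  expect_true(all(mo$angle >= 0 & mo$angle < 180))
  # signed convention spans the full circle
  mos <- magnitude_orientation(gx, gy, unsigned = FALSE)
  expect_true(all(mos$angle >= 0 & mos$angle < 360))
})

test_that("HOG: degenerate cases, descriptor length, and the cell oracle", {
  cfg <- hog_config()
  expect_true(all(compute_hog(matrix(5, 8, 8), cfg) == 0))
  # vertical step edge -> all gradient orientation mass at 0 degrees (bin 1)
  edge <- matrix(0, 8, 8); edge[, 5:8] <- 255
  h <- compute_hog(edge, hog_config(block_norm = "none"))
  hm <- matrix(h, nrow = 9)  # bins x cells
  mass <- rowSums(hm)
  expect_gt(mass[1] / sum(mass), 0.999)
  # 8x8 crop, 4x4 patches, 9 bins, 2x2 blocks -> 36 features
  expect_length(compute_hog(matrix(runif(64), 8, 8), cfg), 36L)
  # default featurization crop: 16x16 cells -> 8x8 blocks of 36
  expect_length(compute_hog(matrix(runif(64 * 64), 64, 64), cfg), 2304L)
  # single-cell soft-binning oracle (no normalization)
  set.seed(12)
  for (trial in 1:100) {
    m <- matrix(runif(16, 0, 255), 4, 4)
    h1 <- compute_hog(m, hog_config(patch_size = 4, block_size_cells = 1,
                                    block_norm = "none"))
    g <- oracle_gradients(m)
    mo <- magnitude_orientation(g$gx, g$gy)
    h2 <- oracle_cell_hog(as.vector(mo$magnitude), as.vector(mo$angle), 9)
    expect_equal(h1, h2, tolerance = 1e-9)
  }
})

test_that("HOG L2 block normalization bounds the descriptor", {
  set.seed(13)
  v <- compute_hog(matrix(runif(64, 0, 255), 8, 8), hog_config())
  expect_lte(sqrt(sum(v^2)), 1 + 1e-9)  # one block, L2-normalized
  v2 <- compute_hog(matrix(runif(64, 0, 255), 8, 8),
                    hog_config(block_norm = "L2-hys"))
  expect_lte(sqrt(sum(v2^2)), 1 + 1e-9)
})

test_that("HOG 90-degree rotation permutes orientation bins (unsigned)", {
  set.seed(14)
  cfg <- hog_config(patch_size = 8, n_orientation_bins = 4,
                    block_size_cells = 1, block_norm = "none")
  for (trial in 1:20) {
    m <- matrix(runif(64, 0, 255), 8, 8)
    h <- compute_hog(m, cfg)
    hr <- compute_hog(t(m)[8:1, , drop = FALSE], cfg)  # rotate 90 degrees
    # 90 degrees = 2 bins of 45; total mass per shifted bin is preserved
    expect_equal(sort(h), sort(hr), tolerance = 1e-6)
    expect_equal(h[c(3, 4, 1, 2)], hr, tolerance = 1e-6)
  }
})

test_that("LBP code: constant window, dominant center, exact oracle", {
  expect_equal(lbp_code(matrix(5, 3, 3)), 255L)
  w <- matrix(1, 3, 3); w[2, 2] <- 9
  expect_equal(lbp_code(w), 0L)
  expect_error(lbp_code(matrix(1, 2, 2)), "3x3")
  set.seed(15)
  for (trial in 1:100) {
    win <- matrix(sample(0:255, 9, replace = TRUE), 3, 3)
    expect_identical(as.numeric(lbp_code(win)), oracle_lbp_code(win))
  }
})

test_that("LBP histogram: conservation, constant crop, exact oracle, shift invariance", {
  cfg <- lbp_config()
  h <- compute_lbp(matrix(3, 6, 6), cfg)
  expect_equal(h[256], 16)        # all interior codes are 255
  expect_equal(sum(h), 16)
  set.seed(16)
  for (trial in 1:100) {
    m <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    h <- compute_lbp(m, cfg)
    expect_equal(sum(h), 36)      # (8-2)*(8-2) interior pixels
    expect_equal(h, oracle_lbp_hist(m))
    expect_equal(compute_lbp(m + 40, cfg), h)  # intensity-shift invariance
  }
  hn <- compute_lbp(matrix(runif(64), 8, 8), lbp_config(normalize = TRUE))
  expect_equal(sum(hn), 1)
  expect_error(lbp_config(n_neighbors = 16), "8-neighbor")
})

test_that("masked LBP restricts the histogram support", {
  m <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  msk <- matrix(0L, 10, 10); msk[3:6, 3:6] <- 1L
  h <- compute_lbp(m, lbp_config(masked_only = TRUE), mask = msk)
  expect_equal(sum(h), 16)
})

test_that("diameter: exact cases, brute-force oracle, dilation monotonicity", {
  m <- matrix(0L, 6, 6); m[1, 1] <- 1L; m[4, 5] <- 1L
  expect_equal(nodule_diameter(m), 5)
  m1 <- matrix(0L, 3, 3); m1[2, 2] <- 1L
  expect_equal(nodule_diameter(m1), 0)
  expect_error(nodule_diameter(matrix(0L, 3, 3)), "no foreground")
  set.seed(17)
  for (trial in 1:100) {
    blob <- random_blob_mask()
    expect_equal(nodule_diameter(blob), oracle_diameter(blob))
    # dilate by one 4-neighbor step
    d <- blob
    d[-1, ] <- pmax(d[-1, ], blob[-nrow(blob), ])
    d[, -1] <- pmax(d[, -1], blob[, -ncol(blob)])
    expect_gte(nodule_diameter(d), nodule_diameter(blob))
  }
})

test_that("fusion concatenates, round-trips, and validates", {
  hog <- runif(36); lbp <- runif(256); geo <- 12.5
  fv <- fuse(hog, lbp, geo)
  expect_length(fv$fused, 293L)
  expect_identical(fv$fused[1:36], hog)
  expect_identical(fv$fused[37:292], lbp)
  expect_identical(fv$fused[293], geo)
  expect_error(fuse(c(hog, NA), lbp, geo), "hog")
  expect_error(fuse(hog, lbp, Inf), "geometric")
})

test_that("standardization fits on the given matrix only", {
  set.seed(18)
  X <- cbind(matrix(rnorm(200, 5, 3), 50), constant = 1)
  st <- standardize_fit(X)
  Z <- st$apply(X)
  expect_true(max(abs(colMeans(Z))) < 1e-10)
  expect_equal(unname(apply(Z[, 1:4], 2, sd)), rep(1, 4), tolerance = 1e-10)
  expect_true(all(Z[, 5] == 0))   # constant column maps to zero, not NaN
})
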