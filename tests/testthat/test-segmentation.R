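# Network contracts, training mechanics, mask prediction, region extraction
# and the segmentation metric suite.

test_that("forward pass preserves spatial dims and softmax-normalizes", {
  for (s in c(32L, 48L)) {
    net <- build_network(seg_net_config(c(s, s, 3L)), seed = 2L)
    img <- array(0, c(s, s, 3))
    pr <- focalseg:::segnet_forward(net, img)
    expect_equal(dim(pr), c(s, s, 2L))
    expect_true(max(abs(pr[, , 1] + pr[, , 2] - 1)) < 1e-6)
  }
})

test_that("odd input sizes are rejected by the config", {
  expect_error(seg_net_config(c(33L, 33L, 3L)), "divisible by 2")
  expect_error(seg_net_config(c(32L, 32L, 1L)), "c\\(H, W, 3\\)")
})

test_that("identical seeds give identical untrained networks and logits", {
  n1 <- build_network(seg_net_config(c(32L, 32L, 3L)), seed = 11L)
  n2 <- build_network(seg_net_config(c(32L, 32L, 3L)), seed = 11L)
  expect_identical(n1$params, n2$params)
  img <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  expect_identical(focalseg:::segnet_forward(n1, img),
                   focalseg:::segnet_forward(n2, img))
  n3 <- build_network(seg_net_config(c(32L, 32L, 3L)), seed = 12L)
  expect_false(identical(n1$params$conv1$w, n3$params$conv1$w))
})

test_that("first conv layer reproduces a hand-computed 3x3 convolution", {
  set.seed(4)
  img4 <- array(runif(4 * 4 * 3, 0, 255), c(4, 4, 3))
  net <- build_network(seg_net_config(c(4L, 4L, 3L)), seed = 1L)
  k <- array(rnorm(3 * 3 * 3 * 32), c(3, 3, 3, 32))
  b <- rnorm(32)
  net$params$conv1$w <- k
  net$params$conv1$b <- b
  fw <- focalseg:::segnet_forward(net, img4, cache = TRUE)
  # the input layer scales by 1/255 (channel means are zero untrained)
  expected <- oracle_conv2d(img4 / 255, k, b, stride = 1, pad = 1)
  expect_equal(fw$z1, expected, tolerance = 1e-12)
})

test_that("strided and padded convolution primitives match the oracle", {
  set.seed(8)
  for (trial in 1:10) {
    C <- sample(1:3, 1); FF <- sample(1:4, 1)
    x <- array(rnorm(6 * 6 * C), c(6, 6, C))
    k <- sample(c(1, 3, 4), 1)
    stride <- sample(1:2, 1); pad <- sample(0:1, 1)
    if ((6 + 2 * pad - k) %% stride != 0) next
    w <- array(rnorm(k * k * C * FF), c(k, k, C, FF))
    b <- rnorm(FF)
    expect_equal(focalseg:::cpp_conv2d_fwd(x, w, b, as.integer(stride),
                                           as.integer(pad)),
                 oracle_conv2d(x, w, b, stride, pad), tolerance = 1e-10)
  }
})

test_that("the 70/30 split is exact, seeded and stratified", {
  slices <- make_slices(10, seed = 5L)
  sp <- focalseg:::split_slices(slices, 0.7, seed = 3L)
  expect_length(sp$train, 7L)
  expect_length(sp$test, 3L)
  expect_identical(sort(c(sp$train, sp$test)), 1:10)
  sp2 <- focalseg:::split_slices(slices, 0.7, seed = 3L)
  expect_identical(sp, sp2)
  sp3 <- focalseg:::split_slices(slices, 0.7, seed = 4L)
  expect_false(identical(sp$train, sp3$train))
})

test_that("training rejects degenerate inputs", {
  slices <- make_slices(4, image_size = 32L, seed = 2L,
                        nodule_diameter_range_benign = c(5, 8),
                        nodule_diameter_range_malignant = c(9, 12))
  for (i in seq_along(slices)) slices[[i]]$mask[] <- 0L
  net <- build_network(seg_net_config(c(32L, 32L, 3L)))
  expect_error(train_segnet(net, slices, train_config(epochs = 1L)), "nodule")
  expect_error(train_segnet(net, list(slices[[1]]), train_config()), "at least 2")
  expect_error(train_config(train_fraction = 1.3), "train_fraction")
})

test_that("predict_mask arg-maxes with ties to background", {
  net <- build_network(seg_net_config(c(32L, 32L, 3L)), seed = 1L)
  # zero all weights: logits identical -> tie everywhere -> background
  for (nm in names(net$params)) {
    net$params[[nm]]$w[] <- 0
    net$params[[nm]]$b[] <- 0
  }
  img <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  pm <- predict_mask(net, img)
  expect_true(all(pm == 0L))
  # biasing the nodule logit flips every pixel
  net$params$conv5$b <- c(0, 1)
  expect_true(all(predict_mask(net, img) == 1L))
  expect_error(predict_mask(net, array(0, c(16, 16, 3))), "expects 32x32")
})

test_that("extract_nodule_regions finds components with correct extents", {
  mask <- matrix(0L, 64, 64)
  rr <- matrix(seq_len(64), 64, 64); cc <- t(rr)
  mask[(rr - 20)^2 + (cc - 20)^2 <= 100] <- 1L  # disc radius 10
  mask[(rr - 48)^2 + (cc - 48)^2 <= 25] <- 1L   # disc radius 5
  img <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  regs <- extract_nodule_regions(img, mask)
  expect_length(regs, 2L)
  bb <- regs[[1]]$bounding_box
  side <- max(bb[3] - bb[1], bb[4] - bb[2]) + 1
  expect_gte(side, 20); expect_lte(side, 22)
  expect_equal(dim(regs[[1]]$crop), c(64L, 64L))
  expect_true(all(regs[[1]]$crop_mask %in% c(0L, 1L)))
  # empty mask -> empty list; tiny specks below min_area are dropped
  expect_length(extract_nodule_regions(img, matrix(0L, 64, 64)), 0L)
  speck <- matrix(0L, 64, 64); speck[5, 5] <- 1L
  expect_length(extract_nodule_regions(img, speck, min_area = 9L), 0L)
})

test_that("seg metrics: perfect, complement and bounds", {
  t <- matrix(0L, 16, 16); t[4:9, 5:11] <- 1L
  m <- compute_seg_metrics(t, t)
  expect_equal(m$global_accuracy, 1)
  expect_equal(m$mean_accuracy, 1)
  expect_equal(m$mean_iou, 1)
  expect_equal(m$weighted_iou, 1)
  expect_equal(m$mean_bf_score, 1)
  mc <- compute_seg_metrics(1L - t, t)
  expect_equal(mc$global_accuracy, 0)
  expect_error(compute_seg_metrics(t, matrix(0L, 8, 8)), "shapes differ")
  expect_error(compute_seg_metrics(t * 2L, t), "binary")
})

test_that("seg metrics equal the per-pixel enumeration on random masks", {
  set.seed(42)
  for (trial in 1:100) {
    p <- matrix(rbinom(256, 1, runif(1, 0.1, 0.9)), 16, 16)
    t <- matrix(rbinom(256, 1, runif(1, 0.1, 0.9)), 16, 16)
    m <- compute_seg_metrics(p, t)
    o <- oracle_seg_metrics(as.vector(p), as.vector(t))
    expect_equal(m$global_accuracy, o$global)
    expect_equal(m$mean_accuracy, o$mean_acc)
    expect_equal(m$mean_iou, o$mean_iou)
    expect_equal(m$weighted_iou, o$weighted_iou)
    ious <- m$per_class_iou[!is.na(m$per_class_iou)]
    expect_gte(m$weighted_iou + 1e-12, min(ious))
    expect_lte(m$weighted_iou - 1e-12, max(ious))
    expect_true(all(unlist(m[c("global_accuracy", "mean_accuracy", "mean_iou",
                               "weighted_iou", "mean_bf_score")]) >= 0))
    expect_true(all(unlist(m[c("global_accuracy", "mean_accuracy", "mean_iou",
                               "weighted_iou", "mean_bf_score")]) <= 1))
  }
})

test_that("network checkpoints round-trip", {
  td <- withr::local_tempdir()
  net <- build_network(seg_net_config(c(32L, 32L, 3L)), seed = 6L)
  p <- file.path(td, "net.ckpt")
  save_network(net, p)
  expect_identical(load_network(p), net)
  saveRDS(list(a = 1), file.path(td, "junk.rds"))
  expect_error(load_network(file.path(td, "junk.rds")), "checkpoint")
})
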