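# Compact encoder-decoder semantic segmentation network for nodule vs
# background pixel classification.  Fixed 14-unit stack: image input
# (zero-center), three 3x3/32 conv+ReLU blocks, 2x2 max-pool, one more
# 3x3/32 conv+ReLU, a 4x4/32 stride-2 transposed convolution (crop 1 on
# each border) that restores the input resolution, a 1x1/2 conv, softmax,
# and a weighted pixel-classification (cross-entropy) loss.
#
# The transposed convolution is computed as the exact adjoint of a
# stride-2 4x4 convolution, which is the only reading of "cropping
# [1 1 1 1]" under which the x2 up-sample exactly inverts the x2 pool.

#' Segmentation network configuration
#'
#' The layer stack is fixed; only the input size is configurable.  Height
#' and width must be even (one 2x pool / 2x up-sample pair).
#'
#' @param input_size `c(H, W, 3)`.
#' @return An object of class `seg_net_config`.
#' @export
seg_net_config <- function(input_size = c(128L, 128L, 3L)) {
  if (length(input_size) != 3 || input_size[3] != 3)
    stopf("input_size must be c(H, W, 3)")
  if (any(input_size[1:2] %% 2 != 0))
    stopf("input height/width must be divisible by 2 (pool/up-sample pair), got %dx%d",
          input_size[1], input_size[2])
  structure(list(
    input_size = as.integer(input_size),
    n_classes = 2L,
    layers = c("image-input (zero-center)",
               "conv 3x3x32 s1 p1 + ReLU",
               "conv 3x3x32 s1 p1 + ReLU",
               "conv 3x3x32 s1 p1 + ReLU",
               "maxpool 2x2 s2",
               "conv 3x3x32 s1 p1 + ReLU",
               "transposed-conv 4x4x32 s2 crop1",
               "conv 1x1x2 s1 p0",
               "softmax",
               "pixel-classification")
  ), class = "seg_net_config")
}

#' @export
print.seg_net_config <- function(x, ...) {
  cat("<seg_net_config> input", paste(x$input_size, collapse = "x"), "\n")
  for (l in x$layers) cat("  -", l, "\n")
  invisible(x)
}

he_init <- function(dims) {
  fan_in <- prod(dims[1:3])
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

#' Build an untrained segmentation network
#'
#' Weights use He initialization under the given seed; the zero-center
#' channel means start at zero and are set from the training set by
#' [train_segnet()].
#'
#' @param config a [seg_net_config()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `seg_network`.
#' @export
build_network <- function(config = seg_net_config(), seed = 1L) {
  if (!inherits(config, "seg_net_config")) stopf("config must be a seg_net_config")
  with_local_seed(derive_seed(seed, 4242L), {
    params <- list(
      conv1 = list(w = he_init(c(3, 3, 3, 32)), b = numeric(32)),
      conv2 = list(w = he_init(c(3, 3, 32, 32)), b = numeric(32)),
      conv3 = list(w = he_init(c(3, 3, 32, 32)), b = numeric(32)),
      conv4 = list(w = he_init(c(3, 3, 32, 32)), b = numeric(32)),
      # transposed conv: kernel indexed (4, 4, C_out = 32, C_in = 32)
      deconv = list(w = he_init(c(4, 4, 32, 32)), b = numeric(32)),
      conv5 = list(w = he_init(c(1, 1, 32, 2)), b = numeric(2))
    )
    structure(list(config = config, params = params,
                   channel_means = numeric(3), version = 1L),
              class = "seg_network")
  })
}

#' @export
print.seg_network <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$w) + length(p$b), numeric(1)))
  cat("<seg_network>", paste(x$config$input_size, collapse = "x"), "input,",
      format(np, big.mark = ","), "parameters\n")
  invisible(x)
}

relu <- function(x) { x[x < 0] <- 0; x }

# softmax over the 3rd (class) dimension of an (H, W, K) array
softmax_hw <- function(z) {
  zm <- pmax(z[, , 1], z[, , 2])
  e1 <- exp(z[, , 1] - zm); e2 <- exp(z[, , 2] - zm)
  s <- e1 + e2
  array(c(e1 / s, e2 / s), dim = dim(z))
}

# forward pass; with cache = TRUE returns intermediates for backprop.
# The input layer zero-centers with the training-set channel means and
# scales by 1/255 so activations are O(1) (raw 8-bit inputs saturate the
# softmax at He initialization and destabilize SGD).
segnet_forward <- function(net, image, cache = FALSE) {
  p <- net$params
  x0 <- array(as.numeric(image), dim = dim(image))
  for (ch in 1:3) x0[, , ch] <- (x0[, , ch] - net$channel_means[ch]) / 255
  z1 <- cpp_conv2d_fwd(x0, p$conv1$w, p$conv1$b, 1L, 1L); a1 <- relu(z1)
  z2 <- cpp_conv2d_fwd(a1, p$conv2$w, p$conv2$b, 1L, 1L); a2 <- relu(z2)
  z3 <- cpp_conv2d_fwd(a2, p$conv3$w, p$conv3$b, 1L, 1L); a3 <- relu(z3)
  pl <- cpp_maxpool_fwd(a3, 2L, 2L)
  z4 <- cpp_conv2d_fwd(pl$y, p$conv4$w, p$conv4$b, 1L, 1L); a4 <- relu(z4)
  # transposed conv: adjoint of a stride-2 4x4 conv, then per-channel bias
  H <- dim(a3)[1]; W <- dim(a3)[2]
  u <- cpp_conv2d_bwd_input(p$deconv$w, a4, H, W, 2L, 1L)
  u <- sweep(u, 3, p$deconv$b, "+")
  z5 <- cpp_conv2d_fwd(u, p$conv5$w, p$conv5$b, 1L, 0L)
  probs <- softmax_hw(z5)
  if (!cache) return(probs)
  list(probs = probs, x0 = x0, z1 = z1, a1 = a1, z2 = z2, a2 = a2, z3 = z3,
       a3 = a3, pool = pl, z4 = z4, a4 = a4, u = u, z5 = z5)
}

# Weighted pixel-wise cross-entropy loss and its gradient at the logits.
# truth: (H, W) in {0,1}; class_w: weights for (background, nodule).
segnet_loss_grad <- function(fw, truth, class_w) {
  p1 <- fw$probs[, , 2]          # nodule probability
  y <- truth
  wpix <- ifelse(y == 1L, class_w[2], class_w[1])
  norm <- sum(wpix)
  eps <- 1e-12
  loss <- -sum(wpix * ifelse(y == 1L, log(p1 + eps), log(1 - p1 + eps))) / norm
  # d loss / d z  (softmax + CE): (p - onehot) * w / norm
  g <- array(0, dim = dim(fw$probs))
  g[, , 1] <- (fw$probs[, , 1] - (y == 0L)) * wpix / norm
  g[, , 2] <- (fw$probs[, , 2] - (y == 1L)) * wpix / norm
  list(loss = loss, gz5 = g)
}

segnet_backward <- function(net, fw, gz5) {
  p <- net$params
  g <- list()
  # conv5 (1x1)
  bf <- cpp_conv2d_bwd_filter(fw$u, gz5, 1L, 1L, 1L, 0L)
  g$conv5 <- list(w = bf$gw, b = bf$gb)
  gu <- cpp_conv2d_bwd_input(p$conv5$w, gz5, dim(fw$u)[1], dim(fw$u)[2], 1L, 0L)
  # transposed conv: forward was adjoint-of-conv, so input grad is the conv
  g$deconv <- list(b = apply(gu, 3, sum))
  bf <- cpp_conv2d_bwd_filter(gu, fw$a4, 4L, 4L, 2L, 1L)
  g$deconv$w <- bf$gw
  ga4 <- cpp_conv2d_fwd(gu, p$deconv$w, numeric(32), 2L, 1L)
  gz4 <- ga4 * (fw$z4 > 0)
  bf <- cpp_conv2d_bwd_filter(fw$pool$y, gz4, 3L, 3L, 1L, 1L)
  g$conv4 <- list(w = bf$gw, b = bf$gb)
  gpool <- cpp_conv2d_bwd_input(p$conv4$w, gz4, dim(fw$pool$y)[1],
                                dim(fw$pool$y)[2], 1L, 1L)
  ga3 <- cpp_maxpool_bwd(gpool, fw$pool$argmax, dim(fw$a3)[1], dim(fw$a3)[2],
                         dim(fw$a3)[3])
  gz3 <- ga3 * (fw$z3 > 0)
  bf <- cpp_conv2d_bwd_filter(fw$a2, gz3, 3L, 3L, 1L, 1L)
  g$conv3 <- list(w = bf$gw, b = bf$gb)
  ga2 <- cpp_conv2d_bwd_input(p$conv3$w, gz3, dim(fw$a2)[1], dim(fw$a2)[2], 1L, 1L)
  gz2 <- ga2 * (fw$z2 > 0)
  bf <- cpp_conv2d_bwd_filter(fw$a1, gz2, 3L, 3L, 1L, 1L)
  g$conv2 <- list(w = bf$gw, b = bf$gb)
  ga1 <- cpp_conv2d_bwd_input(p$conv2$w, gz2, dim(fw$a1)[1], dim(fw$a1)[2], 1L, 1L)
  gz1 <- ga1 * (fw$z1 > 0)
  bf <- cpp_conv2d_bwd_filter(fw$x0, gz1, 3L, 3L, 1L, 1L)
  g$conv1 <- list(w = bf$gw, b = bf$gb)
  g
}

#' Training configuration for the segmentation network
#'
#' @param train_fraction fraction of slices used for training (0, 1).
#' @param epochs training epochs.
#' @param learning_rate SGD learning rate.
#' @param batch_size mini-batch size (gradients averaged over the batch).
#' @param class_weighting `"inverse-frequency"` (default; nodule pixels are
#'   a small minority) or `"none"`.
#' @param momentum classical momentum coefficient.
#' @param seed integer seed controlling the split, shuffling and weight
#'   initialization.
#' @export
train_config <- function(train_fraction = 0.7, epochs = 30L,
                         learning_rate = 1e-3, batch_size = 4L,
                         class_weighting = c("inverse-frequency", "none"),
                         momentum = 0.9, seed = 1L) {
  check_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("field 'train_fraction' must be strictly between 0 and 1, got %s",
          train_fraction)
  check_number(epochs, "epochs", min = 1, integer = TRUE)
  check_number(learning_rate, "learning_rate", min = 1e-12)
  check_number(batch_size, "batch_size", min = 1, integer = TRUE)
  check_number(momentum, "momentum", min = 0, max = 1)
  check_number(seed, "seed", integer = TRUE)
  structure(list(train_fraction = train_fraction, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 class_weighting = match.arg(class_weighting),
                 momentum = momentum, seed = as.integer(seed)),
            class = "train_config")
}

# 70/30-style split by slice, stratified on "slice contains >= 1 malignant
# nodule" with largest-remainder rounding so the total train count is
# exactly round(fraction * n).
split_slices <- function(slices, train_fraction, seed) {
  n <- length(slices)
  has_mal <- vapply(slices, function(s) {
    !is.null(s$nodules) && any(s$nodules$class == "malignant")
  }, logical(1))
  n_train <- round(train_fraction * n)
  idx_by <- split(seq_len(n), has_mal)
  quota <- vapply(idx_by, function(ix) train_fraction * length(ix), numeric(1))
  take <- floor(quota)
  rem <- quota - take
  short <- n_train - sum(take)
  if (short > 0) {
    ord <- order(rem, decreasing = TRUE)
    take[ord[seq_len(short)]] <- take[ord[seq_len(short)]] + 1
  }
  train_idx <- integer(0)
  with_local_seed(derive_seed(seed, 77L), {
    for (g in seq_along(idx_by)) {
      ix <- idx_by[[g]]
      k <- min(length(ix), take[g])
      train_idx <- c(train_idx, sample(ix, k))
    }
    # largest-remainder may still over/under-shoot when a stratum is tiny
    extra <- n_train - length(train_idx)
    pool <- setdiff(seq_len(n), train_idx)
    if (extra > 0) train_idx <- c(train_idx, sample(pool, extra))
  })
  train_idx <- sort(train_idx)
  list(train = train_idx, test = setdiff(seq_len(n), train_idx))
}

#' Train the segmentation network
#'
#' Splits slices 70/30 (by slice, stratified on malignant content), sets the
#' zero-center channel means from the training images, and optimizes the
#' class-weighted pixel cross-entropy with SGD + momentum.
#'
#' @param network a [build_network()] result.
#' @param slices list of `labeled_slice` objects (or lists with `image` and
#'   `mask`).
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return A list with `network` (trained), `history` (data frame
#'   `epoch,loss,val_iou`), `metrics` (held-out [compute_seg_metrics()]
#'   pooled over test slices) and `split`.
#' @export
train_segnet <- function(network, slices, cfg = train_config(), verbose = FALSE) {
  if (!inherits(network, "seg_network")) stopf("network must be a seg_network")
  if (length(slices) < 2) stopf("need at least 2 slices to split")
  sp <- split_slices(slices, cfg$train_fraction, cfg$seed)
  train_set <- slices[sp$train]; test_set <- slices[sp$test]

  n_nod <- sum(vapply(train_set, function(s) sum(s$mask == 1L), numeric(1)))
  n_bg <- sum(vapply(train_set, function(s) sum(s$mask == 0L), numeric(1)))
  if (n_nod == 0) stopf("class 'nodule' absent from training pixels")
  if (n_bg == 0) stopf("class 'background' absent from training pixels")
  class_w <- if (cfg$class_weighting == "inverse-frequency") {
    f <- c(n_bg, n_nod) / (n_bg + n_nod)
    w <- 1 / f; w / mean(w)
  } else c(1, 1)

  ch_means <- rowMeans(vapply(train_set, function(s)
    apply(s$image, 3, mean), numeric(3)))
  network$channel_means <- as.numeric(ch_means)

  vel <- lapply(network$params, function(p)
    list(w = array(0, dim = dim(p$w)), b = numeric(length(p$b))))

  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_iou = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_local_seed(derive_seed(cfg$seed, 1000L + ep),
                           sample(length(train_set)))
    ep_loss <- 0
    nb <- 0
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      bidx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      acc <- NULL
      bloss <- 0
      for (i in bidx) {
        fw <- segnet_forward(network, train_set[[i]]$image, cache = TRUE)
        lg <- segnet_loss_grad(fw, train_set[[i]]$mask, class_w)
        bloss <- bloss + lg$loss
        g <- segnet_backward(network, fw, lg$gz5)
        if (is.null(acc)) acc <- g
        else for (nm in names(g)) {
          acc[[nm]]$w <- acc[[nm]]$w + g[[nm]]$w
          acc[[nm]]$b <- acc[[nm]]$b + g[[nm]]$b
        }
      }
      k <- length(bidx)
      for (nm in names(network$params)) {
        vel[[nm]]$w <- cfg$momentum * vel[[nm]]$w -
          cfg$learning_rate * acc[[nm]]$w / k
        vel[[nm]]$b <- cfg$momentum * vel[[nm]]$b -
          cfg$learning_rate * acc[[nm]]$b / k
        network$params[[nm]]$w <- network$params[[nm]]$w + vel[[nm]]$w
        network$params[[nm]]$b <- network$params[[nm]]$b + vel[[nm]]$b
      }
      ep_loss <- ep_loss + bloss
      nb <- nb + k
    }
    val_iou <- if (length(test_set)) {
      mean(vapply(test_set, function(s) {
        pm <- predict_mask(network, s$image)
        compute_seg_metrics(pm, s$mask)$mean_iou
      }, numeric(1)))
    } else NA_real_
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / nb,
                                         val_iou = val_iou))
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f  val mean IoU %.3f",
                      ep, cfg$epochs, ep_loss / nb, val_iou))
  }

  metrics <- if (length(test_set)) {
    pooled_seg_metrics(lapply(test_set, function(s)
      predict_mask(network, s$image)), lapply(test_set, `[[`, "mask"))
  } else NULL
  list(network = network, history = history, metrics = metrics, split = sp)
}

#' Predict a binary nodule mask
#'
#' Arg-max over the two softmax channels; ties go to background (class 0).
#'
#' @param network a trained `seg_network`.
#' @param image (H, W, 3) array matching the configured input size.
#' @return (H, W) integer matrix in \{0, 1\}.
#' @export
predict_mask <- function(network, image) {
  sz <- network$config$input_size
  if (!all(dim(image)[1:2] == sz[1:2]))
    stopf("image is %dx%d but network expects %dx%d", dim(image)[1],
          dim(image)[2], sz[1], sz[2])
  pr <- segnet_forward(network, image)
  matrix(as.integer(pr[, , 2] > pr[, , 1]), dim(image)[1], dim(image)[2])
}

#' Extract per-nodule regions from a mask
#'
#' One region per 8-connected foreground component with area >= `min_area`.
#' The crop is the component bounding box padded by `pad` pixels (clamped to
#' the image) and resized to `crop_size` x `crop_size` (bilinear for the
#' image, nearest-neighbor for the mask).
#'
#' @param image (H, W, 3) array or (H, W) matrix.
#' @param mask (H, W) binary matrix.
#' @param min_area minimum component area in pixels.
#' @param crop_size output side length for featurization.
#' @param pad bounding-box padding in pixels.
#' @return List of regions: `crop` (crop_size^2 matrix), `crop_mask`,
#'   `bounding_box` (`c(row0, col0, row1, col1)`), `centroid`, `area`.
#' @export
extract_nodule_regions <- function(image, mask, min_area = 9L,
                                   crop_size = 64L, pad = 2L) {
  gray <- as_gray(image)
  if (!all(dim(gray) == dim(mask))) stopf("image and mask dimensions differ")
  lab <- label_components(mask, connectivity = 8)
  k <- max(lab)
  out <- list()
  for (comp in seq_len(k)) {
    w <- which(lab == comp, arr.ind = TRUE)
    if (nrow(w) < min_area) next
    r0 <- max(1L, min(w[, 1]) - pad); r1 <- min(nrow(mask), max(w[, 1]) + pad)
    c0 <- max(1L, min(w[, 2]) - pad); c1 <- min(ncol(mask), max(w[, 2]) + pad)
    crop <- resize_bilinear(gray[r0:r1, c0:c1, drop = FALSE], crop_size, crop_size)
    cmask <- resize_nearest((lab[r0:r1, c0:c1, drop = FALSE] == comp) * 1L,
                            crop_size, crop_size)
    out[[length(out) + 1L]] <- list(
      crop = crop, crop_mask = cmask,
      # component mask at native resolution: geometric measurements must
      # not be taken on the resized crop (resizing destroys scale)
      native_mask = (lab[r0:r1, c0:c1, drop = FALSE] == comp) * 1L,
      bounding_box = c(min(w[, 1]), min(w[, 2]), max(w[, 1]), max(w[, 2])),
      centroid = c(mean(w[, 1]), mean(w[, 2])), area = nrow(w))
  }
  out
}

#' Save / load a segmentation network checkpoint
#'
#' Single-file checkpoint with a version header.
#' @param network a `seg_network`.
#' @param path checkpoint path.
#' @export
save_network <- function(network, path) {
  stopifnot(inherits(network, "seg_network"))
  saveRDS(list(format = "focalseg-segnet", version = network$version,
               network = network), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "focalseg-segnet"))
    stopf("'%s' is not a focalseg network checkpoint", path)
  obj$network
}
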