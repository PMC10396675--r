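# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately share no code with the package implementation.

# plain double-loop 2-d convolution (stride/pad), single channel set
oracle_conv2d <- function(x, w, b, stride, pad) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; FF <- dim(w)[4]
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, C))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  y <- array(0, c(Ho, Wo, FF))
  for (f in seq_len(FF)) for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    s <- 0
    for (cc in seq_len(C)) for (di in seq_len(kh)) for (dj in seq_len(kw))
      s <- s + xp[(i - 1) * stride + di, (j - 1) * stride + dj, cc] *
        w[di, dj, cc, f]
    y[i, j, f] <- s + b[f]
  }
  y
}

# central-difference gradients with replicated edges, elementwise
oracle_gradients <- function(m) {
  h <- nrow(m); w <- ncol(m)
  gx <- gy <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    gx[r, c] <- m[r, min(c + 1, w)] - m[r, max(c - 1, 1)]
    gy[r, c] <- m[min(r + 1, h), c] - m[max(r - 1, 1), c]
  }
  list(gx = gx, gy = gy)
}

# 8-step manual threshold-and-sum enumeration of the LBP code
oracle_lbp_code <- function(win) {
  ctr <- win[2, 2]
  offs <- list(c(1, 1), c(1, 2), c(1, 3), c(2, 3), c(3, 3), c(3, 2),
               c(3, 1), c(2, 1))
  code <- 0
  for (n in seq_along(offs)) {
    v <- win[offs[[n]][1], offs[[n]][2]]
    if (v - ctr >= 0) code <- code + 2^(n - 1)
  }
  code
}

oracle_lbp_hist <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- numeric(256)
  for (r in 2:(h - 1)) for (c in 2:(w - 1)) {
    code <- oracle_lbp_code(m[(r - 1):(r + 1), (c - 1):(c + 1)])
    out[code + 1] <- out[code + 1] + 1
  }
  out
}

# O(n^2) max pairwise distance over ALL foreground pixels (no hull)
oracle_diameter <- function(mask) {
  pts <- which(mask == 1, arr.ind = TRUE)
  if (nrow(pts) < 2) return(0)
  best <- 0
  for (i in seq_len(nrow(pts) - 1)) for (j in (i + 1):nrow(pts)) {
    d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    if (d > best) best <- d
  }
  best
}

# literal per-pixel enumeration of the non-boundary segmentation metrics
oracle_seg_metrics <- function(pred, truth) {
  n <- length(truth)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    else if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  rec <- c(); iou <- c(); wiou <- 0
  # class 0 (background)
  if (tn + fp > 0) {
    rec <- c(rec, tn / (tn + fp))
  }
  if (tn + fp + fn > 0) iou <- c(iou, i0 <- tn / (tn + fp + fn))
  # class 1 (nodule)
  if (tp + fn > 0) rec <- c(rec, tp / (tp + fn))
  if (tp + fp + fn > 0) iou <- c(iou, i1 <- tp / (tp + fp + fn))
  w0 <- (tn + fp) / n; w1 <- (tp + fn) / n
  wiou <- 0
  if (w0 > 0) wiou <- wiou + w0 * tn / (tn + fp + fn)
  if (w1 > 0) wiou <- wiou + w1 * tp / (tp + fp + fn)
  list(global = (tp + tn) / n, mean_acc = mean(rec), mean_iou = mean(iou),
       weighted_iou = wiou)
}

# single-cell HOG oracle: magnitude-weighted soft binning between the two
# nearest centers at multiples of (period / nbins)
oracle_cell_hog <- function(mag, ang, nbins, period = 180) {
  width <- period / nbins
  h <- numeric(nbins)
  for (i in seq_along(mag)) {
    pos <- (ang[i] %% period) / width
    b0 <- floor(pos); fr <- pos - b0
    h[(b0 %% nbins) + 1] <- h[(b0 %% nbins) + 1] + mag[i] * (1 - fr)
    h[((b0 + 1) %% nbins) + 1] <- h[((b0 + 1) %% nbins) + 1] + mag[i] * fr
  }
  h
}

random_blob_mask <- function(n = 12, npix = 30) {
  m <- matrix(0L, n, n)
  ctr <- c(sample(4:(n - 3), 1), sample(4:(n - 3), 1))
  m[ctr[1], ctr[2]] <- 1L
  while (sum(m) < npix) {
    pts <- which(m == 1L, arr.ind = TRUE)
    p <- pts[sample(nrow(pts), 1), ]
    q <- p + sample(c(-1L, 0L, 1L), 2, replace = TRUE)
    if (all(q >= 1) && all(q <= n)) m[q[1], q[2]] <- 1L
  }
  m
}

make_slices <- function(n, ...) {
  spec <- phantom_spec(n_slices = n, ...)
  lapply(seq_len(n) - 1L, function(i) generate_slice(spec, i))
}
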