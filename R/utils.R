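# Internal helpers shared across modules: scoped RNG, seed derivation,
# image resizing, connected-component labeling, and small validators.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.  All stochastic operations in the package go through this.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministically derive a sub-seed from a master seed and an index,
# keeping the result a valid 32-bit R integer.
derive_seed <- function(seed, index) {
  s <- (abs(as.numeric(seed)) %% 1000003) * 2011 + abs(as.numeric(index)) * 7919
  as.integer(s %% 2147483587 + 1)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, field, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("field '%s' must be a single finite number", field)
  if (integer && x != round(x))
    stopf("field '%s' must be an integer", field)
  if (x < min || x > max)
    stopf("field '%s' must be in [%s, %s], got %s", field, min, max, x)
  invisible(x)
}

# Bilinear resize of a 2-d matrix (used for intensity images).
resize_bilinear <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  if (h == out_h && w == out_w) return(m)
  # map output pixel centers into input pixel-center coordinates
  ri <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  ci <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  ri <- pmin(pmax(ri, 1), h); ci <- pmin(pmax(ci, 1), w)
  r0 <- pmin(floor(ri), h - 1L); c0 <- pmin(floor(ci), w - 1L)
  fr <- ri - r0; fc <- ci - c0
  a <- m[r0, c0, drop = FALSE]; b <- m[r0 + 1, c0, drop = FALSE]
  d <- m[r0, c0 + 1, drop = FALSE]; e <- m[r0 + 1, c0 + 1, drop = FALSE]
  wr <- matrix(fr, out_h, out_w); wc <- matrix(fc, out_h, out_w, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * wr * (1 - wc) + d * (1 - wr) * wc + e * wr * wc
}

# Nearest-neighbor resize (used for masks so labels stay binary).
resize_nearest <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  if (h == out_h && w == out_w) return(m)
  ri <- pmin(pmax(ceiling((seq_len(out_h) - 0.5) * h / out_h), 1), h)
  ci <- pmin(pmax(ceiling((seq_len(out_w) - 0.5) * w / out_w), 1), w)
  m[ri, ci, drop = FALSE]
}

# Label connected components of a binary matrix (8- or 4-connectivity).
# Two-pass union-find; returns an integer matrix of labels (0 = background).
label_components <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find_root <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nxt <- 0L
  for (cc in seq_len(w)) {
    for (rr in seq_len(h)) {
      if (mask[rr, cc] == 0) next
      nb <- integer(0)
      if (rr > 1 && lab[rr - 1, cc] > 0) nb <- c(nb, lab[rr - 1, cc])
      if (cc > 1 && lab[rr, cc - 1] > 0) nb <- c(nb, lab[rr, cc - 1])
      if (connectivity == 8 && cc > 1) {
        if (rr > 1 && lab[rr - 1, cc - 1] > 0) nb <- c(nb, lab[rr - 1, cc - 1])
        if (rr < h && lab[rr + 1, cc - 1] > 0) nb <- c(nb, lab[rr + 1, cc - 1])
      }
      if (length(nb) == 0) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[rr, cc] <- nxt
      } else {
        roots <- vapply(unique(nb), find_root, integer(1))
        r0 <- min(roots)
        lab[rr, cc] <- r0
        for (r in roots) parent[r] <- r0
      }
    }
  }
  if (nxt == 0L) return(lab)
  # flatten and relabel 1..K
  roots <- vapply(seq_len(nxt), find_root, integer(1))
  remap <- integer(nxt)
  remap[sort(unique(roots))] <- seq_along(unique(roots))
  pos <- lab > 0
  lab[pos] <- remap[roots[lab[pos]]]
  lab
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# luminance plane of an (H, W, 3) array or pass-through for matrices
as_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3) return(apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean))
  stopf("expected a matrix or (H, W, C) array")
}
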