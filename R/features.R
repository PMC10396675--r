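# Handcrafted nodule descriptors, implemented from first principles:
# magnitude-weighted orientation histograms (HOG) over small patches with
# block-wise normalization, 8-neighbor local binary patterns, and the
# convex-hull caliper diameter.  These are the discriminative features the
# downstream classifier bank consumes.

#' HOG configuration
#'
#' @param patch_size cell side in pixels (default 4).
#' @param n_orientation_bins orientation bins (default 9).
#' @param signed_orientation use 0-360 degrees if `TRUE`; default unsigned
#'   (0-180).
#' @param block_size_cells cells per block side (blocks are square).
#' @param block_norm `"L2"`, `"L2-hys"` or `"none"`.
#' @param block_stride_cells stride between blocks in cells; defaults to
#'   `block_size_cells` (non-overlapping tiling, which keeps the descriptor
#'   compact); set to 1 for classic overlapping blocks.
#' @export
hog_config <- function(patch_size = 4L, n_orientation_bins = 9L,
                       signed_orientation = FALSE, block_size_cells = 2L,
                       block_norm = c("L2", "L2-hys", "none"),
                       block_stride_cells = NULL) {
  check_number(patch_size, "patch_size", min = 2, integer = TRUE)
  check_number(n_orientation_bins, "n_orientation_bins", min = 2, integer = TRUE)
  check_number(block_size_cells, "block_size_cells", min = 1, integer = TRUE)
  if (is.null(block_stride_cells)) block_stride_cells <- block_size_cells
  check_number(block_stride_cells, "block_stride_cells", min = 1, integer = TRUE)
  structure(list(patch_size = as.integer(patch_size),
                 n_orientation_bins = as.integer(n_orientation_bins),
                 signed_orientation = isTRUE(signed_orientation),
                 block_size_cells = as.integer(block_size_cells),
                 block_norm = match.arg(block_norm),
                 block_stride_cells = as.integer(block_stride_cells)),
            class = "hog_config")
}

#' LBP configuration
#'
#' The canonical 8-neighbor, radius-1 local binary pattern; codes lie in
#' 0..255 and the descriptor is their 256-bin histogram.
#'
#' @param normalize return frequencies instead of counts.
#' @param masked_only histogram only interior pixels with mask == 1 when a
#'   mask is supplied to [compute_lbp()].
#' @param n_neighbors,radius fixed at 8 and 1 (the canonical 3x3 code);
#'   other values are rejected.
#' @export
lbp_config <- function(normalize = FALSE, masked_only = FALSE,
                       n_neighbors = 8L, radius = 1L) {
  if (n_neighbors != 8L || radius != 1L)
    stopf("only the 8-neighbor, radius-1 LBP is implemented")
  structure(list(n_neighbors = 8L, radius = 1L,
                 normalize = isTRUE(normalize),
                 masked_only = isTRUE(masked_only)),
            class = "lbp_config")
}

#' Image gradients by central differences
#'
#' `Gx(r,c) = I(r,c+1) - I(r,c-1)` and `Gy(r,c) = I(r+1,c) - I(r-1,c)` with
#' replicated edges.  Multi-channel input is reduced to luminance first.
#'
#' @param crop single-channel matrix (>= 3x3) or (H, W, C) array.
#' @return `list(gx, gy)` of matrices.
#' @export
gradients <- function(crop) {
  if (!is.matrix(crop)) {
    message("gradients: multi-channel input converted to luminance")
    crop <- as_gray(crop)
  }
  if (nrow(crop) < 3 || ncol(crop) < 3) stopf("crop must be at least 3x3")
  h <- nrow(crop); w <- ncol(crop)
  left <- cbind(crop[, 1, drop = FALSE], crop[, -w, drop = FALSE])
  right <- cbind(crop[, -1, drop = FALSE], crop[, w, drop = FALSE])
  up <- rbind(crop[1, , drop = FALSE], crop[-h, , drop = FALSE])
  down <- rbind(crop[-1, , drop = FALSE], crop[h, , drop = FALSE])
  list(gx = right - left, gy = down - up)
}

#' Gradient magnitude and orientation
#'
#' Magnitude is `sqrt(gx^2 + gy^2)`; the angle is the quadrant-aware
#' arctangent `atan2(gy, gx)` in degrees, folded to \[0, 180) for the
#' unsigned convention.  `transposed_angle = TRUE` reproduces the
#' `atan(gx/gy)` variant (axes swapped, a 90-degree relabeling of bins).
#'
#' @param gx,gy equal-shaped gradient matrices.
#' @param unsigned fold angles to \[0, 180).
#' @param transposed_angle use `atan2(gx, gy)` instead of `atan2(gy, gx)`.
#' @return `list(magnitude, angle)` (angle in degrees).
#' @export
magnitude_orientation <- function(gx, gy, unsigned = TRUE,
                                  transposed_angle = FALSE) {
  if (!all(dim(gx) == dim(gy))) stopf("gx and gy shapes differ")
  mag <- sqrt(gx^2 + gy^2)
  ang <- if (transposed_angle) atan2(gx, gy) else atan2(gy, gx)
  ang <- ang * 180 / pi
  ang <- if (unsigned) ang %% 180 else ang %% 360
  list(magnitude = mag, angle = ang)
}

# soft-assign magnitudes to orientation bins with centers at
# b * (period / nbins), b = 0..nbins-1, wrapping at the period
orientation_histogram <- function(mag, ang, nbins, period) {
  width <- period / nbins
  pos <- ang / width                 # fractional bin position
  b0 <- floor(pos)
  frac <- pos - b0
  b0 <- as.integer(b0 %% nbins)
  b1 <- as.integer((b0 + 1L) %% nbins)
  h <- numeric(nbins)
  for (b in seq_len(nbins) - 1L) {
    h[b + 1L] <- sum(mag[b0 == b] * (1 - frac[b0 == b])) +
      sum(mag[b1 == b] * frac[b1 == b])
  }
  h
}

#' Histogram of oriented gradients
#'
#' Gradients by central difference, magnitude-weighted soft binning into
#' orientation bins per `patch_size` cell (linear interpolation between the
#' two nearest bin centers, centers at multiples of the bin width), and
#' block-wise normalization over `block_size_cells` x `block_size_cells`
#' cell groups, concatenated in row-major block order.
#'
#' @param crop single-channel matrix; dimensions must be divisible by
#'   `patch_size` (otherwise the crop is resized up to the next multiple,
#'   with a message).
#' @param cfg a [hog_config()].
#' @return Numeric feature vector.
#' @export
compute_hog <- function(crop, cfg = hog_config()) {
  if (!is.matrix(crop)) crop <- as_gray(crop)
  ps <- cfg$patch_size
  if (nrow(crop) %% ps != 0 || ncol(crop) %% ps != 0) {
    nh <- ceiling(nrow(crop) / ps) * ps
    nw <- ceiling(ncol(crop) / ps) * ps
    message(sprintf("compute_hog: resizing %dx%d crop to %dx%d (multiple of patch_size)",
                    nrow(crop), ncol(crop), nh, nw))
    crop <- resize_bilinear(crop, nh, nw)
  }
  g <- gradients(crop)
  mo <- magnitude_orientation(g$gx, g$gy, unsigned = !cfg$signed_orientation)
  period <- if (cfg$signed_orientation) 360 else 180
  ncr <- nrow(crop) %/% ps; ncc <- ncol(crop) %/% ps
  nb <- cfg$n_orientation_bins
  cells <- array(0, dim = c(ncr, ncc, nb))
  for (i in seq_len(ncr)) for (j in seq_len(ncc)) {
    rs <- ((i - 1) * ps + 1):(i * ps); cs <- ((j - 1) * ps + 1):(j * ps)
    cells[i, j, ] <- orientation_histogram(mo$magnitude[rs, cs],
                                           mo$angle[rs, cs], nb, period)
  }
  bs <- cfg$block_size_cells
  stride <- cfg$block_stride_cells
  if (ncr < bs || ncc < bs)
    stopf("crop has %dx%d cells, smaller than block_size_cells %d", ncr, ncc, bs)
  out <- numeric(0)
  for (bi in seq(1, ncr - bs + 1, by = stride)) {
    for (bj in seq(1, ncc - bs + 1, by = stride)) {
      v <- as.vector(aperm(cells[bi:(bi + bs - 1), bj:(bj + bs - 1), ,
                                 drop = FALSE], c(3, 2, 1)))
      # order: bins fastest, then cell column, then cell row (row-major cells)
      if (cfg$block_norm != "none") {
        nrm <- sqrt(sum(v^2) + 1e-10)
        v <- v / nrm
        if (cfg$block_norm == "L2-hys") {
          v <- pmin(v, 0.2)
          v <- v / sqrt(sum(v^2) + 1e-10)
        }
      }
      out <- c(out, v)
    }
  }
  out
}

#' Local binary pattern code of one 3x3 window
#'
#' Thresholds the 8 neighbors against the center (`s(z) = 1` for `z >= 0`)
#' and accumulates powers of two clockwise from the top-left neighbor.
#'
#' @param window 3x3 numeric matrix.
#' @return Integer in 0..255.
#' @export
lbp_code <- function(window) {
  if (!is.matrix(window) || !all(dim(window) == c(3, 3)))
    stopf("window must be a 3x3 matrix")
  ctr <- window[2, 2]
  # clockwise from top-left: (1,1) (1,2) (1,3) (2,3) (3,3) (3,2) (3,1) (2,1)
  nb <- c(window[1, 1], window[1, 2], window[1, 3], window[2, 3],
          window[3, 3], window[3, 2], window[3, 1], window[2, 1])
  sum(as.integer(nb - ctr >= 0) * 2L^(0:7))
}

# vectorized LBP codes for all interior pixels of a matrix
lbp_code_matrix <- function(m) {
  h <- nrow(m); w <- ncol(m)
  ctr <- m[2:(h - 1), 2:(w - 1)]
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- matrix(0L, h - 2, w - 2)
  for (n in seq_along(offs)) {
    o <- offs[[n]]
    nb <- m[(2 + o[1]):(h - 1 + o[1]), (2 + o[2]):(w - 1 + o[2])]
    code <- code + as.integer(nb - ctr >= 0) * 2L^(n - 1)
  }
  code
}

#' Local binary pattern histogram
#'
#' Computes the 8-bit LBP code at every interior pixel and returns the
#' 256-bin histogram (bins 0..255).
#'
#' @param crop single-channel matrix, at least 3x3.
#' @param cfg an [lbp_config()].
#' @param mask optional binary matrix; with `cfg$masked_only` the histogram
#'   is restricted to interior pixels where `mask == 1`.
#' @return Numeric vector of length 256 (counts, or frequencies if
#'   `cfg$normalize`).
#' @export
compute_lbp <- function(crop, cfg = lbp_config(), mask = NULL) {
  if (!is.matrix(crop)) crop <- as_gray(crop)
  if (nrow(crop) < 3 || ncol(crop) < 3) stopf("crop must be at least 3x3")
  codes <- lbp_code_matrix(crop)
  keep <- rep(TRUE, length(codes))
  if (cfg$masked_only && !is.null(mask)) {
    im <- mask[2:(nrow(mask) - 1), 2:(ncol(mask) - 1)]
    keep <- as.vector(im == 1)
  }
  h <- tabulate(codes[keep] + 1L, nbins = 256L)
  if (cfg$normalize && sum(h) > 0) h <- h / sum(h)
  as.numeric(h)
}

#' Convex-hull caliper diameter of a mask
#'
#' Convex hull of the foreground pixel coordinates, then the maximum
#' pairwise Euclidean distance between hull vertices.  A single-pixel mask
#' has diameter 0.
#'
#' @param crop_mask binary matrix with at least one foreground pixel.
#' @return Diameter in pixels.
#' @export
nodule_diameter <- function(crop_mask) {
  pts <- which(crop_mask == 1, arr.ind = TRUE)
  if (nrow(pts) == 0) stopf("mask has no foreground pixels")
  if (nrow(pts) == 1) return(0)
  hull <- if (nrow(pts) >= 3) {
    hidx <- tryCatch(grDevices::chull(pts[, 2], pts[, 1]),
                     error = function(e) seq_len(nrow(pts)))
    pts[hidx, , drop = FALSE]
  } else pts
  if (nrow(hull) < 2) hull <- pts
  max(stats::dist(hull))
}

#' Fuse feature components by concatenation
#'
#' Plain concatenation in the fixed order HOG, LBP histogram, geometric.
#'
#' @param hog HOG vector.
#' @param lbp_hist 256-bin LBP histogram.
#' @param geometric geometric feature(s), typically the caliper diameter.
#' @param provenance optional nodule identifier carried along.
#' @return Object of class `feature_vector` with fields `hog`, `lbp_hist`,
#'   `geometric`, `fused` and `provenance`.
#' @export
fuse <- function(hog, lbp_hist, geometric, provenance = NA_character_) {
  for (nm in c("hog", "lbp_hist", "geometric")) {
    v <- get(nm)
    if (!is.numeric(v) || any(!is.finite(v)))
      stopf("component '%s' contains non-finite values", nm)
  }
  structure(list(hog = as.numeric(hog), lbp_hist = as.numeric(lbp_hist),
                 geometric = as.numeric(geometric),
                 fused = c(as.numeric(hog), as.numeric(lbp_hist),
                           as.numeric(geometric)),
                 provenance = provenance),
            class = "feature_vector")
}

#' Featurize one nodule region
#'
#' @param region an element of [extract_nodule_regions()] output.
#' @param hog_cfg,lbp_cfg feature configurations.
#' @param include_geometric include the caliper diameter (default `TRUE`).
#' @export
featurize_region <- function(region, hog_cfg = hog_config(),
                             lbp_cfg = lbp_config(),
                             include_geometric = TRUE) {
  hog <- compute_hog(region$crop, hog_cfg)
  lbp <- compute_lbp(region$crop, lbp_cfg, mask = region$crop_mask)
  geo <- if (include_geometric) {
    m <- if (!is.null(region$native_mask)) region$native_mask else region$crop_mask
    nodule_diameter(m)
  } else numeric(0)
  fuse(hog, lbp, geo)
}

#' Column-standardize a feature matrix
#'
#' Fits centers/scales on `x` (a training fold) and returns a function that
#' applies them; constant columns get scale 1.
#'
#' @param x numeric matrix.
#' @export
standardize_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(center = mu, scale = sd,
       apply = function(m) sweep(sweep(m, 2, mu, "-"), 2, sd, "/"))
}
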