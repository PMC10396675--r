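# Seeded phantom generator: CT-like slices containing bright nodules
# (benign: near-circular; malignant: larger, irregular) among vessel-like
# elongated distractors rendered at the same intensity, so that the
# segmentation problem shows the intensity confound seen in real chest CT.

.PHANTOM_BG <- 30   # background intensity (8-bit scale)
.PHANTOM_FG <- 200  # structure intensity: nodules and vessels share it

#' Phantom dataset specification
#'
#' Describes a synthetic population of CT-like slices.  Defaults emulate a
#' cohort of 146 slices with a benign:malignant nodule mix of roughly
#' 103:49 and nodule calipers spanning the 3-30 mm "focal opacity" band at
#' a nominal 0.7 mm/pixel scale.
#'
#' @param image_size pixels per side (square slices); >= 32.  128 keeps test
#'   runs fast; 512 matches full-resolution CT slices.
#' @param n_slices number of slices to generate.
#' @param benign_fraction probability that a nodule is benign, in \[0, 1\].
#' @param nodule_diameter_range_benign benign caliper diameter range
#'   (pixels), `c(low, high)`.
#' @param nodule_diameter_range_malignant malignant caliper diameter range
#'   (pixels); must lie strictly above the benign range.
#' @param vessel_count elongated same-intensity distractor structures per
#'   slice (they are background in the ground-truth mask).
#' @param noise_sigma additive Gaussian noise scale in 8-bit intensity units.
#' @param nodules_per_slice nodules placed per slice (non-overlapping).
#' @param mm_per_px nominal physical scale used only when converting pixel
#'   diameters to millimetres in reports.
#' @param seed integer master seed; every slice derives its own stream from
#'   `(seed, slice_index)`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 128L,
                         n_slices = 146L,
                         benign_fraction = 103 / 152,
                         nodule_diameter_range_benign = c(8, 18),
                         nodule_diameter_range_malignant = c(20, 34),
                         vessel_count = 4L,
                         noise_sigma = 8,
                         nodules_per_slice = 1L,
                         mm_per_px = 0.7,
                         seed = 1L) {
  check_number(image_size, "image_size", min = 32, integer = TRUE)
  check_number(n_slices, "n_slices", min = 0, integer = TRUE)
  check_number(benign_fraction, "benign_fraction", min = 0, max = 1)
  check_number(vessel_count, "vessel_count", min = 0, integer = TRUE)
  check_number(noise_sigma, "noise_sigma", min = 0)
  check_number(nodules_per_slice, "nodules_per_slice", min = 1, integer = TRUE)
  check_number(mm_per_px, "mm_per_px", min = 1e-6)
  check_number(seed, "seed", integer = TRUE)
  for (fld in c("nodule_diameter_range_benign", "nodule_diameter_range_malignant")) {
    rng <- get(fld)
    if (!is.numeric(rng) || length(rng) != 2L || any(!is.finite(rng)))
      stopf("field '%s' must be a numeric c(low, high)", fld)
    if (rng[1] <= 0 || rng[2] < rng[1])
      stopf("field '%s' must satisfy 0 < low <= high", fld)
  }
  if (nodule_diameter_range_malignant[1] <= nodule_diameter_range_benign[2])
    stopf(paste0("field 'nodule_diameter_range_malignant' must lie strictly ",
                 "above 'nodule_diameter_range_benign' (got malignant low %s ",
                 "<= benign high %s)"),
          nodule_diameter_range_malignant[1], nodule_diameter_range_benign[2])
  if (nodule_diameter_range_malignant[2] >= image_size - 4)
    stopf("field 'nodule_diameter_range_malignant' high %s does not fit image_size %s",
          nodule_diameter_range_malignant[2], image_size)
  structure(list(
    image_size = as.integer(image_size),
    n_slices = as.integer(n_slices),
    benign_fraction = benign_fraction,
    nodule_diameter_range_benign = as.numeric(nodule_diameter_range_benign),
    nodule_diameter_range_malignant = as.numeric(nodule_diameter_range_malignant),
    vessel_count = as.integer(vessel_count),
    noise_sigma = noise_sigma,
    nodules_per_slice = as.integer(nodules_per_slice),
    mm_per_px = mm_per_px,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>", x$n_slices, "slice(s) of", x$image_size, "x",
      x$image_size, "\n")
  cat("  benign fraction", round(x$benign_fraction, 3),
      "| diameters benign [", paste(x$nodule_diameter_range_benign, collapse = ", "),
      "] malignant [", paste(x$nodule_diameter_range_malignant, collapse = ", "), "] px\n")
  cat("  vessels", x$vessel_count, "| noise sd", x$noise_sigma,
      "| seed", x$seed, "\n")
  invisible(x)
}

# star-convex radius function r(theta) for an irregular (malignant) blob:
# low-order random Fourier perturbation of a disc, kept positive
irregular_radius <- function(theta, coefs) {
  r <- rep(1, length(theta))
  for (m in seq_len(nrow(coefs)))
    r <- r + coefs[m, 1] * cos((m + 1) * theta) + coefs[m, 2] * sin((m + 1) * theta)
  pmax(r, 0.2)
}

# Sample a nodule shape.  For malignant nodules the low-order Fourier
# coefficients are drawn here (before placement) so the placement margin can
# use the shape's true maximum radius; the radius function is rescaled so the
# shape's maximum caliper equals the sampled diameter.
sample_nodule_shape <- function(diameter, class) {
  if (class == "benign")
    return(list(class = class, diameter = diameter, max_radius = diameter / 2))
  coefs <- matrix(stats::rnorm(8, 0, 0.09), 4, 2)
  theta_dense <- seq(0, 2 * pi, length.out = 361L)[-361L]
  rd <- irregular_radius(theta_dense, coefs)
  px <- rd * cos(theta_dense); py <- rd * sin(theta_dense)
  cal <- max(stats::dist(cbind(px, py)))
  scale <- diameter / cal
  list(class = class, diameter = diameter, coefs = coefs, scale = scale,
       max_radius = scale * max(rd))
}

render_nodule <- function(img, mask, center, shape) {
  s <- nrow(img)
  rr <- matrix(seq_len(s), s, s)
  cc <- matrix(seq_len(s), s, s, byrow = TRUE)
  dr <- rr - center[1]; dc <- cc - center[2]
  dist <- sqrt(dr^2 + dc^2)
  if (shape$class == "benign") {
    inside <- dist <= shape$diameter / 2
  } else {
    theta <- atan2(dc, dr)
    inside <- dist <= shape$scale * irregular_radius(theta, shape$coefs)
  }
  img[inside] <- .PHANTOM_FG
  mask[inside] <- 1L
  list(img = img, mask = mask)
}

render_vessel <- function(img, s) {
  # a wiggly thick poly-line crossing the slice at structure intensity
  start <- stats::runif(2, 1, s)
  ang <- stats::runif(1, 0, 2 * pi)
  len <- stats::runif(1, 0.5 * s, 1.2 * s)
  amp <- stats::runif(1, 0, 0.06 * s)
  freq <- stats::runif(1, 1, 3)
  width <- stats::runif(1, 0.8, 2.0)
  t <- seq(0, 1, length.out = max(64L, ceiling(2 * len)))
  nrm <- c(-sin(ang), cos(ang))
  pr <- start[1] + t * len * cos(ang) + amp * sin(2 * pi * freq * t) * nrm[1]
  pc <- start[2] + t * len * sin(ang) + amp * sin(2 * pi * freq * t) * nrm[2]
  keep <- pr >= 1 - width & pr <= s + width & pc >= 1 - width & pc <= s + width
  pr <- pr[keep]; pc <- pc[keep]
  if (length(pr) == 0) return(img)
  w <- ceiling(width)
  for (i in seq_along(pr)) {
    r0 <- max(1L, floor(pr[i] - w)); r1 <- min(s, ceiling(pr[i] + w))
    c0 <- max(1L, floor(pc[i] - w)); c1 <- min(s, ceiling(pc[i] + w))
    if (r0 > r1 || c0 > c1) next
    sub_r <- r0:r1; sub_c <- c0:c1
    d2 <- outer((sub_r - pr[i])^2, (sub_c - pc[i])^2, "+")
    hit <- d2 <= width^2
    if (any(hit)) {
      blk <- img[sub_r, sub_c, drop = FALSE]
      blk[hit] <- .PHANTOM_FG
      img[sub_r, sub_c] <- blk
    }
  }
  img
}

#' Generate one labeled phantom slice
#'
#' Deterministic for a fixed `(spec$seed, slice_index)` pair regardless of the
#' caller's RNG state.  Vessels are rendered first (background class), then
#' nodules on top; Gaussian noise is added last and the result is quantized
#' to 8-bit.
#'
#' @param spec a [phantom_spec()].
#' @param slice_index zero-based slice index.
#' @return An object of class `labeled_slice`: `image` (H x W x 3 integer
#'   array, 0-255, identical channels), `mask` (H x W integer matrix of
#'   \{0, 1\}) and `nodules` (data frame with `nodule_id`, `class`,
#'   `diameter_px`, `centroid_row`, `centroid_col`).
#' @export
generate_slice <- function(spec, slice_index) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  check_number(slice_index, "slice_index", min = 0, integer = TRUE)
  s <- spec$image_size
  with_local_seed(derive_seed(spec$seed, slice_index), {
    img <- matrix(.PHANTOM_BG, s, s)
    mask <- matrix(0L, s, s)
    if (spec$vessel_count > 0)
      for (v in seq_len(spec$vessel_count)) img <- render_vessel(img, s)

    placed <- list()  # (center, max_radius)
    rows <- list()
    for (k in seq_len(spec$nodules_per_slice)) {
      cls <- if (stats::runif(1) < spec$benign_fraction) "benign" else "malignant"
      rng <- if (cls == "benign") spec$nodule_diameter_range_benign
             else spec$nodule_diameter_range_malignant
      d <- stats::runif(1, rng[1], rng[2])
      shape <- sample_nodule_shape(d, cls)
      margin <- shape$max_radius + 3
      if (2 * margin >= s)
        stopf("nodule of diameter %.1f does not fit image_size %d", d, s)
      ok <- FALSE
      for (try in seq_len(100L)) {
        ctr <- stats::runif(2, margin, s - margin)
        clear <- TRUE
        for (p in placed) {
          if (sqrt(sum((ctr - p$center)^2)) <
              shape$max_radius + p$max_radius + 3) {
            clear <- FALSE; break
          }
        }
        if (clear) { ok <- TRUE; break }
      }
      if (!ok)
        stopf("could not place nodule %d of %d without overlap; reduce nodules_per_slice or diameters",
              k, spec$nodules_per_slice)
      drawn <- render_nodule(img, mask, ctr, shape)
      img <- drawn$img; mask <- drawn$mask
      placed[[length(placed) + 1L]] <-
        list(center = ctr, max_radius = shape$max_radius)
      rows[[length(rows) + 1L]] <- data.frame(
        nodule_id = k, class = cls, diameter_px = d,
        centroid_row = round(ctr[1]), centroid_col = round(ctr[2]))
    }
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(s * s, 0, spec$noise_sigma), s, s)
    img <- round(clamp(img, 0, 255))
    image3 <- array(as.integer(img), dim = c(s, s, 3L))
    structure(list(
      image = image3,
      mask = mask,
      nodules = do.call(rbind, rows),
      slice_index = as.integer(slice_index)
    ), class = "labeled_slice")
  })
}

#' @export
print.labeled_slice <- function(x, ...) {
  cat("<labeled_slice>", dim(x$mask)[1], "x", dim(x$mask)[2], "-",
      nrow(x$nodules), "nodule(s):",
      paste(x$nodules$class, collapse = ", "), "\n")
  invisible(x)
}

#' Generate a phantom dataset on disk
#'
#' Writes per-slice image and mask PNGs plus a CSV manifest and returns the
#' manifest.  With `n_slices = 0` no image files are written and the manifest
#' is empty (header only).
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if missing).
#' @param mask_values `"0-255"` (default, visually inspectable) or `"0-1"`.
#' @return Invisibly, the manifest data frame with columns
#'   `slice_id,nodule_id,class,diameter_px,centroid_row,centroid_col`.
#' @export
generate_dataset <- function(spec, out_dir, mask_values = c("0-255", "0-1")) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  mask_values <- match.arg(mask_values)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory '%s'", out_dir)
  rows <- list()
  for (i in seq_len(spec$n_slices)) {
    sl <- generate_slice(spec, i - 1L)
    sid <- sprintf("slice_%04d", i - 1L)
    write_image_png(sl$image, file.path(out_dir, paste0(sid, ".png")))
    write_mask_png(sl$mask, file.path(out_dir, paste0(sid, "_mask.png")),
                   values = mask_values)
    nod <- sl$nodules
    nod <- cbind(data.frame(slice_id = sid), nod)
    rows[[i]] <- nod
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(slice_id = character(0), nodule_id = integer(0),
               class = character(0), diameter_px = numeric(0),
               centroid_row = numeric(0), centroid_col = numeric(0))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
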