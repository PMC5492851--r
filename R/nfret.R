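# ---- corrected FRET index and NFRET ----------------------------------------

#' Cross-talk-corrected FRET index
#'
#' Youvan correction: \code{F_index = I_FRET - A * I_D - B * I_A}, applied
#' pixelwise to background-subtracted channels. The result may be negative;
#' negatives are only clamped later at the NFRET stage.
#'
#' @param images an [image_set()] (background-subtracted, QC-passed).
#' @param bleed a [bleedthrough_params()] (or \code{calibration_fit} pair via
#'   \code{bleedthrough_params(fitA$slope, fitB$slope)}).
#' @return numeric matrix of F_index values (counts).
#' @export
#' @examples
#' im <- image_set(matrix(100, 2, 2), matrix(100, 2, 2), matrix(50, 2, 2))
#' compute_fret_index(im, bleedthrough_params(0.1, 0.25))[1, 1] # 15
compute_fret_index <- function(images, bleed) {
  stopifnot(inherits(images, "image_set"), inherits(bleed, "bleedthrough_params"))
  images$fret - bleed$A * images$donor - bleed$B * images$acceptor
}

#' Normalized FRET (NFRET) map
#'
#' \code{NFRET = 100 * F_index / sqrt(I_D * I_A)} at pixels where both the
#' donor and acceptor channels exceed \code{signal_floor}; negative values are
#' clamped to zero (a clamped zero is distinguishable from an invalid pixel
#' via \code{valid_mask}; invalid pixels are \code{NA} in \code{values}).
#'
#' @param images an [image_set()] (background-subtracted, QC-passed).
#' @param bleed a [bleedthrough_params()].
#' @param signal_floor counts; pixels with either channel at or below this are
#'   marked invalid (default 15, about 3x the background standard deviation of
#'   a 20-count Poisson background with read noise).
#' @return object of class \code{nfret_map}: \code{values} (x100 scale, NA at
#'   invalid pixels), \code{raw} (unclamped), \code{valid_mask},
#'   \code{signal_floor}.
#' @export
compute_nfret <- function(images, bleed, signal_floor = 15) {
  f <- compute_fret_index(images, bleed)
  valid <- images$donor > signal_floor & images$acceptor > signal_floor
  raw <- matrix(NA_real_, nrow(f), ncol(f))
  raw[valid] <- 100 * f[valid] / sqrt(images$donor[valid] * images$acceptor[valid])
  values <- raw
  values[valid & raw < 0] <- 0
  if (!any(valid))
    cst_warning("cst_empty_result", "no pixel passes the NFRET signal floor")
  structure(list(values = values, raw = raw, valid_mask = valid,
                 signal_floor = signal_floor),
            class = "nfret_map")
}

#' @export
print.nfret_map <- function(x, ...) {
  v <- x$values[x$valid_mask]
  cat(sprintf("<nfret_map> %d x %d px, %d valid (%.1f%%)\n",
              nrow(x$values), ncol(x$values), length(v),
              100 * mean(x$valid_mask)))
  if (length(v))
    cat(sprintf("  NFRET (x100): mean %.2f, median %.2f, max %.2f\n",
                mean(v), stats::median(v), max(v)))
  invisible(x)
}

# ---- filament masking -------------------------------------------------------

# Otsu threshold for a plain numeric vector, delegating to EBImage's
# histogram-based implementation on a rescaled 1-row image.
otsu_vec <- function(v) {
  rng <- range(v)
  if (diff(rng) <= 0) return(rng[1])
  img <- EBImage::Image(matrix((v - rng[1]) / diff(rng), nrow = 1))
  rng[1] + EBImage::otsu(img, range = c(0, 1), levels = 256L) * diff(rng)
}

# Zhang-Suen binary thinning; vectorized over the whole image via shifted
# copies. Converges in a handful of passes on filament-width structures.
skeletonize_mask <- function(mask, max_iter = 100L) {
  p <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbors clockwise from north; rows increase downward
      p2 <- shift_mat(p, 1, 0);  p3 <- shift_mat(p, 1, -1)
      p4 <- shift_mat(p, 0, -1); p5 <- shift_mat(p, -1, -1)
      p6 <- shift_mat(p, -1, 0); p7 <- shift_mat(p, -1, 1)
      p8 <- shift_mat(p, 0, 1);  p9 <- shift_mat(p, 1, 1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (pass == 1) {
        cond <- p == 1 & B >= 2 & B <= 6 & A == 1 &
          p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p == 1 & B >= 2 & B <= 6 & A == 1 &
          p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      if (any(cond)) { p[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  p == 1L
}

#' Segment filamentous structures from a structure channel
#'
#' Gaussian-smooths the image, applies a two-stage Otsu threshold (cell vs
#' background, then filaments vs cytosol within the cell), thins the result
#' to a one-pixel skeleton (Zhang-Suen) and dilates by \code{dilate_px}.
#'
#' @param image numeric matrix, typically the acceptor or a tubulin channel
#'   (background-subtracted).
#' @param smooth_sigma Gaussian smoothing sigma in px.
#' @param dilate_px dilation radius applied to the skeleton.
#' @return logical matrix of filamentous pixels.
#' @export
filament_mask <- function(image, smooth_sigma = 1, dilate_px = 2) {
  if (all(image == max(image))) {
    cst_warning("cst_empty_mask", "blank image: returning empty filament mask")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  sm <- EBImage::imageData(EBImage::gblur(image, sigma = smooth_sigma))
  t1 <- otsu_vec(as.vector(sm))
  cellish <- sm > t1
  if (!any(cellish)) {
    cst_warning("cst_empty_mask", "no foreground after thresholding")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  t2 <- otsu_vec(sm[cellish])
  fil <- sm > t2
  sk <- skeletonize_mask(fil)
  if (dilate_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(dilate_px) + 1L, shape = "diamond")
    sk <- EBImage::imageData(EBImage::dilate(EBImage::Image(sk * 1), brush)) > 0.5
  }
  sk
}

# ---- line profiles ----------------------------------------------------------

bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- pmin(pmax(floor(r), 1), nr); r1 <- pmin(r0 + 1, nr)
  c0 <- pmin(pmax(floor(c), 1), nc); c1 <- pmin(c0 + 1, nc)
  fr <- r - r0; fc <- c - c0
  (1 - fr) * (1 - fc) * m[cbind(r0, c0)] + fr * (1 - fc) * m[cbind(r1, c0)] +
    (1 - fr) * fc * m[cbind(r0, c1)] + fr * fc * m[cbind(r1, c1)]
}

#' Intensity profile along a polyline
#'
#' Resamples the path at uniform arc-length steps and reads single-pixel-width
#' values by bilinear interpolation; NFRET maps are sampled on their
#' \code{values} matrix (invalid pixels propagate \code{NA}).
#'
#' @param x numeric matrix or \code{nfret_map}.
#' @param polyline n x 2 matrix of (row, col) vertices in pixel coordinates.
#' @param step sampling step along the path, px.
#' @return data.frame with \code{position} (px along the path, strictly
#'   increasing) and \code{value}.
#' @export
extract_line_profile <- function(x, polyline, step = 1) {
  m <- if (inherits(x, "nfret_map")) x$values else x
  polyline <- as.matrix(polyline)
  if (ncol(polyline) != 2L || nrow(polyline) < 2L)
    cst_error("cst_config_error", "polyline must be an n x 2 matrix, n >= 2")
  if (min(polyline) < 1 || max(polyline[, 1]) > nrow(m) ||
      max(polyline[, 2]) > ncol(m))
    cst_error("cst_out_of_bounds", "polyline extends outside the image")
  seg <- sqrt(diff(polyline[, 1])^2 + diff(polyline[, 2])^2)
  s <- c(0, cumsum(seg))
  at <- seq(0, s[length(s)], by = step)
  r <- stats::approx(s, polyline[, 1], xout = at)$y
  c_ <- stats::approx(s, polyline[, 2], xout = at)$y
  data.frame(position = at, value = bilinear_sample(m, r, c_))
}

# ---- region statistics ------------------------------------------------------

#' NFRET statistics over a region
#'
#' With \code{cell_labels}, computes one mean per cell over the masked valid
#' pixels of that cell and then mean / SEM / SD across cells (the convention
#' behind per-cell box plots); without labels, per-pixel statistics over the
#' masked valid pixels.
#'
#' @param nfret an \code{nfret_map} or numeric matrix.
#' @param mask logical matrix selecting the region (e.g. a filament mask).
#' @param cell_labels optional integer matrix of cell labels (0 = none).
#' @param region character label stored in the result.
#' @return one-row data.frame: \code{region}, \code{mean}, \code{sem},
#'   \code{sd}, \code{n}, \code{mode}.
#' @export
region_nfret_stats <- function(nfret, mask, cell_labels = NULL,
                               region = "filament") {
  values <- if (inherits(nfret, "nfret_map")) nfret$values else nfret
  valid <- if (inherits(nfret, "nfret_map")) nfret$valid_mask else !is.na(values)
  if (!any(mask)) cst_error("cst_empty_mask", "region mask is empty")
  sel <- mask & valid
  if (!any(sel)) cst_error("cst_empty_mask", "no valid pixels inside the mask")
  if (is.null(cell_labels)) {
    v <- values[sel]
    data.frame(region = region, mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)), sd = stats::sd(v),
               n = length(v), mode = "per-pixel", stringsAsFactors = FALSE)
  } else {
    labs <- sort(unique(cell_labels[cell_labels > 0 & sel]))
    if (length(labs) == 0L)
      cst_error("cst_empty_mask", "no labeled cell intersects the mask")
    per_cell <- vapply(labs, function(k) mean(values[sel & cell_labels == k]),
                       numeric(1))
    data.frame(region = region, mean = mean(per_cell),
               sem = stats::sd(per_cell) / sqrt(length(per_cell)),
               sd = stats::sd(per_cell), n = length(per_cell),
               mode = "per-cell", stringsAsFactors = FALSE)
  }
}

#' Sample NFRET at random cytosolic points
#'
#' Uniformly samples \code{n} valid cytosolic pixels (inside the cell, off the
#' filament mask) with a fixed seed; the convention used to quantify
#' dissociated Tau in depolymerized cells.
#'
#' @param nfret an \code{nfret_map}.
#' @param cell_mask,filament_mask logical matrices.
#' @param n number of points.
#' @param seed integer seed.
#' @return data.frame with pixel indices and NFRET values.
#' @export
sample_cytosol_nfret <- function(nfret, cell_mask, filament_mask, n = 50,
                                 seed = 1) {
  pool <- which(cell_mask & !filament_mask & nfret$valid_mask)
  if (length(pool) == 0L) cst_error("cst_empty_mask", "no cytosolic pixels")
  idx <- with_seed(derive_seed(seed, "cytosol-sample"),
                   sample(pool, min(n, length(pool))))
  data.frame(pixel = idx, value = nfret$values[idx])
}

# ---- colocalization ---------------------------------------------------------

#' Pearson colocalization coefficient
#'
#' Standard Pearson correlation of two channels over the masked pixels.
#'
#' @param img1,img2 numeric matrices of identical dimensions.
#' @param mask optional logical matrix; default all pixels.
#' @return correlation coefficient in \code{[-1, 1]}.
#' @export
pearson_colocalization <- function(img1, img2, mask = NULL) {
  if (!identical(dim(img1), dim(img2)))
    cst_error("cst_shape_error", "images must share dimensions")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img1), ncol(img1))
  v1 <- img1[mask]; v2 <- img2[mask]
  if (length(v1) < 2L)
    cst_error("cst_degenerate", "need at least 2 pixels in the mask")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    cst_error("cst_degenerate", "zero variance: correlation undefined")
  stats::cor(v1, v2)
}

# ---- false-color rendering --------------------------------------------------

# 32 control points of the standard fire lookup table (black - red - yellow -
# white), linearly interpolated to 256 entries so rendering is
# bit-reproducible.
FIRE_R <- c(0, 0, 1, 25, 49, 73, 98, 122, 146, 162, 173, 184, 195, 207, 217,
            229, 240, 252, 255, 255, 255, 255, 255, 255, 255, 255, 255, 255,
            255, 255, 255, 255)
FIRE_G <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 14, 35, 57, 79, 101, 117,
            133, 147, 161, 175, 190, 205, 219, 234, 248, 255, 255, 255, 255)
FIRE_B <- c(0, 61, 96, 130, 165, 192, 220, 227, 210, 181, 151, 122, 93, 64,
            35, 5, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 35, 98, 160, 223, 255)

#' The 256-entry fire lookup table
#'
#' @return 256 x 3 integer matrix of RGB values in 0..255; entry 1 is black,
#'   entry 256 is white.
#' @export
fire_lut <- function() {
  at <- seq(1, 32, length.out = 256)
  lut <- cbind(r = stats::approx(1:32, FIRE_R, xout = at)$y,
               g = stats::approx(1:32, FIRE_G, xout = at)$y,
               b = stats::approx(1:32, FIRE_B, xout = at)$y)
  round(lut)
}

#' Render an NFRET map in false color
#'
#' Linearly maps NFRET into the fire LUT over \code{display_range} (default
#' 0-60 on the x100 scale, chosen to make low signals visible); values above
#' the range clip to the top color, values below to black, and invalid pixels
#' are black. Index rounding is round-half-to-even, so mid-range maps to LUT
#' index 128 (0-based).
#'
#' @param nfret an \code{nfret_map} or numeric matrix.
#' @param display_range numeric length 2.
#' @return integer array \code{h x w x 3} of 8-bit RGB values, class
#'   \code{nfret_render}.
#' @export
render_false_color <- function(nfret, display_range = c(0, 60)) {
  values <- if (inherits(nfret, "nfret_map")) nfret$values else nfret
  lut <- fire_lut()
  norm <- (values - display_range[1]) / diff(display_range)
  norm[is.na(norm)] <- 0
  norm <- pmin(pmax(norm, 0), 1)
  idx <- round(norm * 255) + 1
  out <- array(0L, c(nrow(values), ncol(values), 3L))
  for (ch in 1:3) out[, , ch] <- matrix(lut[idx, ch], nrow(values))
  structure(out, class = "nfret_render")
}

#' Write a rendered map as PNG
#'
#' @param render an \code{nfret_render}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_render_png <- function(render, path) {
  png::writePNG(unclass(render) / 255, path)
  invisible(path)
}

# ---- time courses -----------------------------------------------------------

#' NFRET time series over a list of image sets
#'
#' Computes per-timepoint on-mask NFRET statistics. The filament mask is
#' either recomputed for every frame (\code{"per-frame"}) or frozen at the
#' first frame (\code{"freeze"}).
#'
#' @param image_sets list of background-subtracted [image_set()] objects.
#' @param times numeric timestamps (seconds).
#' @param bleed a [bleedthrough_params()].
#' @param signal_floor NFRET validity floor in counts.
#' @param mask_policy \code{"per-frame"} or \code{"freeze"}.
#' @param structure_channel channel used for masking.
#' @return data.frame with one row per timepoint: \code{time}, \code{mean},
#'   \code{sem}, \code{sd}, \code{n}.
#' @export
nfret_timecourse <- function(image_sets, times, bleed, signal_floor = 15,
                             mask_policy = c("per-frame", "freeze"),
                             structure_channel = "acceptor") {
  mask_policy <- match.arg(mask_policy)
  if (length(image_sets) < 2L)
    cst_error("cst_config_error", "need at least 2 timepoints")
  stopifnot(length(times) == length(image_sets))
  frozen <- NULL
  rows <- lapply(seq_along(image_sets), function(i) {
    im <- image_sets[[i]]
    mask <- if (mask_policy == "freeze") {
      if (is.null(frozen)) frozen <<- filament_mask(im[[structure_channel]])
      frozen
    } else filament_mask(im[[structure_channel]])
    nf <- compute_nfret(im, bleed, signal_floor)
    st <- region_nfret_stats(nf, mask)
    data.frame(time = times[i], mean = st$mean, sem = st$sem, sd = st$sd,
               n = st$n)
  })
  do.call(rbind, rows)
}
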