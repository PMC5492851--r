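# ---- background strategies --------------------------------------------------

#' Background estimation strategies
#'
#' \code{bg_roi()} averages a user-supplied off-cell rectangle;
#' \code{bg_percentile()} uses a low percentile of the whole image.
#'
#' @param rows,cols integer index vectors of the background rectangle.
#' @param p percentile in \code{(0, 50]}.
#' @return a background-strategy object for [subtract_background()].
#' @export
bg_roi <- function(rows, cols) {
  if (length(rows) == 0L || length(cols) == 0L)
    cst_error("cst_empty_roi", "background ROI is empty")
  structure(list(rows = as.integer(rows), cols = as.integer(cols)),
            class = c("bg_roi", "bg_strategy"))
}

#' @rdname bg_roi
#' @export
bg_percentile <- function(p = 1) {
  if (!(p > 0 && p <= 50))
    cst_error("cst_config_error", "percentile must be in (0, 50]")
  structure(list(p = p), class = c("bg_percentile", "bg_strategy"))
}

estimate_background <- function(image, strategy) {
  if (inherits(strategy, "bg_roi")) {
    if (max(strategy$rows) > nrow(image) || max(strategy$cols) > ncol(image) ||
        min(strategy$rows) < 1L || min(strategy$cols) < 1L)
      cst_error("cst_empty_roi", "background ROI outside image bounds")
    mean(image[strategy$rows, strategy$cols])
  } else if (inherits(strategy, "bg_percentile")) {
    unname(stats::quantile(image, strategy$p / 100))
  } else {
    cst_error("cst_config_error", "unknown background strategy")
  }
}

#' Subtract a scalar background estimate from an image
#'
#' Estimates a single background level from an off-cell ROI or a low
#' percentile and subtracts it, flooring the result at zero. For an
#' [image_set()] the background is estimated and subtracted per channel.
#'
#' @param image numeric matrix or [image_set()].
#' @param strategy a [bg_roi()] or [bg_percentile()] strategy.
#' @return same type as \code{image}; the scalar estimate(s) are attached as
#'   attribute \code{background}.
#' @export
#' @examples
#' img <- matrix(100, 8, 8)
#' range(subtract_background(img, bg_percentile(1)))
subtract_background <- function(image, strategy = bg_percentile(1)) {
  if (inherits(image, "image_set")) {
    bgs <- vapply(c("donor", "acceptor", "fret"),
                  function(ch) estimate_background(image[[ch]], strategy),
                  numeric(1))
    out <- image_set(pmax(image$donor - bgs[["donor"]], 0),
                     pmax(image$acceptor - bgs[["acceptor"]], 0),
                     pmax(image$fret - bgs[["fret"]], 0),
                     bit_depth = image$bit_depth, pixel_size = image$pixel_size)
    attr(out, "background") <- bgs
    return(out)
  }
  if (length(image) == 0L) cst_error("cst_value_error", "empty image")
  b <- estimate_background(image, strategy)
  out <- pmax(image - b, 0)
  attr(out, "background") <- b
  out
}

# ---- saturation QC ----------------------------------------------------------

#' Whole-image saturation quality control
#'
#' An image (or any channel of an image set) is rejected when the fraction of
#' pixels at or above the detector ceiling exceeds \code{pixel_tolerance};
#' with the default tolerance of 0 a single saturated pixel rejects the whole
#' image, matching the discard-the-image rule used for sensitized-emission
#' calibration.
#'
#' @param image numeric matrix or [image_set()].
#' @param max_code detector ceiling (default 65535 for 16-bit).
#' @param pixel_tolerance highest acceptable saturated-pixel fraction.
#' @return list of class \code{qc_verdict}: \code{pass} (logical),
#'   \code{saturated_fraction}, \code{n_saturated}.
#' @export
flag_saturation <- function(image, max_code = 65535, pixel_tolerance = 0) {
  vals <- if (inherits(image, "image_set"))
    c(image$donor, image$acceptor, image$fret) else as.vector(image)
  n_sat <- sum(vals >= max_code)
  frac <- n_sat / length(vals)
  structure(list(pass = frac <= pixel_tolerance,
                 saturated_fraction = frac,
                 n_saturated = n_sat,
                 max_code = max_code),
            class = "qc_verdict")
}

#' @export
print.qc_verdict <- function(x, ...) {
  cat(sprintf("<qc_verdict> %s (%d px at >= %g, fraction %.3g)\n",
              if (x$pass) "pass" else "reject",
              x$n_saturated, x$max_code, x$saturated_fraction))
  invisible(x)
}

# ---- bleed-through parameters ----------------------------------------------

#' Donor/acceptor bleed-through fractions
#'
#' @param A donor leak fraction into the FRET channel.
#' @param B acceptor leak fraction into the FRET channel.
#' @return object of class \code{bleedthrough_params}.
#' @export
bleedthrough_params <- function(A, B) {
  if (A < 0 || A >= 1 || B < 0 || B >= 1)
    cst_error("cst_config_error", "bleed-through fractions must be in [0, 1)")
  structure(list(A = A, B = B), class = "bleedthrough_params")
}

#' @export
print.bleedthrough_params <- function(x, ...) {
  cat(sprintf("<bleedthrough_params> A = %.4f  B = %.4f\n", x$A, x$B))
  invisible(x)
}

# ---- regression -------------------------------------------------------------

#' Estimate a bleed-through fraction from single-fluorophore reference images
#'
#' Pools pixels across background-subtracted, QC-passed reference image sets
#' and fits an ordinary least squares line (free intercept) of FRET-channel
#' intensity against the donor channel (mode \code{"donor"}, slope = A) or
#' the acceptor channel (mode \code{"acceptor"}, slope = B). Pixels whose
#' reference-channel intensity is at or below \code{signal_floor} are
#' excluded to keep the regression away from the read-noise floor.
#'
#' @param reference_images an [image_set()] or list of them.
#' @param mode \code{"donor"} or \code{"acceptor"}.
#' @param signal_floor counts; default 6 (3x a 2-count read noise).
#' @return object of class \code{calibration_fit}: \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{n_pixels},
#'   \code{channel_pair}.
#' @export
#' @examples
#' p <- cst_preset("paper-typical-bleedthrough")
#' sc <- generate_calibration_scene("donor-only", p, seed = 7)
#' fit <- estimate_bleedthrough(subtract_background(sc, bg_roi(1:16, 1:16)),
#'                              mode = "donor")
#' round(fit$slope, 3)
estimate_bleedthrough <- function(reference_images,
                                  mode = c("donor", "acceptor"),
                                  signal_floor = 6) {
  mode <- match.arg(mode)
  if (inherits(reference_images, "image_set"))
    reference_images <- list(reference_images)
  ref_ch <- if (mode == "donor") "donor" else "acceptor"
  x <- unlist(lapply(reference_images, function(im) as.vector(im[[ref_ch]])))
  y <- unlist(lapply(reference_images, function(im) as.vector(im$fret)))
  keep <- x > signal_floor
  x <- x[keep]; y <- y[keep]
  if (length(x) < 100L)
    cst_error("cst_underdetermined",
              sprintf("only %d usable pixels (need >= 100)", length(x)))
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  intercept <- unname(fit$coefficients[1])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) max(0, 1 - ss_res / ss_tot) else 0
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 n_pixels = length(x),
                 channel_pair = paste0("fret~", ref_ch)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> %s: slope %.4f, intercept %.2f, R^2 %.3f, n = %d px\n",
              x$channel_pair, x$slope, x$intercept, x$r_squared, x$n_pixels))
  invisible(x)
}
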