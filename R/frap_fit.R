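# ---- trace containers -------------------------------------------------------

#' FRAP trace container
#'
#' Per-frame mean intensities of the bleached ROI and of the whole cell, with
#' the prebleach frame count. Row \code{n_pre + 1} is the first post-bleach
#' frame.
#'
#' @param time_s frame times in seconds, strictly increasing.
#' @param roi_intensity,wholecell_intensity per-frame mean counts.
#' @param n_pre number of prebleach frames (>= 1).
#' @param phase optional character vector \code{"pre"}/\code{"post"}; derived
#'   from \code{n_pre} when missing.
#' @return data.frame of class \code{frap_trace} with attribute \code{n_pre}.
#' @export
frap_trace <- function(time_s, roi_intensity, wholecell_intensity, n_pre,
                       phase = NULL) {
  n <- length(time_s)
  stopifnot(length(roi_intensity) == n, length(wholecell_intensity) == n)
  if (any(diff(time_s) <= 0))
    cst_error("cst_config_error", "time must be strictly increasing")
  n_pre <- as.integer(n_pre)
  if (n_pre < 1L || n_pre >= n)
    cst_error("cst_config_error", "need 1 <= n_pre < number of frames")
  if (is.null(phase)) phase <- rep(c("pre", "post"), c(n_pre, n - n_pre))
  out <- data.frame(time_s = time_s, roi_intensity = roi_intensity,
                    wholecell_intensity = wholecell_intensity, phase = phase,
                    stringsAsFactors = FALSE)
  attr(out, "n_pre") <- n_pre
  class(out) <- c("frap_trace", "data.frame")
  out
}

#' Extract ROI and whole-cell traces from an image stack
#'
#' Per-frame mean intensity over a circular ROI and over a whole-cell mask.
#' A radius of 0 selects the single center pixel.
#'
#' @param stack numeric array \code{rows x cols x frames}.
#' @param center numeric length 2, ROI center (row, col) in px.
#' @param radius ROI radius in px.
#' @param cell_mask logical matrix of whole-cell pixels.
#' @param frame_times frame times in seconds.
#' @param n_pre number of prebleach frames.
#' @return a [frap_trace()].
#' @export
extract_roi_trace <- function(stack, center, radius, cell_mask, frame_times,
                              n_pre) {
  d <- dim(stack)
  if (length(d) != 3L) cst_error("cst_shape_error", "stack must be 3-D")
  if (center[1] - radius < 1 || center[1] + radius > d[1] ||
      center[2] - radius < 1 || center[2] + radius > d[2])
    cst_error("cst_out_of_bounds", "ROI extends outside the image")
  R <- matrix(seq_len(d[1]), d[1], d[2])
  C <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  disc <- (R - center[1])^2 + (C - center[2])^2 <= radius^2
  roi <- apply(stack, 3, function(fr) mean(fr[disc]))
  wc <- apply(stack, 3, function(fr) mean(fr[cell_mask]))
  frap_trace(frame_times, roi, wc, n_pre = n_pre)
}

# ---- normalization ----------------------------------------------------------

#' Four-step FRAP trace normalization
#'
#' (1) subtract the background from the ROI and whole-cell series; (2) divide
#' the ROI by its mean prebleach value; (3) correct acquisition
#' photobleaching by multiplying each post-bleach point by
#' (mean prebleach whole-cell) / (whole-cell at that frame); (4) subtract the
#' first post-bleach value and rescale by one minus it, so 0 is the bleach
#' floor and 1 is full recovery. Time is re-origined at the first post-bleach
#' frame, making the fitted amplitude sum a true mobile fraction.
#'
#' @param trace a [frap_trace()].
#' @param background scalar background in counts, or named
#'   \code{c(roi = , wholecell = )}.
#' @return data.frame of class \code{normalized_trace} with \code{time}
#'   (s since first post-bleach frame) and \code{value}; the bleach-floor
#'   value before rescaling is kept as attribute \code{v0}.
#' @export
normalize_trace <- function(trace, background = 0) {
  stopifnot(inherits(trace, "frap_trace"))
  n_pre <- attr(trace, "n_pre")
  bg_roi <- if (length(background) == 2L) background[["roi"]] else background
  bg_wc <- if (length(background) == 2L) background[["wholecell"]] else background
  pre <- seq_len(n_pre)
  post <- (n_pre + 1L):nrow(trace)
  if (bg_roi >= min(trace$roi_intensity[pre]))
    cst_error("cst_corrupt_trace", "background exceeds prebleach ROI intensity")
  roi <- trace$roi_intensity - bg_roi
  wc <- trace$wholecell_intensity - bg_wc
  if (any(wc <= 0))
    cst_error("cst_corrupt_trace", "whole-cell intensity <= 0 after background subtraction")
  f_pre <- mean(roi[pre])
  w_pre <- mean(wc[pre])
  v <- roi / f_pre
  v[post] <- v[post] * (w_pre / wc[post])
  v0 <- v[post][1]
  if (1 - v0 < 1e-9)
    cst_error("cst_corrupt_trace", "no bleach depth: first post-bleach value ~ prebleach")
  out <- data.frame(time = trace$time_s[post] - trace$time_s[post][1],
                    value = (v[post] - v0) / (1 - v0))
  attr(out, "v0") <- v0
  attr(out, "f_pre") <- f_pre
  class(out) <- c("normalized_trace", "data.frame")
  out
}

# ---- two-phase exponential association fit ----------------------------------

two_phase_model <- function(t, y0, A1, A2, tau1, tau2) {
  y0 + A1 * (1 - exp(-t / tau1)) + A2 * (1 - exp(-t / tau2))
}

failed_fit <- function(n_points) {
  structure(list(y0 = NA_real_, A1_star = NA_real_, A2_star = NA_real_,
                 tau1 = NA_real_, tau2 = NA_real_, A1 = NA_real_,
                 A2 = NA_real_, Mob_calc = NA_real_, rss = NA_real_,
                 converged = FALSE, ill_conditioned = TRUE,
                 n_points = n_points), class = "frap_fit")
}

#' Fit the two-phase exponential association model
#'
#' Bounded Levenberg-Marquardt least squares of
#' \code{y = y0 + A1*(1 - exp(-t/tau1)) + A2*(1 - exp(-t/tau2))} on a
#' normalized recovery trace, with amplitudes constrained non-negative and
#' time constants positive. Initialization: tau1 = time to reach 25% of the
#' final plateau, tau2 = 8 tau1, amplitudes split 30/70 of the plateau. Up to
#' \code{restarts} deterministic perturbed re-initializations are tried; the
#' lowest-RSS converged fit is kept, and total failure returns a fit flagged
#' \code{converged = FALSE} rather than an error. Components are relabeled so
#' tau1 <= tau2; the fit is flagged ill-conditioned when tau2/tau1 < 1.5 or
#' either amplitude collapses below 1e-4 (degenerate second component).
#'
#' @param trace a \code{normalized_trace} (or data.frame with \code{time} and
#'   \code{value}).
#' @param restarts number of perturbed re-initializations after the first
#'   attempt.
#' @return object of class \code{frap_fit}: \code{y0}, \code{A1_star},
#'   \code{A2_star}, \code{tau1}, \code{tau2}, normalized fractions
#'   \code{A1}, \code{A2}, \code{Mob_calc}, \code{rss}, \code{converged},
#'   \code{ill_conditioned}, \code{n_points}.
#' @export
#' @examples
#' t <- 0:119
#' y <- two_phase_model(t, 0, 0.21, 0.55, 4.9, 35.2)
#' fit <- fit_two_phase(data.frame(time = t, value = y))
#' round(c(fit$tau1, fit$tau2, fit$Mob_calc), 3)
fit_two_phase <- function(trace, restarts = 3L) {
  t <- trace$time
  y <- trace$value
  n <- length(t)
  if (n < 20L)
    cst_error("cst_underdetermined", "need >= 20 post-bleach points")
  plat <- mean(utils::tail(y, max(5L, n %/% 10L)))
  t25 <- t[which(y >= 0.25 * plat)[1]]
  dt <- stats::median(diff(t))
  tau1_0 <- max(if (is.na(t25)) 2 * dt else t25, dt)
  start0 <- c(y0 = 0, A1 = 0.3 * max(plat, 0.05), A2 = 0.7 * max(plat, 0.05),
              tau1 = tau1_0, tau2 = 8 * tau1_0)
  # deterministic perturbations of the time-constant guesses
  perturb <- list(c(1, 1), c(1 / 3, 1 / 3), c(3, 3), c(1, 10))
  best <- NULL
  for (k in seq_len(1L + max(0L, restarts))) {
    st <- start0
    st["tau1"] <- start0["tau1"] * perturb[[k]][1]
    st["tau2"] <- max(start0["tau2"] * perturb[[k]][2], 2 * st[["tau1"]])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ two_phase_model(t, y0, A1, A2, tau1, tau2),
        data = data.frame(t = t, y = y),
        start = as.list(st),
        lower = c(y0 = -0.5, A1 = 0, A2 = 0, tau1 = 1e-8, tau2 = 1e-8),
        upper = c(y0 = 0.5, A1 = 2, A2 = 2, tau1 = Inf, tau2 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(failed_fit(n))
  cf <- stats::coef(best$fit)
  a1 <- cf[["A1"]]; a2 <- cf[["A2"]]
  tau1 <- cf[["tau1"]]; tau2 <- cf[["tau2"]]
  if (tau1 > tau2) { # relabel so the fast component comes first
    tmp <- a1; a1 <- a2; a2 <- tmp
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
  }
  mob <- a1 + a2
  structure(list(
    y0 = cf[["y0"]], A1_star = a1, A2_star = a2, tau1 = tau1, tau2 = tau2,
    A1 = if (mob > 0) a1 / mob else NA_real_,
    A2 = if (mob > 0) a2 / mob else NA_real_,
    Mob_calc = mob, rss = best$rss, converged = TRUE,
    ill_conditioned = (tau2 / tau1 < 1.5) || min(a1, a2) < 1e-4,
    n_points = n), class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  if (!x$converged) { cat("<frap_fit> not converged\n"); return(invisible(x)) }
  cat(sprintf("<frap_fit> Mob = %.3f (A1* = %.3f @ tau1 = %.2fs, A2* = %.3f @ tau2 = %.2fs)\n",
              x$Mob_calc, x$A1_star, x$tau1, x$A2_star, x$tau2))
  cat(sprintf("  shares A1 = %.3f A2 = %.3f; y0 = %.4f; rss = %.3g%s\n",
              x$A1, x$A2, x$y0, x$rss,
              if (x$ill_conditioned) " [ill-conditioned]" else ""))
  invisible(x)
}

#' Normalized fractions and mobile fraction of a two-phase fit
#'
#' \code{A1 = A1_star / (A1_star + A2_star)}, \code{A2 = 1 - A1},
#' \code{Mob_calc = A1_star + A2_star}.
#'
#' @param fit a \code{frap_fit}, or numeric length 2 \code{c(A1_star, A2_star)}.
#' @return list with \code{A1}, \code{A2}, \code{Mob_calc}.
#' @export
derive_fractions <- function(fit) {
  amps <- if (inherits(fit, "frap_fit")) c(fit$A1_star, fit$A2_star) else fit
  total <- sum(amps)
  if (!is.finite(total) || total <= 0)
    cst_error("cst_degenerate", "zero total amplitude: fractions undefined")
  list(A1 = amps[1] / total, A2 = amps[2] / total, Mob_calc = total)
}

# ---- condition summaries ----------------------------------------------------

#' Summarize two-phase fits across traces of one condition
#'
#' Mean and SEM of the mobile fraction, normalized fractions and time
#' constants across converged fits; non-converged fits are excluded and
#' counted.
#'
#' @param fits list of \code{frap_fit} objects.
#' @param label condition label.
#' @return one-row data.frame.
#' @export
summarize_condition <- function(fits, label = "condition") {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0L)
    cst_error("cst_empty_summary", "all fits failed")
  if (length(conv) < 2L)
    cst_error("cst_underdetermined", "need >= 2 converged fits")
  g <- function(field) vapply(conv, `[[`, numeric(1), field)
  mstat <- function(v) c(mean(v), stats::sd(v) / sqrt(length(v)))
  mob <- mstat(g("Mob_calc")); a1 <- mstat(g("A1")); a2 <- mstat(g("A2"))
  t1 <- mstat(g("tau1")); t2 <- mstat(g("tau2"))
  data.frame(condition = label, n = length(conv),
             n_failed = length(fits) - length(conv),
             mob_mean = mob[1], mob_sem = mob[2],
             a1_mean = a1[1], a1_sem = a1[2],
             a2_mean = a2[1], a2_sem = a2[2],
             tau1_mean = t1[1], tau1_sem = t1[2],
             tau2_mean = t2[1], tau2_sem = t2[2],
             stringsAsFactors = FALSE)
}

#' Normalize and fit a batch of generated FRAP traces
#'
#' Convenience wrapper: applies [normalize_trace()] and [fit_two_phase()] to
#' the output of [generate_frap_series()].
#'
#' @param series list as returned by [generate_frap_series()].
#' @param background passed to [normalize_trace()].
#' @return list of \code{frap_fit} objects.
#' @export
fit_frap_series <- function(series, background = 20) {
  lapply(series, function(el) fit_two_phase(normalize_trace(el$trace,
                                                            background)))
}
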