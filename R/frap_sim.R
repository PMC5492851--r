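#' Generate synthetic FRAP time series with known ground truth
#'
#' Emulates the three-phase FRAP protocol: \code{n_pre} prebleach frames, an
#' instantaneous bleach dropping the ROI to \code{bleach_residual} of its
#' prebleach level, and \code{n_post} postbleach frames during which the
#' normalized recovery follows the two-phase exponential association
#' \deqn{g(t) = A_1^* (1 - e^{-t/\tau_1}) + A_2^* (1 - e^{-t/\tau_2}).}
#' Acquisition photobleaching multiplies all fluorescence by a smooth loss
#' curve \eqn{L(t)} decaying to \code{1 - acquisition_loss_total} over the
#' postbleach series; a whole-cell trace (background + \eqn{L(t)} times the
#' prebleach whole-cell level) is emitted alongside the ROI trace so the
#' analyzer can perform the loss correction. Per-frame Gaussian noise on the
#' ROI and whole-cell means is applied when the preset's \code{noise_scale}
#' is nonzero. Deterministic per \code{(seed, trace index)}.
#'
#' @param preset a \code{scene_preset}.
#' @param seed integer seed.
#' @param n_traces number of independent traces to generate.
#' @param bg,bg_wholecell background counts for the ROI and whole-cell series.
#' @param roi_prebleach,wholecell_prebleach prebleach plateau levels (counts).
#' @param noise_sd_roi,noise_sd_wholecell per-frame Gaussian noise, as a
#'   fraction of the respective prebleach level.
#' @return list of length \code{n_traces}; each element has \code{trace}
#'   (a [frap_trace()]) and \code{truth} (class \code{frap_truth} with the
#'   generating parameters, \code{g} and the per-frame loss curve).
#' @export
#' @examples
#' tr <- generate_frap_series(cst_preset("CST-untreated"), seed = 1)[[1]]
#' head(tr$trace)
generate_frap_series <- function(preset, seed, n_traces = 1L,
                                 bg = 20, bg_wholecell = 20,
                                 roi_prebleach = 1000,
                                 wholecell_prebleach = 800,
                                 noise_sd_roi = 0.01,
                                 noise_sd_wholecell = 0.005) {
  if (n_traces < 1) cst_error("cst_config_error", "n_traces must be >= 1")
  dt <- preset$frame_interval
  n_pre <- preset$n_pre
  n_post <- preset$n_post
  A1 <- preset$frap_fractions[["A1_star"]]
  A2 <- preset$frap_fractions[["A2_star"]]
  tau1 <- preset$frap_taus[["tau1"]]
  tau2 <- preset$frap_taus[["tau2"]]
  f0 <- preset$bleach_residual
  loss <- preset$acquisition_loss_total
  g <- function(tp) A1 * (1 - exp(-tp / tau1)) + A2 * (1 - exp(-tp / tau2))

  t_post_rel <- (seq_len(n_post) - 1) * dt
  T_post <- max(t_post_rel[length(t_post_rel)], dt)
  L_post <- (1 - loss)^(t_post_rel / T_post)
  L <- c(rep(1, n_pre), L_post)
  time_s <- c((seq_len(n_pre) - 1) * dt, n_pre * dt + t_post_rel)
  phase <- c(rep("pre", n_pre), rep("post", n_post))
  roi_clean <- c(rep(roi_prebleach, n_pre),
                 L_post * roi_prebleach * (f0 + (1 - f0) * g(t_post_rel)))
  wc_clean <- c(rep(wholecell_prebleach, n_pre), L_post * wholecell_prebleach)
  noisy <- preset$noise_scale > 0

  lapply(seq_len(n_traces), function(i) {
    roi <- bg + roi_clean
    wc <- bg_wholecell + wc_clean
    if (noisy) {
      eps <- with_seed(derive_seed(seed, "frap-trace", i), list(
        roi = stats::rnorm(length(roi), 0, noise_sd_roi * roi_prebleach),
        wc = stats::rnorm(length(wc), 0,
                          noise_sd_wholecell * wholecell_prebleach)))
      roi <- roi + eps$roi
      wc <- wc + eps$wc
    }
    trace <- frap_trace(time_s, roi, wc, n_pre = n_pre, phase = phase)
    truth <- structure(list(
      g = g, A1_star = A1, A2_star = A2, tau1 = tau1, tau2 = tau2,
      bleach_residual = f0, loss_curve = L,
      acquisition_loss_total = loss, preset = preset$name
    ), class = "frap_truth")
    list(trace = trace, truth = truth)
  })
}
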