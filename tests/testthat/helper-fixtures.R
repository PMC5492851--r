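# Shared fixtures: small fields keep unit tests fast; noiseless variants give
# exact oracles.

small_preset <- function(name = "CST-untreated", noise = NULL, field = 128L) {
  p <- cst_preset(name)
  p$field_size <- as.integer(field)
  if (!is.null(noise)) p$noise_scale <- noise
  p
}

noiseless <- function(name = "CST-untreated", ...) {
  small_preset(name, noise = 0, ...)
}

corner_bg <- function() bg_roi(1:16, 1:16)

typical_bleed <- function() bleedthrough_params(0.1, 0.25)

# analytic two-phase recovery curve
biexp_curve <- function(t, y0 = 0, A1 = 0.21128, A2 = 0.54872,
                        tau1 = 4.9, tau2 = 35.2) {
  y0 + A1 * (1 - exp(-t / tau1)) + A2 * (1 - exp(-t / tau2))
}

# Grid-search oracle for the biexponential fit: exhaustive (tau1, tau2) grid
# with y0 and amplitudes solved by linear least squares at each node.
grid_search_biexp_rss <- function(t, y, taus = exp(seq(log(0.5), log(200),
                                                       length.out = 40))) {
  best <- Inf
  for (i in seq_along(taus)) {
    for (j in seq_along(taus)) {
      if (taus[j] <= taus[i]) next
      X <- cbind(1, 1 - exp(-t / taus[i]), 1 - exp(-t / taus[j]))
      fit <- stats::lm.fit(X, y)
      rss <- sum(fit$residuals^2)
      if (rss < best) best <- rss
    }
  }
  best
}

run_scene_nfret <- function(preset, seed, bleed = typical_bleed()) {
  sc <- generate_filament_scene(preset, seed)
  im <- subtract_background(sc$images, corner_bg())
  nf <- compute_nfret(im, bleed)
  mask <- filament_mask(im$acceptor)
  list(scene = sc, images = im, nfret = nf, mask = mask)
}
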