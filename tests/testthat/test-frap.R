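test_that("ROI extraction averages discs and whole-cell masks per frame", {
  stack <- array(3, c(16, 16, 5))
  cell <- matrix(TRUE, 16, 16)
  tr <- extract_roi_trace(stack, center = c(8, 8), radius = 3, cell_mask = cell,
                          frame_times = 0:4, n_pre = 2)
  expect_s3_class(tr, "frap_trace")
  expect_equal(tr$roi_intensity, rep(3, 5))
  expect_equal(tr$wholecell_intensity, rep(3, 5))
  # radius 0 reads the single center pixel
  stack[8, 8, ] <- 99
  tr0 <- extract_roi_trace(stack, c(8, 8), 0, cell, 0:4, 2)
  expect_equal(tr0$roi_intensity, rep(99, 5))
  expect_error(extract_roi_trace(stack, c(2, 2), 5, cell, 0:4, 2),
               class = "cst_out_of_bounds")
})

test_that("four-step normalization inverts the clean forward model", {
  p <- noiseless()
  el <- generate_frap_series(p, seed = 1)[[1]]
  nt <- normalize_trace(el$trace, background = 20)
  expect_equal(nt$value[1], 0) # first post-bleach point pinned to 0
  expect_equal(nt$value, el$truth$g(nt$time), tolerance = 1e-10)
  # recovery approaches (but cannot exceed) the mobile fraction within the
  # 120 s window: g(119) = 0.741 of a 0.76 plateau for the untreated taus
  expect_lt(max(nt$value), sum(p$frap_fractions))
  expect_gt(max(nt$value), 0.95 * sum(p$frap_fractions))
})

test_that("loss correction flattens the acquisition-photobleaching decay", {
  # oracle: an immobile, residual-free trace after steps 1-3 should be flat at
  # zero; with loss uncorrected it would follow L(t)
  p <- noiseless()
  p$frap_fractions <- c(A1_star = 0, A2_star = 0)
  p$bleach_residual <- 0.5
  el <- generate_frap_series(p, seed = 1)[[1]]
  nt <- normalize_trace(el$trace, background = 20)
  expect_lt(max(abs(nt$value)), 1e-10) # immobile: flat at the bleach floor
  # direct oracle on the whole-cell ratio: step 3 equals 1/L(t)
  post <- el$trace$phase == "post"
  w <- el$trace$wholecell_intensity - 20
  ratio <- mean(w[!post]) / w[post]
  expect_equal(ratio, 1 / el$truth$loss_curve[post], tolerance = 1e-10)
})

test_that("normalization is idempotent on normalized-like traces", {
  p <- noiseless()
  el <- generate_frap_series(p, seed = 1)[[1]]
  nt <- normalize_trace(el$trace, background = 20)
  # re-wrap as a raw trace: prebleach plateau 1, flat whole-cell, background 0
  n_pre <- 3L
  again <- frap_trace(c(-(n_pre:1), nt$time),
                      c(rep(1, n_pre), nt$value),
                      rep(1, n_pre + nrow(nt)), n_pre = n_pre)
  nt2 <- normalize_trace(again, background = 0)
  expect_equal(nt2$value, nt$value, tolerance = 1e-12)
})

test_that("corrupt traces are refused", {
  tr <- frap_trace(0:9, rep(100, 10), c(rep(50, 5), 0, rep(50, 4)), n_pre = 3)
  expect_error(normalize_trace(tr, background = 10),
               class = "cst_corrupt_trace")
  tr2 <- frap_trace(0:9, rep(100, 10), rep(50, 10), n_pre = 3)
  expect_error(normalize_trace(tr2, background = 200),
               class = "cst_corrupt_trace")
})

test_that("noiseless biexponential fits recover parameters to 1e-6", {
  t <- seq(0, 119, by = 1)
  y <- biexp_curve(t)
  fit <- fit_two_phase(data.frame(time = t, value = y))
  expect_true(fit$converged)
  expect_lt(abs(fit$A1_star - 0.21128) / 0.21128, 1e-6)
  expect_lt(abs(fit$A2_star - 0.54872) / 0.54872, 1e-6)
  expect_lt(abs(fit$tau1 - 4.9) / 4.9, 1e-6)
  expect_lt(abs(fit$tau2 - 35.2) / 35.2, 1e-6)
  expect_lt(abs(fit$Mob_calc - 0.76) / 0.76, 1e-6)
  expect_equal(fit$A1 + fit$A2, 1)
})

test_that("single-exponential truth collapses to one component and is flagged", {
  t <- seq(0, 119, by = 1)
  y <- biexp_curve(t, A1 = 0.6, A2 = 0, tau1 = 8, tau2 = 50)
  fit <- fit_two_phase(data.frame(time = t, value = y))
  expect_true(fit$converged)
  expect_equal(fit$Mob_calc, 0.6, tolerance = 1e-6)
  expect_true(fit$ill_conditioned) # degenerate second amplitude or tau ratio
})

test_that("component relabeling makes the fit invariant to truth label order", {
  t <- seq(0, 119, by = 1)
  y_fast_first <- biexp_curve(t, A1 = 0.2, A2 = 0.5, tau1 = 5, tau2 = 40)
  y_slow_first <- biexp_curve(t, A1 = 0.5, A2 = 0.2, tau1 = 40, tau2 = 5)
  expect_equal(y_fast_first, y_slow_first) # same curve by construction
  f <- fit_two_phase(data.frame(time = t, value = y_fast_first))
  expect_lte(f$tau1, f$tau2)
  expect_equal(c(f$A1_star, f$tau1, f$A2_star, f$tau2),
               c(0.2, 5, 0.5, 40), tolerance = 1e-6)
})

test_that("fit matches a grid-search oracle on toy traces", {
  t <- seq(0, 95, by = 5) # 20-point toy traces
  cases <- list(c(0.3, 0.4, 4, 30), c(0.1, 0.7, 8, 60), c(0.5, 0.2, 2, 20))
  for (cs in cases) {
    y <- biexp_curve(t, 0, cs[1], cs[2], cs[3], cs[4])
    set.seed(11)
    y <- y + rnorm(length(y), 0, 0.01)
    fit <- fit_two_phase(data.frame(time = t, value = y))
    oracle <- grid_search_biexp_rss(t, y)
    expect_lte(fit$rss, oracle + 1e-10)
  }
})

test_that("derived fractions follow the amplitude arithmetic", {
  fr <- derive_fractions(c(0.25, 0.75))
  expect_equal(fr$A1, 0.25)
  expect_equal(fr$A2, 0.75)
  expect_equal(fr$Mob_calc, 1)
  # untreated-condition cross-check: 0.212 + 0.548 gives Mob 0.76, share ~0.279
  fr2 <- derive_fractions(c(0.212, 0.548))
  expect_equal(fr2$Mob_calc, 0.76)
  expect_equal(fr2$A1, 0.2789, tolerance = 1e-3)
  fr3 <- derive_fractions(c(0.6, 0))
  expect_equal(fr3$A1, 1)
  expect_equal(fr3$A2, 0)
  expect_error(derive_fractions(c(0, 0)), class = "cst_degenerate")
})

test_that("condition summaries aggregate converged fits and refuse empty input", {
  t <- seq(0, 119, by = 1)
  fit <- fit_two_phase(data.frame(time = t, value = biexp_curve(t)))
  s <- summarize_condition(list(fit, fit, fit), "replicated")
  expect_equal(s$mob_sem, 0)
  expect_equal(s$n, 3)
  expect_equal(s$n_failed, 0)
  bad <- list(structure(list(converged = FALSE), class = "frap_fit"))
  expect_error(summarize_condition(bad, "x"), class = "cst_empty_summary")
})

test_that("fitted parameters are unbiased across generated traces", {
  p <- cst_preset("CST-untreated")
  fits <- fit_frap_series(generate_frap_series(p, seed = 11, n_traces = 12),
                          background = 20)
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))
  g <- function(f) vapply(fits, `[[`, numeric(1), f)
  for (spec_ in list(list("Mob_calc", 0.76), list("tau1", 4.9),
                     list("tau2", 35.2))) {
    v <- g(spec_[[1]])
    se <- stats::sd(v) / sqrt(length(v))
    # bias below ~2 SE plus a small numerical margin for fit nonlinearity
    expect_lt(abs(mean(v) - spec_[[2]]), 2 * se + 0.05 * spec_[[2]])
  }
})

test_that("trace containers enforce timing and phase invariants", {
  expect_error(frap_trace(c(0, 1, 1, 2), rep(1, 4), rep(1, 4), n_pre = 2),
               class = "cst_config_error")
  expect_error(frap_trace(0:3, rep(1, 4), rep(1, 4), n_pre = 4),
               class = "cst_config_error")
  tr <- frap_trace(0:9, rep(2, 10), rep(3, 10), n_pre = 4)
  expect_equal(attr(tr, "n_pre"), 4L)
  expect_equal(tr$phase, rep(c("pre", "post"), c(4, 6)))
})
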