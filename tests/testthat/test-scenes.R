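test_that("same seed gives bit-identical scenes, different seeds differ", {
  p <- small_preset()
  a <- generate_filament_scene(p, seed = 3)
  b <- generate_filament_scene(p, seed = 3)
  expect_identical(a$images$fret, b$images$fret)
  expect_identical(a$truth$filament_mask, b$truth$filament_mask)
  c <- generate_filament_scene(p, seed = 4)
  expect_false(identical(a$images$fret, c$images$fret))
})

test_that("truth and images share dimensions and truth NFRET is structured", {
  sc <- generate_filament_scene(small_preset(), seed = 2)
  W <- small_preset()$field_size
  expect_identical(dim(sc$images), c(W, W))
  expect_identical(dim(sc$truth$filament_mask), dim(sc$images))
  expect_identical(dim(sc$truth$nfret_truth), dim(sc$images))
  expect_true(all(sc$truth$nfret_truth >= 0))
  # on-mask truth = filament level; in-cell off-mask = cytosol; outside = 0
  tm <- sc$truth$filament_mask
  cm <- sc$truth$cell_mask
  expect_true(all(sc$truth$nfret_truth[tm] == 14.5))
  expect_true(all(sc$truth$nfret_truth[cm & !tm] == 5))
  expect_true(all(sc$truth$nfret_truth[!cm] == 0))
})

test_that("noiseless scene is an exact inverse of the NFRET pipeline", {
  sc <- generate_filament_scene(noiseless(), seed = 1)
  im <- subtract_background(sc$images, corner_bg())
  nf <- compute_nfret(im, typical_bleed())
  tm <- sc$truth$filament_mask
  on_mask <- nf$values[tm & nf$valid_mask]
  expect_lt(max(abs(on_mask - 14.5)) / 14.5, 1e-6)
  cyt <- nf$values[sc$truth$cell_mask & !tm & nf$valid_mask]
  expect_lt(max(abs(cyt - 5)) / 5, 1e-6)
})

test_that("zero-FRET preset yields a null corrected index", {
  p <- noiseless()
  p$nfret_filament <- 0
  p$nfret_cytosol <- 0
  sc <- generate_filament_scene(p, seed = 1)
  im <- subtract_background(sc$images, corner_bg())
  f <- compute_fret_index(im, typical_bleed())
  expect_lt(max(abs(f)), 1e-6)
})

test_that("noisy scenes recover the on-mask preset level within the MC band", {
  # band from repeated-seed pilot runs: single-scene on-truth-mask mean has
  # SD ~0.1 at the 128 px field; 0.5 is > 4 sigma
  p <- small_preset()
  means <- vapply(1:3, function(s) {
    sc <- generate_filament_scene(p, seed = s)
    im <- subtract_background(sc$images, corner_bg())
    nf <- compute_nfret(im, typical_bleed())
    tm <- sc$truth$filament_mask
    mean(nf$values[tm & nf$valid_mask])
  }, numeric(1))
  expect_lt(abs(mean(means) - 14.5), 0.5)
})

test_that("calibration scenes encode a pure single-fluorophore leak", {
  bt <- noiseless("paper-typical-bleedthrough")
  d <- generate_calibration_scene("donor-only", bt, seed = 1)
  sig <- d$donor - 20
  ratio <- (d$fret - 20)[sig > 1] / sig[sig > 1]
  expect_lt(max(abs(ratio - 0.1)), 1e-9)
  expect_true(all(d$acceptor == 20))
  # acceptor-only with zero B leaves the FRET channel at background
  bt0 <- bt
  bt0$bleed_B <- 0
  a <- generate_calibration_scene("acceptor-only", bt0, seed = 1)
  expect_true(all(a$fret == 20))
})

test_that("FRAP generator matches its analytic ground truth when clean", {
  p <- noiseless()
  p$bleach_residual <- 0
  p$acquisition_loss_total <- 0
  el <- generate_frap_series(p, seed = 1)[[1]]
  nt <- normalize_trace(el$trace, background = 20)
  expect_equal(nt$value, el$truth$g(nt$time), tolerance = 1e-12)
  expect_equal(nt$value[1], 0)
  expect_true(all(diff(el$truth$g(nt$time)) >= 0))
})

test_that("immobile FRAP sample stays flat at the bleach floor", {
  p <- noiseless()
  p$frap_fractions <- c(A1_star = 0, A2_star = 0)
  el <- generate_frap_series(p, seed = 1)[[1]]
  post <- el$trace$phase == "post"
  expected <- 20 + el$truth$loss_curve[post] * 1000 * p$bleach_residual
  expect_equal(el$trace$roi_intensity[post], expected, tolerance = 1e-12)
})

test_that("depolymerization time course starts at the base scene and halves on schedule", {
  p <- small_preset()
  base <- generate_filament_scene(p, seed = 5)
  tc <- generate_nocodazole_timecourse(p, seed = 5, timepoints = c(0, 600),
                                       half_time_s = 600)
  expect_identical(tc[[1]]$images$fret, base$images$fret)
  expect_identical(tc[[1]]$truth$filament_mask, base$truth$filament_mask)
  # at one half-time the on-filament excess over cytosol is halved
  excess0 <- tc[[1]]$truth$nfret_filament_t - p$nfret_cytosol
  excess1 <- tc[[2]]$truth$nfret_filament_t - p$nfret_cytosol
  expect_equal(excess1, excess0 / 2)
  # and the filament mask shrinks
  expect_lt(sum(tc[[2]]$truth$filament_mask), sum(tc[[1]]$truth$filament_mask))
  expect_error(generate_nocodazole_timecourse(p, 1, c(600, 0)),
               class = "cst_config_error")
})

test_that("a preset implying saturated clean signal is rejected", {
  p <- small_preset()
  p$noise_scale <- 6e4 # pushes clean channels past the 16-bit ceiling
  expect_error(generate_filament_scene(p, seed = 1),
               class = "cst_config_error")
})
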