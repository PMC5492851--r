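const_set <- function(d, a, f, n = 4) {
  image_set(matrix(d, n, n), matrix(a, n, n), matrix(f, n, n))
}

test_that("corrected FRET index evaluates the cross-talk formula", {
  b <- typical_bleed()
  expect_equal(compute_fret_index(const_set(100, 100, 50), b)[1, 1], 15)
  # A = B = 0 is the identity on the FRET channel
  im <- const_set(80, 120, 33)
  expect_equal(compute_fret_index(im, bleedthrough_params(0, 0)), im$fret)
  # exact cancellation when the FRET channel is pure bleed-through
  im2 <- const_set(100, 200, 0.1 * 100 + 0.25 * 200)
  expect_true(all(abs(compute_fret_index(im2, b)) < 1e-12))
  expect_error(image_set(matrix(1, 2, 2), matrix(1, 3, 3), matrix(1, 2, 2)),
               class = "cst_shape_error")
})

test_that("NFRET is the x100 normalized index with clamping and validity", {
  b <- typical_bleed()
  nf <- compute_nfret(const_set(100, 100, 50), b, signal_floor = 15)
  expect_equal(nf$values[1, 1], 15) # F_index 15, denominator 100
  # quadrupling all channels leaves NFRET unchanged (gain invariance)
  nf4 <- compute_nfret(const_set(400, 400, 200), b, signal_floor = 15)
  expect_equal(nf4$values, nf$values)
  # negative index clamps to zero but stays valid
  neg <- compute_nfret(const_set(100, 100, 10), b)
  expect_equal(neg$values[1, 1], 0)
  expect_lt(neg$raw[1, 1], 0)
  expect_true(neg$valid_mask[1, 1])
  # below the signal floor pixels are invalid NA, not zero, with a warning
  expect_warning(
    dim_px <- compute_nfret(const_set(10, 10, 50), b, signal_floor = 15),
    class = "cst_empty_result")
  expect_true(all(is.na(dim_px$values)))
  expect_false(any(dim_px$valid_mask))
})

test_that("clamping only raises values, with equality where raw is non-negative", {
  sc <- generate_filament_scene(small_preset(), seed = 6)
  nf <- compute_nfret(subtract_background(sc$images, corner_bg()),
                      typical_bleed())
  v <- nf$valid_mask
  expect_true(all(nf$values[v] >= nf$raw[v]))
  pos <- v & !is.na(nf$raw) & nf$raw >= 0
  expect_identical(nf$values[pos], nf$raw[pos])
})

test_that("filament mask overlaps generator truth and tracks depolymerization", {
  # at the preset's native field size, where filament density matches the
  # crowding the masking defaults were designed for
  res <- run_scene_nfret(cst_preset("CST-untreated"), seed = 1)
  tm <- res$scene$truth$filament_mask
  jac <- sum(res$mask & tm) / sum(res$mask | tm)
  expect_gt(jac, 0.5)
  # blank image gives an empty mask with a warning
  expect_warning(mk0 <- filament_mask(matrix(0, 32, 32)),
                 class = "cst_empty_mask")
  expect_false(any(mk0))
  # mask area shrinks monotonically along a depolymerization series
  tc <- generate_nocodazole_timecourse(small_preset(), seed = 2,
                                       timepoints = c(0, 900, 1800),
                                       half_time_s = 600)
  areas <- vapply(tc, function(el) {
    im <- subtract_background(el$images, corner_bg())
    sum(filament_mask(im$acceptor))
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("line profiles interpolate along paths and find filament crossings", {
  expect_equal(extract_line_profile(matrix(7, 16, 16),
                                    rbind(c(2, 2), c(2, 14)))$value,
               rep(7, 13))
  # single peak where a horizontal line crosses a vertical stripe
  img <- matrix(0, 32, 32)
  img[, 16] <- 10
  prof <- extract_line_profile(img, rbind(c(16, 4), c(16, 28)), step = 1)
  expect_equal(prof$position[which.max(prof$value)], 12) # 4 + 12 = col 16
  expect_true(all(diff(prof$position) > 0))
  expect_error(extract_line_profile(img, rbind(c(1, 1), c(40, 1))),
               class = "cst_out_of_bounds")
  # profile over a real NFRET map peaks in the on-filament range
  res <- run_scene_nfret(small_preset(), seed = 3)
  pl <- res$scene$truth$filament_polylines[[1]]
  mid <- pl[nrow(pl) %/% 2, ]
  path <- rbind(mid + c(-6, -6), mid + c(6, 6))
  path <- pmin(pmax(path, 2), small_preset()$field_size - 1)
  prof <- extract_line_profile(res$nfret, path, step = 0.5)
  expect_gt(max(prof$value, na.rm = TRUE), 10)
})

test_that("region statistics support per-pixel and per-cell conventions", {
  vals <- matrix(10, 8, 8)
  mask <- matrix(TRUE, 8, 8)
  st <- region_nfret_stats(vals, mask)
  expect_equal(st$mean, 10)
  expect_equal(st$sd, 0)
  expect_equal(st$n, 64)
  # per-cell: means per label first, then across cells
  labels <- matrix(rep(1:2, each = 32), 8, 8)
  vals2 <- matrix(c(rep(10, 32), rep(20, 32)), 8, 8)
  st2 <- region_nfret_stats(vals2, mask, cell_labels = labels)
  expect_equal(st2$mean, 15)
  expect_equal(st2$n, 2)
  expect_equal(st2$mode, "per-cell")
  expect_error(region_nfret_stats(vals, matrix(FALSE, 8, 8)),
               class = "cst_empty_mask")
})

test_that("intramolecular-control analogue: no sensitized term means ~0 NFRET", {
  # co-localized donor/acceptor with S = 0 (both NFRET levels zero) must be
  # statistically indistinguishable from zero after clamping-aware averaging
  p <- small_preset()
  p$nfret_filament <- 0
  p$nfret_cytosol <- 0
  means <- vapply(1:5, function(s) {
    res <- run_scene_nfret(p, seed = s)
    tm <- res$scene$truth$filament_mask
    mean(res$nfret$raw[tm & res$nfret$valid_mask]) # raw: unbiased around 0
  }, numeric(1))
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se + 0.02)
})

test_that("Pearson colocalization matches known correlations", {
  img <- matrix(runif(400), 20, 20)
  expect_equal(pearson_colocalization(img, img), 1)
  expect_equal(pearson_colocalization(img, -img + 5), -1)
  expect_error(pearson_colocalization(img, matrix(1, 20, 20)),
               class = "cst_degenerate")
  # bivariate field with population rho = 0.8 at n = 10^4
  n <- 100
  set.seed(42)
  x <- matrix(rnorm(n * n), n, n)
  e <- matrix(rnorm(n * n), n, n)
  y <- 0.8 * x + sqrt(1 - 0.8^2) * e
  expect_lt(abs(pearson_colocalization(x, y) - 0.8), 0.02)
})

test_that("fire rendering maps the display range onto the LUT", {
  lut <- fire_lut()
  expect_equal(dim(lut), c(256L, 3L))
  expect_equal(unname(lut[1, ]), c(0, 0, 0))
  expect_equal(unname(lut[256, ]), c(255, 255, 255))
  # column-major fill: [1,1]=0, [2,1]=30, [1,2]=60, [2,2]=90, [1,3]=NA
  vals <- matrix(c(0, 30, 60, 90, NA_real_, 15), 2, 3)
  r <- render_false_color(vals, display_range = c(0, 60))
  expect_equal(r[1, 1, ], c(0L, 0L, 0L)) # 0 -> black
  expect_equal(r[2, 1, ], unname(lut[129, ])) # 30 -> 0-based index 128
  expect_equal(r[1, 2, ], unname(lut[256, ])) # 60 = top of range
  expect_equal(r[2, 2, ], unname(lut[256, ])) # 90 clips to top color
  expect_equal(r[1, 3, ], c(0L, 0L, 0L)) # invalid pixel renders black
})

test_that("NFRET time course is flat for static scenes, decays under depolymerization", {
  sc <- generate_filament_scene(small_preset(), seed = 4)
  im <- subtract_background(sc$images, corner_bg())
  ts <- nfret_timecourse(list(im, im, im), c(0, 60, 120), typical_bleed())
  expect_equal(nrow(ts), 3)
  expect_equal(ts$mean, rep(ts$mean[1], 3))
  tc <- generate_nocodazole_timecourse(small_preset(), seed = 7,
                                       timepoints = c(0, 600, 1800),
                                       half_time_s = 600)
  ims <- lapply(tc, function(el) subtract_background(el$images, corner_bg()))
  ts2 <- nfret_timecourse(ims, c(0, 600, 1800), typical_bleed(),
                          mask_policy = "per-frame")
  expect_true(all(diff(ts2$mean) < 0))
})

test_that("cytosolic random sampling is reproducible and reads cytosol levels", {
  res <- run_scene_nfret(small_preset(), seed = 9)
  cm <- res$scene$truth$cell_mask
  tm <- res$scene$truth$filament_mask
  s1 <- sample_cytosol_nfret(res$nfret, cm, tm, n = 50, seed = 3)
  s2 <- sample_cytosol_nfret(res$nfret, cm, tm, n = 50, seed = 3)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 50)
  expect_lt(abs(mean(s1$value) - 5), 2.5) # cytosol truth is 5 on this preset
})
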