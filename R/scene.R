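# ---- geometry ---------------------------------------------------------------

# Cell body (rotated ellipse) plus persistent-random-walk filament polylines
# radiating from a microtubule-organizing-center-like point. Pure function of
# the RNG state: callers wrap it in with_seed().
scene_geometry <- function(preset, n_filaments = 12L, step = 1.5,
                           turn_sd = 0.12) {
  W <- preset$field_size
  cx <- W / 2 + runif(1, -0.03, 0.03) * W
  cy <- W / 2 + runif(1, -0.03, 0.03) * W
  a <- 0.42 * W
  b <- 0.30 * W
  th <- runif(1, 0, pi)
  R <- matrix(seq_len(W), W, W)
  C <- matrix(seq_len(W), W, W, byrow = TRUE)
  u <- (R - cx) * cos(th) + (C - cy) * sin(th)
  v <- -(R - cx) * sin(th) + (C - cy) * cos(th)
  cell <- (u / a)^2 + (v / b)^2 <= 1
  inside <- function(x, y) {
    uu <- (x - cx) * cos(th) + (y - cy) * sin(th)
    vv <- -(x - cx) * sin(th) + (y - cy) * cos(th)
    (uu / a)^2 + (vv / b)^2 <= 0.96 # keep filaments just inside the membrane
  }
  mtoc <- c(cx, cy) + runif(2, -0.08, 0.08) * W
  max_steps <- ceiling(2.5 * W / step)
  polylines <- vector("list", n_filaments)
  for (i in seq_len(n_filaments)) {
    for (try in 1:50) {
      x <- mtoc[1] + rnorm(1, 0, 2)
      y <- mtoc[2] + rnorm(1, 0, 2)
      dir <- runif(1, 0, 2 * pi)
      px <- numeric(max_steps); py <- numeric(max_steps)
      n <- 0L
      while (n < max_steps && inside(x, y)) {
        n <- n + 1L
        px[n] <- x; py[n] <- y
        dir <- dir + rnorm(1, 0, turn_sd)
        x <- x + step * cos(dir)
        y <- y + step * sin(dir)
      }
      if (n >= 8L) { polylines[[i]] <- cbind(x = px[1:n], y = py[1:n]); break }
    }
    if (is.null(polylines[[i]])) # pathological cell: fall back to a short stub
      polylines[[i]] <- cbind(x = c(cx, cx + 8), y = c(cy, cy))
  }
  list(cell = cell, polylines = polylines, field_size = W)
}

# Rasterize polylines into a fluorophore density with ~Gaussian cross-section
# (sigma 1 px, unit peak for a single filament) and a ground-truth mask of
# pixels within `mask_radius` px of any polyline. `frac` truncates each
# polyline to that fraction of its length (used by the depolymerization
# time course).
rasterize_filaments <- function(polylines, W, frac = 1, sigma = 1,
                                mask_radius = 2) {
  raster <- matrix(0, W, W)
  marker <- matrix(0, W, W)
  sub <- 0.5 # resampling step along the path, px
  for (pl in polylines) {
    n <- nrow(pl)
    keep <- max(2L, ceiling(frac * n))
    if (frac <= 0) next
    pl <- pl[seq_len(min(keep, n)), , drop = FALSE]
    seg <- sqrt(diff(pl[, 1])^2 + diff(pl[, 2])^2)
    s <- c(0, cumsum(seg))
    if (s[length(s)] <= 0) next
    at <- seq(0, s[length(s)], by = sub)
    xs <- stats::approx(s, pl[, 1], xout = at)$y
    ys <- stats::approx(s, pl[, 2], xout = at)$y
    ri <- round(xs); ci <- round(ys)
    ok <- ri >= 1 & ri <= W & ci >= 1 & ci <= W
    idx <- ri[ok] + (ci[ok] - 1) * W
    tab <- tabulate(idx, nbins = W * W)
    raster <- raster + matrix(tab, W, W) * sub
    marker[idx] <- 1
  }
  density <- EBImage::imageData(EBImage::gblur(raster, sigma = sigma)) *
    sqrt(2 * pi) * sigma
  if (any(marker > 0)) {
    dist <- EBImage::imageData(EBImage::distmap(1 - marker))
    mask <- dist <= mask_radius
  } else {
    mask <- matrix(FALSE, W, W)
  }
  list(density = density, mask = mask)
}

# ---- emission ---------------------------------------------------------------

MAX_CODE_16BIT <- 65535

# Clean (noiseless) channel model. The sensitized term is constructed as the
# exact algebraic inverse of the NFRET definition so that the analysis
# pipeline recovers the preset truth exactly in the noiseless limit:
#   S(x) = nfret_truth(x)/100 * sqrt(D(x) * Acc(x))
#   I_FRET = bg + A*D + B*Acc + S
scene_clean <- function(cell, density, mask, preset, nfret_fil, bg = 20,
                        cytosol_frac = 0.25) {
  amp <- if (preset$noise_scale > 0) preset$noise_scale else 1000
  shape <- cytosol_frac * cell + (1 - cytosol_frac) * pmin(density, 4 / 3)
  D <- amp * shape
  Acc <- amp * shape
  nfret_truth <- matrix(0, nrow(cell), ncol(cell))
  nfret_truth[cell] <- preset$nfret_cytosol
  nfret_truth[mask] <- nfret_fil
  S <- nfret_truth / 100 * sqrt(D * Acc)
  fret_clean <- bg + preset$bleed_A * D + preset$bleed_B * Acc + S
  if (max(fret_clean, bg + D, bg + Acc) > MAX_CODE_16BIT)
    cst_error("cst_config_error",
              "preset implies clean signal above the 16-bit saturation ceiling")
  list(donor = D, acceptor = Acc, fret_clean = fret_clean,
       nfret_truth = nfret_truth, bg = bg)
}

# Poisson shot noise at the photon-count scale plus Gaussian read noise,
# floored at zero counts. Draws consume the RNG stream channel by channel.
add_shot_noise <- function(mu, read_sd = 2) {
  n <- matrix(stats::rpois(length(mu), mu) + stats::rnorm(length(mu), 0, read_sd),
              nrow(mu), ncol(mu))
  pmax(n, 0)
}

emit_channels <- function(clean, preset, noise_seed, read_sd = 2) {
  bg <- clean$bg
  mu_d <- bg + clean$donor
  mu_a <- bg + clean$acceptor
  mu_f <- clean$fret_clean
  if (preset$noise_scale > 0) {
    with_seed(noise_seed, {
      d <- add_shot_noise(mu_d, read_sd)
      a <- add_shot_noise(mu_a, read_sd)
      f <- add_shot_noise(mu_f, read_sd)
      image_set(d, a, f)
    })
  } else {
    image_set(mu_d, mu_a, mu_f)
  }
}

# ---- public generators ------------------------------------------------------

#' Generate a three-channel filament scene with known ground truth
#'
#' Builds a cell body containing smooth filament polylines (persistent random
#' walks with a ~1 px Gaussian cross-section), assigns donor and acceptor
#' signals proportional to local fluorophore density, and constructs the FRET
#' channel as background + bleed-through + a sensitized-emission term that is
#' the exact inverse of the NFRET definition. With nonzero
#' \code{noise_scale}, Poisson shot noise and Gaussian read noise are added.
#' Deterministic for fixed \code{(preset, seed)}.
#'
#' @param preset a \code{scene_preset} (see [cst_presets()]).
#' @param seed integer seed; all randomness derives from it.
#' @param bg flat background level in counts.
#' @param n_filaments number of filament polylines.
#' @return list with elements \code{images} (an [image_set()]) and
#'   \code{truth} (class \code{scene_truth}: \code{filament_mask},
#'   \code{filament_polylines}, \code{nfret_truth}, \code{clean_donor},
#'   \code{clean_acceptor}, \code{cell_mask}, \code{background}).
#' @export
#' @examples
#' sc <- generate_filament_scene(cst_preset("CST-untreated"), seed = 1)
#' dim(sc$images)
generate_filament_scene <- function(preset, seed, bg = 20, n_filaments = 12L) {
  geom <- with_seed(derive_seed(seed, "scene-geom"),
                    scene_geometry(preset, n_filaments = n_filaments))
  ras <- rasterize_filaments(geom$polylines, geom$field_size)
  mask <- ras$mask & geom$cell
  clean <- scene_clean(geom$cell, ras$density, mask, preset,
                       preset$nfret_filament, bg = bg)
  images <- emit_channels(clean, preset, derive_seed(seed, "scene-noise"))
  truth <- structure(list(
    filament_mask = mask,
    filament_polylines = geom$polylines,
    nfret_truth = clean$nfret_truth,
    clean_donor = clean$donor,
    clean_acceptor = clean$acceptor,
    cell_mask = geom$cell,
    background = bg
  ), class = "scene_truth")
  list(images = images, truth = truth)
}

#' Generate a single-fluorophore calibration scene
#'
#' Emulates reference cells expressing only the donor (or only the acceptor):
#' the FRET channel contains background plus the corresponding leak-through
#' term only. Calibration cells are rendered bright (20x the scene amplitude)
#' so pixel intensities span a wide dynamic range and the bleed-through
#' regression is well-conditioned.
#'
#' @param kind \code{"donor-only"} or \code{"acceptor-only"}.
#' @param preset a \code{scene_preset} supplying the bleed fractions and noise.
#' @param seed integer seed.
#' @param bg flat background level in counts.
#' @param gain amplitude multiplier relative to the preset noise scale.
#' @return an [image_set()].
#' @export
generate_calibration_scene <- function(kind = c("donor-only", "acceptor-only"),
                                       preset, seed, bg = 20, gain = 20) {
  kind <- match.arg(kind)
  geom <- with_seed(derive_seed(seed, paste0("calib-geom-", kind)),
                    scene_geometry(preset))
  ras <- rasterize_filaments(geom$polylines, geom$field_size)
  amp <- gain * (if (preset$noise_scale > 0) preset$noise_scale else 1000)
  shape <- 0.25 * geom$cell + 0.75 * pmin(ras$density, 4 / 3)
  sig <- amp * shape
  if (bg + max(sig) * max(1, 1) > MAX_CODE_16BIT * 0.9)
    sig <- sig * (MAX_CODE_16BIT * 0.9 - bg) / max(sig)
  zero <- matrix(0, nrow(sig), ncol(sig))
  if (kind == "donor-only") {
    mu_d <- bg + sig; mu_a <- bg + zero; mu_f <- bg + preset$bleed_A * sig
  } else {
    mu_d <- bg + zero; mu_a <- bg + sig; mu_f <- bg + preset$bleed_B * sig
  }
  if (preset$noise_scale > 0) {
    with_seed(derive_seed(seed, paste0("calib-noise-", kind)), {
      image_set(add_shot_noise(mu_d), add_shot_noise(mu_a), add_shot_noise(mu_f))
    })
  } else {
    image_set(mu_d, mu_a, mu_f)
  }
}

#' Generate a microtubule-depolymerization NFRET time course
#'
#' Emulates nocodazole treatment: from the same base scene geometry as
#' [generate_filament_scene()] (the frame at time 0 is identical for the same
#' seed), the on-filament NFRET excess over the cytosolic level decays
#' exponentially with half-time \code{half_time_s}, and filament polylines
#' shorten by the same factor so the filament mask area shrinks.
#'
#' @param preset a \code{scene_preset}.
#' @param seed integer seed.
#' @param timepoints nondecreasing vector of times in seconds.
#' @param half_time_s half-time of the on-filament NFRET excess decay, seconds.
#' @param bg flat background level in counts.
#' @return list of per-timepoint lists \code{(time, images, truth)}.
#' @export
generate_nocodazole_timecourse <- function(preset, seed, timepoints,
                                           half_time_s = 600, bg = 20) {
  if (is.unsorted(timepoints))
    cst_error("cst_config_error", "timepoints must be nondecreasing")
  geom <- with_seed(derive_seed(seed, "scene-geom"), scene_geometry(preset))
  lapply(seq_along(timepoints), function(i) {
    t <- timepoints[i]
    w <- 2^(-t / half_time_s)
    ras <- rasterize_filaments(geom$polylines, geom$field_size, frac = w)
    mask <- ras$mask & geom$cell
    nfret_fil <- preset$nfret_cytosol +
      (preset$nfret_filament - preset$nfret_cytosol) * w
    clean <- scene_clean(geom$cell, ras$density, mask, preset, nfret_fil,
                         bg = bg)
    images <- emit_channels(clean, preset,
                            derive_seed(seed, "scene-noise", i - 1L))
    truth <- structure(list(
      filament_mask = mask,
      filament_polylines = geom$polylines,
      nfret_truth = clean$nfret_truth,
      clean_donor = clean$donor,
      clean_acceptor = clean$acceptor,
      cell_mask = geom$cell,
      background = bg,
      nfret_filament_t = nfret_fil
    ), class = "scene_truth")
    list(time = t, images = images, truth = truth)
  })
}
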