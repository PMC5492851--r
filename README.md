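# cstquant

Quantitative imaging pipeline for a **conformational-sensitive Tau sensor
(CST)** — full-length Tau with ECFP/EYFP fused at its N- and C-termini, which
folds into a FRET-permissive hairpin when bound to microtubules and is
extended (FRET-silent) when soluble. The package implements the two
measurements that characterize this sensor, for researchers analyzing
sensitized-emission FRET microscopy and FRAP of cytoskeleton-associated
proteins:

**Sensitized-emission FRET.** Donor/acceptor bleed-through fractions `A`, `B`
are calibrated by pixelwise OLS on single-fluorophore reference images; the
cross-talk-corrected index and its intensity-normalized form are computed
pixelwise:

    F_index = I_FRET − A·I_D − B·I_A
    NFRET   = 100 · F_index / √(I_D · I_A)      (negatives clamped to 0)

with saturation QC, filament segmentation (Otsu + skeletonization), line
profiles, per-cell region statistics, Pearson colocalization and fire-LUT
false-color rendering.

**FRAP.** Recovery traces are normalized in four steps (background; mean
prebleach; whole-cell acquisition-loss correction
`F_pre-wholecell / F_post-wholecell` per frame; bleach-floor re-zeroing and
rescaling) and fitted with the two-phase exponential association

    y = y0 + A1*·(1 − exp(−t/τ1)) + A2*·(1 − exp(−t/τ2))

giving the mobile fraction `Mob = A1* + A2*` and the normalized fast
(diffusive) and slow (microtubule-exchange) shares `A1 = A1*/Mob`,
`A2 = 1 − A1`.

Because the original live-cell images are not deposited, the package ships a
**synthetic microscopy generator** — filament scenes, single-fluorophore
calibration scenes, FRAP series and depolymerization time courses — whose
named presets encode the measured condition parameters (untreated,
nocodazole, paclitaxel, P301L, dK280, AT8mut). The generator is the exact
algebraic inverse of the correction formulas, so the whole pipeline is
verified by parameter recovery: exactly (≤1e-6) without noise, within
Monte-Carlo bands with noise.

## Worked example

```r
library(cstquant)

# calibrate bleed-through from a simulated donor-only reference cell
bt <- cst_preset("paper-typical-bleedthrough")
cal <- generate_calibration_scene("donor-only", bt, seed = 7)
fit <- estimate_bleedthrough(subtract_background(cal, bg_roi(1:16, 1:16)), "donor")
fit
#> <calibration_fit> fret~donor: slope 0.0999, intercept 0.12, R^2 0.997, n = 30741 px

# quantify NFRET on a simulated untreated cell
sc <- generate_filament_scene(cst_preset("CST-untreated"), seed = 1)
im <- subtract_background(sc$images, bg_roi(1:16, 1:16))
nf <- compute_nfret(im, bleedthrough_params(0.1, 0.25))
region_nfret_stats(nf, filament_mask(im$acceptor))
#>     region     mean        sem       sd    n      mode
#> 1 filament 14.56488 0.05675589 3.394932 3578 per-pixel

# FRAP: normalize and fit one simulated untreated-cell trace
el <- generate_frap_series(cst_preset("CST-untreated"), seed = 1)[[1]]
fit_two_phase(normalize_trace(el$trace, background = 20))
#> <frap_fit> Mob = 0.764 (A1* = 0.211 @ tau1 = 5.48s, A2* = 0.553 @ tau2 = 35.55s)
#>   shares A1 = 0.276 A2 = 0.724; y0 = -0.0035; rss = 0.0186
```

The NFRET mean (14.5 on the ×100 scale) is the hairpin-fold signal on the
microtubule network; the FRAP fit says ~76% of sensor molecules are mobile,
~28% of them in the fast diffusive pool (τ1 ≈ 5 s) and the rest exchanging
with the microtubule-bound state (τ2 ≈ 35 s).

The numbered scripts under `analysis/` run the full study narrative:
`01_simulate.R` (example raw data on disk), `02_calibrate.R` (A/B
regression), `03_nfret.R` (condition NFRET table and nocodazole time
course), `04_frap.R` (30-trace mobility summaries per condition),
`05_report.R` (single-seed orchestrated pipeline via `run_pipeline()`).
Tables and rendered maps land under `results/`.

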