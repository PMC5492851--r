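# ---- configuration ----------------------------------------------------------

#' Pipeline configuration
#'
#' Bundles everything one reproducible run needs: the condition presets to
#' simulate, the single master seed (every stage derives its own stream from
#' it via [derive_seed()]), output directory and analysis settings. The
#' configuration round-trips losslessly through JSON.
#'
#' @param presets character vector of preset names (see [cst_presets()]).
#' @param seed master integer seed.
#' @param out_dir output directory (created on run).
#' @param n_scenes filament scenes (= cells) per condition.
#' @param n_traces FRAP traces per condition.
#' @param n_calibration single-fluorophore scenes per calibration mode.
#' @param display_range NFRET false-color display range.
#' @param stats_mode \code{"per-cell"} (one mean per scene, then across
#'   scenes) or \code{"per-pixel"} (pool all masked pixels).
#' @param signal_floor NFRET validity floor, counts.
#' @param background_counts known acquisition background used for FRAP trace
#'   normalization.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(presets = setdiff(names(cst_presets()),
                                              "paper-typical-bleedthrough"),
                            seed = 1L,
                            out_dir = tempfile("cstquant-run-"),
                            n_scenes = 3L,
                            n_traces = 10L,
                            n_calibration = 3L,
                            display_range = c(0, 60),
                            stats_mode = c("per-cell", "per-pixel"),
                            signal_floor = 15,
                            background_counts = 20) {
  stats_mode <- match.arg(stats_mode)
  reg <- names(cst_presets())
  missing <- setdiff(presets, reg)
  if (length(missing))
    cst_error("cst_missing_preset",
              paste("unknown preset(s):", paste(missing, collapse = ", ")))
  structure(list(presets = presets, seed = as.integer(seed), out_dir = out_dir,
                 n_scenes = as.integer(n_scenes),
                 n_traces = as.integer(n_traces),
                 n_calibration = as.integer(n_calibration),
                 display_range = display_range, stats_mode = stats_mode,
                 signal_floor = signal_floor,
                 background_counts = background_counts),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a \code{pipeline_config}.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj[setdiff(names(obj), character(0))])
}

# corner rectangle guaranteed off-cell for generator scenes
corner_bg_strategy <- function() bg_roi(1:16, 1:16)

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    cst_error("cst_stage_error",
              sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

# ---- pipeline ---------------------------------------------------------------

#' Run the full simulate - calibrate - quantify - fit - report pipeline
#'
#' Stages: (1) generate single-fluorophore calibration scenes and estimate
#' the bleed-through fractions A and B by pixelwise regression; (2) per
#' condition preset, generate filament scenes, apply saturation QC and
#' background subtraction, compute NFRET maps and on-filament statistics;
#' (3) generate FRAP series, normalize and fit the two-phase model, and
#' summarize per condition; (4) write the report (JSON), stats tables (CSV)
#' and one false-color NFRET rendering per condition (PNG). Fully
#' deterministic for a fixed configuration.
#'
#' @param config a [pipeline_config()].
#' @return object of class \code{run_report} (also written to
#'   \code{config$out_dir/report.json}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  qc_rejects <- 0L
  calib_preset <- cst_preset("paper-typical-bleedthrough")

  calib <- run_stage("calibrate", {
    est_one <- function(kind, mode) {
      scenes <- lapply(seq_len(config$n_calibration), function(i) {
        sc <- generate_calibration_scene(
          kind, calib_preset, derive_seed(config$seed, paste0("calib-", kind), i))
        if (!flag_saturation(sc)$pass) { qc_rejects <<- qc_rejects + 1L; NULL }
        else subtract_background(sc, corner_bg_strategy())
      })
      estimate_bleedthrough(Filter(Negate(is.null), scenes), mode = mode)
    }
    list(donor = est_one("donor-only", "donor"),
         acceptor = est_one("acceptor-only", "acceptor"))
  })
  bleed <- bleedthrough_params(calib$donor$slope, calib$acceptor$slope)

  nfret_rows <- list()
  frap_rows <- list()
  fit_failures <- 0L
  for (preset_name in config$presets) {
    preset <- cst_preset(preset_name)
    run_stage(paste0("nfret:", preset_name), {
      per_scene <- vapply(seq_len(config$n_scenes), function(i) {
        sc <- generate_filament_scene(
          preset, derive_seed(config$seed, paste0("scene-", preset_name), i))
        if (!flag_saturation(sc$images)$pass) {
          qc_rejects <<- qc_rejects + 1L
          return(NA_real_)
        }
        im <- subtract_background(sc$images, corner_bg_strategy())
        nf <- compute_nfret(im, bleed, config$signal_floor)
        mask <- filament_mask(im$acceptor)
        if (!any(mask)) mask <- sc$truth$cell_mask # depolymerized condition
        if (i == 1L) {
          render <- render_false_color(nf, config$display_range)
          write_render_png(render, file.path(config$out_dir,
                                             paste0("nfret_", preset_name,
                                                    ".png")))
        }
        if (config$stats_mode == "per-cell")
          region_nfret_stats(nf, mask)$mean
        else mean(nf$values[mask & nf$valid_mask])
      }, numeric(1))
      per_scene <- per_scene[!is.na(per_scene)]
      nfret_rows[[preset_name]] <- data.frame(
        condition = preset_name, mean = mean(per_scene),
        sem = stats::sd(per_scene) / sqrt(length(per_scene)),
        sd = stats::sd(per_scene), n = length(per_scene),
        mode = config$stats_mode, stringsAsFactors = FALSE)
    })
    run_stage(paste0("frap:", preset_name), {
      series <- generate_frap_series(
        preset, derive_seed(config$seed, paste0("frap-", preset_name)),
        n_traces = config$n_traces)
      fits <- fit_frap_series(series, background = config$background_counts)
      fit_failures <- fit_failures +
        sum(!vapply(fits, `[[`, logical(1), "converged"))
      frap_rows[[preset_name]] <- summarize_condition(fits, preset_name)
    })
  }

  nfret_stats <- do.call(rbind, unname(nfret_rows))
  frap_summary <- do.call(rbind, unname(frap_rows))
  report <- structure(list(
    config = unclass(config),
    calibration = list(A = bleed$A, B = bleed$B,
                       donor_fit = unclass(calib$donor),
                       acceptor_fit = unclass(calib$acceptor)),
    nfret_stats = nfret_stats,
    frap_summary = frap_summary,
    qc = list(saturation_rejects = qc_rejects, fit_failures = fit_failures),
    provenance = list(package = "cstquant",
                      version = as.character(utils::packageVersion("cstquant")),
                      r_version = R.version.string,
                      seed = config$seed,
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), class = "run_report")
  utils::write.csv(nfret_stats, file.path(config$out_dir, "nfret_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(frap_summary, file.path(config$out_dir, "frap_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(report), file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  calibration: A = %.4f, B = %.4f\n", x$calibration$A,
              x$calibration$B))
  cat("  NFRET (on-filament, x100):\n")
  for (i in seq_len(nrow(x$nfret_stats)))
    cat(sprintf("    %-18s %.2f +/- %.2f (n = %d %s)\n",
                x$nfret_stats$condition[i], x$nfret_stats$mean[i],
                x$nfret_stats$sem[i], x$nfret_stats$n[i],
                x$nfret_stats$mode[i]))
  cat("  FRAP mobile fractions:\n")
  for (i in seq_len(nrow(x$frap_summary)))
    cat(sprintf("    %-18s Mob %.3f +/- %.3f, tau1 %.1fs, tau2 %.1fs (n = %d)\n",
                x$frap_summary$condition[i], x$frap_summary$mob_mean[i],
                x$frap_summary$mob_sem[i], x$frap_summary$tau1_mean[i],
                x$frap_summary$tau2_mean[i], x$frap_summary$n[i]))
  cat(sprintf("  QC: %d saturation rejects, %d fit failures\n",
              x$qc$saturation_rejects, x$qc$fit_failures))
  invisible(x)
}
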