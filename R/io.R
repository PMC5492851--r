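# ---- TIFF channels ----------------------------------------------------------

#' Read one grayscale channel TIFF as counts
#'
#' 16-bit input is read natively; 8-bit input is accepted and promoted to the
#' numeric count scale with a warning.
#'
#' @param path TIFF file path.
#' @return numeric matrix of counts with attribute \code{bit_depth}.
#' @export
read_channel_tiff <- function(path) {
  if (!file.exists(path))
    cst_error("cst_io_error", sprintf("cannot read '%s'", path))
  x <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  bits <- attr(x, "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  if (bits == 8L)
    cst_warning("cst_promoted_input",
                sprintf("'%s' is 8-bit; promoting to the numeric count scale",
                        path))
  m <- matrix(as.numeric(x), nrow(x), ncol(x))
  attr(m, "bit_depth") <- as.integer(bits)
  m
}

#' Write one channel as 16-bit grayscale TIFF
#'
#' @param m numeric matrix of counts (clipped at 65535).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_channel_tiff <- function(m, path) {
  tiff::writeTIFF(pmin(pmax(round(m), 0), MAX_CODE_16BIT) / MAX_CODE_16BIT,
                  path, bits.per.sample = 16L)
  invisible(path)
}

#' Read / write a three-channel image set
#'
#' \code{write_image_set()} writes \code{<prefix>_donor.tif},
#' \code{_acceptor.tif} and \code{_fret.tif}; \code{read_image_set()} loads
#' three channel files, erroring with the offending file name on dimension
#' mismatch.
#'
#' @param donor_path,acceptor_path,fret_path channel TIFF paths.
#' @return an [image_set()].
#' @export
read_image_set <- function(donor_path, acceptor_path, fret_path) {
  d <- read_channel_tiff(donor_path)
  a <- read_channel_tiff(acceptor_path)
  f <- read_channel_tiff(fret_path)
  for (ch in list(list(a, acceptor_path), list(f, fret_path)))
    if (!identical(dim(ch[[1]]), dim(d)))
      cst_error("cst_shape_error",
                sprintf("dimensions of '%s' differ from '%s'", ch[[2]],
                        donor_path))
  image_set(d, a, f, bit_depth = attr(d, "bit_depth"))
}

#' @rdname read_image_set
#' @param images an [image_set()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @export
write_image_set <- function(images, dir, prefix = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_", c("donor", "acceptor", "fret"),
                                 ".tif"))
  write_channel_tiff(images$donor, paths[1])
  write_channel_tiff(images$acceptor, paths[2])
  write_channel_tiff(images$fret, paths[3])
  invisible(paths)
}

# ---- float maps -------------------------------------------------------------

#' Save / load a scalar map as 32-bit float TIFF
#'
#' Values are stored divided by \code{scale} (default 100, covering the NFRET
#' x100 range) as page 1 of a two-page 32-bit float TIFF; page 2 is a
#' validity mask so \code{NA} pixels survive the round trip, which is exact
#' to 32-bit float precision. The scale is recorded in a JSON sidecar.
#'
#' @param values numeric matrix (non-negative, at most \code{scale}).
#' @param path output TIFF path (sidecar written at \code{<path>.json}).
#' @param scale value mapped to 1.0 in the file.
#' @return \code{path}, invisibly.
#' @export
save_map <- function(values, path, scale = 100) {
  v <- values
  na <- is.na(v)
  v[na] <- 0
  if (max(v) > scale || min(v) < 0)
    cst_error("cst_value_error", "values must lie in [0, scale]")
  tiff::writeTIFF(list(v / scale, (!na) * 1), path, bits.per.sample = 32L,
                  reduce = FALSE)
  jsonlite::write_json(list(scale = scale), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_map
#' @export
load_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  pages <- tiff::readTIFF(path, all = TRUE)
  m <- pages[[1]] * meta$scale
  m[pages[[2]] < 0.5] <- NA_real_
  m
}

# ---- traces and calibration -------------------------------------------------

#' Read / write FRAP traces as CSV
#'
#' Columns: \code{time_s}, \code{roi_intensity}, \code{wholecell_intensity},
#' \code{phase} (\code{pre}/\code{post}).
#'
#' @param trace a [frap_trace()].
#' @param path CSV path.
#' @return the trace / the path.
#' @export
write_frap_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_trace
#' @export
read_frap_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "roi_intensity", "wholecell_intensity", "phase")
  if (!all(need %in% names(df)))
    cst_error("cst_io_error", sprintf("'%s' lacks columns: %s", path,
                                      paste(setdiff(need, names(df)),
                                            collapse = ", ")))
  frap_trace(df$time_s, df$roi_intensity, df$wholecell_intensity,
             n_pre = sum(df$phase == "pre"), phase = df$phase)
}

#' Read / write bleed-through calibration as JSON
#'
#' @param params a [bleedthrough_params()] or a list with two
#'   \code{calibration_fit} objects named \code{donor} and \code{acceptor}.
#' @param path JSON path.
#' @export
write_calibration <- function(params, path) {
  obj <- if (inherits(params, "bleedthrough_params"))
    list(A = params$A, B = params$B)
  else
    list(A = params$donor$slope, B = params$acceptor$slope,
         donor_fit = unclass(params$donor),
         acceptor_fit = unclass(params$acceptor))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path)
  bleedthrough_params(obj$A, obj$B)
}
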