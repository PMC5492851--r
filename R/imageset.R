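#' Three-channel image set
#'
#' Container for one registered field: donor channel \code{I_D}, acceptor
#' channel \code{I_A} and FRET (sensitized-emission) channel \code{I_FRET},
#' all in detector counts as numeric matrices of identical dimensions.
#'
#' @param donor,acceptor,fret numeric matrices (counts, >= 0).
#' @param bit_depth detector bit depth (default 16).
#' @param pixel_size physical pixel size in microns, or \code{NA}.
#' @return an object of class \code{image_set}.
#' @export
image_set <- function(donor, acceptor, fret, bit_depth = 16L, pixel_size = NA_real_) {
  if (!is.matrix(donor) || !is.matrix(acceptor) || !is.matrix(fret))
    cst_error("cst_shape_error", "channels must be matrices")
  d <- dim(donor)
  if (!identical(d, dim(acceptor)) || !identical(d, dim(fret)))
    cst_error("cst_shape_error", "donor, acceptor and fret channels must share dimensions")
  if (min(donor, acceptor, fret) < 0)
    cst_error("cst_value_error", "channel counts must be non-negative")
  structure(list(donor = donor, acceptor = acceptor, fret = fret,
                 bit_depth = as.integer(bit_depth), pixel_size = pixel_size),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("<image_set> %d x %d px, %d-bit\n", nrow(x$donor), ncol(x$donor),
              x$bit_depth))
  for (ch in c("donor", "acceptor", "fret"))
    cat(sprintf("  %-8s mean %.1f  max %.1f\n", ch, mean(x[[ch]]), max(x[[ch]])))
  invisible(x)
}

#' @export
dim.image_set <- function(x) dim(x$donor)

# apply a function to all three channels, returning a new image_set
map_channels <- function(images, f, ...) {
  image_set(f(images$donor, ...), f(images$acceptor, ...), f(images$fret, ...),
            bit_depth = images$bit_depth, pixel_size = images$pixel_size)
}
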