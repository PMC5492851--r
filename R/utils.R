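#' Evaluate an expression with a temporary RNG state
#'
#' Saves the global \code{.Random.seed}, seeds the generator with \code{seed},
#' evaluates \code{code}, and restores the previous state so library calls do
#' not perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Single-seed fan-out rule used throughout the package: every stage of a run
#' derives its own 32-bit seed from the master seed, a stage label and an
#' index, so that all randomness flows from one integer while independent
#' stages get decorrelated streams.
#'
#' @param seed master integer seed.
#' @param stage character stage label (e.g. \code{"scene"}, \code{"frap"}).
#' @param k integer index within the stage (default 0).
#' @return an integer in \code{[1, 2^31 - 2]}.
#' @export
derive_seed <- function(seed, stage, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # arithmetic in double, reduced mod a Mersenne prime to stay inside int range
  v <- ((abs(seed) %% 1000003) * 40009 + h * 101 + k) %% 2147483646
  as.integer(v) + 1L
}

# shift a matrix by (dr, dc) with zero padding; used by the thinning pass
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# condition helpers: all package errors carry a subclass for testable handling
cst_error <- function(class, msg, call = sys.call(-1)) {
  stop(structure(class = c(class, "cst_error", "error", "condition"),
                 list(message = msg, call = call)))
}

cst_warning <- function(class, msg) {
  warning(structure(class = c(class, "cst_warning", "warning", "condition"),
                    list(message = msg, call = sys.call(-1))))
}
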