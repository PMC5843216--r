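# Standard conditions used for gas-volume normalization
P_STANDARD_BAR <- 1.013
T_STANDARD_K <- 293.15

SECONDS_PER_DAY <- 86400

#' Run code with a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic components of the package (sensor noise, random artifact
#' placement) draw their randomness through this helper so that a given seed
#' reproduces a run bit-identically without disturbing the global RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  code
}

# Quantize a reading to integer multiples of the sensor resolution.
quantize <- function(x, resolution) {
  if (resolution <= 0) return(x)
  round(x / resolution) * resolution
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) stopf("`%s` must be > 0 (got %g)", name, x)
  invisible(x)
}
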