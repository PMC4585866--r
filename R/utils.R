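#' Root-mean-square amplitude
#'
#' @param x numeric vector.
#' @return scalar RMS.
#' @export
rms <- function(x) sqrt(mean(x^2))

#' Normalize a waveform to unit RMS
#'
#' @param x numeric vector with at least one non-zero sample.
#' @return `x` scaled so that `rms(x) == 1`.
#' @export
rms_normalize <- function(x) {
  r <- rms(x)
  if (!is.finite(r) || r == 0) {
    stop("cannot RMS-normalize a silent (all-zero) waveform")
  }
  x / r
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state. All of the package's stochastic components draw
#' their randomness through this helper so that every stage of a run is
#' reproducible from named seeds.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
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
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed and a stream index
#'
#' Deterministic mixing of `(seed, stream)` into a new seed below 2^31,
#' so independent pipeline stages get decorrelated RNG streams from one
#' master seed.
#'
#' @param seed master integer seed.
#' @param stream stream index.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) * 48271 + as.double(stream) * 1000003) %% 2147483629
  as.integer(s) + 1L
}

# Clip probabilities away from 0/1 for log-likelihoods and deviances.
clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a
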