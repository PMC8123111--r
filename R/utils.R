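# Internal helpers shared across the pipeline.

#' Convert between dB and linear power
#'
#' Volume backscattering strength is carried through the pipeline in dB
#' (uncalibrated, so relative). Averaging is done in the linear power domain;
#' order statistics (min/median/max) are order-preserving and computed in dB.
#'
#' @param x numeric vector or matrix.
#' @return transformed values, same shape.
#' @keywords internal
db_to_linear <- function(x) 10^(x / 10)

#' @rdname db_to_linear
#' @keywords internal
linear_to_db <- function(x) 10 * log10(x)

deg2rad <- function(x) x * pi / 180

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replicate-pad a matrix by `k` cells on every side
#' @keywords internal
pad_replicate <- function(m, k = 1L) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, k), seq_len(nr), rep(nr, k))
  ci <- c(rep(1L, k), seq_len(nc), rep(nc, k))
  m[ri, ci, drop = FALSE]
}

# Stable integer sub-seed derivation so one user-facing seed drives all stages
# without the stages sharing an RNG stream position.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 131) %% 2147483629)
}

# meters per degree of latitude used by the local equirectangular projection
.M_PER_DEG <- 111320
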