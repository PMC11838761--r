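#' Draw from a zero-mean Laplace distribution
#'
#' Inverse-CDF sampler for the double-exponential distribution used by the
#' privacy mechanism (variance \code{2 * scale^2}).
#'
#' @param n number of draws.
#' @param scale scale parameter (must be positive); the privacy mechanism
#'   uses \code{1 / epsilon}.
#' @return numeric vector of length \code{n}.
#' @export
rlaplace <- function(n, scale = 1) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("`scale` must be a single positive number", call. = FALSE)
  u <- stats::runif(n, -0.5, 0.5)
  -scale * sign(u) * log1p(-2 * abs(u))
}

#' Round half away from zero
#'
#' Deterministic commercial rounding used for noisy user counts, where
#' \code{round()}'s round-half-even rule would be surprising.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive a per-stage random seed from a root seed
#'
#' All randomness in a pipeline run flows from one root seed; each stage
#' draws from its own stream derived from the root seed and a stage label,
#' so inserting or reordering stages does not perturb the others.
#'
#' @param seed root integer seed.
#' @param label character stage label.
#' @return a single integer in \code{[0, 2^31 - 2]}.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
}

#' Month index over the two-year study window
#'
#' Maps (year, month) to a consecutive index 1..24 with the first study year
#' at 1..12. Both modelling pathways run the temporal effect over this
#' concatenated index.
#'
#' @param year calendar year vector.
#' @param month month-of-year vector (1..12).
#' @param base_year first study year (default 2018).
#' @return integer vector.
#' @export
month_index <- function(year, month, base_year = 2018L) {
  (year - base_year) * 12L + month
}
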