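#' @keywords internal
"_PACKAGE"

# degrees <-> radians
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Sample from a truncated exponential distribution
#'
#' Draws from an exponential distribution shifted to start at `lower` and
#' truncated at `upper`, with the rate chosen so that the truncated mean
#' equals `mean`. Used for the inter-trial and feedback delays of the task.
#'
#' @param n Number of draws.
#' @param lower,upper Support bounds (same units as `mean`).
#' @param mean Desired mean of the truncated distribution; must lie strictly
#'   between `lower` and the mid-point of the support.
#' @return Numeric vector of length `n`.
#' @export
rtruncexp <- function(n, lower, upper, mean) {
  stopifnot(upper > lower, mean > lower, mean < (lower + upper) / 2)
  span <- upper - lower
  m <- (mean - lower) / span # target mean on [0, 1]
  # mean of Exp(rate) truncated to [0, 1]: 1/rate - 1/(exp(rate) - 1)
  f <- function(rate) 1 / rate - 1 / (expm1(rate)) - m
  rate <- stats::uniroot(f, c(1e-6, 1e3), tol = 1e-10)$root
  u <- stats::runif(n)
  # inverse CDF of truncated exponential on [0, 1]
  x <- -log(1 - u * (1 - exp(-rate))) / rate
  lower + span * x
}

# trapezoidal integration of y over x
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

# Ornstein-Uhlenbeck noise series: stationary sd `sd`, time constant `tau`
ou_noise <- function(n, sd, tau, dt) {
  if (sd <= 0) return(numeric(n))
  a <- exp(-dt / tau)
  e <- stats::rnorm(n, 0, sd * sqrt(1 - a^2))
  e[1] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(e, a, method = "recursive"))
}

# derive a child integer seed from a base seed and a stream label
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
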