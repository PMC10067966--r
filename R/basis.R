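#' Boxcar design expansion of a continuous predictor
#'
#' Expands a predictor into indicator columns over `n_bins` equal-width bins
#' spanning `range`. Values outside the range are clipped into the end bins so
#' the columns always partition the observations (each row has exactly one
#' active column).
#'
#' @param x Numeric predictor vector.
#' @param range Length-2 numeric range spanned by the bins.
#' @param n_bins Number of boxcar functions (default 10).
#' @return A 0/1 matrix with `length(x)` rows and `n_bins` columns, with
#'   attributes `edges` and `centers`.
#' @export
boxcar_design <- function(x, range, n_bins = 10) {
  stopifnot(diff(range) > 0, n_bins >= 2)
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n_bins)
  m <- matrix(0, length(x), n_bins)
  m[cbind(seq_along(x), idx)] <- 1
  attr(m, "edges") <- edges
  attr(m, "centers") <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  m
}

#' Raised-cosine temporal basis
#'
#' Returns a matrix of raised-cosine bump functions sampled at bin resolution.
#' With `log_spaced = FALSE` the centers are evenly spaced over the support
#' and the bumps tile it (their sum is constant away from the edges); with
#' `log_spaced = TRUE` the centers are evenly spaced in warped time
#' log(t + c), giving fine resolution at short lags and coarse resolution at
#' long lags, as appropriate for spike-history and coupling filters.
#'
#' @param span Length-2 numeric support in seconds (e.g. `c(0, 0.6)` for a
#'   causal event filter, `c(-0.3, 0.3)` for a non-causal one).
#' @param n_basis Number of basis functions (default 10).
#' @param dt Sampling resolution (s).
#' @param log_spaced Logical; log-scaled time axis (causal spans only).
#' @param log_offset Warping offset c in log(t + c); defaults to 2% of the
#'   span length.
#' @return Matrix of `n_basis` columns sampled at lags `attr(,"lags")`
#'   (seconds, at bin centers of the support).
#' @export
raised_cosine_basis <- function(span, n_basis = 10, dt, log_spaced = FALSE,
                                log_offset = NULL) {
  stopifnot(diff(span) > 0, n_basis >= 2, dt > 0)
  lags <- seq(span[1] + dt / 2, span[2] - dt / 2 + 1e-12, by = dt)
  if (log_spaced) {
    if (span[1] < 0) stop("log-spaced basis requires a causal (non-negative) span")
    if (is.null(log_offset)) log_offset <- 0.02 * diff(span)
    warp <- function(t) log(t + log_offset)
    wl <- warp(lags)
    centers <- seq(warp(lags[1]), warp(span[2] * 0.85), length.out = n_basis)
    dc <- centers[2] - centers[1]
    B <- vapply(centers, function(cj) {
      arg <- clamp((wl - cj) * pi / (2 * dc), -pi, pi)
      0.5 * (1 + cos(arg))
    }, numeric(length(lags)))
  } else {
    centers <- seq(span[1], span[2], length.out = n_basis)
    dc <- centers[2] - centers[1]
    B <- vapply(centers, function(cj) {
      arg <- clamp((lags - cj) * pi / (2 * dc), -pi, pi)
      0.5 * (1 + cos(arg))
    }, numeric(length(lags)))
  }
  attr(B, "lags") <- lags
  attr(B, "centers") <- centers
  B
}

#' Exponential re-expression basis
#'
#' Seven decaying exponentials with decay constants 6, 12, 24, 48, 96, 192
#' and 384 ms, used to re-express fitted coupling filters and summarize the
#' distribution of interaction timescales.
#'
#' @param span Length-2 causal support in seconds.
#' @param dt Sampling resolution (s).
#' @param decay_ms Decay constants in milliseconds.
#' @return Matrix with one column per decay constant; lags in `attr(,"lags")`.
#' @export
exp_basis <- function(span = c(0, 1.375), dt,
                      decay_ms = c(6, 12, 24, 48, 96, 192, 384)) {
  lags <- seq(span[1] + dt / 2, span[2] - dt / 2 + 1e-12, by = dt)
  B <- vapply(decay_ms / 1000, function(tau) exp(-lags / tau),
              numeric(length(lags)))
  colnames(B) <- paste0("tau", decay_ms)
  attr(B, "lags") <- lags
  attr(B, "decay_ms") <- decay_ms
  B
}

#' Basis set for the encoding model
#'
#' Bundles the bases used by the generalized additive encoding model: ten
#' boxcars per continuous variable, ten raised cosines spanning 600 ms for
#' event and motor kernels (causal [0, 600] ms for target onset, non-causal
#' [-300, 300] ms otherwise), ten log-spaced causal raised cosines spanning
#' 350 ms for spike history and 1.375 s for coupling, and the seven-exponential
#' re-expression basis.
#'
#' @param dt Bin width (s); 6 ms default, the smallest decay constant of the
#'   coupling re-expression basis.
#' @param n_tuning_bins Number of boxcars per continuous variable.
#' @return An object of class `gam_basis`.
#' @export
gam_basis <- function(dt = 0.006, n_tuning_bins = 10) {
  structure(list(
    dt = dt,
    n_tuning_bins = n_tuning_bins,
    event_causal = raised_cosine_basis(c(0, 0.6), 10, dt),
    event_acausal = raised_cosine_basis(c(-0.3, 0.3), 10, dt),
    history = raised_cosine_basis(c(0, 0.35), 10, dt, log_spaced = TRUE),
    coupling = raised_cosine_basis(c(0, 1.375), 10, dt, log_spaced = TRUE),
    exp7 = exp_basis(c(0, 1.375), dt)
  ), class = "gam_basis")
}
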