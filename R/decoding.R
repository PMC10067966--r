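#' Exponentially smoothed firing rates
#'
#' Convolves binned spike counts with a causal exponential kernel of time
#' constant `eta`, unit-normalized so that a steady train of rate lambda
#' converges to lambda (in Hz).
#'
#' @param counts Bins x neurons matrix (or vector) of spike counts.
#' @param eta Smoothing time constant (s), > 0.
#' @param dt Bin width (s).
#' @param trial_id Optional per-bin trial labels; smoothing restarts at trial
#'   boundaries.
#' @return Matrix (or vector) of rates in Hz.
#' @export
smooth_rates <- function(counts, eta, dt, trial_id = NULL) {
  stopifnot(eta > 0)
  a <- exp(-dt / eta)
  one_series <- function(yc) {
    out <- as.numeric(stats::filter((1 - a) * yc / dt, a, method = "recursive"))
    out
  }
  m <- as.matrix(counts)
  res <- matrix(0, nrow(m), ncol(m))
  if (is.null(trial_id)) trial_id <- rep(1L, nrow(m))
  for (tr in unique(trial_id)) {
    rows <- which(trial_id == tr)
    res[rows, ] <- apply(m[rows, , drop = FALSE], 2, one_series)
  }
  if (is.null(dim(counts))) res[, 1] else res
}

#' Ordinary least-squares population decoder
#'
#' Solves w = (R'R)^-1 R' x. When R'R is numerically singular the
#' pseudo-inverse is used and the fit is flagged.
#'
#' @param R Bins x neurons matrix of firing rates.
#' @param x Target variable series.
#' @return Numeric weight vector with attribute `pseudo_inverse` (logical).
#' @export
fit_linear_decoder <- function(R, x) {
  R <- as.matrix(R)
  stopifnot(nrow(R) == length(x))
  if (all(R == 0)) stop("all-zero rate matrix: decoder undefined")
  G <- crossprod(R)
  w <- tryCatch({
    structure(as.numeric(solve(G, crossprod(R, x))), pseudo_inverse = FALSE)
  }, error = function(e) {
    sv <- svd(R)
    keep <- sv$d > max(sv$d) * 1e-10
    structure(as.numeric(sv$v[, keep, drop = FALSE] %*%
                ((crossprod(sv$u[, keep, drop = FALSE], x)) / sv$d[keep])),
              pseudo_inverse = TRUE)
  })
  w
}

# split trial ids into train/validation/test by proportion
split_trials <- function(trial_ids, prop = c(0.8, 0.1, 0.1)) {
  ids <- sample(unique(trial_ids))
  n <- length(ids)
  n_tr <- max(1L, round(prop[1] * n))
  n_va <- max(1L, round(prop[2] * n))
  list(train = ids[seq_len(n_tr)],
       validation = ids[n_tr + seq_len(min(n_va, n - n_tr - 1L))],
       test = ids[(n_tr + min(n_va, n - n_tr - 1L) + 1L):n])
}

#' Fit a linear decoder with smoothing-timescale selection
#'
#' For each smoothing timescale eta on a logarithmic grid within [25, 250]
#' ms, smooths the population spike trains, fits ordinary least-squares
#' decoding weights on the training trials (80%), and evaluates the decoding
#' error epsilon = sqrt(sum_t (w'R_t - x_t)^2) on the validation trials
#' (10%). The eta minimizing validation error is selected and performance
#' (Pearson r between decoded and true series) is reported on the held-out
#' test trials (10%).
#'
#' @param session A `nav_session` with spikes.
#' @param variable Name of the decoded variable (column of
#'   `session$signals`).
#' @param eta_grid Timescale grid (s); default 8 log-spaced points in
#'   [0.025, 0.25].
#' @param trial_ids Trials to use (default all); the analysis window is
#'   target onset to stop (bins with `bin_time <=` the trial's stop time).
#' @param seed Optional seed for the trial split.
#' @return Object of class `decoder_fit`: weights `w`, selected `eta`, the
#'   split, per-eta validation errors, and test-set performance `r_test`.
#' @export
select_timescale <- function(session, variable,
                             eta_grid = exp(seq(log(0.025), log(0.25),
                                                length.out = 8)),
                             trial_ids = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- session$trial_table
  if (is.null(trial_ids)) trial_ids <- tab$trial_id
  if (length(trial_ids) < 30) stop("need at least 30 trials")
  split <- split_trials(trial_ids)
  stops <- stats::setNames(tab$stop_time, tab$trial_id)
  in_window <- session$bin_time <= stops[as.character(session$trial_id)]
  x <- session$signals[, variable]
  rows_of <- function(ids) which(session$trial_id %in% ids & in_window)
  r_tr <- rows_of(split$train); r_va <- rows_of(split$validation)
  r_te <- rows_of(split$test)
  errs <- numeric(length(eta_grid))
  ws <- vector("list", length(eta_grid))
  for (g in seq_along(eta_grid)) {
    R <- smooth_rates(session$counts, eta_grid[g], session$dt,
                      session$trial_id)
    w <- fit_linear_decoder(R[r_tr, , drop = FALSE], x[r_tr])
    pred <- as.numeric(R[r_va, , drop = FALSE] %*% w)
    errs[g] <- sqrt(sum((pred - x[r_va])^2))
    ws[[g]] <- list(w = w, R = NULL)
  }
  best <- which.min(errs)
  R <- smooth_rates(session$counts, eta_grid[best], session$dt,
                    session$trial_id)
  w <- ws[[best]]$w
  pred_te <- as.numeric(R[r_te, , drop = FALSE] %*% w)
  structure(list(variable = variable, w = w, eta = eta_grid[best],
                 eta_grid = eta_grid, validation_error = errs,
                 split = split, r_test = stats::cor(pred_te, x[r_te]),
                 dt = session$dt),
            class = "decoder_fit")
}

#' @export
print.decoder_fit <- function(x, ...) {
  cat(sprintf("decoder_fit: %s, eta = %.0f ms, test r = %.3f (%d neurons)\n",
              x$variable, x$eta * 1000, x$r_test, length(x$w)))
  invisible(x)
}

#' Decode a variable over the session with a fitted decoder
#'
#' @param fit A `decoder_fit`.
#' @param session The session to decode.
#' @return Numeric series of decoded values, one per bin.
#' @export
decode_series <- function(fit, session) {
  R <- smooth_rates(session$counts, fit$eta, session$dt, session$trial_id)
  as.numeric(R %*% fit$w)
}

# rank-based AUC: probability that a draw from `pos` exceeds one from `neg`
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Error-propagation analyses linking decoding errors to behavior
#'
#' Computes per-trial time-averaged decoding errors over the navigation
#' window and relates them to behavior: (i) the correlation between the
#' error in decoding distance-to-target and the signed behavioral error
#' (stop distance minus target distance; negative = undershoot), (ii) an
#' ROC/AUC classification of undershoot vs overshoot trials from the
#' distance-decoding errors, and (iii) sensory-to-latent error correlations
#' (linear velocity vs target distance, angular velocity vs target angle).
#'
#' @param session A `nav_session`.
#' @param fits Named list of `decoder_fit`s containing at least
#'   `target_distance`, `linear_velocity`, `angular_velocity`,
#'   `target_angle`.
#' @return List with `trial_errors` (per-trial mean decoding errors),
#'   `r_decode_vs_behavior`, `undershoot_overshoot_auc` (`NA` if either
#'   class is empty), `r_sensory_latent_linear`, `r_sensory_latent_angular`.
#' @export
error_analysis <- function(session, fits) {
  need <- c("target_distance", "linear_velocity", "angular_velocity",
            "target_angle")
  stopifnot(all(need %in% names(fits)))
  tab <- session$trial_table
  stops <- stats::setNames(tab$stop_time, tab$trial_id)
  in_window <- session$bin_time <= stops[as.character(session$trial_id)]
  errs <- sapply(need, function(v) {
    dec <- decode_series(fits[[v]], session)
    e <- dec - session$signals[, v]
    tapply(e[in_window], session$trial_id[in_window], mean)
  })
  ids <- as.integer(rownames(errs))
  tab <- tab[match(ids, tab$trial_id), ]
  behav_err <- tab$response_r - tab$target_r   # negative = undershoot
  r_db <- stats::cor(errs[, "target_distance"], behav_err)
  under <- behav_err < 0; over <- behav_err > 0
  auc <- if (any(under) && any(over))
    rank_auc(errs[over, "target_distance"], errs[under, "target_distance"])
  else NA_real_
  list(trial_errors = data.frame(trial_id = ids, errs, behavioral = behav_err),
       r_decode_vs_behavior = r_db,
       undershoot_overshoot_auc = auc,
       r_sensory_latent_linear =
         stats::cor(errs[, "linear_velocity"], errs[, "target_distance"]),
       r_sensory_latent_angular =
         stats::cor(errs[, "angular_velocity"], errs[, "target_angle"]))
}

#' Surrogate-mode null distribution for decoder error correlations
#'
#' The decoding weight vectors of two variables are generally not orthogonal;
#' correlations between their projections could arise from geometry alone.
#' This null fixes the angle: it draws random unit vectors u and an
#' orthogonal complement direction, forms v = cos(phi) u + sin(phi) u_perp
#' with phi the angle between the two (unit-normalized) decoders, projects
#' the population activity on u and v, and computes the correlation of
#' per-trial mean projections, repeated `n_surrogate` times.
#'
#' @param w_a,w_b Decoder weight vectors (common neuron set).
#' @param R Bins x neurons activity matrix.
#' @param trial_id Per-bin trial labels.
#' @param n_surrogate Number of surrogate pairs.
#' @return List with `phi` (radians), `correlations` (length
#'   `n_surrogate`), and `angles` of the surrogate pairs (for verification).
#' @export
surrogate_angle_null <- function(w_a, w_b, R, trial_id, n_surrogate = 100) {
  na <- sqrt(sum(w_a^2)); nb <- sqrt(sum(w_b^2))
  if (na == 0 || nb == 0) stop("zero decoder vector: angle undefined")
  ua <- w_a / na; ub <- w_b / nb
  phi <- acos(clamp(sum(ua * ub), -1, 1))
  p <- length(w_a)
  cors <- numeric(n_surrogate)
  angs <- numeric(n_surrogate)
  for (s in seq_len(n_surrogate)) {
    u <- stats::rnorm(p); u <- u / sqrt(sum(u^2))
    z <- stats::rnorm(p)
    z <- z - sum(z * u) * u
    z <- z / sqrt(sum(z^2))
    v <- cos(phi) * u + sin(phi) * z
    angs[s] <- acos(clamp(sum(u * v), -1, 1))
    pu <- tapply(as.numeric(R %*% u), trial_id, mean)
    pv <- tapply(as.numeric(R %*% v), trial_id, mean)
    cors[s] <- stats::cor(pu, pv)
  }
  list(phi = phi, correlations = cors, angles = angs)
}
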