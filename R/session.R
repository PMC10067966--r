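#' Assemble a binned session from behavioral trials
#'
#' Bins each trial's continuous channels at the encoding-model resolution and
#' derives the full predictor set: linear and angular velocity, distance and
#' angle to target (recomputed from position and target in every bin), two
#' motor channels, LFP phase, and two gaze channels, plus binary event series
#' (target onset, reward delivery). Excluded trials are dropped.
#'
#' @param trials A `nav_trials` object.
#' @param dt Bin width (s); must be an integer multiple of the behavioral
#'   sampling interval.
#' @param post_stop Extra time (s) retained after the feedback event.
#' @param lfp_freq_hz,lfp_jitter_sd LFP oscillator parameters.
#' @param gaze_sd,gaze_tau Gaze channel OU noise scale (deg) and time
#'   constant (s).
#' @param seed Optional seed for the LFP/motor/gaze noise streams.
#' @return Object of class `nav_session` without spikes: `signals` (bins x 9
#'   matrix), `events` (bins x 2), `trial_id`, `bin_time` (within-trial bin
#'   centers, s), `trial_table`, `dt`.
#' @export
bin_session <- function(trials, dt = 0.006, post_stop = 0.3,
                        lfp_freq_hz = 15, lfp_jitter_sd = 1,
                        gaze_sd = 10, gaze_tau = 0.3, seed = NULL) {
  stopifnot(inherits(trials, "nav_trials"))
  if (!is.null(seed)) set.seed(seed)
  sr <- trials$config$sample_rate
  k <- round(dt * sr)
  if (abs(k - dt * sr) > 1e-6)
    stop("dt must be an integer multiple of the behavioral sampling interval")
  tl <- Filter(function(tr) !tr$excluded, trials$trials)
  if (length(tl) == 0) stop("no non-excluded trials")
  per_trial <- lapply(tl, function(tr) {
    n_raw <- length(tr$linear_velocity)
    # extend beyond the recorded stop so the feedback event is in-session
    n_ext <- ceiling((tr$events$feedback_time + post_stop) * sr)
    idx <- pmin(seq_len(max(n_raw, n_ext)), n_raw)
    v <- tr$linear_velocity[idx]; v[seq_along(idx) > n_raw] <- 0
    w <- tr$angular_velocity[idx]; w[seq_along(idx) > n_raw] <- 0
    x <- tr$position[idx, 1]; y <- tr$position[idx, 2]
    motor <- derive_motor_channels(tr)
    m1 <- motor[idx, 1]; m2 <- motor[idx, 2]
    still <- seq_along(idx) > n_raw
    m1[still] <- 0; m2[still] <- 0
    n_bins <- floor(length(idx) / k)
    if (n_bins < 1) return(NULL)
    binm <- function(s) colMeans(matrix(s[seq_len(n_bins * k)], nrow = k))
    bx <- binm(x); by <- binm(y)
    dist <- sqrt((tr$target$x - bx)^2 + (tr$target$y - by)^2)
    bh <- binm(tr$heading[idx])
    dxr <- tr$target$x - bx; dyr <- tr$target$y - by
    hr <- deg2rad(bh)
    ang <- rad2deg(atan2(dxr * cos(hr) - dyr * sin(hr),
                         dxr * sin(hr) + dyr * cos(hr)))
    n <- n_bins
    sig <- cbind(linear_velocity = binm(v), angular_velocity = binm(w),
                 target_distance = dist, target_angle = ang,
                 motor1 = binm(m1), motor2 = binm(m2),
                 lfp_phase = simulate_lfp(n * dt, dt, lfp_freq_hz, lfp_jitter_sd),
                 gaze_x = ou_noise(n, gaze_sd, gaze_tau, dt),
                 gaze_y = ou_noise(n, gaze_sd, gaze_tau, dt))
    ev <- matrix(0, n, 2, dimnames = list(NULL, c("target_on", "reward")))
    ev[1, "target_on"] <- 1
    fb_bin <- min(n, max(1L, ceiling(tr$events$feedback_time / dt)))
    if (tr$rewarded) ev[fb_bin, "reward"] <- 1
    list(sig = sig, ev = ev, id = tr$trial_id,
         t = (seq_len(n) - 0.5) * dt)
  })
  per_trial <- Filter(Negate(is.null), per_trial)
  structure(list(
    signals = do.call(rbind, lapply(per_trial, `[[`, "sig")),
    events = do.call(rbind, lapply(per_trial, `[[`, "ev")),
    trial_id = unlist(lapply(per_trial, function(p) rep(p$id, nrow(p$sig)))),
    bin_time = unlist(lapply(per_trial, `[[`, "t")),
    trial_table = trial_table(tl),
    dt = dt, counts = NULL, spikes = NULL, truth = NULL,
    electrode = NULL
  ), class = "nav_session")
}

#' @export
print.nav_session <- function(x, ...) {
  cat(sprintf("nav_session: %d trials, %d bins at %.1f ms%s\n",
              nrow(x$trial_table), nrow(x$signals), x$dt * 1000,
              if (!is.null(x$counts))
                sprintf(", %d neurons (%.1f Hz mean rate)", ncol(x$counts),
                        mean(x$counts) / x$dt)
              else " (no spikes)"))
  invisible(x)
}

#' Generate spike trains from a ground-truth encoding
#'
#' Sequential bin-by-bin generative pass of the coupled Poisson model: the
#' log-rate of each neuron is its baseline plus tuning-function lookups on
#' the current bin's continuous variables, convolved event filters, its own
#' spike history through the history filter, and other neurons' past spikes
#' through the coupling filters. Emission is Poisson per bin (counts above 1
#' allowed); spike times are placed uniformly within their bin. History and
#' coupling do not leak across trial boundaries.
#'
#' @param session A `nav_session` from [bin_session()].
#' @param truth A [ground_truth_encoding()] with matching `dt`.
#' @param rate_cap Maximum expected count per bin; log-rates above
#'   `log(rate_cap)` are clipped (clips are counted and reported via a
#'   warning).
#' @param seed Optional seed.
#' @return The session with `counts` (bins x neurons), `spikes` (per-neuron
#'   data frame of trial / within-trial time), `truth` and `electrode` filled
#'   in.
#' @export
simulate_spikes <- function(session, truth, rate_cap = 5, seed = NULL) {
  stopifnot(inherits(session, "nav_session"),
            inherits(truth, "ground_truth_encoding"),
            abs(session$dt - truth$dt) < 1e-12)
  if (!is.null(seed)) set.seed(seed)
  dt <- session$dt
  N <- truth$n_neurons
  nb <- truth$basis$n_tuning_bins
  n_tot <- nrow(session$signals)
  vars <- colnames(session$signals)

  # task-driven log-rate, identical for the whole session (vectorized)
  base <- matrix(rep(truth$b, each = n_tot), n_tot, N)
  for (v in vars) {
    rg <- truth$var_ranges[[v]]
    edges <- seq(rg[1], rg[2], length.out = nb + 1)
    idx <- clamp(findInterval(session$signals[, v], edges,
                              rightmost.closed = TRUE), 1L, nb)
    W <- vapply(truth$tuning, function(tf) tf[[v]], numeric(nb))  # nb x N
    if (any(W != 0)) base <- base + W[idx, , drop = FALSE]
  }
  # event filters (reconstructed at dt, added at each event occurrence)
  B_on <- truth$basis$event_causal
  B_rw <- truth$basis$event_acausal
  F_on <- B_on %*% vapply(truth$event, `[[`, numeric(ncol(B_on)), "target_on")
  F_rw <- B_rw %*% vapply(truth$event, `[[`, numeric(ncol(B_rw)), "reward")
  lag_on <- round(attr(B_on, "lags") / dt - 0.5) + 1L  # bins after event
  lag_rw <- round(attr(B_rw, "lags") / dt - 0.5) + 1L  # signed bin offsets
  tid <- session$trial_id
  trial_starts <- which(c(TRUE, tid[-1] != tid[-n_tot]))
  trial_ends <- c(trial_starts[-1] - 1L, n_tot)
  add_event <- function(base, at, Fmat, lags, t0, t1) {
    rows <- at + lags
    ok <- rows >= t0 & rows <= t1
    base[rows[ok], ] <- base[rows[ok], ] + Fmat[ok, , drop = FALSE]
    base
  }
  for (j in seq_along(trial_starts)) {
    t0 <- trial_starts[j]; t1 <- trial_ends[j]
    base <- add_event(base, t0, F_on, lag_on, t0, t1)
    rw <- which(session$events[t0:t1, "reward"] == 1)
    if (length(rw)) base <- add_event(base, t0 + rw[1] - 1L, F_rw, lag_rw, t0, t1)
  }

  # motor-channel kernels (acausal convolution with the motor signals)
  if (!is.null(truth$motor_kernel)) {
    MK1 <- vapply(truth$motor_kernel, `[[`, numeric(10), "motor1")
    MK2 <- vapply(truth$motor_kernel, `[[`, numeric(10), "motor2")
    if (any(MK1 != 0) || any(MK2 != 0)) {
      Bm <- truth$basis$event_acausal
      lags_m <- as.integer(floor(attr(Bm, "lags") / dt)) + 1L
      C1 <- session_conv(session$signals[, "motor1"], Bm, lags_m, tid)
      C2 <- session_conv(session$signals[, "motor2"], Bm, lags_m, tid)
      base <- base + C1 %*% MK1 + C2 %*% MK2
    }
  }

  # reconstructed history and coupling filters at bin resolution
  H <- truth$basis$history %*% vapply(truth$history, identity,
                                      numeric(ncol(truth$basis$history)))
  Lh <- nrow(H)
  Bc <- truth$basis$coupling
  Lc <- nrow(Bc)
  coup_from <- vapply(truth$coupling, `[[`, numeric(1), "from")
  coup_to <- vapply(truth$coupling, `[[`, numeric(1), "to")
  coup_filt <- lapply(truth$coupling, function(cp) as.numeric(Bc %*% cp$coef))
  coup_by_src <- split(seq_along(coup_from), factor(coup_from, levels = seq_len(N)))

  counts <- matrix(0L, n_tot, N)
  spk <- vector("list", N)
  for (i in seq_len(N)) spk[[i]] <- list()
  log_cap <- log(rate_cap)
  n_clipped <- 0L
  Lmax <- max(Lh, Lc)

  for (j in seq_along(trial_starts)) {
    t0 <- trial_starts[j]; t1 <- trial_ends[j]
    n_tr <- t1 - t0 + 1L
    A <- matrix(0, n_tr + Lmax, N)  # history/coupling log-rate buffer
    for (t in seq_len(n_tr)) {
      lr <- base[t0 + t - 1L, ] + A[t, ]
      over <- lr > log_cap
      if (any(over)) { lr[over] <- log_cap; n_clipped <- n_clipped + sum(over) }
      c_t <- stats::rpois(N, exp(lr))
      fired <- which(c_t > 0L)
      if (length(fired)) {
        counts[t0 + t - 1L, fired] <- c_t[fired]
        for (i in fired) {
          ci <- c_t[i]
          A[t + seq_len(Lh), i] <- A[t + seq_len(Lh), i] + ci * H[, i]
          for (kk in coup_by_src[[i]]) {
            tgt <- coup_to[kk]
            A[t + seq_len(Lc), tgt] <- A[t + seq_len(Lc), tgt] +
              ci * coup_filt[[kk]]
          }
          spk[[i]][[length(spk[[i]]) + 1L]] <-
            c(tid[t0], rep((t - 1L) * dt, ci) + stats::runif(ci) * dt)
        }
      }
    }
  }
  if (n_clipped > 0L)
    warning(sprintf("log-rate clipped at cap in %d bin-neuron entries", n_clipped))
  spikes <- lapply(spk, function(s) {
    if (!length(s)) return(data.frame(trial = integer(0), t = numeric(0)))
    df <- do.call(rbind, lapply(s, function(e)
      cbind(trial = e[1], t = e[-1])))
    data.frame(trial = as.integer(df[, 1]), t = df[, 2])
  })
  session$counts <- counts
  session$spikes <- spikes
  session$truth <- truth
  session$electrode <- truth$electrode
  session
}

#' Simulate a complete synthetic session
#'
#' Convenience wrapper: simulates behavior, flags disengaged trials, bins the
#' session and generates spikes from a ground-truth encoding.
#'
#' @param n_trials Number of trials.
#' @param truth A [ground_truth_encoding()] (defaults to a fresh one).
#' @param config,ctrl Task and controller parameters.
#' @param condition Condition label for [simulate_trial()].
#' @param seed Optional seed covering all stages.
#' @return A `nav_session` with spikes.
#' @export
simulate_session <- function(n_trials, truth = NULL,
                             config = task_config(),
                             ctrl = controller_params(),
                             condition = "baseline", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(truth)) truth <- ground_truth_encoding()
  trials <- simulate_trials(n_trials, config, ctrl, condition = condition)
  trials <- exclude_disengaged(trials)
  session <- bin_session(trials, dt = truth$dt)
  simulate_spikes(session, truth)
}
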