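#' Ground-truth encoding model for synthetic sessions
#'
#' Constructs a known coupled Poisson encoding model from which spike trains
#' can be generated, so that every downstream fitting stage can be tested by
#' parameter recovery. Per neuron it holds piecewise-constant tuning functions
#' over continuous task variables, event filters and a spike-history filter on
#' raised-cosine bases, sparse directed coupling filters to other neurons, a
#' baseline log-rate, and an electrode-grid position.
#'
#' Default tuning shapes follow the qualitative structure of parietal
#' recordings in this task: preferred speeds tile the velocity range, most
#' neurons prefer small target distances and extreme target angles, and
#' spiking probability peaks 18 degrees before the LFP trough. All shapes can
#' be overridden after construction.
#'
#' @param n_neurons Number of neurons.
#' @param dt Bin width (s).
#' @param baseline_hz Range of baseline firing rates (Hz) sampled uniformly.
#' @param n_couplings Number of non-zero directed coupling filters.
#' @param coupling_amp Peak magnitude of coupling-filter basis coefficients
#'   (log-rate units).
#' @param motor_kernel_amp Amplitude of the acausal motor-channel kernels
#'   (log-rate units per unit channel value); 0 disables the motor drive.
#' @param tuned_variables Continuous variables given non-flat tuning.
#' @param grid_dim Electrode grid dimensions (rows, cols); 400 um pitch.
#' @param seed Optional seed.
#' @return Object of class `ground_truth_encoding`.
#' @export
ground_truth_encoding <- function(n_neurons = 20, dt = 0.006,
                                  baseline_hz = c(5, 15),
                                  n_couplings = 10,
                                  coupling_amp = 0.8,
                                  motor_kernel_amp = 0,
                                  tuned_variables = c("linear_velocity",
                                                      "angular_velocity",
                                                      "target_distance",
                                                      "target_angle",
                                                      "lfp_phase"),
                                  grid_dim = c(10, 10),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  basis <- gam_basis(dt)
  nb <- basis$n_tuning_bins
  var_ranges <- list(linear_velocity = c(0, 2), angular_velocity = c(-90, 90),
                     target_distance = c(0, 4.25), target_angle = c(-55, 55),
                     motor1 = c(-2, 2), motor2 = c(-2, 2),
                     lfp_phase = c(-180, 180), gaze_x = c(-30, 30),
                     gaze_y = c(-30, 30))
  centers <- lapply(var_ranges, function(rg) {
    e <- seq(rg[1], rg[2], length.out = nb + 1); (e[-1] + e[-(nb + 1)]) / 2
  })
  bump <- function(x, pref, width, amp) {
    f <- amp * exp(-(x - pref)^2 / (2 * width^2)); f - mean(f)
  }
  tuning <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    tf <- lapply(var_ranges, function(rg) rep(0, nb))
    if ("linear_velocity" %in% tuned_variables)
      tf$linear_velocity <- bump(centers$linear_velocity,
                                 stats::runif(1, 0, 2), 0.7, 0.6)
    if ("angular_velocity" %in% tuned_variables)
      tf$angular_velocity <- bump(centers$angular_velocity,
                                  stats::runif(1, -90, 90), 35, 0.6)
    if ("target_distance" %in% tuned_variables) {
      f <- if (stats::runif(1) < 0.7)
        0.9 * exp(-centers$target_distance / 1.2)   # prefers small distances
      else bump(centers$target_distance, stats::runif(1, 0, 4.25), 1, 0.7)
      tf$target_distance <- f - mean(f)
    }
    if ("target_angle" %in% tuned_variables) {
      s <- sample(c(-1, 1), 1)                       # prefers one extreme
      f <- 0.7 * s * centers$target_angle / 55
      tf$target_angle <- f - mean(f)
    }
    if ("lfp_phase" %in% tuned_variables)            # peak 18 deg before trough
      tf$lfp_phase <- 0.3 * cos(deg2rad(centers$lfp_phase - 162))
    tuning[[i]] <- tf
  }
  # event filters: ON response to target onset at ~120 ms; weak reward response
  ev_centers_on <- attr(basis$event_causal, "centers")
  ev_centers_rw <- attr(basis$event_acausal, "centers")
  event <- lapply(seq_len(n_neurons), function(i) {
    lat <- stats::rnorm(1, 0.12, 0.015)
    amp <- stats::runif(1, 0.3, 1)
    list(target_on = amp * exp(-(ev_centers_on - lat)^2 / (2 * 0.06^2)),
         reward = stats::runif(1, 0, 0.15) *
           exp(-(ev_centers_rw - 0.1)^2 / (2 * 0.08^2)))
  })
  # acausal motor kernels (bumps at random lead/lag around hand motion)
  motor_kernel <- lapply(seq_len(n_neurons), function(i) {
    if (motor_kernel_amp == 0)
      return(list(motor1 = rep(0, 10), motor2 = rep(0, 10)))
    mk <- function() motor_kernel_amp * stats::runif(1, 0.5, 1) *
      exp(-(ev_centers_rw - stats::runif(1, -0.2, 0.2))^2 / (2 * 0.08^2))
    list(motor1 = mk(), motor2 = mk())
  })
  # refractory spike history
  history <- lapply(seq_len(n_neurons), function(i)
    c(-4, -2, -0.8, -0.2, rep(0, 6)) * stats::runif(1, 0.7, 1.2))
  # sparse directed couplings
  pairs <- expand.grid(from = seq_len(n_neurons), to = seq_len(n_neurons))
  pairs <- pairs[pairs$from != pairs$to, ]
  sel <- pairs[sample.int(nrow(pairs), min(n_couplings, nrow(pairs))), ]
  coupling <- lapply(seq_len(nrow(sel)), function(k) {
    s <- sample(c(-1, 1), 1)
    list(from = sel$from[k], to = sel$to[k],
         coef = s * coupling_amp * exp(-(seq_len(10) - 1) / 2.5))
  })
  b <- log(stats::runif(n_neurons, baseline_hz[1], baseline_hz[2]) * dt)
  electrode <- data.frame(
    neuron = seq_len(n_neurons),
    row = sample.int(grid_dim[1], n_neurons, replace = TRUE),
    col = sample.int(grid_dim[2], n_neurons, replace = TRUE))
  structure(list(n_neurons = n_neurons, dt = dt, basis = basis,
                 var_ranges = var_ranges, tuning_centers = centers,
                 tuning = tuning, event = event, motor_kernel = motor_kernel,
                 history = history, coupling = coupling, b = b,
                 electrode = electrode, pitch_um = 400),
            class = "ground_truth_encoding")
}

#' Rerandomize parts of a ground-truth encoding
#'
#' Used to emulate a task manipulation at the generative level: draws new
#' coupling filters and/or new latent-variable tuning while holding the other
#' components (sensory and motor tuning, events, history, baselines) fixed.
#'
#' @param truth A [ground_truth_encoding()].
#' @param what Components to rerandomize: subset of `"coupling"`, `"latent"`.
#' @param seed Optional seed.
#' @return A modified `ground_truth_encoding`.
#' @export
perturb_encoding <- function(truth, what = c("coupling", "latent"),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- truth$n_neurons
  if ("coupling" %in% what) {
    k <- length(truth$coupling)
    pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
    pairs <- pairs[pairs$from != pairs$to, ]
    sel <- pairs[sample.int(nrow(pairs), k), ]
    amp <- max(abs(truth$coupling[[1]]$coef))
    truth$coupling <- lapply(seq_len(k), function(j) {
      s <- sample(c(-1, 1), 1)
      list(from = sel$from[j], to = sel$to[j],
           coef = s * amp * exp(-(seq_len(10) - 1) / 2.5))
    })
  }
  if ("latent" %in% what) {
    ctr <- truth$tuning_centers
    for (i in seq_len(n)) {
      f <- 0.9 * exp(-(ctr$target_distance - stats::runif(1, 0, 4.25))^2 / 2)
      truth$tuning[[i]]$target_distance <- f - mean(f)
      g <- 0.7 * sin(deg2rad(stats::runif(1, 0, 360))) *
        sin(pi * (ctr$target_angle + 55) / 110 + stats::runif(1, 0, pi))
      truth$tuning[[i]]$target_angle <- g - mean(g)
    }
  }
  truth
}

#' Instantaneous LFP phase series
#'
#' Phase of a ~15 Hz oscillator with small frequency jitter. Phase is in
#' degrees in [-180, 180), with 0 at the oscillation peak and +/-180 at the
#' trough.
#'
#' @param duration Duration (s).
#' @param dt Sampling resolution (s).
#' @param freq_hz Mean oscillation frequency (Hz).
#' @param jitter_sd Sd of the Ornstein-Uhlenbeck frequency jitter (Hz).
#' @return Numeric phase series of length `round(duration/dt)`.
#' @export
simulate_lfp <- function(duration, dt = 0.006, freq_hz = 15, jitter_sd = 1) {
  stopifnot(duration > 0)
  n <- max(1L, round(duration / dt))
  f <- freq_hz + ou_noise(n, jitter_sd, 0.2, dt)
  phase <- (cumsum(f) * dt * 360) %% 360
  phase - 360 * (phase >= 180)
}

#' Derive synthetic motor channels from a trial
#'
#' Produces two smooth velocity channels as an invertible linear mix of the
#' trial's normalized linear and angular velocities plus low-pass noise.
#' These stand in for hand speed along the two leading principal components
#' of hand position.
#'
#' @param trial A `nav_trial`.
#' @param noise_sd Sd of the additive low-pass (OU, 150 ms) noise.
#' @param mix 2x2 invertible mixing matrix.
#' @return Matrix with columns `motor1`, `motor2` at the trial sample rate.
#' @export
derive_motor_channels <- function(trial, noise_sd = 0.1,
                                  mix = rbind(c(0.8, 0.6), c(-0.5, 0.9))) {
  stopifnot(abs(det(mix)) > 1e-8)
  n <- length(trial$linear_velocity)
  dt <- 1 / trial$sample_rate
  src <- rbind(trial$linear_velocity / 2, trial$angular_velocity / 90)
  m <- t(mix %*% src)
  m[, 1] <- m[, 1] + ou_noise(n, noise_sd, 0.15, dt)
  m[, 2] <- m[, 2] + ou_noise(n, noise_sd, 0.15, dt)
  colnames(m) <- c("motor1", "motor2")
  m
}
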