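#' Sample target locations
#'
#' Draws target locations within the task's annular sector. By default the
#' sampling is uniform over ground-plane area, so the radial density is
#' proportional to r; setting `area_uniform_targets = FALSE` in the config
#' gives sampling uniform in (r, theta) instead.
#'
#' @param n Number of targets.
#' @param config A [task_config()].
#' @return Data frame with columns `r` (m), `theta` (deg, positive rightward),
#'   and Cartesian `x`, `y` (m; heading 0 is the +y axis).
#' @export
sample_target <- function(n, config = task_config()) {
  r0 <- config$target_r_range[1]
  r1 <- config$target_r_range[2]
  if (config$area_uniform_targets) {
    r <- sqrt(stats::runif(n, r0^2, r1^2))
  } else {
    r <- stats::runif(n, r0, r1)
  }
  theta <- stats::runif(n, config$target_theta_range[1],
                        config$target_theta_range[2])
  data.frame(r = r, theta = theta,
             x = r * sin(deg2rad(theta)), y = r * cos(deg2rad(theta)))
}

#' Integrate unicycle kinematics
#'
#' Forward-Euler integration of the unicycle model at the behavioral sample
#' rate: heading' = omega, x' = v sin(heading), y' = v cos(heading). Heading 0
#' points along +y (straight ahead) and positive omega turns rightward.
#'
#' @param v Linear velocity series (m/s).
#' @param omega Angular velocity series (deg/s).
#' @param dt Time step (s).
#' @return List with numeric series `x`, `y`, `heading` (deg), each aligned to
#'   the end of the corresponding step.
#' @export
integrate_unicycle <- function(v, omega, dt) {
  stopifnot(length(v) == length(omega), dt > 0)
  heading <- cumsum(omega) * dt
  hr <- deg2rad(heading)
  x <- cumsum(v * sin(hr)) * dt
  y <- cumsum(v * cos(hr)) * dt
  list(x = x, y = y, heading = heading)
}

#' Apply a Gaussian-profile velocity perturbation
#'
#' Adds the passive-displacement pulse used by the trajectory-perturbation
#' manipulation: a Gaussian velocity profile with standard deviation 0.2 s,
#' truncated to a 1 s window centred on the profile peak, added to both
#' velocity channels.
#'
#' @param v,omega Velocity series (m/s, deg/s) sampled at `config$sample_rate`.
#' @param amp_v Peak linear amplitude, within [-2, 2] m/s.
#' @param amp_omega Peak angular amplitude, within [-120, 120] deg/s.
#' @param t_onset Pulse window start (s from the start of the series).
#' @param config A [task_config()].
#' @param sigma Gaussian profile sd (s).
#' @param duration Truncation window (s).
#' @return List with perturbed `v` and `omega` series.
#' @export
apply_perturbation <- function(v, omega, amp_v, amp_omega, t_onset,
                               config = task_config(),
                               sigma = 0.2, duration = 1) {
  if (abs(amp_v) > 2 || abs(amp_omega) > 120)
    stop("perturbation amplitude out of bounds: |amp_v| <= 2 m/s, |amp_omega| <= 120 deg/s")
  t <- (seq_along(v) - 1) / config$sample_rate
  t_peak <- t_onset + duration / 2
  profile <- exp(-(t - t_peak)^2 / (2 * sigma^2))
  profile[t < t_onset | t > t_onset + duration] <- 0
  list(v = v + amp_v * profile, omega = omega + amp_omega * profile)
}

# Gaussian pulse series on its own (helper shared with simulate_trial)
perturbation_profile <- function(n, dt, amp, t_onset, sigma = 0.2, duration = 1) {
  t <- (seq_len(n) - 1) * dt
  t_peak <- t_onset + duration / 2
  p <- amp * exp(-(t - t_peak)^2 / (2 * sigma^2))
  p[t < t_onset | t > t_onset + duration] <- 0
  p
}

#' Simulate one closed-loop navigation trial
#'
#' The synthetic agent observes its own velocity through noisy channels,
#' integrates the observations into an internal pose estimate, steers toward
#' the remembered target with a saturating proportional controller, and
#' releases the joystick once its estimated distance to target falls below
#' its stopping distance. The true pose evolves under unicycle kinematics;
#' the joystick gain multiplies both commanded velocities; reward follows the
#' 0.6 m rule after a truncated-exponential feedback delay.
#'
#' @param config A [task_config()].
#' @param ctrl A [controller_params()].
#' @param target One-row data frame from [sample_target()] (or a list with
#'   `x`, `y`, `r`, `theta`).
#' @param condition Character label: `"baseline"`, `"density"`, `"gain"` or
#'   `"perturbation"`. Density and gain effects are carried by the values in
#'   `config`; `"perturbation"` adds a random passive displacement pulse.
#' @param perturbation Optional list `(amp_v, amp_omega, t_onset)`; drawn
#'   randomly if `condition == "perturbation"` and omitted.
#' @param trial_id Integer identifier stored in the trial.
#' @return An object of class `nav_trial`: target/response coordinates,
#'   velocity/position/heading series, event times, reward and exclusion
#'   flags.
#' @export
simulate_trial <- function(config, ctrl, target, condition = "baseline",
                           perturbation = NULL, trial_id = 1L) {
  dt <- 1 / config$sample_rate
  n_max <- ceiling(config$max_trial_duration / dt)
  g <- config$gain

  sens_sd <- ctrl$sensory_noise_sd
  if (condition == "density" && config$density < 1)
    sens_sd <- sens_sd * ctrl$density_noise_factor

  rt <- stats::runif(1, ctrl$reaction_time_range[1], ctrl$reaction_time_range[2])
  if (condition == "perturbation" && is.null(perturbation)) {
    perturbation <- list(amp_v = stats::runif(1, -2, 2),
                         amp_omega = stats::runif(1, -120, 120),
                         t_onset = rt + stats::runif(1, 0, 1))
  }
  pert_v <- pert_w <- NULL
  if (!is.null(perturbation)) {
    pert_v <- perturbation_profile(n_max, dt, perturbation$amp_v, perturbation$t_onset)
    pert_w <- perturbation_profile(n_max, dt, perturbation$amp_omega, perturbation$t_onset)
  }

  # noise streams (Ornstein-Uhlenbeck; motor 200 ms, sensory 100 ms)
  ang_scale <- config$omega_max / config$v_max
  mn_v <- ou_noise(n_max, ctrl$motor_noise_sd, 0.2, dt)
  mn_w <- ou_noise(n_max, ctrl$motor_noise_sd * ang_scale, 0.2, dt)
  sn_v <- ou_noise(n_max, sens_sd, 0.1, dt)
  sn_w <- ou_noise(n_max, sens_sd * ang_scale, 0.1, dt)

  v_s <- w_s <- x_s <- y_s <- h_s <- numeric(n_max)
  x <- y <- h <- 0      # true pose
  xe <- ye <- he <- 0   # agent's internal estimate
  tx <- target$x; ty <- target$y
  d2r <- pi / 180
  v_max <- config$v_max; omega_max <- config$omega_max
  k_v <- ctrl$gain_linear; k_w <- ctrl$gain_angular
  stop_d <- ctrl$stop_distance; stop_v <- ctrl$stop_threshold
  stopped_intent <- FALSE
  moved <- FALSE
  still_count <- 0L
  still_needed <- max(1L, round(0.05 / dt)) # 50 ms of stillness
  stop_idx <- NA_integer_
  move_idx <- NA_integer_

  for (i in seq_len(n_max)) {
    t <- (i - 1) * dt
    v_cmd <- 0; w_cmd <- 0
    if (t >= rt && !stopped_intent) {
      dx <- tx - xe; dy <- ty - ye
      her <- he * d2r
      sh <- sin(her); ch <- cos(her)
      fwd <- dx * sh + dy * ch
      lat <- dx * ch - dy * sh
      d_hat <- sqrt(fwd * fwd + lat * lat)
      if (d_hat < stop_d) {
        stopped_intent <- TRUE
      } else {
        psi_r <- atan2(lat, fwd)
        v_cmd <- min(v_max, k_v * d_hat) * max(0, cos(psi_r))
        w_cmd <- k_w * psi_r / d2r
        if (w_cmd > omega_max) w_cmd <- omega_max
        else if (w_cmd < -omega_max) w_cmd <- -omega_max
      }
    }
    if (v_cmd != 0 || w_cmd != 0) {
      v_joy <- v_cmd + mn_v[i]
      if (v_joy > v_max) v_joy <- v_max else if (v_joy < -v_max) v_joy <- -v_max
      w_joy <- w_cmd + mn_w[i]
      if (w_joy > omega_max) w_joy <- omega_max
      else if (w_joy < -omega_max) w_joy <- -omega_max
    } else {
      v_joy <- 0; w_joy <- 0
    }
    v <- g * v_joy; w <- g * w_joy
    if (!is.null(pert_v)) { v <- v + pert_v[i]; w <- w + pert_w[i] }

    hr <- h * d2r
    x <- x + v * sin(hr) * dt
    y <- y + v * cos(hr) * dt
    h <- h + w * dt

    v_obs <- v + sn_v[i]; w_obs <- w + sn_w[i]
    her <- he * d2r
    xe <- xe + v_obs * sin(her) * dt
    ye <- ye + v_obs * cos(her) * dt
    he <- he + w_obs * dt

    v_s[i] <- v; w_s[i] <- w; x_s[i] <- x; y_s[i] <- y; h_s[i] <- h

    if (!moved && abs(v) > stop_v) { moved <- TRUE; move_idx <- i }
    if (moved && t >= rt) {
      if (abs(v) < stop_v && abs(w) < 1) {
        still_count <- still_count + 1L
        if (still_count >= still_needed) { stop_idx <- i; break }
      } else still_count <- 0L
    }
  }

  timed_out <- is.na(stop_idx)
  n_used <- if (timed_out) n_max else stop_idx
  stop_time <- if (timed_out) config$max_trial_duration else (stop_idx - 1) * dt
  keep <- seq_len(n_used)
  resp_x <- x_s[n_used]; resp_y <- y_s[n_used]
  err <- sqrt((resp_x - target$x)^2 + (resp_y - target$y)^2)
  feedback_time <- stop_time + rtruncexp(1, config$feedback_delay[1],
                                         config$feedback_delay[2],
                                         config$feedback_delay[3])

  structure(list(
    trial_id = as.integer(trial_id),
    target = list(r = target$r, theta = target$theta, x = target$x, y = target$y),
    response = list(r = sqrt(resp_x^2 + resp_y^2),
                    theta = rad2deg(atan2(resp_x, resp_y)),
                    x = resp_x, y = resp_y),
    linear_velocity = v_s[keep],
    angular_velocity = w_s[keep],
    position = cbind(x = x_s[keep], y = y_s[keep]),
    heading = h_s[keep],
    events = list(target_on = 0, target_off = config$target_display,
                  movement_onset = if (is.na(move_idx)) NA_real_ else (move_idx - 1) * dt,
                  stop_time = stop_time, feedback_time = feedback_time),
    rewarded = !timed_out && err <= config$reward_radius,
    stop_error = err,
    condition = condition,
    perturbation = perturbation,
    timed_out = timed_out,
    excluded = FALSE,
    sample_rate = config$sample_rate
  ), class = "nav_trial")
}

#' Build a trial from explicit joystick command series (open loop)
#'
#' Bypasses the synthetic agent: the supplied joystick series are scaled by
#' the config's joystick gain and integrated under unicycle kinematics.
#' Useful for controlled tests of the plant (e.g. the gain manipulation
#' scales both velocities by the same factor for identical commands).
#'
#' @param config A [task_config()].
#' @param v_joy,omega_joy Joystick command series (m/s, deg/s), clamped to the
#'   kinematic limits before the gain is applied.
#' @param target Optional target (as in [simulate_trial()]); defaults to the
#'   end of the resulting trajectory.
#' @param trial_id Integer identifier.
#' @return A `nav_trial`.
#' @export
open_loop_trial <- function(config, v_joy, omega_joy, target = NULL,
                            trial_id = 1L) {
  dt <- 1 / config$sample_rate
  v <- config$gain * clamp(v_joy, -config$v_max, config$v_max)
  w <- config$gain * clamp(omega_joy, -config$omega_max, config$omega_max)
  traj <- integrate_unicycle(v, w, dt)
  n <- length(v)
  resp_x <- traj$x[n]; resp_y <- traj$y[n]
  if (is.null(target))
    target <- list(x = resp_x, y = resp_y,
                   r = sqrt(resp_x^2 + resp_y^2),
                   theta = rad2deg(atan2(resp_x, resp_y)))
  moving <- abs(v) > 1e-9
  stop_time <- (n - 1) * dt
  timed_out <- stop_time >= config$max_trial_duration - dt || moving[n]
  err <- sqrt((resp_x - target$x)^2 + (resp_y - target$y)^2)
  structure(list(
    trial_id = as.integer(trial_id),
    target = target,
    response = list(r = sqrt(resp_x^2 + resp_y^2),
                    theta = rad2deg(atan2(resp_x, resp_y)),
                    x = resp_x, y = resp_y),
    linear_velocity = v, angular_velocity = w,
    position = cbind(x = traj$x, y = traj$y), heading = traj$heading,
    events = list(target_on = 0, target_off = config$target_display,
                  movement_onset = if (any(moving)) (which(moving)[1] - 1) * dt else NA_real_,
                  stop_time = stop_time, feedback_time = stop_time + 0.25),
    rewarded = !timed_out && err <= config$reward_radius,
    stop_error = err, condition = "baseline", perturbation = NULL,
    timed_out = timed_out, excluded = FALSE, sample_rate = config$sample_rate
  ), class = "nav_trial")
}

#' Simulate a block of navigation trials
#'
#' @param n Number of trials.
#' @param config A [task_config()].
#' @param ctrl A [controller_params()].
#' @param condition Condition label passed to [simulate_trial()].
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `nav_trials`: a list with elements `trials`
#'   (list of `nav_trial`), `config` and `ctrl`.
#' @export
simulate_trials <- function(n, config = task_config(),
                            ctrl = controller_params(),
                            condition = "baseline", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  targets <- sample_target(n, config)
  trials <- vector("list", n)
  for (i in seq_len(n))
    trials[[i]] <- simulate_trial(config, ctrl, targets[i, ],
                                  condition = condition, trial_id = i)
  structure(list(trials = trials, config = config, ctrl = ctrl),
            class = "nav_trials")
}

#' @export
print.nav_trials <- function(x, ...) {
  tab <- trial_table(x)
  cat(sprintf("nav_trials: %d trials (%d rewarded, %d excluded), condition(s): %s\n",
              nrow(tab), sum(tab$rewarded), sum(tab$excluded),
              paste(unique(tab$condition), collapse = ", ")))
  invisible(x)
}

#' Flag disengaged trials
#'
#' Marks trials in which the agent either remained stationary throughout
#' (peak speed below the stopping threshold) or failed to stop before the
#' trial timed out. Downstream analyses operate on the non-excluded trials.
#'
#' @param trials A `nav_trials` object or a list of `nav_trial`.
#' @param stop_threshold Speed threshold (m/s) defining "stationary".
#' @return The input with the `excluded` flag set on each trial.
#' @export
exclude_disengaged <- function(trials, stop_threshold = 0.01) {
  tl <- if (inherits(trials, "nav_trials")) trials$trials else trials
  for (i in seq_along(tl)) {
    tr <- tl[[i]]
    stationary <- max(abs(tr$linear_velocity)) < stop_threshold
    tl[[i]]$excluded <- stationary || isTRUE(tr$timed_out)
  }
  if (inherits(trials, "nav_trials")) { trials$trials <- tl; trials } else tl
}

#' Tabulate trials
#'
#' @param trials A `nav_trials` object or list of `nav_trial`.
#' @return Data frame, one row per trial: identifiers, target and response
#'   polar coordinates, stopping error, reward/exclusion flags, event times.
#' @export
trial_table <- function(trials) {
  tl <- if (inherits(trials, "nav_trials")) trials$trials else trials
  do.call(rbind, lapply(tl, function(tr) {
    data.frame(trial_id = tr$trial_id,
               target_r = tr$target$r, target_theta = tr$target$theta,
               target_x = tr$target$x, target_y = tr$target$y,
               response_r = tr$response$r, response_theta = tr$response$theta,
               response_x = tr$response$x, response_y = tr$response$y,
               stop_error = tr$stop_error, rewarded = tr$rewarded,
               condition = tr$condition, excluded = tr$excluded,
               movement_onset = tr$events$movement_onset,
               stop_time = tr$events$stop_time,
               feedback_time = tr$events$feedback_time)
  }))
}

#' Write a trial table as tab-separated text
#'
#' @param trials A `nav_trials` object or list of `nav_trial`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.table(trial_table(trials), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
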