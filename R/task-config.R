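#' Task configuration for the closed-loop navigation task
#'
#' Holds the geometry, kinematic limits, timing and manipulation parameters of
#' the virtual navigation task: the subject steers by joystick to a briefly
#' cued target on a ground plane rendered only through optic flow, and is
#' rewarded for stopping within a fixed radius of the remembered target.
#'
#' @param target_r_range Radial range (m) of target locations, default
#'   `c(0.7, 4)`.
#' @param target_theta_range Angular range (deg) of target locations, default
#'   `c(-40, 40)`.
#' @param target_radius Radius of the target disc (m).
#' @param reward_radius Radius of the reward zone around the target centre (m).
#' @param v_max Maximum linear speed (m/s).
#' @param omega_max Maximum angular speed (deg/s).
#' @param target_display Duration the target is visible (s).
#' @param max_trial_duration Trial timeout (s).
#' @param sample_rate Behavioral sampling rate (Hz); the task's native rate is
#'   833 1/3 Hz.
#' @param density Optic-flow ground-plane element density (elements/m^2):
#'   baseline 2.5, low-density manipulation 0.1.
#' @param gain Joystick gain multiplying both commanded velocities (1 at
#'   baseline; 1.5 or 2 under the gain manipulation).
#' @param feedback_delay Length-3 numeric `c(lower, upper, mean)` of the
#'   truncated-exponential waiting period between stopping and feedback (s).
#' @param intertrial_delay Length-3 numeric `c(lower, upper, mean)` of the
#'   truncated-exponential inter-trial delay (s).
#' @param area_uniform_targets If `TRUE` (default) targets are sampled
#'   uniformly over ground-plane area within the annular sector (radial
#'   density proportional to r); if `FALSE`, uniformly in (r, theta).
#' @return An object of class `task_config`.
#' @export
task_config <- function(target_r_range = c(0.7, 4),
                        target_theta_range = c(-40, 40),
                        target_radius = 0.2,
                        reward_radius = 0.6,
                        v_max = 2,
                        omega_max = 90,
                        target_display = 0.3,
                        max_trial_duration = 7,
                        sample_rate = 2500 / 3,
                        density = 2.5,
                        gain = 1,
                        feedback_delay = c(0.1, 0.6, 0.25),
                        intertrial_delay = c(0.2, 2.0, 0.5),
                        area_uniform_targets = TRUE) {
  if (diff(target_r_range) <= 0)
    stop("degenerate target_r_range: r_min must be < r_max")
  stopifnot(
    target_r_range[1] > 0, diff(target_theta_range) > 0,
    target_radius > 0, reward_radius > 0, v_max > 0, omega_max > 0,
    target_display > 0, max_trial_duration > 0, sample_rate > 0,
    density > 0, gain > 0,
    reward_radius < target_r_range[1]
  )
  structure(as.list(environment()), class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Navigation task configuration\n")
  cat(sprintf("  targets: r in [%.2f, %.2f] m, theta in [%g, %g] deg (%s)\n",
              x$target_r_range[1], x$target_r_range[2],
              x$target_theta_range[1], x$target_theta_range[2],
              if (x$area_uniform_targets) "area-uniform" else "(r, theta)-uniform"))
  cat(sprintf("  limits: v_max %.1f m/s, omega_max %g deg/s, gain %g\n",
              x$v_max, x$omega_max, x$gain))
  cat(sprintf("  reward radius %.2f m, timeout %g s, sample rate %.1f Hz\n",
              x$reward_radius, x$max_trial_duration, x$sample_rate))
  invisible(x)
}

#' Parameters of the synthetic steering agent
#'
#' The synthetic agent stands in for the animal: it observes its own velocity
#' through noisy channels (emulating optic-flow estimation), integrates the
#' observations into an internal position estimate, and steers toward the
#' remembered target with a saturating proportional controller. Noise scales
#' are stationary standard deviations of Ornstein-Uhlenbeck processes.
#'
#' @param gain_linear Proportional gain (1/s) from estimated target distance
#'   to commanded linear speed.
#' @param gain_angular Proportional gain (1/s) from estimated target bearing
#'   to commanded angular speed.
#' @param motor_noise_sd Motor noise sd added to joystick commands (m/s on the
#'   linear channel; scaled by `omega_max/v_max` on the angular channel).
#' @param sensory_noise_sd Velocity-observation noise sd (m/s); multiplied by
#'   `density_noise_factor` when optic-flow density is at its low value.
#' @param density_noise_factor Multiplier applied to `sensory_noise_sd` under
#'   the low-density manipulation.
#' @param stop_threshold Linear speed (m/s) below which the agent counts as
#'   stopped (the angular criterion is 1 deg/s).
#' @param stop_distance Estimated distance to target (m) below which the
#'   agent releases the joystick.
#' @param reaction_time_range Range (s) of the uniform movement-onset delay
#'   after target onset.
#' @return An object of class `controller_params`.
#' @export
controller_params <- function(gain_linear = 1.5,
                              gain_angular = 3,
                              motor_noise_sd = 0.15,
                              sensory_noise_sd = 0.5,
                              density_noise_factor = 5,
                              stop_threshold = 0.01,
                              stop_distance = 0.15,
                              reaction_time_range = c(0.2, 0.5)) {
  stopifnot(motor_noise_sd >= 0, sensory_noise_sd >= 0,
            density_noise_factor >= 1, stop_threshold > 0, stop_distance > 0)
  structure(as.list(environment()), class = "controller_params")
}
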