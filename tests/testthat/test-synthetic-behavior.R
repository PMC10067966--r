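test_that("target sampling respects ranges, determinism, and area-uniformity", {
  cfg <- task_config()
  set.seed(1)
  tg <- sample_target(10000, cfg)
  expect_true(all(tg$r >= 0.7 & tg$r <= 4))
  expect_true(all(abs(tg$theta) <= 40))

  set.seed(99); a <- sample_target(50, cfg)
  set.seed(99); b <- sample_target(50, cfg)
  expect_identical(a, b)

  # area-uniform sampling: P(r <= 2.875) = (2.875^2 - 0.7^2) / (4^2 - 0.7^2)
  closed_form <- (2.875^2 - 0.7^2) / (4^2 - 0.7^2)
  expect_equal(mean(tg$r <= 2.875), closed_form, tolerance = 0.02)
  # independent Monte-Carlo oracle by rejection from the ground-plane area
  set.seed(7)
  xy <- matrix(runif(2e5, -4, 4), ncol = 2)
  r_mc <- sqrt(rowSums(xy^2))
  th_mc <- abs(atan2(xy[, 1], xy[, 2])) * 180 / pi
  keep <- r_mc >= 0.7 & r_mc <= 4 & th_mc <= 40
  expect_equal(mean(r_mc[keep] <= 2.875), closed_form, tolerance = 0.02)

  expect_error(task_config(target_r_range = c(3, 3)), "degenerate")
})

test_that("open-loop gain manipulation scales both velocities exactly", {
  n <- 2000
  v_cmd <- pmin(2, seq(0, 3, length.out = n))
  w_cmd <- 30 * sin(seq(0, 4 * pi, length.out = n))
  t1 <- open_loop_trial(task_config(gain = 1), v_cmd, w_cmd)
  t2 <- open_loop_trial(task_config(gain = 2), v_cmd, w_cmd)
  expect_equal(t2$linear_velocity, 2 * t1$linear_velocity)
  expect_equal(t2$angular_velocity, 2 * t1$angular_velocity)
  expect_true(all(abs(t2$linear_velocity) <= 2 * 2 + 1e-12))
})

test_that("closed loop: null controller times out, noiseless agent is rewarded", {
  cfg <- task_config()
  null_ctrl <- controller_params(gain_linear = 0, gain_angular = 0,
                                 motor_noise_sd = 0, sensory_noise_sd = 0)
  set.seed(2)
  tr <- simulate_trial(cfg, null_ctrl, list(x = 0, y = 2, r = 2, theta = 0))
  expect_true(tr$timed_out)
  expect_equal(tr$events$stop_time, cfg$max_trial_duration)

  clean <- controller_params(motor_noise_sd = 0, sensory_noise_sd = 0)
  set.seed(3)
  tr2 <- simulate_trial(cfg, clean, list(x = 0, y = 2, r = 2, theta = 0))
  expect_lt(tr2$stop_error, 0.6)
  expect_true(tr2$rewarded)
})

test_that("perturbation pulse is additive with the derived integral", {
  cfg <- task_config()
  n <- round(3 * cfg$sample_rate)
  v <- rep(1, n); w <- rep(0, n)
  out <- apply_perturbation(v, w, amp_v = 1.5, amp_omega = -60, t_onset = 0.5,
                            config = cfg)
  added <- out$v - v
  t_peak_idx <- which.max(added)
  expect_equal((t_peak_idx - 1) / cfg$sample_rate, 1.0, tolerance = 2 / cfg$sample_rate)
  expect_equal(max(added), 1.5, tolerance = 1e-3)

  # zero amplitudes leave the series unchanged
  same <- apply_perturbation(v, w, 0, 0, 0.5, cfg)
  expect_equal(same$v, v); expect_equal(same$omega, w)

  # time-integral matches numeric quadrature of the truncated Gaussian
  oracle <- integrate(function(t) 1.5 * exp(-(t - 1)^2 / (2 * 0.2^2)),
                      0.5, 1.5)$value
  expect_equal(sum(added) / cfg$sample_rate, oracle, tolerance = 1e-3)
  expect_error(apply_perturbation(v, w, 3, 0, 0.5, cfg), "out of bounds")
})

test_that("disengaged-trial exclusion flags stationary and timed-out trials", {
  cfg <- task_config()
  n <- 800
  still <- open_loop_trial(cfg, rep(0, n), rep(0, n))
  moving <- open_loop_trial(cfg, c(rep(1, n), rep(0, 300)), rep(0, n + 300))
  timed <- open_loop_trial(cfg, rep(1, round(7 * cfg$sample_rate)),
                           rep(0, round(7 * cfg$sample_rate)))
  trials <- c(list(still, still, still, timed, timed), rep(list(moving), 15))
  out <- exclude_disengaged(trials)
  expect_equal(sum(vapply(out, `[[`, logical(1), "excluded")), 5L)
  expect_false(out[[10]]$excluded)
  expect_identical(exclude_disengaged(list()), list())
})

test_that("unicycle integration matches a midpoint-rule oracle and noiseless slope is 1", {
  dt <- 1 / task_config()$sample_rate
  n <- 2000
  t <- (seq_len(n) - 1) * dt
  v <- 1.5 * exp(-t)
  w <- 40 * sin(2 * pi * t)
  traj <- integrate_unicycle(v, w, dt)
  # midpoint-rule oracle at the same step
  h <- cumsum(w) * dt
  hm <- (c(0, h[-n]) + h) / 2 * pi / 180
  x_mid <- cumsum(v * sin(hm)) * dt
  y_mid <- cumsum(v * cos(hm)) * dt
  expect_lt(max(abs(traj$x - x_mid)), 0.01)
  expect_lt(max(abs(traj$y - y_mid)), 0.01)

  clean <- controller_params(motor_noise_sd = 0, sensory_noise_sd = 0)
  set.seed(11)
  s <- simulate_trials(40, task_config(), clean)
  reg <- response_regression(s)
  expect_equal(reg$slope_radial, 1, tolerance = 0.1)
  expect_gt(reg$r_radial, 0.98)
})

test_that("density manipulation changes only the sensory noise scale", {
  cfg_base <- task_config()
  cfg_low <- task_config(density = 0.1)
  clean <- controller_params(motor_noise_sd = 0, sensory_noise_sd = 0)
  tgt <- list(x = 0.8, y = 2.5, r = sqrt(0.8^2 + 2.5^2),
              theta = atan2(0.8, 2.5) * 180 / pi)
  set.seed(5); t1 <- simulate_trial(cfg_base, clean, tgt, condition = "baseline")
  set.seed(5); t2 <- simulate_trial(cfg_low, clean, tgt, condition = "density")
  # with zero sensory noise the manipulated trial is identical: no kinematic change
  expect_equal(t1$linear_velocity, t2$linear_velocity)
  expect_equal(t1$position, t2$position)

  noisy <- controller_params(sensory_noise_sd = 0.3, motor_noise_sd = 0)
  set.seed(6); e_base <- mean(trial_table(simulate_trials(30, cfg_base, noisy))$stop_error)
  set.seed(6); e_low <- mean(trial_table(
    simulate_trials(30, cfg_low, noisy, condition = "density"))$stop_error)
  expect_gt(e_low, e_base)
})
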