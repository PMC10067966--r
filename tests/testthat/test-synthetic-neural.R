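test_that("LFP phase has ~15 Hz cycles, bounded phase, exact advance without jitter", {
  dt <- 0.006
  set.seed(1)
  ph <- simulate_lfp(60, dt)
  expect_true(all(ph >= -180 & ph < 180))
  # mean cycle length ~ 66.7 ms from wrap count
  wraps <- sum(diff(ph) < -180)
  expect_equal(60 / wraps, 1 / 15, tolerance = 0.05)
  ph0 <- simulate_lfp(1, dt, jitter_sd = 0)
  steps <- diff(ph0)
  steps <- steps[steps > -180]
  expect_equal(unique(round(steps, 9)), 360 * 15 * dt)
})

test_that("motor channels mix joystick velocities and are reproducible", {
  cfg <- task_config()
  clean <- controller_params(motor_noise_sd = 0, sensory_noise_sd = 0)
  set.seed(2)
  tr <- simulate_trial(cfg, clean, list(x = 1, y = 2.5, r = sqrt(7.25),
                                        theta = atan2(1, 2.5) * 180 / pi))
  m0 <- derive_motor_channels(tr, noise_sd = 0)
  # zero motion, zero noise -> zero channels
  still <- open_loop_trial(cfg, rep(0, 500), rep(0, 500))
  expect_true(all(derive_motor_channels(still, noise_sd = 0) == 0))
  # channels correlate with joystick velocity at default noise
  set.seed(3)
  m1 <- derive_motor_channels(tr)
  expect_gt(abs(cor(m1[, 1], tr$linear_velocity)), 0.5)
  set.seed(4); a <- derive_motor_channels(tr)
  set.seed(4); b <- derive_motor_channels(tr)
  expect_identical(a, b)
})

test_that("spike generator: baseline rate, refractoriness, and determinism", {
  # flat encoding at 10 Hz: empirical rate within Poisson error over ~600 s
  truth <- ground_truth_encoding(n_neurons = 2, n_couplings = 0,
                                 tuned_variables = character(0), seed = 5)
  truth$b[] <- log(10 * truth$dt)
  for (i in 1:2) {
    truth$event[[i]]$target_on[] <- 0
    truth$event[[i]]$reward[] <- 0
    truth$history[[i]][] <- 0
  }
  cfg <- task_config()
  trials <- exclude_disengaged(simulate_trials(120, cfg, seed = 6))
  ses <- bin_session(trials, dt = truth$dt, seed = 7)
  ses <- simulate_spikes(ses, truth, seed = 8)
  dur <- nrow(ses$counts) * truth$dt
  rate <- colSums(ses$counts) / dur
  se <- sqrt(10 / dur)
  expect_true(all(abs(rate - 10) < 4 * se))

  # strongly negative short-lag history suppresses short ISIs
  truth2 <- truth
  truth2$history[[1]] <- c(-8, -6, rep(0, 8))
  ses2 <- simulate_spikes(ses, truth2, seed = 9)
  isi_short <- function(s, i) {
    sp <- s$spikes[[i]]
    isis <- unlist(tapply(sp$t, sp$trial, function(x) diff(sort(x))))
    mean(isis < 0.006)
  }
  expect_lt(isi_short(ses2, 1), isi_short(ses, 1))

  ses3 <- simulate_spikes(ses, truth, seed = 8)
  expect_identical(ses3$counts, ses$counts)
})

test_that("excitatory coupling raises the cross-correlation at positive lags", {
  truth <- ground_truth_encoding(n_neurons = 2, n_couplings = 0,
                                 tuned_variables = character(0), seed = 10)
  truth$b[] <- log(15 * truth$dt)
  for (i in 1:2) {
    truth$event[[i]]$target_on[] <- 0
    truth$event[[i]]$reward[] <- 0
    truth$history[[i]][] <- 0
  }
  truth_c <- truth
  truth_c$coupling <- list(list(from = 1, to = 2,
                                coef = 1.2 * exp(-(0:9) / 2)))
  cfg <- task_config()
  trials <- exclude_disengaged(simulate_trials(60, cfg, seed = 11))
  ses0 <- bin_session(trials, dt = truth$dt, seed = 12)
  sesu <- simulate_spikes(ses0, truth, seed = 13)
  sesc <- suppressWarnings(simulate_spikes(ses0, truth_c, seed = 13))
  cc_u <- cross_correlation(sesu$counts[, 2], sesu$counts[, 1], max_lag = 10,
                            baseline = "rj")
  cc_c <- cross_correlation(sesc$counts[, 2], sesc$counts[, 1], max_lag = 10,
                            baseline = "rj")
  pos <- cc_c$lag >= 1 & cc_c$lag <= 6
  expect_gt(mean(cc_c$value[pos]), mean(cc_u$value[pos]) + 0.005)
})

test_that("with other drives silent, conditional rates follow exp of the tuning", {
  truth <- ground_truth_encoding(n_neurons = 1, n_couplings = 0,
                                 tuned_variables = "target_distance",
                                 baseline_hz = c(15, 15), seed = 30)
  truth$event[[1]]$target_on[] <- 0
  truth$event[[1]]$reward[] <- 0
  truth$history[[1]][] <- 0
  cfg <- task_config()
  trials <- exclude_disengaged(simulate_trials(80, cfg, seed = 31))
  ses <- bin_session(trials, dt = truth$dt, seed = 32)
  ses <- suppressWarnings(simulate_spikes(ses, truth, seed = 33))
  x <- ses$signals[, "target_distance"]
  rg <- truth$var_ranges$target_distance
  edges <- seq(rg[1], rg[2], length.out = 11)
  bin <- pmin(pmax(findInterval(x, edges), 1L), 10L)
  emp <- tapply(ses$counts[, 1], bin, mean)
  keep <- as.integer(names(emp))
  # log conditional rate tracks the tuning function up to an additive constant
  expect_gt(cor(log(pmax(emp, 1e-4)),
                truth$tuning[[1]]$target_distance[keep]), 0.9)
})
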