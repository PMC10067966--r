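test_that("exponential smoothing: impulse response and steady state", {
  dt <- 0.006
  eta <- 0.05
  counts <- rep(0, 400); counts[100] <- 1
  r <- smooth_rates(counts, eta, dt)
  expect_true(all(r[1:99] == 0))
  dtau <- (0:50) * dt
  expect_equal(r[100 + 0:50] / r[100], exp(-dtau / eta) * exp(-dt / eta)^0,
               tolerance = 1e-10)
  # eta halved: impulse response decays twice as fast
  r2 <- smooth_rates(counts, eta / 2, dt)
  expect_equal(r2[130] / r2[100], (r[130] / r[100])^2, tolerance = 1e-10)

  # constant 20 Hz train converges to 20 Hz
  lam <- 20
  steady <- smooth_rates(rep(lam * dt, 3000), eta, dt)
  expect_equal(steady[3000], lam, tolerance = 1e-6)
})

test_that("ordinary least-squares decoder worked examples", {
  expect_equal(fit_linear_decoder(diag(2), c(3, 5)), c(3, 5),
               ignore_attr = TRUE)
  expect_equal(fit_linear_decoder(matrix(c(1, 2), 2, 1), c(2, 4)), 2,
               ignore_attr = TRUE)
  set.seed(1)
  R <- matrix(rnorm(300), 100, 3)
  w_true <- c(0.5, -1, 2)
  w <- fit_linear_decoder(R, as.numeric(R %*% w_true))
  expect_equal(w, w_true, ignore_attr = TRUE, tolerance = 1e-10)
  expect_error(fit_linear_decoder(matrix(0, 5, 2), rnorm(5)), "all-zero")
  # singular case falls back to the pseudo-inverse and flags it
  Rs <- cbind(R[, 1], R[, 1])
  ws <- fit_linear_decoder(Rs, R[, 1])
  expect_true(attr(ws, "pseudo_inverse"))
  expect_equal(sum(ws), 1, tolerance = 1e-8)
})

test_that("timescale selection is self-consistent and respects the grid", {
  ses <- small_session()
  # construct a target variable generated by rates smoothed at eta0 = 100 ms
  eta0 <- 0.1
  R0 <- smooth_rates(ses$counts, eta0, ses$dt, ses$trial_id)
  set.seed(2)
  w_true <- rnorm(ncol(R0))
  ses2 <- ses
  ses2$signals <- cbind(ses$signals, driven = as.numeric(R0 %*% w_true))
  fit <- select_timescale(ses2, "driven", seed = 3)
  grid <- fit$eta_grid
  step <- which(abs(grid - fit$eta) < 1e-12)
  target_step <- which.min(abs(grid - eta0))
  expect_lte(abs(step - target_step), 1)
  expect_gte(fit$eta, 0.025); expect_lte(fit$eta, 0.25)
  expect_gt(fit$r_test, 0.95)

  fit_b <- select_timescale(ses2, "driven", seed = 3)
  expect_identical(fit$eta, fit_b$eta)
  expect_identical(fit$split, fit_b$split)
})

test_that("latent state decodes from the small coupled session", {
  # only 6 neurons here, so performance is modest but well above chance;
  # the session-scale check (20 neurons) lives with the end-to-end tests
  ses <- small_session()
  fit <- select_timescale(ses, "target_distance", seed = 4)
  expect_gt(fit$r_test, 0.35)
})

test_that("error analysis: identity construction and permutation null", {
  ses <- small_session()
  set.seed(5)
  fits <- lapply(c("target_distance", "linear_velocity",
                   "angular_velocity", "target_angle"), function(v)
    select_timescale(ses, v, seed = 6))
  names(fits) <- c("target_distance", "linear_velocity",
                   "angular_velocity", "target_angle")
  ea <- error_analysis(ses, fits)
  expect_true(is.finite(ea$r_decode_vs_behavior))
  expect_true(is.na(ea$undershoot_overshoot_auc) ||
              (ea$undershoot_overshoot_auc >= 0 &&
               ea$undershoot_overshoot_auc <= 1))

  # decoding error identical to behavioral error -> r = 1, AUC = 1
  te <- ea$trial_errors
  fake <- te
  fake$target_distance <- fake$behavioral
  r <- cor(fake$target_distance, fake$behavioral)
  expect_equal(r, 1)
  under <- fake$behavioral < 0; over <- fake$behavioral > 0
  auc <- latentnav:::rank_auc(fake$target_distance[over],
                              fake$target_distance[under])
  expect_equal(auc, 1)

  # permuted decoding errors are uncorrelated with behavior
  set.seed(7)
  perm_r <- replicate(200, cor(sample(te$target_distance), te$behavioral))
  expect_lt(abs(mean(perm_r)), 2 * sd(perm_r))
})

test_that("surrogate modes preserve the decoder angle exactly", {
  set.seed(8)
  w_a <- rnorm(30); w_b <- rnorm(30)
  R <- matrix(rnorm(3000), 100, 30)
  tid <- rep(1:20, each = 5)
  null <- surrogate_angle_null(w_a, w_b, R, tid, n_surrogate = 50)
  expect_true(all(abs(null$angles - null$phi) < 1e-6))
  expect_equal(length(null$correlations), 50)

  # identical decoders: surrogate pairs coincide, correlations are 1
  null0 <- surrogate_angle_null(w_a, w_a, R, tid, n_surrogate = 10)
  expect_true(all(abs(null0$angles) < 1e-6))
  expect_true(all(null0$correlations > 1 - 1e-10))
  expect_error(surrogate_angle_null(0 * w_a, w_b, R, tid), "zero decoder")

  # isotropic activity: mean null correlation approaches cos(phi), checked
  # against a brute-force oracle with independent Gaussian projections
  set.seed(9)
  Riso <- matrix(rnorm(40000), 2000, 20)
  tid2 <- rep(1:400, each = 5)
  wa <- c(1, rep(0, 19)); wb <- c(cos(1), sin(1), rep(0, 18))
  nl <- surrogate_angle_null(wa, wb, Riso, tid2, n_surrogate = 200)
  oracle <- replicate(500, {
    u <- rnorm(400); v <- cos(1) * u + sin(1) * rnorm(400)
    cor(u, v)
  })
  expect_equal(mean(nl$correlations), mean(oracle), tolerance = 0.05)
})

test_that("decoding performance grows with population size", {
  ses <- small_session()
  r_of <- function(neurons) {
    ses_sub <- ses
    ses_sub$counts <- ses$counts[, neurons, drop = FALSE]
    ses_sub$spikes <- ses$spikes[neurons]
    mean(vapply(1:3, function(s)
      select_timescale(ses_sub, "target_distance", seed = s)$r_test,
      numeric(1)))
  }
  expect_gt(r_of(1:6), r_of(1:2))
})
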