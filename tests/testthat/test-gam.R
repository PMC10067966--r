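# minimal hand-built session: 1 trial, 2 neurons, a single spike in neuron 2
impulse_session <- function(n_bins = 300, spike_bin = 50, dt = 0.006) {
  sig <- cbind(linear_velocity = rep(0.5, n_bins))
  ev <- matrix(0, n_bins, 2, dimnames = list(NULL, c("target_on", "reward")))
  ev[1, 1] <- 1
  counts <- matrix(0L, n_bins, 2)
  counts[spike_bin, 2] <- 1L
  structure(list(signals = sig, events = ev, counts = counts,
                 trial_id = rep(1L, n_bins),
                 bin_time = (seq_len(n_bins) - 0.5) * dt,
                 trial_table = data.frame(trial_id = 1L, stop_time = n_bins * dt),
                 dt = dt, spikes = NULL),
            class = "nav_session")
}

test_that("design expansion: impulse response and boxcar partition", {
  ses <- impulse_session()
  des <- build_design(ses, variables = "linear_velocity")
  # a single spike in neuron 2 puts time-shifted copies of the coupling
  # basis into its coupling columns
  B <- des$basis$coupling
  L <- nrow(B)
  block <- des$coup[[2]][50 + seq_len(L), ]
  expect_equal(block, unclass(B)[seq_len(nrow(block)), ],
               ignore_attr = TRUE)
  expect_lt(max(abs(des$coup[[2]][seq_len(50), ])), 1e-10)
  # constant predictor: exactly one boxcar column active per bin
  expect_true(all(rowSums(des$tuning$linear_velocity) == 1))
  expect_error(build_design(ses, variables = "no_such_channel"),
               "no_such_channel")
})

test_that("pseudo-R2 and variance-explained arithmetic", {
  expect_equal(pseudo_r2(-150, -100, -200), 0.5)
  expect_equal(pseudo_r2(-100, -100, -200), 1)
  expect_equal(pseudo_r2(-200, -100, -200), 0)
  expect_error(pseudo_r2(-1, -5, -5), "undefined")

  # two neurons: R2 0.5 with Var 1, R2 0 with Var 9 -> pooled 0.05
  n <- 400
  set.seed(1)
  mkvar <- function(v) { x <- rnorm(n); x / sd(x) * sqrt(v) }
  obs1 <- mkvar(1); err1 <- mkvar(0.5)
  obs2 <- mkvar(9); err2 <- mkvar(9)
  ve <- variance_explained(cbind(obs1 - err1, obs2 - err2),
                           cbind(obs1, obs2))
  expect_equal(unname(ve$r2[1]), 0.5, tolerance = 1e-10)
  expect_equal(unname(ve$r2[2]), 0, tolerance = 1e-10)
  expect_equal(ve$r2_pop, 1 - (0.5 + 9) / (1 + 9), tolerance = 1e-10)

  perfect <- variance_explained(cbind(obs1, obs2), cbind(obs1, obs2))
  expect_equal(perfect$r2_pop, 1)
  const <- variance_explained(cbind(rep(mean(obs1), n)), cbind(obs1))
  expect_equal(unname(const$r2[1]), 0, tolerance = 1e-10)
})

test_that("coupling strength and exponential re-expression", {
  expect_equal(coupling_strength(rep(0, 100)), 1)
  expect_equal(coupling_strength(rep(0.1, 100)), exp(0.1))

  dt <- 0.006
  lags <- seq(dt / 2, 1.375 - dt / 2, by = dt)
  pure24 <- 0.7 * exp(-lags / 0.024)
  re <- refit_exponential_basis(pure24, dt)
  expect_equal(unname(re$weights["tau24"]), 0.7, tolerance = 1e-6)
  expect_lt(max(abs(re$weights[names(re$weights) != "tau24"])), 1e-6)
})

test_that("marginal tuning: flat model, log-additive baseline shift, recovery", {
  dt <- 0.006
  flat <- structure(list(
    tuning = list(linear_velocity = list(weights = rep(0, 10),
                                         edges = seq(0, 2, length.out = 11),
                                         centers = seq(0.1, 1.9, by = 0.2))),
    event = list(), kernel = list(), b = log(10 * dt), dt = dt),
    class = "gam_fit")
  mt <- marginal_tuning(flat, "linear_velocity", NULL)
  expect_equal(mt$rate, rep(10, 10))
  flat2 <- flat; flat2$b <- flat$b + log(2)
  expect_equal(marginal_tuning(flat2, "linear_velocity", NULL)$rate,
               2 * mt$rate)
  expect_error(marginal_tuning(flat, "target_distance", NULL), "not in model")

  # fitted marginal tuning tracks the empirical conditional rate
  ses <- small_session(); des <- small_design(); fits <- small_fits()
  truth <- small_truth()
  amp <- vapply(truth$tuning, function(tf) diff(range(tf$target_distance)),
                numeric(1))
  i <- which.max(amp)
  mt_i <- marginal_tuning(fits[[i]], "target_distance", des)
  x <- ses$signals[, "target_distance"]
  edges <- fits[[i]]$tuning$target_distance$edges
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), 10L)
  emp <- tapply(ses$counts[, i], bin, mean) / ses$dt
  keep <- as.integer(names(emp))
  expect_gt(cor(mt_i$rate[keep], emp), 0.9)
})

test_that("MAP fit recovers generative tuning on the small session", {
  truth <- small_truth(); fits <- small_fits()
  vars <- c("linear_velocity", "angular_velocity", "target_distance",
            "target_angle", "lfp_phase")
  cors <- unlist(lapply(seq_along(fits), function(i)
    vapply(vars, function(v) tuning_recovery_cor(truth, fits[[i]], i, v),
           numeric(1))))
  expect_gt(median(cors, na.rm = TRUE), 0.85)
})

test_that("true couplings stand out and the smoothness penalty limit flattens tuning", {
  truth <- small_truth(); fits <- small_fits()
  true_pairs <- vapply(truth$coupling, function(cp)
    paste(cp$from, cp$to), character(1))
  mag <- c(); is_true <- c()
  for (i in seq_along(fits)) for (cp in fits[[i]]$coupling) {
    mag <- c(mag, max(abs(cp$coef)))
    is_true <- c(is_true, paste(cp$from, i) %in% true_pairs)
  }
  expect_true(all(mag[is_true] > 10 * stats::median(mag[!is_true])))
  expect_gt(sum(mag[!is_true] < 1e-6), 0)  # L1 produces exact zeros

  des <- small_design()
  f_hi <- suppressWarnings(
    fit_gam(des, 1, hp = gam_hyperparams(lambda = 1e6), coupled = FALSE,
            max_iter = 400, tol = 1e-9))
  f_lo <- suppressWarnings(
    fit_gam(des, 1, hp = gam_hyperparams(lambda = 1), coupled = FALSE,
            max_iter = 400, tol = 1e-9))
  r_hi <- diff(range(f_hi$tuning$target_distance$weights))
  r_lo <- diff(range(f_lo$tuning$target_distance$weights))
  expect_lt(r_hi, 0.01 * r_lo)
})

test_that("the MAP objective is convex: different starts agree", {
  des <- small_design()
  f1 <- suppressWarnings(fit_gam(des, 2, max_iter = 800, tol = 1e-10))
  set.seed(42)
  f2 <- suppressWarnings(fit_gam(des, 2, max_iter = 800, tol = 1e-10,
                                 w0 = rnorm(length(f1$coef), 0, 0.1)))
  expect_equal(f1$objective, f2$objective, tolerance = 1e-6)
})

test_that("coupled model beats uncoupled on coupling-generated data only", {
  des <- small_design()
  ses <- small_session()
  trials <- unique(des$trial_id)
  set.seed(7)
  held <- sample(trials, round(0.2 * length(trials)))
  rows_tr <- which(!des$trial_id %in% held)
  rows_te <- which(des$trial_id %in% held)
  heldout_ll <- function(des, coupled) {
    sum(vapply(seq_len(des$N), function(i) {
      fit <- suppressWarnings(fit_gam(des, i, coupled = coupled,
                                      rows = rows_tr, max_iter = 250,
                                      tol = 1e-7))
      mu <- predict(fit, des, rows = rows_te)
      latentnav:::poisson_loglik(des$counts[rows_te, i], mu)
    }, numeric(1)))
  }
  d_coup <- heldout_ll(des, TRUE) - heldout_ll(des, FALSE)
  expect_gt(d_coup, 0)

  # same comparison on data generated without coupling: no reliable gain
  truth0 <- small_truth()
  truth0$coupling <- list()
  ses0 <- ses
  ses0 <- suppressWarnings(simulate_spikes(ses0, truth0, seed = 99))
  des0 <- build_design(ses0, variables = c("linear_velocity",
                                           "target_distance", "lfp_phase"))
  d_unc <- heldout_ll(des0, TRUE) - heldout_ll(des0, FALSE)
  expect_lt(d_unc, d_coup)
  expect_lt(abs(d_unc) / length(rows_te), 0.01)
})

test_that("backward elimination keeps driving groups and drops irrelevant ones", {
  # neuron tuned only to linear velocity, plus a constant-rate neuron
  truth <- ground_truth_encoding(n_neurons = 2, n_couplings = 0,
                                 tuned_variables = "linear_velocity",
                                 seed = 21)
  truth$tuning[[1]]$linear_velocity <-
    1.2 * (seq(0, 1, length.out = 10) - 0.5)
  truth$b[] <- log(12 * truth$dt)
  truth$event[[2]]$target_on[] <- 0
  truth$tuning[[2]]$linear_velocity[] <- 0
  for (i in 1:2) { truth$event[[i]]$reward[] <- 0; truth$history[[i]][] <- 0 }
  cfg <- task_config(target_r_range = c(0.7, 2))
  trials <- exclude_disengaged(simulate_trials(40, cfg, seed = 22))
  ses <- bin_session(trials, dt = truth$dt, seed = 23)
  ses <- suppressWarnings(simulate_spikes(ses, truth, seed = 24))
  des <- build_design(ses, variables = c("linear_velocity", "target_angle"))

  be <- backward_eliminate(des, 1, coupled = FALSE, n_folds = 5, seed = 25,
                           max_iter = 150, tol = 1e-6)
  expect_true("linear_velocity" %in% be$selected)
  expect_false("target_angle" %in% be$selected)

  be0 <- backward_eliminate(des, 2, coupled = FALSE, n_folds = 5, seed = 26,
                            max_iter = 150, tol = 1e-6)
  expect_false(any(c("linear_velocity", "target_angle") %in% be0$selected))
  expect_lt(abs(be0$pseudo_r2_test), 0.05)
  expect_error(backward_eliminate(small_design(), 1, seed = 1,
                                  n_folds = 10, test_frac = 0.9),
               "at least 20")
})

test_that("held-out likelihood degrades at extreme smoothness penalties", {
  des <- small_design()
  gs <- suppressWarnings(
    hp_grid_search(des, 1, which = "lambda", values = c(0.01, 100, 1e6),
                   seed = 30, max_iter = 200, tol = 1e-7))
  expect_lt(gs$heldout_loglik[3], max(gs$heldout_loglik))
})
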