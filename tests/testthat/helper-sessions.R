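# Shared fixtures, built in code and cached for the duration of the test run.
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small coupled session: 6 neurons, 3 true couplings, 40 trials
small_truth <- function() cached_fixture("small_truth", function()
  ground_truth_encoding(n_neurons = 6, n_couplings = 3, seed = 101))

small_session <- function() cached_fixture("small_session", function() {
  truth <- small_truth()
  suppressWarnings(simulate_session(40, truth, seed = 202))
})

small_design <- function() cached_fixture("small_design", function()
  build_design(small_session(),
               variables = c("linear_velocity", "angular_velocity",
                             "target_distance", "target_angle", "lfp_phase")))

small_fits <- function() cached_fixture("small_fits", function()
  suppressWarnings(fit_gam_population(small_design(), max_iter = 400,
                                      tol = 1e-8)))

# recovery-scale session shared by the acceptance checks: 20 neurons,
# 10 true couplings, 500 trials, fit with the study's hyperparameters
recovery_truth <- function() cached_fixture("recovery_truth", function()
  ground_truth_encoding(n_neurons = 20, n_couplings = 10, seed = 303))

recovery_session <- function() cached_fixture("recovery_session", function() {
  truth <- recovery_truth()
  suppressWarnings(simulate_session(500, truth, seed = 404))
})

recovery_design <- function() cached_fixture("recovery_design", function()
  build_design(recovery_session(),
               variables = c("linear_velocity", "angular_velocity",
                             "target_distance", "target_angle", "lfp_phase")))

# 90/10 trial split for held-out model comparison
recovery_split <- function() cached_fixture("recovery_split", function() {
  des <- recovery_design()
  trials <- unique(des$trial_id)
  set.seed(505)
  held <- sample(trials, round(0.1 * length(trials)))
  list(train = which(!des$trial_id %in% held),
       test = which(des$trial_id %in% held))
})

recovery_fits <- function() cached_fixture("recovery_fits", function()
  suppressWarnings(fit_gam_population(recovery_design(),
                                      rows = recovery_split()$train,
                                      max_iter = 120, tol = 1e-7)))

recovery_fits_uncoupled <- function() cached_fixture(
  "recovery_fits_uncoupled", function()
  suppressWarnings(fit_gam_population(recovery_design(), coupled = FALSE,
                                      rows = recovery_split()$train,
                                      max_iter = 120, tol = 1e-7)))

# stability-analysis fixtures: 8 neurons with motor kernels and 10 true
# couplings; five population fits (baseline, its odd/even split, a second
# independent baseline, and a session generated after rerandomizing the
# coupling and latent-tuning ground truth while sensory/motor stay fixed)
stability_truth <- function() cached_fixture("stability_truth", function()
  ground_truth_encoding(n_neurons = 8, n_couplings = 10,
                        motor_kernel_amp = 0.6,
                        tuned_variables = c("linear_velocity",
                                            "angular_velocity",
                                            "target_distance",
                                            "target_angle"),
                        seed = 501))

stability_fit_of <- function(truth, seed_b, n_trials = 140,
                             trial_filter = NULL) {
  cfg <- task_config()
  trials <- exclude_disengaged(simulate_trials(n_trials, cfg, seed = seed_b))
  ses <- bin_session(trials, dt = truth$dt, seed = seed_b + 1)
  ses <- suppressWarnings(simulate_spikes(ses, truth, seed = seed_b + 2))
  if (!is.null(trial_filter)) {
    keep_trials <- trial_filter(ses$trial_table$trial_id)
    rows <- ses$trial_id %in% keep_trials
    ses$signals <- ses$signals[rows, , drop = FALSE]
    ses$events <- ses$events[rows, , drop = FALSE]
    ses$counts <- ses$counts[rows, , drop = FALSE]
    ses$bin_time <- ses$bin_time[rows]
    ses$trial_id <- ses$trial_id[rows]
    ses$trial_table <- ses$trial_table[
      ses$trial_table$trial_id %in% keep_trials, ]
    ses$spikes <- lapply(ses$spikes, function(s)
      s[s$trial %in% keep_trials, , drop = FALSE])
  }
  des <- build_design(ses, variables = c("linear_velocity",
                                         "angular_velocity",
                                         "target_distance", "target_angle",
                                         "motor1", "motor2"))
  suppressWarnings(fit_gam_population(des, max_iter = 200, tol = 1e-7))
}

stability_fits <- function() cached_fixture("stability_fits", function() {
  truth <- stability_truth()
  manip <- perturb_encoding(truth, what = c("coupling", "latent"),
                            seed = 502)
  list(
    base = stability_fit_of(truth, 1000),
    odd = stability_fit_of(truth, 1000,
                           trial_filter = function(id) id[id %% 2 == 1]),
    even = stability_fit_of(truth, 1000,
                            trial_filter = function(id) id[id %% 2 == 0]),
    h1 = stability_fit_of(truth, 1000,
                          trial_filter = function(id)
                            id[id <= stats::median(id)]),
    h2 = stability_fit_of(truth, 1000,
                          trial_filter = function(id)
                            id[id > stats::median(id)]),
    manip = stability_fit_of(manip, 3000))
})

# correlation between a true piecewise-constant tuning curve and a fitted
# one, evaluated on a common grid over the generator's variable range
tuning_recovery_cor <- function(truth, fit, neuron, variable, n_grid = 60) {
  tw <- truth$tuning[[neuron]][[variable]]
  rg <- truth$var_ranges[[variable]]
  edges <- seq(rg[1], rg[2], length.out = length(tw) + 1)
  grid <- seq(rg[1] + 0.03 * diff(rg), rg[2] - 0.03 * diff(rg),
              length.out = n_grid)
  tv <- tw[pmin(pmax(findInterval(grid, edges, rightmost.closed = TRUE), 1L),
               length(tw))]
  ft <- fit$tuning[[variable]]
  fv <- ft$weights[pmin(pmax(findInterval(grid, ft$edges,
                                          rightmost.closed = TRUE), 1L),
                        length(ft$weights))]
  if (stats::sd(tv) == 0) return(NA_real_)
  stats::cor(tv, fv)
}

# convert fitted population models back into a generative encoding, for
# simulating spikes from the fitted model
fits_to_encoding <- function(fits, truth_template) {
  truth <- truth_template
  N <- length(fits)
  for (i in seq_len(N)) {
    f <- fits[[i]]
    for (v in names(f$tuning)) {
      truth$var_ranges[[v]] <- range(f$tuning[[v]]$edges)
      truth$tuning[[i]][[v]] <- f$tuning[[v]]$weights
    }
    for (v in setdiff(names(truth$var_ranges), names(f$tuning)))
      truth$tuning[[i]][[v]] <- rep(0, length(truth$tuning[[i]][[v]]))
    truth$event[[i]]$target_on <- f$event$target_on$coef
    truth$event[[i]]$reward <- f$event$reward$coef
    truth$motor_kernel[[i]] <- list(
      motor1 = if (is.null(f$kernel$motor1)) rep(0, 10) else f$kernel$motor1$coef,
      motor2 = if (is.null(f$kernel$motor2)) rep(0, 10) else f$kernel$motor2$coef)
    truth$history[[i]] <- f$history$coef
    truth$b[i] <- f$b
  }
  truth$coupling <- list()
  for (i in seq_len(N)) {
    for (cp in fits[[i]]$coupling) {
      if (max(abs(cp$coef)) > 1e-8)
        truth$coupling[[length(truth$coupling) + 1L]] <-
          list(from = cp$from, to = i, coef = cp$coef)
    }
  }
  truth
}
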