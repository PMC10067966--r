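#' Grouped backward elimination of encoding-model predictors
#'
#' Selects the combination of predictor groups with the highest
#' cross-validated likelihood. Groups are each continuous variable (tuning
#' function or motor kernel), each event filter, the spike history, and all
#' coupling filters taken together as one group. A fraction of trials is
#' first reserved as a final test set; the remaining trials are split into
#' `n_folds` folds (each fold holds ~9% of all trials when `n_folds = 10`
#' and `test_frac = 0.1`, so selection uses 90% of the data). At each step,
#' the group whose removal yields the highest mean cross-validated
#' log-likelihood is dropped, provided the paired fold-wise change does not
#' fall more than one standard error below zero; elimination stops when no
#' group is droppable.
#'
#' @param design A [build_design()] result.
#' @param neuron Target neuron.
#' @param hp A [gam_hyperparams()].
#' @param coupled Start from the coupled model.
#' @param n_folds Cross-validation folds (trials are the sampling unit).
#' @param test_frac Fraction of trials reserved for final evaluation.
#' @param seed Optional seed for the trial partition.
#' @param max_iter,tol Solver controls (looser than final fits; the ranking
#'   of groups is insensitive to the last decimals).
#' @return List with `selected` (group names), `trace` (data frame of
#'   eliminated groups and CV log-likelihoods), `fit` (final model refit on
#'   all selection trials), `cv_loglik` (per fold, final model),
#'   `pseudo_r2_test` (on the held-out test trials).
#' @export
backward_eliminate <- function(design, neuron, hp = gam_hyperparams(),
                               coupled = TRUE, n_folds = 10,
                               test_frac = 0.1, seed = NULL,
                               max_iter = 300, tol = 1e-7) {
  trials <- unique(design$trial_id)
  if (length(trials) < 20 ||
      (1 - test_frac) * length(trials) < 2 * n_folds)
    stop("backward elimination needs at least 20 trials (folds degenerate)")
  if (!is.null(seed)) set.seed(seed)
  trials <- sample(trials)
  n_test <- max(1L, round(test_frac * length(trials)))
  test_trials <- trials[seq_len(n_test)]
  cv_trials <- trials[-seq_len(n_test)]
  fold_of <- rep(seq_len(n_folds), length.out = length(cv_trials))
  test_rows <- which(design$trial_id %in% test_trials)
  cv_rows <- which(design$trial_id %in% cv_trials)
  fold_rows <- lapply(seq_len(n_folds), function(f)
    which(design$trial_id %in% cv_trials[fold_of == f]))

  all_groups <- c(design$variables, design$kernel_variables,
                  names(design$event), "history",
                  if (coupled) "coupling")

  cv_score <- function(groups) {
    dm <- design_matrix(design, neuron, coupled = "coupling" %in% groups,
                        include_history = "history" %in% groups,
                        groups = groups, hp = hp)
    lls <- vapply(seq_len(n_folds), function(f) {
      held <- fold_rows[[f]]
      train <- setdiff(cv_rows, held)
      fit <- fit_map_core(dm$X[train, , drop = FALSE], dm$y[train], dm$P,
                          dm$l1_idx, dm$l1_weights,
                          max_iter = max_iter, tol = tol)
      mu <- exp(clamp(as.numeric(dm$X[held, , drop = FALSE] %*% fit$coef),
                      -30, 30))
      poisson_loglik(dm$y[held], mu) / length(held)
    }, numeric(1))
    list(mean = mean(lls), se = stats::sd(lls) / sqrt(n_folds), folds = lls)
  }

  current <- all_groups
  cur <- cv_score(current)
  trace <- data.frame(step = 0L, removed = NA_character_,
                      cv_loglik = cur$mean, se = cur$se,
                      stringsAsFactors = FALSE)
  step <- 0L
  while (length(current) > 0L) {
    cand <- lapply(current, function(g) cv_score(setdiff(current, g)))
    means <- vapply(cand, `[[`, numeric(1), "mean")
    best <- which.max(means)
    # droppable if the paired fold-wise change does not fall more than one
    # standard error below zero
    d <- cand[[best]]$folds - cur$folds
    if (mean(d) < -stats::sd(d) / sqrt(n_folds)) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = current[best],
                                     cv_loglik = means[best],
                                     se = cand[[best]]$se))
    current <- setdiff(current, current[best])
    cur <- cand[[best]]
    if (!length(current)) break
  }

  fit <- if (length(current)) {
    fit_gam(design, neuron, hp = hp, coupled = "coupling" %in% current,
            include_history = "history" %in% current, groups = current,
            rows = cv_rows, max_iter = max_iter * 2, tol = tol / 10)
  } else NULL
  y_test <- design$counts[test_rows, neuron]
  mu_test <- if (is.null(fit)) rep(mean(design$counts[cv_rows, neuron]),
                                   length(test_rows))
             else predict(fit, design, rows = test_rows)
  bounds <- loglik_bounds(y_test)
  pr2 <- pseudo_r2(poisson_loglik(y_test, mu_test),
                   bounds$saturated, bounds$null)
  list(selected = current, trace = trace, fit = fit,
       cv_loglik = cur$folds, pseudo_r2_test = pr2,
       test_trials = test_trials)
}

#' Held-out likelihood over a hyperparameter grid
#'
#' Refits one neuron with each value of a single hyperparameter (the others
#' held at their defaults) and scores the mean log-likelihood per bin on a
#' held-out set of trials; used to verify that the default penalty weights
#' sit in the high-likelihood region on synthetic data.
#'
#' @param design A [build_design()] result.
#' @param neuron Target neuron.
#' @param which One of `"lambda"`, `"gamma"`, `"alpha"`, `"beta"`.
#' @param values Grid of penalty values (the study searched 0.001-1000 on a
#'   log scale).
#' @param hp Baseline hyperparameters.
#' @param val_frac Held-out trial fraction.
#' @param coupled Fit the coupled model.
#' @param seed Optional seed.
#' @param ... Passed to [fit_gam()].
#' @return Data frame with `value` and `heldout_loglik` (per bin).
#' @export
hp_grid_search <- function(design, neuron, which = "lambda",
                           values = 10^seq(-3, 3), hp = gam_hyperparams(),
                           val_frac = 0.1, coupled = FALSE, seed = NULL,
                           ...) {
  if (!is.null(seed)) set.seed(seed)
  trials <- sample(unique(design$trial_id))
  n_val <- max(1L, round(val_frac * length(trials)))
  val_rows <- which(design$trial_id %in% trials[seq_len(n_val)])
  train_rows <- setdiff(seq_along(design$trial_id), val_rows)
  out <- data.frame(value = values, heldout_loglik = NA_real_)
  for (i in seq_along(values)) {
    hp_i <- hp
    hp_i[[switch(which, lambda = "lambda", gamma = "gamma",
                 alpha = "alpha", beta = "beta")]] <- values[i]
    fit <- fit_gam(design, neuron, hp = hp_i, coupled = coupled,
                   rows = train_rows, ...)
    mu <- predict(fit, design, rows = val_rows)
    out$heldout_loglik[i] <-
      poisson_loglik(design$counts[val_rows, neuron], mu) / length(val_rows)
  }
  out
}
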