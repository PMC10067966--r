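#' Regress responses against target locations
#'
#' Ordinary least-squares regression of the radial and angular coordinates of
#' the stopping location against those of the target, with the trial start as
#' the origin. An unbiased navigator has slopes near one. Slopes are reported
#' both with an intercept and through the origin.
#'
#' @param trials A `nav_trials` object, list of `nav_trial`, or a trial table
#'   (data frame with `target_r`, `target_theta`, `response_r`,
#'   `response_theta` and optionally `excluded`).
#' @return List with `slope_radial`, `slope_angular` (with intercept),
#'   `slope_radial_origin`, `slope_angular_origin` (through the origin),
#'   `r_radial`, `r_angular` (Pearson correlations) and `n` trials used.
#' @export
response_regression <- function(trials) {
  tab <- if (is.data.frame(trials)) trials else trial_table(trials)
  if (!is.null(tab$excluded)) tab <- tab[!tab$excluded, ]
  if (nrow(tab) < 3) stop("need at least 3 non-excluded trials")
  if (stats::var(tab$target_r) == 0 || stats::var(tab$target_theta) == 0)
    stop("all targets identical: regression slope undefined")
  fr <- stats::lm(response_r ~ target_r, data = tab)
  fa <- stats::lm(response_theta ~ target_theta, data = tab)
  list(slope_radial = unname(stats::coef(fr)[2]),
       slope_angular = unname(stats::coef(fa)[2]),
       slope_radial_origin =
         sum(tab$target_r * tab$response_r) / sum(tab$target_r^2),
       slope_angular_origin =
         sum(tab$target_theta * tab$response_theta) / sum(tab$target_theta^2),
       r_radial = stats::cor(tab$target_r, tab$response_r),
       r_angular = stats::cor(tab$target_theta, tab$response_theta),
       n = nrow(tab))
}

#' Psychometric curve over hypothetical reward boundaries
#'
#' For each hypothetical reward boundary on a grid over [0, 4] m, computes the
#' proportion of trials whose stopping location lies within that boundary of
#' the target ("true" curve), and the same proportion after shuffling target
#' locations across trials, which destroys the target-response relationship
#' ("shuffled" curve). The shuffle is a derangement (no trial keeps its own
#' target), so error-free responses give a strictly separated ROC. Plotting
#' true against shuffled proportions gives the behavioral ROC curve.
#'
#' @param trials As in [response_regression()]; needs Cartesian target and
#'   response columns (`target_x`, `target_y`, `response_x`, `response_y`).
#' @param boundaries Boundary grid (m); default 200 evenly spaced points on
#'   [0, 4].
#' @param n_shuffle Number of random target permutations averaged for the
#'   shuffled curve (default 1).
#' @return Object of class `psychometric_curve`: `boundaries`,
#'   `p_correct_true`, `p_correct_shuffled`, and the per-trial error vectors.
#' @export
psychometric_curve <- function(trials, boundaries = seq(0, 4, length.out = 200),
                               n_shuffle = 1) {
  tab <- if (is.data.frame(trials)) trials else trial_table(trials)
  if (!is.null(tab$excluded)) tab <- tab[!tab$excluded, ]
  n <- nrow(tab)
  if (n < 2) stop("need at least 2 trials")
  err <- sqrt((tab$response_x - tab$target_x)^2 +
              (tab$response_y - tab$target_y)^2)
  p_true <- vapply(boundaries, function(b) mean(err <= b), numeric(1))
  p_shuf <- rep(0, length(boundaries))
  err_shuf_all <- numeric(0)
  for (s in seq_len(n_shuffle)) {
    # derangement: every trial is paired with another trial's target, so the
    # shuffle destroys the target-response relationship on every trial
    perm <- sample.int(n)
    while (any(perm == seq_len(n))) perm <- sample.int(n)
    e <- sqrt((tab$response_x - tab$target_x[perm])^2 +
              (tab$response_y - tab$target_y[perm])^2)
    err_shuf_all <- c(err_shuf_all, e)
    p_shuf <- p_shuf + vapply(boundaries, function(b) mean(e <= b), numeric(1))
  }
  p_shuf <- p_shuf / n_shuffle
  structure(list(boundaries = boundaries,
                 p_correct_true = p_true,
                 p_correct_shuffled = p_shuf,
                 errors = err, errors_shuffled = err_shuf_all),
            class = "psychometric_curve")
}

#' Area under the behavioral ROC curve
#'
#' Integrates the true-correct proportion against the shuffled-correct
#' proportion across reward boundaries (trapezoidal rule). The endpoints
#' (0, 0) and (1, 1) are appended so chance-level behavior (responses
#' independent of targets) gives an AUC of 0.5 and error-free responses give
#' an AUC of 1.
#'
#' @param curve A [psychometric_curve()].
#' @return Scalar AUC in [0, 1].
#' @export
behavioral_auc <- function(curve) {
  stopifnot(inherits(curve, "psychometric_curve"))
  x <- c(0, curve$p_correct_shuffled, 1)
  y <- c(0, curve$p_correct_true, 1)
  o <- order(x, y)
  trapz(x[o], y[o])
}

#' Behavioral AUC from target/response coordinates
#'
#' Convenience wrapper: builds the psychometric curve and returns its AUC.
#'
#' @inheritParams psychometric_curve
#' @return Scalar AUC.
#' @export
behavior_auc_from_trials <- function(trials,
                                     boundaries = seq(0, 4, length.out = 200),
                                     n_shuffle = 1) {
  behavioral_auc(psychometric_curve(trials, boundaries, n_shuffle))
}
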