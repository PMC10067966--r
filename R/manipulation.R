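# evaluate a fitted piecewise-constant tuning curve at arbitrary x
eval_tuning <- function(fit, variable, x) {
  tt <- fit$tuning[[variable]]
  if (is.null(tt)) stop("variable not in fit: ", variable)
  idx <- clamp(findInterval(x, tt$edges, rightmost.closed = TRUE), 1L,
               length(tt$weights))
  tt$weights[idx]
}

#' Similarity of fitted filters or tuning between two model fits
#'
#' Pearson correlations between the components of two population fits with
#' identical neuron sets, used to quantify representation change across task
#' conditions. For `"coupling"` the reconstructed filters of every directed
#' pair are correlated; for the tuning classes the curves are evaluated on
#' the FIRST fit's (baseline) variable domain, and for `"sensory"` /
#' `"latent"` the two constituent curves (linear + angular velocity,
#' distance + angle) are concatenated per neuron; `"motor"` concatenates the
#' two motor-channel temporal kernels.
#'
#' @param fits_a,fits_b Lists of `gam_fit` over the same neurons (e.g.
#'   baseline vs manipulation fits from [fit_gam_population()]).
#' @param what One of `"coupling"`, `"sensory"`, `"latent"`, `"motor"`.
#' @param shuffle If `TRUE`, correlate randomly re-paired units (the
#'   chance-level null).
#' @param n_eval Evaluation grid size per variable.
#' @return Numeric vector of correlations (one per directed pair for
#'   coupling, one per neuron otherwise).
#' @export
filter_similarity <- function(fits_a, fits_b,
                              what = c("coupling", "sensory", "latent",
                                       "motor"),
                              shuffle = FALSE, n_eval = 50) {
  what <- match.arg(what)
  if (length(fits_a) != length(fits_b))
    stop("fits must cover the same neurons")
  n <- length(fits_a)
  if (what == "coupling") {
    pairs <- list()
    for (i in seq_len(n)) {
      for (nm in names(fits_a[[i]]$coupling)) {
        fa <- fits_a[[i]]$coupling[[nm]]$filter
        pairs[[length(pairs) + 1L]] <- list(i = i, nm = nm, fa = fa)
      }
    }
    vapply(pairs, function(pr) {
      j <- if (shuffle) sample.int(n, 1) else pr$i
      cps <- fits_b[[j]]$coupling
      nm <- if (shuffle) sample(names(cps), 1) else pr$nm
      fb <- cps[[nm]]$filter
      if (is.null(fb) || stats::sd(pr$fa) == 0 || stats::sd(fb) == 0)
        return(NA_real_)
      stats::cor(pr$fa, fb)
    }, numeric(1))
  } else {
    vars <- switch(what,
      sensory = c("linear_velocity", "angular_velocity"),
      latent = c("target_distance", "target_angle"),
      motor = c("motor1", "motor2"))
    vapply(seq_len(n), function(i) {
      j <- if (shuffle) sample.int(n, 1) else i
      if (what == "motor") {
        ca <- unlist(lapply(vars, function(v) fits_a[[i]]$kernel[[v]]$filter))
        cb <- unlist(lapply(vars, function(v) fits_b[[j]]$kernel[[v]]$filter))
      } else {
        # evaluate both fits over the baseline (fits_a) domain
        ca <- cb <- numeric(0)
        for (v in vars) {
          rg <- range(fits_a[[i]]$tuning[[v]]$edges)
          x <- seq(rg[1], rg[2], length.out = n_eval)
          ca <- c(ca, eval_tuning(fits_a[[i]], v, x))
          cb <- c(cb, eval_tuning(fits_b[[j]], v, x))
        }
      }
      if (!length(ca) || stats::sd(ca) == 0 || stats::sd(cb) == 0)
        return(NA_real_)
      stats::cor(ca, cb)
    }, numeric(1))
  }
}

#' Stability index
#'
#' SI = (rho - rho0) / (rho* - rho0), where rho is the median correlation
#' between components fit with and without the manipulation, rho* the median
#' correlation between fits to odd and even baseline trials (the noise
#' ceiling), and rho0 the median of the shuffled-pair null. 0 means the
#' match to baseline is at chance; 1 means perfectly stable. Values outside
#' [0, 1] can occur with noisy inputs and are reported unclipped.
#'
#' @param rho,rho_star,rho0 Median correlations (each in [-1, 1]), or
#'   vectors of correlations from [filter_similarity()] whose medians are
#'   taken.
#' @return Scalar SI.
#' @export
stability_index <- function(rho, rho_star, rho0) {
  m <- function(x) stats::median(x, na.rm = TRUE)
  rho <- m(rho); rho_star <- m(rho_star); rho0 <- m(rho0)
  if (abs(rho_star - rho0) < 1e-12)
    stop("stability index undefined: noise ceiling equals chance level")
  (rho - rho0) / (rho_star - rho0)
}

#' Mixed selectivity index (participation ratio)
#'
#' PR = (sum v)^2 / sum(v^2) over the variance contributions of the K task
#' variables; 1 when a single variable carries all the explained variance,
#' K when all contribute equally.
#'
#' @param v Non-negative variance contributions (length K).
#' @return Scalar in [1, K].
#' @export
mixed_selectivity_index <- function(v) {
  stopifnot(all(v >= 0))
  if (sum(v) == 0) stop("participation ratio undefined for all-zero input")
  sum(v)^2 / sum(v^2)
}

#' Task-relevant neural dimensionality by canonical correlation analysis
#'
#' Iteratively finds pairs of unit-norm directions (a_i, b_i) maximizing the
#' correlation between the projections of the task-variable block X and the
#' neural block R, each new pair constrained to be uncorrelated with the
#' previous canonical variables (implemented by residualizing both blocks
#' against them). Dimensionality D is the participation ratio of the
#' canonical covariances, 1 <= D <= P = min(ncol(X), ncol(R)).
#'
#' @param X Bins x M matrix of task variables (the study's set is linear and
#'   angular velocity, target distance and angle, and the two motor
#'   channels).
#' @param R Bins x N matrix of neural activity.
#' @param tol Relative singular-value threshold below which a block is
#'   treated as rank deficient (reduces P, with a message).
#' @return List with `a`, `b` (unit-norm direction matrices), `variates_x`,
#'   `variates_r` (the canonical variables), `correlations`, `covariances`,
#'   and `D`.
#' @export
cca_dimensionality <- function(X, R, tol = 1e-8) {
  X <- scale(as.matrix(X), scale = FALSE)
  R <- scale(as.matrix(R), scale = FALSE)
  first_pair <- function(Xr, Rr) {
    sx <- svd(Xr); sr <- svd(Rr)
    kx <- sum(sx$d > tol * sx$d[1]); kr <- sum(sr$d > tol * sr$d[1])
    if (kx == 0 || kr == 0) return(NULL)
    M <- crossprod(sx$u[, seq_len(kx), drop = FALSE],
                   sr$u[, seq_len(kr), drop = FALSE])
    sv <- svd(M)
    a <- sx$v[, seq_len(kx), drop = FALSE] %*% (sv$u[, 1] / sx$d[seq_len(kx)])
    b <- sr$v[, seq_len(kr), drop = FALSE] %*% (sv$v[, 1] / sr$d[seq_len(kr)])
    list(a = a / sqrt(sum(a^2)), b = b / sqrt(sum(b^2)), r = sv$d[1])
  }
  P_max <- min(ncol(X), ncol(R))
  rX <- sum(svd(X)$d > tol * max(svd(X)$d))
  if (rX < ncol(X))
    message(sprintf("task block rank %d < %d variables; P reduced", rX, ncol(X)))
  a_mat <- matrix(0, ncol(X), 0); b_mat <- matrix(0, ncol(R), 0)
  U <- V <- matrix(0, nrow(X), 0)
  cors <- covs <- numeric(0)
  Xr <- X; Rr <- R
  for (i in seq_len(P_max)) {
    fp <- first_pair(Xr, Rr)
    if (is.null(fp) || !is.finite(fp$r) || fp$r < tol) break
    u <- Xr %*% fp$a; v <- Rr %*% fp$b
    U <- cbind(U, u); V <- cbind(V, v)
    a_mat <- cbind(a_mat, fp$a); b_mat <- cbind(b_mat, fp$b)
    cors <- c(cors, stats::cor(u, v))
    covs <- c(covs, stats::cov(u, v))
    # residualize both blocks against the new canonical variables;
    # orthonormalizing first keeps this stable when u and v are collinear
    qu <- qr(cbind(u, v))
    Q <- qr.Q(qu)[, seq_len(qu$rank), drop = FALSE]
    Xr <- Xr - Q %*% crossprod(Q, Xr)
    Rr <- Rr - Q %*% crossprod(Q, Rr)
  }
  D <- if (length(covs)) sum(abs(covs))^2 / sum(covs^2) else NA_real_
  list(a = a_mat, b = b_mat, variates_x = U, variates_r = V,
       correlations = as.numeric(cors), covariances = as.numeric(covs),
       D = D)
}

#' Coupling strength versus electrode distance
#'
#' Bins the directed-pair coupling gains by the Euclidean distance between
#' the electrodes the two neurons were recorded from (grid pitch 400 um),
#' reporting the mean absolute log-gain separately for excitatory
#' (gain > 1) and inhibitory (gain < 1) couplings.
#'
#' @param fits List of coupled `gam_fit` (one per neuron).
#' @param electrode Data frame with columns `neuron`, `row`, `col`.
#' @param pitch_um Electrode spacing (um).
#' @return Data frame with columns `distance_um`, `n`, `mean_abs_log_gain`,
#'   `excitatory`, `inhibitory`. Neurons missing an electrode assignment are
#'   skipped and counted in `attr(, "n_skipped")`.
#' @export
coupling_vs_distance <- function(fits, electrode, pitch_um = 400) {
  pos <- electrode[match(seq_along(fits), electrode$neuron), ]
  skipped <- 0L
  rows <- list()
  for (i in seq_along(fits)) {
    for (cp in fits[[i]]$coupling) {
      j <- cp$from
      if (any(is.na(pos[c(i, j), "row"]))) { skipped <- skipped + 1L; next }
      d <- pitch_um * sqrt((pos$row[i] - pos$row[j])^2 +
                           (pos$col[i] - pos$col[j])^2)
      g <- coupling_strength(cp$filter)
      rows[[length(rows) + 1L]] <-
        data.frame(distance_um = pitch_um * round(d / pitch_um),
                   log_gain = log(g))
    }
  }
  df <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(df, df$distance_um), function(s)
    data.frame(distance_um = s$distance_um[1], n = nrow(s),
               mean_abs_log_gain = mean(abs(s$log_gain)),
               excitatory = if (any(s$log_gain > 0))
                 mean(s$log_gain[s$log_gain > 0]) else NA_real_,
               inhibitory = if (any(s$log_gain < 0))
                 mean(s$log_gain[s$log_gain < 0]) else NA_real_)))
  out <- out[order(out$distance_um), ]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}
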