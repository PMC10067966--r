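# Convolve a session-long signal with each column of a temporal basis,
# respecting trial boundaries (no leakage). `lag_bins` gives the integer lag
# (in bins) of each basis row; positive lags look into the past. Uses one FFT
# of the gap-padded signal, reused across basis columns.
session_conv <- function(z, B, lag_bins, trial_id) {
  n <- length(z)
  stopifnot(nrow(B) == length(lag_bins))
  gap <- max(abs(lag_bins)) + 1L
  starts <- which(c(TRUE, trial_id[-1] != trial_id[-n]))
  ends <- c(starts[-1] - 1L, n)
  n_tr <- length(starts)
  # position of each real bin in the padded stream
  offsets <- cumsum(c(0L, (ends - starts + 1L + gap)[-n_tr]))
  pos <- sequence(ends - starts + 1L) +
    rep(offsets + gap, ends - starts + 1L) # gap zeros before each trial too
  P <- max(pos) + gap
  P2 <- stats::nextn(P)
  zp <- numeric(P2)
  zp[pos] <- z
  Z <- stats::fft(zp)
  k0 <- min(lag_bins)
  K_len <- max(lag_bins) - k0 + 1L
  out <- matrix(0, n, ncol(B))
  for (j in seq_len(ncol(B))) {
    kern <- numeric(P2)
    kern[lag_bins - k0 + 1L] <- B[, j]
    conv <- Re(stats::fft(Z * stats::fft(kern), inverse = TRUE)) / P2
    # c[t'] = sum_lag f_lag z[t' - lag + k0]  =>  desired index t' = t - k0
    idx <- pos - k0
    vals <- numeric(length(pos))
    ok <- idx >= 1L & idx <= P2
    vals[ok] <- conv[idx[ok]]
    out[, j] <- vals
  }
  out
}

#' Hyperparameters of the MAP objective
#'
#' Penalty weights of the smoothness (squared first differences of adjacent
#' basis weights) and sparseness (L1 on coupling coefficients) priors.
#' Defaults are the values selected by cross-validation in the source study:
#' lambda = 100 for tuning functions, gamma = alpha = 10 for event and
#' spike-history filters, beta = 10 for coupling filters.
#'
#' @param lambda Tuning-function smoothness weight.
#' @param gamma Event-filter smoothness weight.
#' @param alpha Spike-history smoothness weight.
#' @param beta Coupling L1 weight.
#' @return Object of class `gam_hyperparams`.
#' @export
gam_hyperparams <- function(lambda = 100, gamma = 10, alpha = 10, beta = 10) {
  stopifnot(lambda >= 0, gamma >= 0, alpha >= 0, beta >= 0)
  structure(list(lambda = lambda, gamma = gamma, alpha = alpha, beta = beta),
            class = "gam_hyperparams")
}

#' Build the predictor expansion for the encoding model
#'
#' Expands the session's channels into the design blocks of the generalized
#' additive model: boxcar indicator columns for each continuous variable
#' (ranges set from the 1st-99th percentile over the session, so outer bins
#' are never empty), convolution of the binary event series with raised
#' cosines (causal for target onset, non-causal for reward), and convolution
#' of every neuron's spike counts with the spike-history and coupling bases.
#' The model is linear in all coefficients, so the fit is a penalized Poisson
#' GLM on this expansion. Blocks are shared across neurons; per-neuron
#' matrices are assembled by [design_matrix()].
#'
#' @param session A `nav_session` with spikes.
#' @param basis A [gam_basis()]; defaults to one at the session's `dt`.
#' @param variables Continuous variables to include (column names of
#'   `session$signals`). Variables listed in `kernel_variables` enter
#'   through non-causal temporal kernels instead of tuning functions.
#' @param events Event series to include.
#' @param kernel_variables Continuous variables fit with acausal [-300, 300]
#'   ms temporal kernels rather than tuning curves (the motor channels
#'   change phasically around movement onset/offset, which kernels capture
#'   better).
#' @param tuning_quantiles Quantiles defining each variable's boxcar range
#'   (LFP phase always uses the full circle).
#' @return Object of class `gam_design`.
#' @export
build_design <- function(session, basis = NULL,
                         variables = colnames(session$signals),
                         events = c("target_on", "reward"),
                         kernel_variables = intersect(variables,
                                                      c("motor1", "motor2")),
                         tuning_quantiles = c(0.01, 0.99)) {
  stopifnot(inherits(session, "nav_session"), !is.null(session$counts))
  if (is.null(basis)) basis <- gam_basis(session$dt)
  dt <- session$dt
  missing_vars <- setdiff(variables, colnames(session$signals))
  if (length(missing_vars))
    stop("missing channel(s) in session: ", paste(missing_vars, collapse = ", "))
  nb <- basis$n_tuning_bins
  N <- ncol(session$counts)
  tid <- session$trial_id
  kernel_variables <- intersect(kernel_variables, variables)
  tuning_vars <- setdiff(variables, kernel_variables)

  tuning <- lapply(tuning_vars, function(v) {
    x <- session$signals[, v]
    rg <- if (v == "lfp_phase") c(-180, 180)
          else as.numeric(stats::quantile(x, tuning_quantiles))
    if (diff(rg) <= 0) rg <- range(x) + c(-0.5, 0.5)
    boxcar_design(x, rg, nb)
  })
  names(tuning) <- tuning_vars

  kernels <- lapply(kernel_variables, function(v) {
    B <- basis$event_acausal
    lags <- as.integer(floor(attr(B, "lags") / dt)) + 1L
    session_conv(session$signals[, v], B, lags, tid)
  })
  names(kernels) <- kernel_variables

  event <- lapply(events, function(e) {
    z <- session$events[, e]
    B <- if (e == "target_on") basis$event_causal else basis$event_acausal
    lags <- as.integer(floor(attr(B, "lags") / dt)) + 1L
    session_conv(z, B, lags, tid)
  })
  names(event) <- events

  Lh <- nrow(basis$history); Lc <- nrow(basis$coupling)
  hist_list <- vector("list", N)
  coup_list <- vector("list", N)
  for (i in seq_len(N)) {
    zi <- session$counts[, i]
    hist_list[[i]] <- session_conv(zi, basis$history, seq_len(Lh), tid)
    coup_list[[i]] <- session_conv(zi, basis$coupling, seq_len(Lc), tid)
  }

  structure(list(tuning = tuning, kernels = kernels, event = event,
                 hist = hist_list, coup = coup_list,
                 counts = session$counts, trial_id = tid,
                 basis = basis, variables = tuning_vars,
                 kernel_variables = kernel_variables, events = events,
                 N = N, dt = dt),
            class = "gam_design")
}

# first-difference penalty matrix contribution for columns `idx`,
# optionally circular (wrap penalty between last and first weight)
add_diff_penalty <- function(P, idx, weight, circular = FALSE) {
  k <- length(idx)
  D <- diff(diag(k))
  if (circular) D <- rbind(D, c(-1, rep(0, k - 2), 1))
  P[idx, idx] <- P[idx, idx] + weight * crossprod(D)
  P
}

#' Assemble the per-neuron design matrix and penalty structure
#'
#' @param design A [build_design()] result.
#' @param neuron Target neuron index.
#' @param coupled Include coupling filters from the other neurons?
#' @param include_history Include the neuron's own spike-history filter?
#' @param groups Optional character vector restricting which predictor groups
#'   enter (used by backward elimination); defaults to all.
#' @return List with `X` (bins x p), `y` (counts), `P` (quadratic penalty
#'   matrix), `l1_idx` (columns under the L1 penalty), `l1_weight`, `groups`
#'   (named list of column indices), and bookkeeping for reconstruction.
#' @export
design_matrix <- function(design, neuron, coupled = TRUE,
                          include_history = TRUE, groups = NULL,
                          hp = gam_hyperparams()) {
  all_groups <- c(design$variables, design$kernel_variables,
                  names(design$event),
                  if (include_history) "history",
                  if (coupled) "coupling")
  if (is.null(groups)) groups <- all_groups
  blocks <- list()
  gidx <- list()
  pen <- list()
  trans <- list()
  p <- 0L
  add_block <- function(name, M, type, Z = NULL) {
    blocks[[name]] <<- M
    gidx[[name]] <<- p + seq_len(ncol(M))
    pen[[name]] <<- type
    trans[[name]] <<- Z
    p <<- p + ncol(M)
  }
  # orthonormal basis of the sum-to-zero subspace: removes the exact
  # collinearity between each boxcar partition and the intercept
  nb <- design$basis$n_tuning_bins
  Z0 <- qr.Q(qr(cbind(rep(1, nb))), complete = TRUE)[, -1, drop = FALSE]
  for (v in intersect(design$variables, groups))
    add_block(v, design$tuning[[v]] %*% Z0, "tuning", Z = Z0)
  for (kv in intersect(design$kernel_variables, groups))
    add_block(kv, design$kernels[[kv]], "kernel")
  for (e in intersect(names(design$event), groups))
    add_block(e, design$event[[e]], "event")
  if ("history" %in% groups && include_history)
    add_block("history", design$hist[[neuron]], "history")
  if ("coupling" %in% groups && coupled) {
    others <- setdiff(seq_len(design$N), neuron)
    M <- do.call(cbind, design$coup[others])
    attr(M, "sources") <- rep(others, each = ncol(design$basis$coupling))
    add_block("coupling", M, "coupling")
  }
  add_block("(intercept)", matrix(1, nrow(design$counts), 1), "none")
  X <- do.call(cbind, blocks)
  P <- matrix(0, p, p)
  for (name in names(gidx)) {
    idx <- gidx[[name]]
    if (pen[[name]] == "tuning") {
      k <- nrow(trans[[name]])
      D <- diff(diag(k))
      if (identical(name, "lfp_phase")) D <- rbind(D, c(-1, rep(0, k - 2), 1))
      DZ <- D %*% trans[[name]]
      P[idx, idx] <- P[idx, idx] + hp$lambda * crossprod(DZ)
    } else if (pen[[name]] %in% c("event", "kernel")) {
      P <- add_diff_penalty(P, idx, hp$gamma)
    } else if (pen[[name]] == "history") {
      P <- add_diff_penalty(P, idx, hp$alpha)
    }
  }
  l1_idx <- if ("coupling" %in% names(gidx)) gidx$coupling else integer(0)
  # the sparseness prior is the l1 norm of the coupling FILTER (summed over
  # its time samples), which in coefficient space is an area-weighted l1
  n_src <- length(l1_idx) / max(1L, ncol(design$basis$coupling))
  l1_w <- hp$beta * rep(colSums(design$basis$coupling), n_src)
  list(X = X, y = design$counts[, neuron], P = P,
       l1_idx = l1_idx, l1_weights = l1_w,
       groups = gidx, transforms = trans, neuron = neuron,
       coupling_sources = if ("coupling" %in% names(gidx))
         attr(blocks$coupling, "sources") else integer(0))
}
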