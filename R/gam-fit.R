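# Poisson log-likelihood of counts y under per-bin means mu
poisson_loglik <- function(y, mu, floor_mu = 1e-12) {
  mu <- pmax(mu, floor_mu)
  sum(y * log(mu) - mu - lgamma(y + 1))
}

# Accelerated proximal gradient (FISTA) on a column-scaled design, solving
# several neurons at once as a masked multi-response problem. Inputs are in
# the scaled coordinate system (X columns of comparable curvature); `scales`
# maps back to original coefficients (w = scales * w_tilde). The objective
# (Poisson negative log-likelihood + quadratic penalty + L1 on coupling
# coordinates) is convex, so the minimum is optimizer-independent.
map_fista_multi <- function(Xs, Y, Ps, scales, l1_idx, l1_weight, masks,
                            W0 = NULL, max_iter = 500, tol = 1e-9,
                            cap = 30, ridge = 1e-8) {
  n <- nrow(Xs); p <- ncol(Xs); k <- ncol(Y)
  ridge_s2 <- ridge * scales^2
  l1_w <- l1_weight * scales[l1_idx]          # per-coordinate L1 weights
  mean_y <- colMeans(Y)
  W <- if (is.null(W0)) matrix(0, p, k) else W0
  if (is.null(W0)) W[p, ] <- log(pmax(mean_y, 1e-4)) / scales[p]
  for (j in seq_len(k)) W[masks[[j]], j] <- 0

  eta_mu <- function(Wm, cols) {
    ETA <- Xs %*% Wm
    ETA[ETA > cap] <- cap; ETA[ETA < -cap] <- -cap
    list(eta = ETA, mu = exp(ETA))
  }
  smooth_f <- function(Wm, em, cols) {
    quad <- colSums(Wm * (Ps %*% Wm)) + colSums(ridge_s2 * Wm^2)
    colSums(em$mu) - colSums(Y[, cols, drop = FALSE] * em$eta) + quad
  }
  l1_f <- function(Wm) colSums(l1_w * abs(Wm[l1_idx, , drop = FALSE]))
  prox <- function(Wm, step) {
    Wl <- Wm[l1_idx, , drop = FALSE]
    thr <- outer(l1_w, step)
    Wm[l1_idx, ] <- sign(Wl) * pmax(abs(Wl) - thr, 0)
    Wm
  }

  act <- seq_len(k)
  L <- rep(2, k); Tm <- rep(1, k); stall <- integer(k)
  iters <- integer(k); conv <- logical(k)
  Z <- W
  em <- eta_mu(W[, act, drop = FALSE], act)
  F_prev <- smooth_f(W[, act, drop = FALSE], em, act) + l1_f(W[, act, drop = FALSE])
  F_all <- numeric(k); F_all[act] <- F_prev

  for (it in seq_len(max_iter)) {
    if (!length(act)) break
    Za <- Z[, act, drop = FALSE]
    em <- eta_mu(Za, act)
    G <- crossprod(Xs, em$mu - Y[, act, drop = FALSE]) +
      2 * (Ps %*% Za) + 2 * ridge_s2 * Za
    for (jj in seq_along(act)) G[masks[[act[jj]]], jj] <- 0
    f_z <- smooth_f(Za, em, act)
    La <- L[act]
    todo <- seq_along(act)
    Wc <- Za; f_c <- f_z
    for (bt in 1:30) {
      cand <- Za[, todo, drop = FALSE] -
        sweep(G[, todo, drop = FALSE], 2, La[todo], "/")
      cand <- prox(cand, 1 / La[todo])
      Wc[, todo] <- cand
      emc <- eta_mu(cand, act[todo])
      f_c[todo] <- smooth_f(cand, emc, act[todo])
      dW <- cand - Za[, todo, drop = FALSE]
      ok <- f_c[todo] <= f_z[todo] + colSums(G[, todo, drop = FALSE] * dW) +
        La[todo] / 2 * colSums(dW^2) + 1e-10
      if (all(ok)) break
      todo <- todo[!ok]
      La[todo] <- La[todo] * 2
    }
    L[act] <- La
    F_c <- f_c + l1_f(Wc)
    F_old <- F_all[act]
    done <- logical(length(act))
    for (jj in seq_along(act)) {
      j <- act[jj]
      if (F_c[jj] > F_old[jj]) {          # adaptive restart
        Z[, j] <- W[, j]; Tm[j] <- 1
      } else {
        t_new <- (1 + sqrt(1 + 4 * Tm[j]^2)) / 2
        Z[, j] <- Wc[, jj] + ((Tm[j] - 1) / t_new) * (Wc[, jj] - W[, j])
        Tm[j] <- t_new
        W[, j] <- Wc[, jj]
        rel <- abs(F_old[jj] - F_c[jj]) / max(1, abs(F_c[jj]))
        F_all[j] <- F_c[jj]
        if (rel < tol) {
          stall[j] <- stall[j] + 1L
          if (stall[j] >= 3L) { conv[j] <- TRUE; done[jj] <- TRUE }
        } else stall[j] <- 0L
      }
      iters[j] <- it
    }
    L[act] <- pmax(L[act] * 0.9, 1e-8)
    act <- act[!done]
  }
  Worig <- W * scales
  list(coef = Worig, coef_scaled = W, objective = F_all,
       n_iter = iters, converged = conv)
}

#' MAP estimation of the penalized Poisson objective (single neuron)
#'
#' Minimizes the Poisson negative log-likelihood plus the smoothness
#' penalties (squared first differences of adjacent basis weights, encoded
#' in the quadratic form `P`) and the L1 penalty on coupling coefficients.
#' The problem is convex and is solved by diagonally preconditioned
#' accelerated proximal gradient descent with backtracking and adaptive
#' restart, so the result is optimizer-independent up to the stated
#' tolerance. A tiny ridge (1e-8) removes the flat directions shared by the
#' boxcar partitions and the intercept.
#'
#' @param X Design matrix (bins x p); the intercept must be the last column.
#' @param y Spike counts per bin.
#' @param P Quadratic penalty matrix (p x p).
#' @param l1_idx Columns under the L1 penalty.
#' @param l1_weight L1 weight: either the scalar beta, or a per-coordinate
#'   weight vector (e.g. beta times each basis function's area, implementing
#'   the l1 norm of the reconstructed filter).
#' @param w0 Optional warm-start coefficients (original scale).
#' @param max_iter,tol Iteration cap and relative objective tolerance.
#' @param log_rate_cap Cap on the linear predictor (numerical guard).
#' @return List with `coef`, `objective`, `n_iter`, `converged`.
#' @export
fit_map_core <- function(X, y, P, l1_idx = integer(0), l1_weight = 0,
                         w0 = NULL, max_iter = 1000, tol = 1e-10,
                         log_rate_cap = 30) {
  mu_bar <- max(mean(y), 1e-4)
  q <- mu_bar * colSums(X^2) + 2 * diag(P) + 1e-8
  s <- 1 / sqrt(q)
  Xs <- X * rep(s, each = nrow(X))
  Ps <- P * outer(s, s)
  W0 <- if (is.null(w0)) NULL else matrix(w0 / s, ncol = 1)
  res <- map_fista_multi(Xs, matrix(y, ncol = 1), Ps, s, l1_idx, l1_weight,
                         masks = list(integer(0)), W0 = W0,
                         max_iter = max_iter, tol = tol, cap = log_rate_cap)
  if (!res$converged[1] && max_iter >= 200)
    warning(sprintf("MAP fit not fully converged in %d iterations (objective %.6g)",
                    max_iter, res$objective[1]))
  list(coef = as.numeric(res$coef), objective = res$objective[1],
       n_iter = res$n_iter[1], converged = res$converged[1])
}

# reconstruct a gam_fit object from a coefficient vector laid out as in
# design_matrix(): tuning blocks (sum-zero basis), events, history,
# coupling, intercept
make_gam_fit <- function(design, neuron, w, dm, hp, coupled, objective,
                         n_iter, converged) {
  tuning <- list()
  for (v in intersect(design$variables, names(dm$groups))) {
    Z <- dm$transforms[[v]]
    tuning[[v]] <- list(weights = as.numeric(Z %*% w[dm$groups[[v]]]),
                        edges = attr(design$tuning[[v]], "edges"),
                        centers = attr(design$tuning[[v]], "centers"))
  }
  event <- list()
  for (e in intersect(names(design$event), names(dm$groups))) {
    B <- if (e == "target_on") design$basis$event_causal
         else design$basis$event_acausal
    event[[e]] <- list(coef = w[dm$groups[[e]]],
                       filter = as.numeric(B %*% w[dm$groups[[e]]]),
                       lags = attr(B, "lags"))
  }
  kernel <- list()
  for (kv in intersect(design$kernel_variables, names(dm$groups))) {
    B <- design$basis$event_acausal
    kernel[[kv]] <- list(coef = w[dm$groups[[kv]]],
                         filter = as.numeric(B %*% w[dm$groups[[kv]]]),
                         lags = attr(B, "lags"))
  }
  history <- NULL
  if ("history" %in% names(dm$groups)) {
    B <- design$basis$history
    history <- list(coef = w[dm$groups$history],
                    filter = as.numeric(B %*% w[dm$groups$history]),
                    lags = attr(B, "lags"))
  }
  coupling <- NULL
  if ("coupling" %in% names(dm$groups)) {
    B <- design$basis$coupling
    src <- dm$coupling_sources
    coupling <- lapply(unique(src), function(j) {
      cj <- w[dm$groups$coupling[src == j]]
      list(from = j, coef = cj, filter = as.numeric(B %*% cj),
           lags = attr(B, "lags"))
    })
    names(coupling) <- as.character(unique(src))
  }
  structure(list(neuron = neuron, coef = w, groups = dm$groups,
                 transforms = dm$transforms,
                 tuning = tuning, event = event, kernel = kernel,
                 history = history, coupling = coupling,
                 b = unname(w[dm$groups[["(intercept)"]]]),
                 hp = hp, coupled = coupled,
                 objective = objective, n_iter = n_iter,
                 converged = converged, dt = design$dt),
            class = "gam_fit")
}

#' Fit the encoding model for one neuron
#'
#' Assembles the per-neuron design (via [design_matrix()]) and runs the MAP
#' fit with the given hyperparameters, returning an object that carries the
#' fitted tuning functions, temporal filters, coupling filters and baseline.
#'
#' @param design A [build_design()] result.
#' @param neuron Target neuron index.
#' @param hp A [gam_hyperparams()].
#' @param coupled Include coupling filters (the coupled model of the study);
#'   `FALSE` gives the uncoupled model (tuning, events and spike history
#'   only).
#' @param include_history Include the spike-history filter.
#' @param groups Optional restriction of predictor groups.
#' @param rows Optional row (bin) subset, e.g. the training bins of a
#'   cross-validation fold.
#' @param w0 Optional warm start.
#' @param ... Passed to [fit_map_core()].
#' @return Object of class `gam_fit`.
#' @export
fit_gam <- function(design, neuron, hp = gam_hyperparams(), coupled = TRUE,
                    include_history = TRUE, groups = NULL, rows = NULL,
                    w0 = NULL, ...) {
  dm <- design_matrix(design, neuron, coupled = coupled,
                      include_history = include_history, groups = groups,
                      hp = hp)
  X <- dm$X; y <- dm$y
  if (!is.null(rows)) { X <- X[rows, , drop = FALSE]; y <- y[rows] }
  fit <- fit_map_core(X, y, dm$P, dm$l1_idx, dm$l1_weights, w0 = w0, ...)
  make_gam_fit(design, neuron, fit$coef, dm, hp, coupled,
               fit$objective, fit$n_iter, fit$converged)
}

#' Fit the encoding model for a whole population at once
#'
#' Solves the per-neuron MAP problems jointly as a masked multi-response
#' problem sharing one design matrix (tuning and event blocks are common to
#' all neurons; each neuron sees its own spike-history block and the other
#' neurons' coupling blocks). Mathematically identical to calling
#' [fit_gam()] per neuron, but substantially faster because every gradient
#' step is a single matrix-matrix product.
#'
#' @param design A [build_design()] result.
#' @param neurons Neuron indices to fit (default all).
#' @param hp A [gam_hyperparams()].
#' @param coupled Coupled or uncoupled model.
#' @param rows Optional row (bin) subset to fit on, e.g. the training bins
#'   of a held-out evaluation split.
#' @param screen For coupled fits, first solve the uncoupled problem, then
#'   include only the coupling coordinates whose likelihood gradient at
#'   that solution approaches the L1 threshold (margin
#'   `screen_margin`), and verify the discarded coordinates against the
#'   optimality conditions afterwards, re-solving with any violators added
#'   back. This is exact up to the KKT tolerance and much faster, because
#'   under the sparseness prior most coupling coordinates are zero at the
#'   optimum.
#' @param screen_margin Screening margin (fraction of the L1 threshold).
#' @param max_iter,tol Solver controls.
#' @return List of `gam_fit` objects (one per requested neuron).
#' @export
fit_gam_population <- function(design, neurons = seq_len(design$N),
                               hp = gam_hyperparams(), coupled = TRUE,
                               rows = NULL, screen = TRUE,
                               screen_margin = 0.85,
                               max_iter = 400, tol = 1e-9) {
  if (is.null(rows)) rows <- seq_len(nrow(design$counts))
  if (coupled && screen)
    return(fit_gam_population_screened(design, neurons, hp, rows,
                                       screen_margin, max_iter, tol))
  sources <- if (coupled) seq_len(design$N) else integer(0)
  allowed <- lapply(neurons, function(i) setdiff(sources, i))
  sol <- pop_solve(design, neurons, hp, rows, sources, allowed,
                   max_iter, tol)
  if (!all(sol$res$converged))
    warning(sprintf("%d of %d population fits not fully converged",
                    sum(!sol$res$converged), length(neurons)))
  pop_repackage(design, neurons, hp, coupled, sol)
}

# core joint solve over a chosen set of coupling source blocks;
# `allowed[[jj]]` lists the coupling sources neuron `neurons[jj]` may use
pop_solve <- function(design, neurons, hp, rows, sources, allowed,
                      max_iter, tol, W0_orig = NULL) {
  N <- design$N
  n <- length(rows)
  nbz <- ncol(design$tuning[[1]]) - 1L   # sum-zero tuning block width
  Z0 <- qr.Q(qr(cbind(rep(1, nbz + 1L))), complete = TRUE)[, -1, drop = FALSE]
  blocks <- list()
  meta <- list()
  for (v in design$variables) {
    blocks[[length(blocks) + 1L]] <- design$tuning[[v]] %*% Z0
    meta[[length(meta) + 1L]] <- list(name = v, type = "tuning")
  }
  for (kv in design$kernel_variables) {
    blocks[[length(blocks) + 1L]] <- design$kernels[[kv]]
    meta[[length(meta) + 1L]] <- list(name = kv, type = "kernel")
  }
  for (e in names(design$event)) {
    blocks[[length(blocks) + 1L]] <- design$event[[e]]
    meta[[length(meta) + 1L]] <- list(name = e, type = "event")
  }
  for (i in seq_len(N)) {
    blocks[[length(blocks) + 1L]] <- design$hist[[i]]
    meta[[length(meta) + 1L]] <- list(name = paste0("hist", i),
                                      type = "history", neuron = i)
  }
  for (i in sources) {
    blocks[[length(blocks) + 1L]] <- design$coup[[i]]
    meta[[length(meta) + 1L]] <- list(name = paste0("coup", i),
                                      type = "coupling", neuron = i)
  }
  blocks[[length(blocks) + 1L]] <- matrix(1, nrow(design$counts), 1)
  meta[[length(meta) + 1L]] <- list(name = "(intercept)", type = "none")

  widths <- vapply(blocks, ncol, integer(1))
  p <- sum(widths)
  col_end <- cumsum(widths)
  col_idx <- lapply(seq_along(blocks), function(b)
    (col_end[b] - widths[b] + 1L):col_end[b])
  X <- matrix(0, n, p)
  for (b in seq_along(blocks))
    X[, col_idx[[b]]] <- blocks[[b]][rows, , drop = FALSE]
  rm(blocks)

  P <- matrix(0, p, p)
  l1_idx <- integer(0)
  for (b in seq_along(meta)) {
    idx <- col_idx[[b]]
    tp <- meta[[b]]$type
    if (tp == "tuning") {
      k <- nrow(Z0)
      D <- diff(diag(k))
      if (identical(meta[[b]]$name, "lfp_phase"))
        D <- rbind(D, c(-1, rep(0, k - 2), 1))
      DZ <- D %*% Z0
      P[idx, idx] <- P[idx, idx] + hp$lambda * crossprod(DZ)
    } else if (tp %in% c("event", "kernel")) {
      P <- add_diff_penalty(P, idx, hp$gamma)
    } else if (tp == "history") {
      P <- add_diff_penalty(P, idx, hp$alpha)
    } else if (tp == "coupling") {
      l1_idx <- c(l1_idx, idx)
    }
  }

  Y <- design$counts[rows, neurons, drop = FALSE]
  mu_bar <- max(mean(Y), 1e-4)
  q <- mu_bar * colSums(X^2) + 2 * diag(P) + 1e-8
  s <- 1 / sqrt(q)
  for (j in seq_len(p)) X[, j] <- X[, j] * s[j]
  Ps <- P * outer(s, s)

  types <- vapply(meta, `[[`, character(1), "type")
  block_neuron <- vapply(meta, function(m)
    if (is.null(m$neuron)) NA_integer_ else m$neuron, integer(1))
  masks <- lapply(seq_along(neurons), function(jj) {
    i <- neurons[jj]
    drop_b <- which((types == "history" & block_neuron != i) |
                    (types == "coupling" &
                     !(block_neuron %in% allowed[[jj]])))
    unlist(col_idx[drop_b])
  })

  l1_w <- hp$beta * rep(colSums(design$basis$coupling),
                        length(l1_idx) / max(1L, ncol(design$basis$coupling)))
  W0 <- if (is.null(W0_orig)) NULL else W0_orig / s
  res <- map_fista_multi(X, Y, Ps, s, l1_idx, l1_w, masks, W0 = W0,
                         max_iter = max_iter, tol = tol)
  ETA <- X %*% res$coef_scaled
  ETA[ETA > 30] <- 30; ETA[ETA < -30] <- -30
  list(res = res, meta = meta, col_idx = col_idx, types = types,
       block_neuron = block_neuron, p = p, Z0 = Z0, s = s,
       MU = exp(ETA), Y = Y, sources = sources, allowed = allowed)
}

# map a joint solution back into per-neuron gam_fit objects; coupling
# sources absent from the solve carry exact zeros
pop_repackage <- function(design, neurons, hp, coupled, sol) {
  N <- design$N
  nc <- ncol(design$basis$coupling)
  fits <- vector("list", length(neurons))
  for (jj in seq_along(neurons)) {
    i <- neurons[jj]
    wj <- sol$res$coef[, jj]
    dm <- list(groups = list(), transforms = list(),
               coupling_sources = integer(0))
    w_local <- numeric(0)
    add <- function(name, vals, Z = NULL) {
      dm$groups[[name]] <<- length(w_local) + seq_along(vals)
      dm$transforms[[name]] <<- Z
      w_local <<- c(w_local, vals)
    }
    for (b in seq_along(sol$meta)) {
      m <- sol$meta[[b]]
      if (m$type == "tuning") add(m$name, wj[sol$col_idx[[b]]], Z = sol$Z0)
      else if (m$type %in% c("kernel", "event"))
        add(m$name, wj[sol$col_idx[[b]]])
      else if (m$type == "history" && identical(m$neuron, i))
        add("history", wj[sol$col_idx[[b]]])
    }
    if (coupled) {
      others <- setdiff(seq_len(N), i)
      cw <- unlist(lapply(others, function(o) {
        b <- which(sol$types == "coupling" & sol$block_neuron == o)
        if (length(b)) wj[sol$col_idx[[b]]] else rep(0, nc)
      }))
      dm$groups$coupling <- length(w_local) + seq_along(cw)
      dm$coupling_sources <- rep(others, each = nc)
      w_local <- c(w_local, cw)
    }
    add("(intercept)", wj[sol$p])
    fits[[jj]] <- make_gam_fit(design, i, w_local, dm, hp, coupled,
                               sol$res$objective[jj], sol$res$n_iter[jj],
                               sol$res$converged[jj])
  }
  names(fits) <- as.character(neurons)
  fits
}

# gradient of the Poisson likelihood over coupling coordinates at a given
# solution: one (basis x neurons) matrix per source block
coupling_gradients <- function(design, rows, MU, Y) {
  resid <- MU - Y
  lapply(seq_len(design$N), function(j)
    crossprod(design$coup[[j]][rows, , drop = FALSE], resid))
}

# two-phase screened coupled solve (see fit_gam_population)
fit_gam_population_screened <- function(design, neurons, hp, rows,
                                        screen_margin, max_iter, tol) {
  N <- design$N
  nc <- ncol(design$basis$coupling)
  l1_w <- hp$beta * colSums(design$basis$coupling)

  # phase 1: uncoupled solve (a warm start and screening point; moderate
  # accuracy suffices)
  sol0 <- pop_solve(design, neurons, hp, rows, integer(0),
                    lapply(neurons, function(i) integer(0)),
                    min(max_iter, 150L), max(tol, 1e-8))
  G <- coupling_gradients(design, rows, sol0$MU, sol0$Y)
  allowed <- lapply(seq_along(neurons), function(jj) {
    i <- neurons[jj]
    cand <- vapply(seq_len(N), function(j) {
      if (j == i) return(FALSE)
      any(abs(G[[j]][, jj]) > screen_margin * l1_w)
    }, logical(1))
    which(cand)
  })

  # warm start mapped by block name into the phase-2 layout
  build_w0 <- function(sol_from, meta_to, col_idx_to, p_to) {
    W0 <- matrix(0, p_to, ncol(sol_from$res$coef))
    names_from <- vapply(sol_from$meta, `[[`, character(1), "name")
    for (b in seq_along(meta_to)) {
      bf <- match(meta_to[[b]]$name, names_from)
      if (!is.na(bf))
        W0[col_idx_to[[b]], ] <- sol_from$res$coef[sol_from$col_idx[[bf]], ]
    }
    W0
  }

  for (round in 1:3) {
    sources <- sort(unique(unlist(allowed)))
    if (!length(sources)) { sol <- sol0; break }
    # probe layout to map the warm start
    probe <- pop_layout_probe(design, sources)
    W0 <- build_w0(sol0, probe$meta, probe$col_idx, probe$p)
    sol <- pop_solve(design, neurons, hp, rows, sources, allowed,
                     max_iter, tol, W0_orig = W0)
    # KKT check on every screened-out coupling coordinate
    G <- coupling_gradients(design, rows, sol$MU, sol$Y)
    viol <- FALSE
    for (jj in seq_along(neurons)) {
      i <- neurons[jj]
      for (j in setdiff(seq_len(N), c(i, allowed[[jj]]))) {
        if (any(abs(G[[j]][, jj]) > l1_w * (1 + 1e-4))) {
          allowed[[jj]] <- sort(c(allowed[[jj]], j))
          viol <- TRUE
        }
      }
    }
    if (!viol) break
  }
  if (!all(sol$res$converged))
    warning(sprintf("%d of %d population fits not fully converged",
                    sum(!sol$res$converged), length(neurons)))
  pop_repackage(design, neurons, hp, TRUE, sol)
}

# column layout (without building the design matrix) for a given source set
pop_layout_probe <- function(design, sources) {
  nbz <- ncol(design$tuning[[1]]) - 1L
  meta <- list(); widths <- integer(0)
  push <- function(name, type, w, neuron = NULL) {
    meta[[length(meta) + 1L]] <<- list(name = name, type = type,
                                       neuron = neuron)
    widths <<- c(widths, w)
  }
  for (v in design$variables) push(v, "tuning", nbz)
  for (kv in design$kernel_variables)
    push(kv, "kernel", ncol(design$kernels[[kv]]))
  for (e in names(design$event)) push(e, "event", ncol(design$event[[e]]))
  for (i in seq_len(design$N))
    push(paste0("hist", i), "history", ncol(design$hist[[i]]), i)
  for (i in sources)
    push(paste0("coup", i), "coupling", ncol(design$coup[[i]]), i)
  push("(intercept)", "none", 1L)
  col_end <- cumsum(widths)
  col_idx <- lapply(seq_along(widths), function(b)
    (col_end[b] - widths[b] + 1L):col_end[b])
  list(meta = meta, col_idx = col_idx, p = sum(widths))
}

#' @export
print.gam_fit <- function(x, ...) {
  cat(sprintf("gam_fit: neuron %d, %s model, %d coefficients, baseline %.1f Hz\n",
              x$neuron, if (x$coupled) "coupled" else "uncoupled",
              length(x$coef), exp(x$b) / x$dt))
  cat(sprintf("  groups: %s\n",
              paste(setdiff(names(x$groups), "(intercept)"), collapse = ", ")))
  invisible(x)
}

#' Predicted per-bin Poisson means for a fitted neuron
#'
#' @param object A `gam_fit`.
#' @param design The [build_design()] the fit came from (or a compatible one).
#' @param rows Optional row subset.
#' @param ... Unused.
#' @return Numeric vector of expected counts per bin.
#' @export
predict.gam_fit <- function(object, design, rows = NULL, ...) {
  dm <- design_matrix(design, object$neuron, coupled = object$coupled,
                      include_history = !is.null(object$history),
                      groups = names(object$groups), hp = object$hp)
  X <- dm$X
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  exp(clamp(as.numeric(X %*% object$coef), -30, 30))
}

#' Likelihood-based variance explained (pseudo-R2)
#'
#' 1 - (L_sat - L_model) / (L_sat - L_null), where the saturated model sets
#' each bin's mean to the observed count and the null model to a constant
#' rate.
#'
#' @param l_model,l_saturated,l_null Log-likelihoods.
#' @return Scalar pseudo-R2 (1 for a saturated fit, 0 for the null).
#' @export
pseudo_r2 <- function(l_model, l_saturated, l_null) {
  if (abs(l_saturated - l_null) < 1e-12)
    stop("pseudo-R2 undefined: saturated and null likelihoods coincide")
  1 - (l_saturated - l_model) / (l_saturated - l_null)
}

# saturated and null Poisson log-likelihoods for counts y
loglik_bounds <- function(y) {
  mu_sat <- pmax(y, 1e-12)
  list(saturated = sum(y * log(mu_sat) - y - lgamma(y + 1)),
       null = poisson_loglik(y, rep(mean(y), length(y))))
}

#' Gaussian-smoothed firing rates from binned counts
#'
#' @param counts Bins x neurons count matrix (or vector).
#' @param dt Bin width (s).
#' @param sigma Gaussian kernel sd (s), default 60 ms.
#' @return Rates in Hz, same shape as `counts`.
#' @export
smooth_counts_gaussian <- function(counts, dt, sigma = 0.06) {
  counts <- as.matrix(counts)
  half <- ceiling(4 * sigma / dt)
  k <- stats::dnorm(seq(-half, half) * dt, sd = sigma)
  k <- k / sum(k)
  apply(counts, 2, function(yc) {
    n <- length(yc)
    padded <- c(rep(0, half), yc, rep(0, half))
    as.numeric(stats::filter(padded, k, sides = 2))[half + seq_len(n)] / dt
  })
}

#' Coefficient-of-determination variance explained
#'
#' Per-neuron R2 = 1 - Var(predicted - observed) / Var(observed) between
#' model rates and Gaussian-smoothed (60 ms) observed rates, plus the
#' population version that pools the variance sums across neurons (weighting
#' neurons with larger intrinsic variability more).
#'
#' @param pred Bins x neurons matrix of predicted rates (Hz).
#' @param obs Bins x neurons matrix of observed rates (Hz), e.g. from
#'   [smooth_counts_gaussian()].
#' @return List with `r2` (per neuron; `NA` for zero-variance neurons, which
#'   are excluded from pooling) and `r2_pop`.
#' @export
variance_explained <- function(pred, obs) {
  pred <- as.matrix(pred); obs <- as.matrix(obs)
  stopifnot(all(dim(pred) == dim(obs)))
  v_err <- apply(pred - obs, 2, stats::var)
  v_obs <- apply(obs, 2, stats::var)
  ok <- v_obs > 0
  r2 <- ifelse(ok, 1 - v_err / v_obs, NA_real_)
  list(r2 = r2, r2_pop = 1 - sum(v_err[ok]) / sum(v_obs[ok]))
}

#' Marginal tuning curve of a fitted neuron
#'
#' Expected firing rate as a function of one continuous variable, with the
#' other variables integrated out against their empirical marginals: exp of
#' the variable's tuning function, times the marginal expectation of exp of
#' every other tuning function, times the time-averaged event-filter gain,
#' times exp of the baseline. Spike-history and coupling gains are treated
#' as unity (their multiplicative modulation of the mean rate is close to
#' one).
#'
#' @param fit A `gam_fit`.
#' @param variable Variable name (must be in the fit).
#' @param design The [build_design()] providing empirical marginals.
#' @return List with `x` (bin centers), `rate` (Hz).
#' @export
marginal_tuning <- function(fit, variable, design) {
  if (!variable %in% names(fit$tuning))
    stop("variable not in model: ", variable)
  gain_other <- 1
  for (v in setdiff(names(fit$tuning), variable)) {
    occ <- colMeans(design$tuning[[v]])      # empirical marginal P(x_j)
    gain_other <- gain_other * sum(occ * exp(fit$tuning[[v]]$weights))
  }
  for (e in names(fit$event)) {
    conv <- design$event[[e]] %*% fit$event[[e]]$coef
    gain_other <- gain_other * mean(exp(conv))
  }
  for (kv in names(fit$kernel)) {
    conv <- design$kernels[[kv]] %*% fit$kernel[[kv]]$coef
    gain_other <- gain_other * mean(exp(conv))
  }
  tt <- fit$tuning[[variable]]
  list(x = tt$centers,
       rate = exp(tt$weights) * gain_other * exp(fit$b) / fit$dt)
}

#' Coupling (or spike-history) filter strength
#'
#' The multiplicative gain of a filter: the time-average of the exponentiated
#' filter over its support. A null filter has strength exactly 1; greater
#' than 1 is net excitatory, less than 1 net inhibitory.
#'
#' @param filter Filter values at bin resolution (log-rate units).
#' @return Scalar gain.
#' @export
coupling_strength <- function(filter) mean(exp(filter))

#' Re-express a coupling filter on the seven-exponential basis
#'
#' Least-squares refit of a reconstructed filter as a weighted sum of seven
#' exponentials (decay constants 6-384 ms), plus a power-law fit of the
#' weight magnitudes against the decay constants in log-log coordinates.
#'
#' @param filter Filter values sampled at `dt` over the coupling support.
#' @param dt Bin width (s).
#' @return List with `weights` (named by decay constant), `decay_ms`, and
#'   `power_law_exponent` (slope of log|w| vs log tau).
#' @export
refit_exponential_basis <- function(filter, dt) {
  B <- exp_basis(c(0, length(filter) * dt), dt)
  wts <- as.numeric(stats::lm.fit(B, filter)$coefficients)
  names(wts) <- colnames(B)
  decay <- attr(B, "decay_ms")
  mag <- abs(wts)
  ok <- mag > 1e-12
  slope <- if (sum(ok) >= 2)
    unname(stats::coef(stats::lm(log(mag[ok]) ~ log(decay[ok])))[2])
  else NA_real_
  list(weights = wts, decay_ms = decay, power_law_exponent = slope)
}
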