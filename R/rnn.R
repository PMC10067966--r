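#' Configuration of the closed-loop recurrent network
#'
#' A fully connected rate network of `n` tanh units receives a transient
#' two-channel pulse encoding the 2D target location and two feedback
#' channels carrying its own self-motion velocity. Its two outputs encode
#' acceleration of the 'hand': they are integrated once (plus process
#' noise) to velocity, which is fed back with sensory noise, and again to
#' 2D position. The network is trained to reach the target within the
#' deadline t* (circular-trajectory travel time at maximum speed) and stay
#' there.
#'
#' @param n Number of units (100).
#' @param n_in Input channels (4: 2 target pulse + 2 velocity feedback).
#' @param n_out Output channels (2).
#' @param tau Unit time constant (s).
#' @param dt Integration step (s); tau/2 by default.
#' @param pulse_duration Target pulse duration (s).
#' @param hold Required stopping period appended to the deadline (s).
#' @param trial_range Admissible trial durations (s); actual duration is
#'   t* + hold + margin clipped to this range.
#' @param v_max Maximum linear speed of the task (m/s), used for t* and for
#'   input scaling.
#' @param target_scale Divisor mapping target coordinates (m) to pulse
#'   amplitudes in [-1, 1].
#' @param process_noise_sd Process (motor) noise added to the velocity
#'   increments, in m/s per sqrt(s).
#' @param sensory_noise_sd Noise on the velocity feedback channels (m/s).
#' @param metabolic Length-4 non-negative weights penalizing ||y||^2,
#'   ||dy/dt||^2, ||r||^2, ||dr/dt||^2 (0 in the base variant).
#' @return Object of class `rnn_config`.
#' @export
rnn_config <- function(n = 100, n_in = 4, n_out = 2, tau = 0.020, dt = 0.010,
                       pulse_duration = 0.3, hold = 0.6,
                       trial_range = c(2, 3), v_max = 2, target_scale = 4,
                       process_noise_sd = 0.1, sensory_noise_sd = 0.05,
                       metabolic = c(0, 0, 0, 0)) {
  stopifnot(dt < tau, n > 0, n_in >= 4, n_out >= 2, all(metabolic >= 0))
  structure(as.list(environment()), class = "rnn_config")
}

#' Initialize network parameters
#'
#' @param config An [rnn_config()].
#' @param g_rec Spectral scale of the recurrent weights.
#' @param seed Optional seed.
#' @return Object of class `rnn_params` with `W_rec` (n x n), `W_in`
#'   (n x n_in), `W_out` (n_out x n).
#' @export
rnn_init <- function(config = rnn_config(), g_rec = 1.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  structure(list(
    W_rec = matrix(stats::rnorm(n * n, 0, g_rec / sqrt(n)), n, n),
    W_in = matrix(stats::rnorm(n * config$n_in, 0, 1 / sqrt(config$n_in)),
                  n, config$n_in),
    W_out = matrix(stats::rnorm(config$n_out * n, 0, 0.4 / sqrt(n)),
                   config$n_out, n)
  ), class = "rnn_params")
}

#' Deadline for a target: idealized circular-trajectory travel time
#'
#' The deadline t* is the arc length of the circle that starts at the
#' origin tangent to the straight-ahead direction and passes through the
#' target, divided by the maximum linear speed. A straight-ahead target at
#' distance d gives arc d; a target at bearing psi gives arc
#' d psi / sin(psi).
#'
#' @param target Numeric `c(x, y)` in meters (heading 0 along +y).
#' @param config An [rnn_config()] (provides `v_max`).
#' @return t* in seconds (0 for a target at the origin).
#' @export
compute_deadline <- function(target, config = rnn_config()) {
  d <- sqrt(sum(target^2))
  if (d == 0) return(0)
  psi <- abs(atan2(target[1], target[2]))
  arc <- if (psi < 1e-9) d else d * psi / sin(psi)
  arc / config$v_max
}

# batched forward pass; targets is a 2 x B matrix (meters). Returns the
# recorded tensors needed for BPTT when `record = TRUE`.
rnn_forward <- function(params, config, targets, noise = TRUE,
                        manipulation = NULL, record = FALSE) {
  B <- ncol(targets)
  n <- config$n; dt <- config$dt; a <- dt / config$tau
  gain <- 1; extra_sens <- 0; perturb <- NULL
  if (!is.null(manipulation)) {
    if (manipulation$type == "gain") gain <- manipulation$value
    if (manipulation$type == "sensory_noise") extra_sens <- manipulation$value
    if (manipulation$type == "perturbation") perturb <- manipulation
  }
  t_star <- vapply(seq_len(B), function(k)
    compute_deadline(targets[, k], config), numeric(1))
  T_k <- clamp(t_star + config$hold + 0.2, config$trial_range[1],
               config$trial_range[2])
  n_steps <- max(ceiling(T_k / dt))
  pulse_steps <- round(config$pulse_duration / dt)
  sd_p <- if (noise) config$process_noise_sd * sqrt(dt) else 0
  sd_s <- if (noise) config$sensory_noise_sd else 0
  sd_s <- sqrt(sd_s^2 + extra_sens^2)

  pert_series <- NULL
  if (!is.null(perturb)) {
    amp <- matrix(stats::runif(2 * B, -perturb$value, perturb$value), 2, B)
    t_on <- stats::runif(B, config$pulse_duration, pmax(t_star - 1, 0.5))
    tt <- (seq_len(n_steps) - 0.5) * dt
    pert_series <- array(0, c(2, B, n_steps))
    for (k in seq_len(B)) {
      prof <- exp(-(tt - (t_on[k] + 0.5))^2 / (2 * 0.2^2))
      prof[tt < t_on[k] | tt > t_on[k] + 1] <- 0
      pert_series[1, k, ] <- amp[1, k] * prof
      pert_series[2, k, ] <- amp[2, k] * prof
    }
  }

  r <- matrix(0, n, B); z <- matrix(0, 2, B); s <- matrix(0, 2, B)
  R_arr <- if (record) array(0, c(n, B, n_steps))
  TH_arr <- if (record) array(0, c(n, B, n_steps))   # tanh(v_t)
  X_arr <- if (record) array(0, c(config$n_in, B, n_steps))
  S_arr <- array(0, c(2, B, n_steps))
  Z_arr <- array(0, c(2, B, n_steps))
  Y_arr <- array(0, c(2, B, n_steps))
  for (t in seq_len(n_steps)) {
    fb <- z + matrix(stats::rnorm(2 * B, 0, sd_s), 2, B)
    if (!is.null(pert_series)) fb <- fb + pert_series[, , t]
    pulse <- if (t <= pulse_steps) targets / config$target_scale
             else matrix(0, 2, B)
    x_t <- rbind(pulse, fb / config$v_max)
    v <- params$W_rec %*% r + params$W_in %*% x_t
    th <- tanh(v)
    r <- (1 - a) * r + a * th
    y <- params$W_out %*% r
    z <- z + dt * gain * y + matrix(stats::rnorm(2 * B, 0, sd_p), 2, B)
    s <- s + dt * z
    S_arr[, , t] <- s; Z_arr[, , t] <- z; Y_arr[, , t] <- y
    if (record) { R_arr[, , t] <- r; TH_arr[, , t] <- th; X_arr[, , t] <- x_t }
  }
  mask <- matrix(0, B, n_steps)
  for (k in seq_len(B)) {
    steps_k <- ceiling(T_k[k] / dt)
    from <- min(steps_k, ceiling(t_star[k] / dt) + 1L)
    mask[k, from:steps_k] <- 1
  }
  loss <- 0
  for (t in seq_len(n_steps)) {
    dsq <- colSums((S_arr[, , t] - targets)^2)
    loss <- loss + sum(mask[, t] * dsq)
  }
  m <- config$metabolic
  if (any(m > 0) && record) {
    if (m[1] > 0) loss <- loss + m[1] * sum(Y_arr^2)
    if (m[2] > 0) loss <- loss +
      m[2] * sum((Y_arr[, , -1, drop = FALSE] -
                  Y_arr[, , -n_steps, drop = FALSE])^2)
    if (m[3] > 0) loss <- loss + m[3] * sum(R_arr^2)
    if (m[4] > 0) loss <- loss +
      m[4] * sum((R_arr[, , -1, drop = FALSE] -
                  R_arr[, , -n_steps, drop = FALSE])^2)
  }
  list(final_pos = s, S = S_arr, Z = Z_arr, Y = Y_arr, R = R_arr,
       TH = TH_arr, X = X_arr, mask = mask, loss = loss,
       t_star = t_star, T_k = T_k, n_steps = n_steps, gain = gain)
}

#' Simulate closed-loop trials of the network
#'
#' @param params An [rnn_init()] (possibly trained) parameter set.
#' @param config An [rnn_config()].
#' @param targets 2 x B matrix of target coordinates (m), or a data frame
#'   with `x`, `y` columns from [sample_target()].
#' @param noise Include process/sensory noise.
#' @param manipulation Optional list `(type, value)` with type one of
#'   `"gain"` (output gain factor), `"sensory_noise"` (extra feedback noise
#'   sd, m/s), `"perturbation"` (peak amplitude bound of random Gaussian
#'   feedback pulses, m/s).
#' @param record Keep unit activity and inputs (needed for analyses).
#' @param seed Optional seed.
#' @return Object of class `rnn_trials`: `trials` data frame (target and
#'   stop coordinates, reward under the 0.6 m rule, t*, loss), plus the
#'   recorded arrays (`S`, `Z`, `Y`, and if `record` `R` activity).
#' @export
simulate_closed_loop <- function(params, config, targets, noise = TRUE,
                                 manipulation = NULL, record = FALSE,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(targets)) targets <- rbind(targets$x, targets$y)
  fw <- rnn_forward(params, config, targets, noise = noise,
                    manipulation = manipulation, record = record)
  B <- ncol(targets)
  tab <- data.frame(
    trial_id = seq_len(B),
    target_x = targets[1, ], target_y = targets[2, ],
    response_x = fw$final_pos[1, ], response_y = fw$final_pos[2, ],
    t_star = fw$t_star, duration = fw$T_k)
  tab$target_r <- sqrt(tab$target_x^2 + tab$target_y^2)
  tab$target_theta <- rad2deg(atan2(tab$target_x, tab$target_y))
  tab$response_r <- sqrt(tab$response_x^2 + tab$response_y^2)
  tab$response_theta <- rad2deg(atan2(tab$response_x, tab$response_y))
  tab$stop_error <- sqrt((tab$response_x - tab$target_x)^2 +
                         (tab$response_y - tab$target_y)^2)
  tab$rewarded <- tab$stop_error <= 0.6
  structure(list(trials = tab, S = fw$S, Z = fw$Z, Y = fw$Y, R = fw$R,
                 mask = fw$mask, loss = fw$loss, config = config,
                 dt = config$dt),
            class = "rnn_trials")
}

# backward pass through the closed loop; returns gradients of the loss in
# `fw` (a recorded rnn_forward) with respect to the three weight matrices
rnn_backward <- function(params, config, targets, fw) {
  n <- config$n; dt <- config$dt; a <- dt / config$tau
  B <- ncol(targets); n_steps <- fw$n_steps
  gW_rec <- matrix(0, n, n)
  gW_in <- matrix(0, n, config$n_in)
  gW_out <- matrix(0, config$n_out, n)
  gs <- matrix(0, 2, B); gz <- matrix(0, 2, B)
  gr <- matrix(0, n, B); gv_next <- matrix(0, n, B)
  W_in_z <- params$W_in[, 3:4, drop = FALSE]
  m <- config$metabolic
  # first differences for the fluctuation penalties (zero at the edges)
  dpen <- function(A, t) {
    d_now <- if (t > 1) A[, , t] - A[, , t - 1] else 0 * A[, , t]
    d_next <- if (t < n_steps) A[, , t + 1] - A[, , t] else 0 * A[, , t]
    d_now - d_next
  }
  for (t in n_steps:1) {
    gs <- gs + 2 * sweep(fw$S[, , t] - targets, 2, fw$mask[, t], "*")
    # z_t receives: position path, carry from z_{t+1}, and the feedback
    # into x_{t+1} (scaled by 1/v_max)
    gz <- gz + dt * gs
    gy <- dt * fw$gain * gz
    if (m[1] > 0) gy <- gy + 2 * m[1] * fw$Y[, , t]
    if (m[2] > 0) gy <- gy + 2 * m[2] * dpen(fw$Y, t)
    r_t <- fw$R[, , t]
    gr <- t(params$W_out) %*% gy + (1 - a) * gr + t(params$W_rec) %*% gv_next
    if (m[3] > 0) gr <- gr + 2 * m[3] * r_t
    if (m[4] > 0) gr <- gr + 2 * m[4] * dpen(fw$R, t)
    gv <- a * (1 - fw$TH[, , t]^2) * gr
    r_prev <- if (t > 1) fw$R[, , t - 1] else matrix(0, n, B)
    gW_out <- gW_out + gy %*% t(r_t)
    gW_rec <- gW_rec + gv %*% t(r_prev)
    gW_in <- gW_in + gv %*% t(fw$X[, , t])
    # pass to t-1: z_{t-1} feeds x_t's feedback rows
    gz <- gz + (t(W_in_z) %*% gv) / config$v_max
    gv_next <- gv
  }
  list(W_rec = gW_rec, W_in = gW_in, W_out = gW_out, loss = fw$loss)
}

# Adam update state helper
adam_step <- function(state, grad, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mh <- state$m / (1 - b1^state$t)
  vh <- state$v / (1 - b2^state$t)
  state$delta <- lr * mh / (sqrt(vh) + eps)
  state
}

#' Train the closed-loop network by backpropagation through time
#'
#' Gradient descent (Adam, with global gradient-norm clipping) on the loss
#' sum_k sum_{t > t*} |s_k(t) - x_k|^2 over batches of trials with random
#' targets from the task range. Training halts once the network's
#' behavioral ROC/AUC (computed exactly as for the synthetic agent) reaches
#' `auc_criterion`, or after `max_trials` trials.
#'
#' @param config An [rnn_config()].
#' @param task A [task_config()] providing the target distribution.
#' @param params Optional starting parameters (default fresh [rnn_init()]).
#' @param trainable Character subset of `c("W_rec", "W_in", "W_out")`;
#'   manipulation retraining passes only `"W_rec"`.
#' @param manipulation Passed to the forward pass (see
#'   [simulate_closed_loop()]).
#' @param max_trials Trial budget.
#' @param batch Trials per gradient step.
#' @param lr Adam learning rate.
#' @param clip Global gradient-norm clip.
#' @param auc_criterion Stop when evaluation AUC reaches this level.
#' @param eval_every Evaluate AUC every this many trials.
#' @param n_eval Evaluation trials per check.
#' @param seed Optional seed.
#' @param verbose Print progress.
#' @return Object of class `rnn_training`: `params`, `loss_history`,
#'   `auc_history` (data frame trial/auc), `trials_used`, `reached`.
#' @export
train_bptt <- function(config = rnn_config(), task = task_config(),
                       params = NULL,
                       trainable = c("W_rec", "W_in", "W_out"),
                       manipulation = NULL,
                       max_trials = 20000, batch = 16, lr = 2e-3,
                       clip = 2, auc_criterion = 0.85,
                       eval_every = 1000, n_eval = 200,
                       seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params)) params <- rnn_init(config)
  states <- lapply(params, function(M)
    list(t = 0, m = 0 * M, v = 0 * M, delta = 0 * M))
  loss_hist <- numeric(0)
  auc_hist <- data.frame(trial = integer(0), auc = numeric(0))
  used <- 0L
  reached <- FALSE
  eval_auc <- function() {
    tg <- sample_target(n_eval, task)
    ev <- simulate_closed_loop(params, config, tg, noise = TRUE,
                               manipulation = manipulation)
    behavior_auc_from_trials(ev$trials)
  }
  next_eval <- eval_every
  while (used < max_trials) {
    tg <- t(as.matrix(sample_target(batch, task)[, c("x", "y")]))
    fw <- rnn_forward(params, config, tg, noise = TRUE,
                      manipulation = manipulation, record = TRUE)
    if (!is.finite(fw$loss))
      stop("training diverged: non-finite loss at trial ", used)
    gr <- rnn_backward(params, config, tg, fw)
    gnorm <- sqrt(sum(unlist(lapply(gr[trainable], function(g) sum(g^2)))))
    sc <- if (gnorm > clip) clip / gnorm else 1
    for (nm in trainable) {
      states[[nm]] <- adam_step(states[[nm]], sc * gr[[nm]] / batch, lr)
      params[[nm]] <- params[[nm]] - states[[nm]]$delta
    }
    used <- used + batch
    loss_hist <- c(loss_hist, fw$loss / batch)
    if (used >= next_eval) {
      auc <- eval_auc()
      auc_hist <- rbind(auc_hist, data.frame(trial = used, auc = auc))
      if (verbose)
        message(sprintf("trial %d: loss %.3f, AUC %.3f", used,
                        mean(utils::tail(loss_hist, 20)), auc))
      if (auc >= auc_criterion) { reached <- TRUE; break }
      next_eval <- next_eval + eval_every
    }
  }
  structure(list(params = params, config = config,
                 loss_history = loss_hist, auc_history = auc_hist,
                 trials_used = used, reached = reached),
            class = "rnn_training")
}

#' Retrain only the recurrent weights under a task manipulation
#'
#' Freezes the input and output weights (they are returned bit-identical)
#' and updates only `W_rec` until performance under the manipulation reaches
#' the criterion. The sensory-noise manipulation is conventionally evaluated
#' without retraining first, since added feedback noise degrades performance
#' only mildly.
#'
#' @param params Trained `rnn_params`.
#' @param manipulation List `(type, value)` as in [simulate_closed_loop()].
#' @param config,task,... Passed to [train_bptt()].
#' @return An `rnn_training` whose `params` share `W_in`/`W_out` with the
#'   input.
#' @export
retrain_recurrent <- function(params, manipulation, config = rnn_config(),
                              task = task_config(), ...) {
  train_bptt(config, task, params = params, trainable = "W_rec",
             manipulation = manipulation, ...)
}

#' Evaluate a trained network: behavior and unit representations
#'
#' Runs fresh closed-loop trials with activity recording and returns the
#' pieces needed for the analysis battery: behavioral AUC, a rescaled-time
#' rate map of unit activity (activity magnitude |r|, the analog of firing
#' rate for a signed rate unit), its sequentiality index, and per-unit
#' latent tuning assessed by a
#' Gaussian-likelihood encoding analysis: each unit's activity is regressed
#' on boxcar expansions of velocity and distance/angle-to-target, and the
#' latent contribution is the held-out R2 drop when the distance/angle
#' columns are removed.
#'
#' @param params Trained `rnn_params`.
#' @param config An [rnn_config()].
#' @param task A [task_config()].
#' @param n_trials Evaluation trials.
#' @param latent_r2_threshold Held-out R2 drop above which a unit counts as
#'   latent-tuned.
#' @param seed Optional seed.
#' @return List with `auc`, `trials`, `rate_map`, `sequentiality`,
#'   `latent_r2_drop` (per unit), `frac_latent_tuned`, and the recorded
#'   evaluation object.
#' @export
evaluate_network <- function(params, config = rnn_config(),
                             task = task_config(), n_trials = 200,
                             latent_r2_threshold = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tg <- sample_target(n_trials, task)
  ev <- simulate_closed_loop(params, config, tg, noise = TRUE, record = TRUE)
  auc <- behavior_auc_from_trials(ev$trials)

  n <- config$n
  n_steps <- dim(ev$R)[3]
  # rescaled-time rate map over [0, t*] per trial
  M <- 25
  map <- matrix(0, n, M)
  for (k in seq_len(n_trials)) {
    steps_k <- max(2L, ceiling(ev$trials$t_star[k] / config$dt))
    steps_k <- min(steps_k, n_steps)
    bins <- pmin(floor((seq_len(steps_k) - 0.5) / steps_k * M) + 1L, M)
    act <- abs(ev$R[, k, seq_len(steps_k)])
    for (b in unique(bins))
      map[, b] <- map[, b] + rowMeans(act[, bins == b, drop = FALSE])
  }
  map <- map / n_trials
  mx <- apply(map, 1, max)
  map_n <- map / pmax(mx, 1e-12)
  sql <- sequentiality_index(map_n)

  # per-bin predictor table across trials: velocity + latent state
  feats <- list(); acts <- list(); trial_of <- list()
  for (k in seq_len(n_trials)) {
    steps_k <- min(max(2L, ceiling(ev$trials$duration[k] / config$dt)), n_steps)
    idx <- seq_len(steps_k)
    dx <- ev$trials$target_x[k] - ev$S[1, k, idx]
    dy <- ev$trials$target_y[k] - ev$S[2, k, idx]
    feats[[k]] <- cbind(vx = ev$Z[1, k, idx], vy = ev$Z[2, k, idx],
                        dist = sqrt(dx^2 + dy^2), ang = atan2(dx, dy))
    acts[[k]] <- t(ev$R[, k, idx])
    trial_of[[k]] <- rep(k, steps_k)
  }
  Fmat <- do.call(rbind, feats)
  Amat <- do.call(rbind, acts)
  tid <- unlist(trial_of)
  expand <- function(cols) do.call(cbind, lapply(cols, function(cn)
    boxcar_design(Fmat[, cn], range(Fmat[, cn]) + c(-1e-9, 1e-9), 8)))
  X_full <- cbind(expand(c("vx", "vy", "dist", "ang")), 1)
  X_red <- cbind(expand(c("vx", "vy")), 1)
  train <- tid %% 2 == 1
  ridge_fit <- function(X, Y, rows) {
    G <- crossprod(X[rows, ]) + diag(1e-6, ncol(X))
    solve(G, crossprod(X[rows, ], Y[rows, ]))
  }
  r2_of <- function(X) {
    Wb <- ridge_fit(X, Amat, train)
    pred <- X[!train, ] %*% Wb
    obs <- Amat[!train, ]
    1 - colSums((pred - obs)^2) / pmax(colSums(scale(obs, scale = FALSE)^2),
                                       1e-12)
  }
  drop_r2 <- r2_of(X_full) - r2_of(X_red)
  list(auc = auc, trials = ev$trials, rate_map = map_n,
       sequentiality = as.numeric(sql),
       latent_r2_drop = drop_r2,
       frac_latent_tuned = mean(drop_r2 > latent_r2_threshold),
       evaluation = ev)
}
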