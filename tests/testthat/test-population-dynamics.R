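one_hot_map <- function(n = 50) diag(n)

test_that("sequentiality index extremes follow the entropy formulas", {
  # each neuron active in exactly its own bin: f_peak = f_temp = 1
  sql1 <- sequentiality_index(one_hot_map(50))
  expect_equal(as.numeric(sql1), 1)
  expect_equal(attr(sql1, "f_peak"), 1)
  expect_equal(attr(sql1, "f_temp"), 1)

  # all neurons share one peak bin: point-mass peak distribution -> 0
  shared <- matrix(0, 50, 50); shared[, 7] <- 1
  sql0 <- sequentiality_index(shared)
  expect_equal(as.numeric(sql0), 0)
  expect_equal(attr(sql0, "f_peak"), 0)

  # uniform constant map: first-bin tie-breaking makes f_peak 0 and the
  # across-neuron entropy is maximal, so f_temp = 0 as well
  unif <- matrix(1, 40, 30)
  expect_equal(as.numeric(sequentiality_index(unif)), 0)
  expect_error(sequentiality_index(matrix(0, 5, 5)), "all-zero")
})

test_that("sequentiality is invariant to row permutation and rate scaling", {
  set.seed(1)
  m <- matrix(rexp(40 * 30), 40, 30)
  s0 <- as.numeric(sequentiality_index(m))
  expect_gte(s0, 0); expect_lte(s0, 1)
  expect_equal(as.numeric(sequentiality_index(m[sample(40), ])), s0)
  expect_equal(as.numeric(sequentiality_index(3.7 * m)), s0)
})

test_that("rate maps recover a constructed sequence and normalize peaks", {
  ses <- small_session()
  # synthetic sequence: replace spikes with Gaussian bumps tiling rescaled time
  n_neu <- 8
  tab <- ses$trial_table
  spikes <- vector("list", n_neu)
  set.seed(2)
  for (i in seq_len(n_neu)) {
    centre <- (i - 0.5) / n_neu
    sp <- lapply(seq_len(nrow(tab)), function(k) {
      tt <- rnorm(40, centre * tab$stop_time[k], 0.03 * tab$stop_time[k])
      tt <- tt[tt > 0 & tt < tab$stop_time[k]]
      data.frame(trial = tab$trial_id[k], t = tt)
    })
    spikes[[i]] <- do.call(rbind, sp)
  }
  ses_seq <- ses
  ses_seq$spikes <- spikes
  map <- build_rate_map(ses_seq, M = 40)
  expect_equal(map$sort_order, 1:n_neu)
  expect_true(all(apply(map$values, 1, max) == 1))
  expect_gt(as.numeric(sequentiality_index(map)), 0.5)

  # doubling rates leaves the normalized map unchanged
  spikes2 <- lapply(spikes, function(s) rbind(s, s))
  ses2 <- ses; ses2$spikes <- spikes2
  map2 <- build_rate_map(ses2, M = 40)
  expect_equal(map2$values, map$values)
  expect_error(build_rate_map(ses, trial_ids = tab$trial_id[1:3]),
               "at least 5")
})

test_that("pattern similarity: identical, inverted, and independent maps", {
  set.seed(3)
  A <- matrix(rexp(100 * 50), 100, 50)
  ps_same <- pattern_similarity(A, A)
  expect_equal(ps_same$overall, 1)
  expect_true(all(abs(ps_same$timecourse - 1) < 1e-12))

  B <- -scale(A, scale = FALSE)
  ps_inv <- pattern_similarity(scale(A, scale = FALSE), B)
  expect_equal(ps_inv$overall, -1)

  C <- matrix(rexp(100 * 50), 100, 50)
  expect_lt(abs(pattern_similarity(A, C)$overall), 0.05)
  expect_error(pattern_similarity(A, C[1:10, ]), "identical dimensions")
})

test_that("odd/even similarity within a condition exceeds across-condition similarity", {
  truth_a <- small_truth()
  truth_b <- perturb_encoding(truth_a, what = "latent", seed = 55)
  cfg <- task_config()
  trials <- exclude_disengaged(simulate_trials(60, cfg, seed = 56))
  ses0 <- bin_session(trials, dt = truth_a$dt, seed = 57)
  ses_a <- suppressWarnings(simulate_spikes(ses0, truth_a, seed = 58))
  ses_b <- suppressWarnings(simulate_spikes(ses0, truth_b, seed = 58))
  ids <- ses_a$trial_table$trial_id
  odd <- ids[seq_along(ids) %% 2 == 1]
  even <- ids[seq_along(ids) %% 2 == 0]
  m_odd <- build_rate_map(ses_a, odd, M = 30)
  m_even <- build_rate_map(ses_a, even, M = 30)
  m_b <- build_rate_map(ses_b, ids, M = 30)
  within <- pattern_similarity(m_odd, m_even)$overall
  across <- pattern_similarity(m_odd, m_b)$overall
  expect_gt(within, across)
})

test_that("cross-correlation hand-computed value and null behavior", {
  # counts [1,0,1,0], i = j, tau = 0: 2 / (4 * 0.5) - 0.5 = 0.5
  cc <- cross_correlation(c(1, 0, 1, 0), max_lag = 1)
  expect_equal(cc$value[cc$lag == 0], 0.5)
  expect_error(cross_correlation(rep(0, 10)), "silent")

  # independent Poisson trains: flat around rbar_j - rbar_i as printed,
  # and around zero with the rj baseline
  set.seed(4)
  ri <- rpois(20000, 0.1); rj <- rpois(20000, 0.3)
  cc_ri <- cross_correlation(ri, rj, max_lag = 10)
  expect_equal(mean(cc_ri$value), mean(rj) - mean(ri), tolerance = 0.02)
  cc_rj <- cross_correlation(ri, rj, max_lag = 10, baseline = "rj")
  expect_lt(max(abs(cc_rj$value)), 0.05)
})

test_that("a fitted coupled model reproduces the cross-correlation structure", {
  ses <- small_session()
  truth <- small_truth()
  fits <- small_fits()
  enc <- fits_to_encoding(fits, truth)
  ses_sim <- suppressWarnings(simulate_spikes(ses, enc, seed = 77))
  n <- ncol(ses$counts)
  rows <- seq_len(min(25000, nrow(ses$counts)))
  amp_true <- c(); amp_sim <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    amp_true <- c(amp_true, ccf_amplitude(
      cross_correlation(ses$counts[rows, i], ses$counts[rows, j],
                        max_lag = 20, baseline = "rj")))
    amp_sim <- c(amp_sim, ccf_amplitude(
      cross_correlation(ses_sim$counts[rows, i], ses_sim$counts[rows, j],
                        max_lag = 20, baseline = "rj")))
  }
  expect_gt(cor(amp_true, amp_sim), 0.8)
})
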