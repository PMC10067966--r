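test_that("stability index arithmetic and degenerate input", {
  expect_equal(stability_index(0.9, 0.9, 0.1), 1)
  expect_equal(stability_index(0.1, 0.9, 0.1), 0)
  expect_equal(stability_index(0.5, 0.9, 0.1), 0.5)
  expect_error(stability_index(0.5, 0.3, 0.3), "undefined")
  # vector inputs use medians
  expect_equal(stability_index(c(0.4, 0.5, 0.6), c(0.8, 0.9, 1), c(0, 0.1, 0.2)),
               0.5)
})

test_that("participation ratio bounds and worked example", {
  expect_equal(mixed_selectivity_index(c(1, 0, 0, 0, 0, 0)), 1)
  expect_equal(mixed_selectivity_index(rep(2.5, 6)), 6)
  expect_equal(mixed_selectivity_index(c(2, 1, 1, 0, 0, 0)), 16 / 6)
  expect_error(mixed_selectivity_index(rep(0, 6)), "all-zero")
  expect_error(mixed_selectivity_index(c(-1, 2)))
})

test_that("filter similarity: identity, sign flip, and shuffle null", {
  fits <- small_fits()
  self_c <- filter_similarity(fits, fits, "coupling")
  expect_true(all(stats::na.omit(self_c) > 0.999))
  self_s <- filter_similarity(fits, fits, "sensory")
  expect_true(all(abs(self_s - 1) < 1e-8))
  self_l <- filter_similarity(fits, fits, "latent")
  expect_true(all(abs(self_l - 1) < 1e-8))

  neg <- lapply(fits, function(f) {
    for (v in names(f$tuning)) f$tuning[[v]]$weights <- -f$tuning[[v]]$weights
    f
  })
  expect_true(all(abs(filter_similarity(fits, neg, "sensory") + 1) < 1e-8))

  set.seed(1)
  shuf <- filter_similarity(fits, fits, "sensory", shuffle = TRUE)
  expect_lt(abs(mean(shuf, na.rm = TRUE)), abs(mean(self_s)) - 0.2)
})

test_that("CCA dimensionality: shared modes, symmetric construction, worked PR", {
  n <- 3000
  set.seed(2)
  # R driven by one linear combination of X -> D ~ 1
  X <- matrix(rnorm(n * 6), n, 6)
  shared <- as.numeric(X %*% c(1, -1, 0.5, 0, 0, 0))
  R1 <- outer(shared, rnorm(20)) + 0.05 * matrix(rnorm(n * 20), n, 20)
  cc1 <- cca_dimensionality(X, R1)
  expect_lt(cc1$D, 1.3)

  # six orthogonal channels copied into six neuron groups -> D ~ 6
  R6 <- X[, rep(1:6, each = 3)] + 1e-6 * matrix(rnorm(n * 18), n, 18)
  cc6 <- cca_dimensionality(X, R6)
  expect_gt(cc6$D, 5.5)

  # canonical covariances (2, 1, 1) -> D = 16/6
  Z <- scale(matrix(rnorm(n * 3), n, 3))
  Z <- qr.Q(qr(Z)) * sqrt(n - 1)      # orthogonal, unit-variance columns
  Xc <- Z
  Rc <- cbind(2 * Z[, 1], Z[, 2], Z[, 3])
  cc <- cca_dimensionality(Xc, Rc)
  expect_equal(sort(round(abs(cc$covariances), 6)), c(1, 1, 2),
               tolerance = 1e-4)
  expect_equal(cc$D, 16 / 6, tolerance = 1e-4)
})

test_that("first canonical pair matches the reference implementation", {
  set.seed(3)
  X <- matrix(rnorm(500 * 4), 500, 4)
  R <- matrix(rnorm(500 * 7), 500, 7)
  ours <- cca_dimensionality(X, R)
  ref <- stats::cancor(X, R)
  expect_equal(ours$correlations, ref$cor, tolerance = 1e-6)
  # successive canonical variables are uncorrelated across pairs
  expect_lt(abs(cor(ours$variates_x[, 1], ours$variates_x[, 2])), 1e-6)
  expect_lt(abs(cor(ours$variates_x[, 1], ours$variates_r[, 2])), 1e-6)
})

test_that("coupling-distance profile: grid geometry and monotone decay", {
  # hand-built fits with strength decaying in electrode distance
  mk_fit <- function(neuron, coups) {
    structure(list(neuron = neuron, coupling = coups, tuning = list(),
                   kernel = list(), event = list()), class = "gam_fit")
  }
  electrode <- data.frame(neuron = 1:4, row = c(1, 1, 2, 5),
                          col = c(1, 2, 2, 5))
  # raw distances from neuron 1: adjacent 400, diagonal 400*sqrt(2), far
  d_adj <- 400 * sqrt((1 - 1)^2 + (1 - 2)^2)
  d_diag <- 400 * sqrt((1 - 2)^2 + (1 - 2)^2)
  expect_equal(d_adj, 400)
  expect_equal(d_diag, 400 * sqrt(2))
  filt_of <- function(d) rep(0.5 * exp(-d / 1000), 20)
  fits <- list(
    mk_fit(1, list(`2` = list(from = 2, filter = filt_of(d_adj)),
                   `4` = list(from = 4, filter = filt_of(400 * sqrt(32))))),
    mk_fit(2, list()), mk_fit(3, list()), mk_fit(4, list()))
  prof <- coupling_vs_distance(fits, electrode)
  expect_equal(prof$distance_um, c(400, 2400))   # binned to 400-um multiples
  expect_true(all(diff(prof$mean_abs_log_gain) < 0))
  expect_true(all(is.na(prof$inhibitory)))       # all gains excitatory here
})

test_that("shuffled-pair similarity centers on zero for fitted populations", {
  sf <- stability_fits()
  set.seed(9)
  shuf <- replicate(20, median(filter_similarity(sf$h1, sf$h2,
                                                 "coupling",
                                                 shuffle = TRUE),
                               na.rm = TRUE))
  matched <- median(filter_similarity(sf$h1, sf$h2, "coupling"),
                    na.rm = TRUE)
  expect_lt(abs(mean(shuf)), 0.3)
  expect_gt(matched, mean(shuf) + 2 * sd(shuf))
})
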