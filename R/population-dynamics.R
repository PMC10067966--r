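#' Time-rescaled population rate map
#'
#' For each trial in the group, spike times between target onset and the end
#' of movement are mapped to [0, 1] by dividing by the trial's movement end,
#' histogrammed into `M` rescaled-time bins, averaged across trials, and
#' peak-normalized per neuron. Neurons are sorted by the timing of their peak
#' response (earliest bin of the maximum on ties).
#'
#' @param session A `nav_session` with spikes.
#' @param trial_ids Trials forming the group (default all); needs >= 5.
#' @param M Number of rescaled-time bins (default 50).
#' @param group_label Optional label stored with the map.
#' @param normalize Peak-normalize rows (default `TRUE`).
#' @return Object of class `rate_map`: `values` (neurons x M, rows in
#'   original neuron order), `sort_order`, `peak_bin`, `silent` (all-zero
#'   rows, flagged and excluded from the sequentiality index), `group_label`.
#' @export
build_rate_map <- function(session, trial_ids = NULL, M = 50,
                           group_label = NULL, normalize = TRUE) {
  tab <- session$trial_table
  if (is.null(trial_ids)) trial_ids <- tab$trial_id
  if (length(trial_ids) < 5) stop("need at least 5 trials in the group")
  ends <- stats::setNames(tab$stop_time, tab$trial_id)
  N <- length(session$spikes)
  vals <- matrix(0, N, M)
  for (i in seq_len(N)) {
    sp <- session$spikes[[i]]
    sp <- sp[sp$trial %in% trial_ids, , drop = FALSE]
    if (!nrow(sp)) next
    e <- ends[as.character(sp$trial)]
    frac <- sp$t / e
    keep <- frac >= 0 & frac <= 1
    if (!any(keep)) next
    b <- pmin(floor(frac[keep] * M) + 1L, M)
    vals[i, ] <- tabulate(b, nbins = M) / length(trial_ids)
  }
  peak <- max.col(vals, ties.method = "first")
  silent <- apply(vals, 1, function(r) all(r == 0))
  if (normalize) {
    mx <- apply(vals, 1, max)
    vals[!silent, ] <- vals[!silent, , drop = FALSE] / mx[!silent]
  }
  structure(list(values = vals, sort_order = order(peak), peak_bin = peak,
                 silent = silent, M = M, group_label = group_label),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("rate_map: %d neurons x %d rescaled bins%s (%d silent)\n",
              nrow(x$values), x$M,
              if (is.null(x$group_label)) "" else paste0(" [", x$group_label, "]"),
              sum(x$silent)))
  invisible(x)
}

# entropy with the 0 log 0 = 0 convention (natural log)
entropy0 <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p)) + 0   # + 0 avoids IEEE negative zero
}

#' Sequentiality index of a population rate map
#'
#' Geometric mean of peak sparseness and temporal sparseness. Peak sparseness
#' is the entropy of the distribution of peak bins across neurons, normalized
#' by log M (1 when peaks tile all bins uniformly, 0 when all neurons share a
#' peak bin). Temporal sparseness is 1 minus the average over bins of the
#' normalized entropy of the across-neuron activity distribution (1 when a
#' single neuron is active per bin). Silent neurons are excluded; all-zero
#' bins are excluded from the temporal average.
#'
#' @param map A [build_rate_map()] result, or a plain neurons x bins matrix.
#' @return Scalar Sql in [0, 1], with attributes `f_peak` and `f_temp`.
#' @export
sequentiality_index <- function(map) {
  vals <- if (inherits(map, "rate_map")) map$values else as.matrix(map)
  keep <- apply(vals, 1, function(r) any(r > 0))
  if (!any(keep)) stop("all-zero rate map: sequentiality undefined")
  vals <- vals[keep, , drop = FALSE]
  N <- nrow(vals); M <- ncol(vals)
  if (N < 2 || M < 2) stop("need at least 2 neurons and 2 bins")
  peak <- max.col(vals, ties.method = "first")
  p_t <- tabulate(peak, nbins = M) / N
  f_peak <- entropy0(p_t) / log(M)
  col_tot <- colSums(vals)
  active <- col_tot > 0
  col_ent <- vapply(which(active), function(t)
    entropy0(vals[, t] / col_tot[t]) / log(N), numeric(1))
  f_temp <- 1 - mean(col_ent)
  structure(sqrt(max(f_temp, 0) * max(f_peak, 0)),
            f_peak = f_peak, f_temp = f_temp)
}

#' Pattern similarity between two rate maps
#'
#' Overall similarity is the Pearson correlation between the flattened maps;
#' the timecourse is the per-bin correlation between the population activity
#' vectors (columns). Both maps must share neuron order and bin count.
#'
#' @param map_a,map_b [build_rate_map()] results or matrices of equal shape.
#' @return List with `overall` and `timecourse` (length M; `NA` where a
#'   column has zero variance).
#' @export
pattern_similarity <- function(map_a, map_b) {
  A <- if (inherits(map_a, "rate_map")) map_a$values else as.matrix(map_a)
  B <- if (inherits(map_b, "rate_map")) map_b$values else as.matrix(map_b)
  if (!all(dim(A) == dim(B)))
    stop("rate maps must have identical dimensions (same neurons, same M)")
  tc <- vapply(seq_len(ncol(A)), function(t) {
    if (stats::sd(A[, t]) == 0 || stats::sd(B[, t]) == 0) NA_real_
    else stats::cor(A[, t], B[, t])
  }, numeric(1))
  list(overall = stats::cor(as.vector(A), as.vector(B)), timecourse = tc)
}

#' Spike-train cross-correlation function
#'
#' As printed in the source formulation: R_ij(tau) = (1 / (N rbar_i))
#' sum_t r_i(t) r_j(t - tau) - rbar_i, with N the total number of bins and
#' rbar_i the mean count of the reference neuron; edges are zero-padded, and
#' i = j gives the auto-correlation. Interpreted as the excess spike rate in
#' neuron i due to neuron j. Note that with this baseline, independent
#' trains converge to rbar_j - rbar_i rather than zero; `baseline = "rj"`
#' subtracts rbar_j instead (independent trains then give zero in
#' expectation). Both variants are provided because the printed form and the
#' zero-baseline property cannot hold simultaneously.
#'
#' @param r_i,r_j Binned spike counts on a common clock.
#' @param max_lag Maximum lag in bins.
#' @param baseline `"ri"` (as printed) or `"rj"`.
#' @return List with `lag` (bins, -max_lag..max_lag) and `value`.
#' @export
cross_correlation <- function(r_i, r_j = r_i, max_lag = 50,
                              baseline = c("ri", "rj")) {
  baseline <- match.arg(baseline)
  n <- length(r_i)
  stopifnot(length(r_j) == n)
  rbar_i <- mean(r_i)
  if (rbar_i == 0) stop("silent reference neuron: cross-correlation undefined")
  lags <- -max_lag:max_lag
  vals <- vapply(lags, function(tau) {
    if (tau >= 0) {
      idx <- seq_len(n - tau)
      s <- sum(r_i[idx + tau] * r_j[idx])
    } else {
      idx <- seq_len(n + tau)
      s <- sum(r_i[idx] * r_j[idx - tau])
    }
    s / (n * rbar_i)
  }, numeric(1))
  b0 <- if (baseline == "ri") rbar_i else mean(r_j)
  list(lag = lags, value = vals - b0)
}

#' Peak-to-trough amplitude of a cross-correlation function
#'
#' @param ccf A [cross_correlation()] result.
#' @return max - min of the correlation values.
#' @export
ccf_amplitude <- function(ccf) max(ccf$value) - min(ccf$value)
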