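# Trial-label permutation tests and cross-neuron surrogate machinery.
#
# All p-values use the add-one rule p = (1 + #{surrogate >= observed}) /
# (1 + n_surr), so a permutation p is never exactly 0 and is
# exchangeability-valid.

new_perm_result <- function(observed, surrogates, p, seed = NULL, extra = list()) {
  structure(c(list(observed = observed, surrogates = surrogates, p = p,
                   seed = seed), extra), class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> observed = %.4g, n_surr = %d, p = %.4g\n",
              x$observed, length(x$surrogates), x$p))
  invisible(x)
}

#' Permutation test for a strength difference between two responses
#'
#' Statistic: absolute difference in response strength (median spike count in
#' the strength window / window length). The null is built by randomly
#' permuting the trial labels of the two responses.
#'
#' @param counts_i,counts_j per-trial spike counts in each response's
#'   strength window (>= 2 trials each).
#' @param n_surr number of surrogates (default 1000).
#' @param seed optional integer seed.
#' @param window_s window length in seconds used to convert counts to Hz.
#' @return a `perm_result`.
#' @export
perm_strength_diff <- function(counts_i, counts_j, n_surr = 1000,
                               seed = NULL, window_s = 0.7) {
  if (length(counts_i) < 2 || length(counts_j) < 2)
    stop("perm_strength_diff() needs >= 2 trials per response")
  if (!is.null(seed)) set.seed(seed)
  ni <- length(counts_i)
  pool <- c(counts_i, counts_j)
  stat <- function(x) abs(stats::median(x[seq_len(ni)]) -
                            stats::median(x[-seq_len(ni)])) / window_s
  obs <- stat(pool)
  surr <- vapply(seq_len(n_surr), function(b) stat(sample(pool)), numeric(1))
  new_perm_result(obs, surr, perm_pvalue(obs, surr), seed)
}

# First sustained crossing of a rate vector (t in ms, 1 ms grid); NA if none.
crossing_from_vec <- function(hz, t, threshold, params) {
  first_crossing(structure(list(t = t, hz = hz), class = "rate_trace"),
                 threshold, params)
}

#' Permutation test for a latency difference between two responses
#'
#' Statistic: absolute difference between the response onsets, where each
#' onset is re-estimated for every surrogate trial grouping as the first
#' sustained crossing of the group's trial-averaged rate trace over the
#' original detection threshold. A surrogate group whose trace never crosses
#' is censored at `censor_ms`.
#'
#' @param trains_i,trains_j lists of per-trial spike-time vectors (ms).
#' @param threshold detection threshold (Hz) from the original analysis.
#' @param params a [det_params()] list.
#' @param n_surr number of surrogates.
#' @param seed optional integer seed.
#' @param censor_ms latency assigned when a surrogate group has no
#'   qualifying crossing (default 1000, the end of the onset window).
#' @return a `perm_result` with extra fields `latency_i`, `latency_j` and
#'   `n_censored`.
#' @export
perm_latency_diff <- function(trains_i, trains_j, threshold,
                              params = det_params(), n_surr = 1000,
                              seed = NULL, censor_ms = 1000) {
  if (!is.null(seed)) set.seed(seed)
  ni <- length(trains_i)
  all_tr <- c(trains_i, trains_j)
  # smoothed per-trial traces, restricted to t >= 0 (the onset search range)
  hist_all <- rate_histogram(all_tr)
  sm <- t(apply(hist_all, 1, smooth_counts, sigma_ms = params$sigma_ms))
  t_grid <- seq(-1000, 1999)
  keep <- t_grid >= params$onset_search[1]
  sm <- sm[, keep, drop = FALSE]
  tk <- t_grid[keep]
  latency_of <- function(rows) {
    on <- crossing_from_vec(colMeans(sm[rows, , drop = FALSE]), tk,
                            threshold, params)
    if (is.na(on)) censor_ms else on
  }
  li <- latency_of(seq_len(ni))
  lj <- latency_of(ni + seq_along(trains_j))
  obs <- abs(li - lj)
  n_cens <- 0L
  surr <- vapply(seq_len(n_surr), function(b) {
    idx <- sample(length(all_tr))
    a <- latency_of(idx[seq_len(ni)])
    bb <- latency_of(idx[-seq_len(ni)])
    abs(a - bb)
  }, numeric(1))
  new_perm_result(obs, surr, perm_pvalue(obs, surr), seed,
                  extra = list(latency_i = li, latency_j = lj,
                               n_censored = n_cens))
}

# Mahalanobis distance between two waveform groups: pooled within-group
# covariance, shrunk toward its diagonal (waveform dimension can exceed the
# spike count).
mahalanobis_shape <- function(wf_i, wf_j, shrinkage = 0.1) {
  d <- colMeans(wf_i) - colMeans(wf_j)
  S <- ((nrow(wf_i) - 1) * stats::cov(wf_i) +
          (nrow(wf_j) - 1) * stats::cov(wf_j)) / (nrow(wf_i) + nrow(wf_j) - 2)
  Sreg <- (1 - shrinkage) * S + shrinkage * diag(diag(S), ncol(S))
  sol <- try(solve(Sreg, d), silent = TRUE)
  if (inherits(sol, "try-error"))
    stop("perm_shape_diff(): singular covariance after regularization")
  sqrt(max(0, sum(d * sol)))
}

#' Permutation test for a spike-waveform difference between two responses
#'
#' Statistic: Mahalanobis distance between the mean waveforms of the two
#' spike groups (pooled covariance, shrinkage-regularized toward its
#' diagonal), against a null built by shuffling the response labels of the
#' spikes. Used to check that multiple responses come from the same neuron.
#'
#' @param wf_i,wf_j numeric matrices of spike waveforms (rows = spikes,
#'   >= 10 per group).
#' @param n_surr number of surrogates.
#' @param seed optional integer seed.
#' @param shrinkage covariance shrinkage weight toward the diagonal.
#' @return a `perm_result`.
#' @export
perm_shape_diff <- function(wf_i, wf_j, n_surr = 1000, seed = NULL,
                            shrinkage = 0.1) {
  if (nrow(wf_i) < 10 || nrow(wf_j) < 10)
    stop("perm_shape_diff() needs >= 10 spikes per response")
  if (!is.null(seed)) set.seed(seed)
  ni <- nrow(wf_i)
  pool <- rbind(wf_i, wf_j)
  obs <- mahalanobis_shape(wf_i, wf_j, shrinkage)
  surr <- vapply(seq_len(n_surr), function(b) {
    idx <- sample(nrow(pool))
    mahalanobis_shape(pool[idx[seq_len(ni)], , drop = FALSE],
                      pool[idx[-seq_len(ni)], , drop = FALSE], shrinkage)
  }, numeric(1))
  new_perm_result(obs, surr, perm_pvalue(obs, surr), seed)
}

#' Cross-neuron surrogate-pair null for a response metric
#'
#' The observed pairs are all within-unit pairs of responses; their absolute
#' metric differences summarize how similar a unit's multiple responses are.
#' Each of `n_sets` surrogate sets re-draws the same number of pairs using
#' responses from two different units, giving a null distribution of set
#' medians. Also returns the representative surrogate set (the one with the
#' median difference across all sets) and a one-sided rank-sum comparison of
#' the observed differences against it.
#'
#' @param values numeric vector of the per-response metric (strength,
#'   latency, preferred phase...).
#' @param unit_ids unit of each response.
#' @param n_sets number of surrogate sets.
#' @param seed optional integer seed.
#' @param diff_fn difference function for a pair, default `|x - y|`; pass
#'   [circ_diff_deg()] for phases.
#' @return list with `observed_diffs`, `observed_median`,
#'   `surrogate_medians`, `p` (add-one, observed median below the surrogate
#'   medians), `representative` (diffs of the representative set),
#'   `ranksum_p`, `n_skipped`.
#' @export
surrogate_pairs <- function(values, unit_ids, n_sets = 1000, seed = NULL,
                            diff_fn = function(x, y) abs(x - y)) {
  if (length(unique(unit_ids)) < 2)
    stop("surrogate_pairs() needs responses from >= 2 units")
  if (!is.null(seed)) set.seed(seed)
  by_unit <- split(seq_along(values), unit_ids)
  pairs <- do.call(rbind, lapply(by_unit, function(ix) {
    if (length(ix) < 2) return(NULL)
    t(utils::combn(ix, 2))
  }))
  if (is.null(pairs)) stop("surrogate_pairs(): no within-unit response pair")
  d_obs <- diff_fn(values[pairs[, 1]], values[pairs[, 2]])
  skip <- is.na(d_obs)
  d_obs <- d_obs[!skip]
  n_pairs <- length(d_obs)
  uvec <- as.integer(factor(unit_ids))
  surr_sets <- lapply(seq_len(n_sets), function(b) {
    d <- numeric(n_pairs)
    for (q in seq_len(n_pairs)) {
      repeat {
        ij <- sample(length(values), 2)
        if (uvec[ij[1]] != uvec[ij[2]] && !is.na(values[ij[1]]) &&
            !is.na(values[ij[2]])) break
      }
      d[q] <- diff_fn(values[ij[1]], values[ij[2]])
    }
    d
  })
  meds <- vapply(surr_sets, stats::median, numeric(1))
  obs_med <- stats::median(d_obs)
  p <- perm_pvalue(obs_med, meds, tail = "less")
  rep_idx <- which.min(abs(meds - stats::median(meds)))
  rep_set <- surr_sets[[rep_idx]]
  rk <- stats::wilcox.test(d_obs, rep_set, alternative = "less", exact = FALSE)
  list(observed_diffs = d_obs, observed_median = obs_med,
       surrogate_medians = meds, p = p, representative = rep_set,
       ranksum_p = rk$p.value, n_skipped = sum(skip), seed = seed)
}

# Negative exponential fit y = a + b * exp(-x / tau); NULL on failure.
fit_negexp <- function(x, y) {
  a0 <- y[length(y)]
  b0 <- y[1] - a0
  if (abs(b0) < .Machine$double.eps) b0 <- .Machine$double.eps
  tau0 <- max(diff(range(x)) / 3, 1)
  fitter <- if (requireNamespace("minpack.lm", quietly = TRUE))
    minpack.lm::nlsLM else stats::nls
  fit <- try(suppressWarnings(
    fitter(y ~ a + b * exp(-x / tau),
           start = list(a = a0, b = b0, tau = tau0),
           data = data.frame(x = x, y = y))), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  as.list(stats::coef(fit))
}

#' Stability of a response metric versus the number of trials
#'
#' For each response, the metric is computed on trials `1..n_t` for each
#' `n_t` in the grid; the grand average across responses is fitted with a
#' negative exponential `a + b * exp(-n_t / tau)` to check for a plateau.
#' Additionally computes sliding-window estimates (fixed `sliding_nt`
#' trials) and a two-sided paired sign test comparing the estimates from the
#' first window with those from a later window, to separate window-length
#' bias from presentation-order effects.
#'
#' @param metric_fns list of functions, one per response; each takes a
#'   vector of trial indices and returns a scalar.
#' @param n_trials number of trials available to every response.
#' @param nt_grid grid of trial counts, default `2:n_trials`.
#' @param sliding_nt sliding-window width (default 6).
#' @param compare_starts first trials of the two windows compared by the
#'   sign test (default `c(1, 20)`, i.e. trials 1-6 versus 20-25).
#' @return list with `curve` (data.frame `nt`, `value`), `fit` (list
#'   `a`, `b`, `tau`, or `NULL` when the fit fails), `sliding` (matrix,
#'   responses x window starts) and `sign_p`.
#' @export
stability_curve <- function(metric_fns, n_trials, nt_grid = 2:n_trials,
                            sliding_nt = 6, compare_starts = c(1, 20)) {
  stopifnot(max(nt_grid) <= n_trials)
  vals <- sapply(nt_grid, function(nt)
    mean(vapply(metric_fns, function(f) f(seq_len(nt)), numeric(1))))
  curve <- data.frame(nt = nt_grid, value = vals)
  fit <- fit_negexp(curve$nt, curve$value)
  starts <- seq_len(n_trials - sliding_nt + 1)
  sliding <- sapply(starts, function(s0)
    vapply(metric_fns, function(f) f(s0 + seq_len(sliding_nt) - 1), numeric(1)))
  if (length(metric_fns) == 1) sliding <- matrix(sliding, nrow = 1)
  colnames(sliding) <- starts
  sign_p <- NA_real_
  if (all(compare_starts %in% starts)) {
    d <- sliding[, as.character(compare_starts[1])] -
      sliding[, as.character(compare_starts[2])]
    d <- d[d != 0]
    sign_p <- if (!length(d)) 1 else
      stats::binom.test(sum(d > 0), length(d), 0.5,
                        alternative = "two.sided")$p.value
  }
  list(curve = curve, fit = fit, sliding = sliding, sign_p = sign_p)
}

#' Normalized strength difference of a response pair
#'
#' Absolute strength difference divided by the highest strength in the pair.
#'
#' @param s_i,s_j strengths (Hz), not both 0.
#' @return value in `[0, 1]`.
#' @export
norm_strength_diff <- function(s_i, s_j) {
  m <- pmax(s_i, s_j)
  ifelse(m > 0, abs(s_i - s_j) / m, NA_real_)
}
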