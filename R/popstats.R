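# Population-level relations between the number of responses per unit and
# the response latency, strength and baseline.

#' Spearman correlation between response latency and response count
#'
#' Each significant response contributes one point: its onset latency
#' against the number of responsive stimuli of its unit.
#'
#' @param responses data.frame with `unit_id`, `onset_ms` and `n_responses`
#'   (as from [detect_responses()]).
#' @return list with `rho`, `p`, `n`; `rho` is `NA` (flagged via
#'   `degenerate = TRUE`) when either variable has no rank variation.
#' @export
latency_vs_nresponses <- function(responses) {
  if (nrow(responses) < 10)
    stop("latency_vs_nresponses() needs >= 10 responses")
  spearman_or_flag(responses$onset_ms, responses$n_responses)
}

#' Spearman correlation between response strength and response count
#'
#' @param responses data.frame with `strength_hz` and `n_responses`; pass
#'   mean-based strengths for a less discrete statistic.
#' @return as [latency_vs_nresponses()].
#' @export
strength_vs_nresponses <- function(responses) {
  if (nrow(responses) < 10)
    stop("strength_vs_nresponses() needs >= 10 responses")
  spearman_or_flag(responses$strength_hz, responses$n_responses)
}

spearman_or_flag <- function(x, y) {
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(rho = NA_real_, p = NA_real_, n = length(x),
                degenerate = TRUE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       degenerate = FALSE)
}

#' Baseline-matched latency comparison of single- vs multi-responsive units
#'
#' Greedily matches `k` units from each group by nearest baseline strength
#' (without replacement), verifies that the matched baseline distributions
#' do not differ (two-sided rank-sum p > 0.2, else a warning), and compares
#' the latencies of the matched sets with a one-sided rank-sum test
#' (alternative: multi-responsive latencies are earlier).
#'
#' @param single,multi data.frames with columns `baseline_hz` and
#'   `latency_ms`, one row per unit (>= k rows each).
#' @param k units matched per group, default 20.
#' @param seed optional integer seed (tie-breaking in the greedy order).
#' @return list with `p_latency`, `p_baseline_match`, `matched_single`,
#'   `matched_multi` (row indices).
#' @export
baseline_matched_comparison <- function(single, multi, k = 20, seed = NULL) {
  if (nrow(single) < k || nrow(multi) < k)
    stop("baseline_matched_comparison() needs >= k units per group")
  if (!is.null(seed)) set.seed(seed)
  avail_s <- seq_len(nrow(single))
  sel_s <- integer(0); sel_m <- integer(0)
  # visit multi units in random order, pair each with the nearest remaining
  # single unit by baseline strength
  for (mi in sample(seq_len(nrow(multi)), k)) {
    d <- abs(single$baseline_hz[avail_s] - multi$baseline_hz[mi])
    j <- avail_s[which.min(d)]
    sel_s <- c(sel_s, j); sel_m <- c(sel_m, mi)
    avail_s <- setdiff(avail_s, j)
  }
  pb <- stats::wilcox.test(single$baseline_hz[sel_s],
                           multi$baseline_hz[sel_m], exact = FALSE)$p.value
  if (pb <= 0.2)
    warning("baseline_matched_comparison(): matched baselines differ ",
            sprintf("(two-sided rank-sum p = %.3g)", pb))
  pl <- stats::wilcox.test(multi$latency_ms[sel_m], single$latency_ms[sel_s],
                           alternative = "less", exact = FALSE)$p.value
  list(p_latency = pl, p_baseline_match = pb,
       matched_single = sel_s, matched_multi = sel_m)
}
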