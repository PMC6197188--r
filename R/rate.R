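# Instantaneous firing rate and the three-criterion response-detection rule.
#
# The rate trace lives on a 1-ms grid over [-1000, 2000) ms. The smoothing
# kernel is a unit-area Gaussian (sigma = 10 ms) truncated where its
# amplitude falls below 1% of the peak and deliberately NOT renormalized
# after truncation (the truncation loses < 0.3% of the mass).

#' Detection parameters
#'
#' All tunable constants of the response-detection rule, with the defaults
#' used throughout: 10 ms kernel, 75 ms minimum supra-threshold time with
#' sub-20 ms dips disregarded, mean + 4 SD threshold (5 Hz floor) over the
#' pre-stimulus rate, a 500 ms post-onset count window whose median must be
#' at least 2 spikes and exceed mean + 5 SD of the across-stimuli baseline
#' medians, and a one-sided paired sign test at alpha = 0.01.
#'
#' @param sigma_ms Gaussian kernel width (ms).
#' @param min_dur_ms minimum time the rate must stay above threshold (ms).
#' @param max_gap_ms sub-threshold dips shorter than this are disregarded (ms).
#' @param thr_sd number of SDs above the mean for the rate threshold.
#' @param thr_floor_hz lower bound on the rate threshold (Hz).
#' @param thr_window pre-stimulus window for threshold statistics (ms).
#' @param count_window_ms length of the post-onset spike-count window (ms).
#' @param min_median minimum median post-onset spike count.
#' @param base_sd number of SDs above the across-stimuli baseline mean the
#'   median count must exceed.
#' @param base_window baseline window for the count criteria (ms).
#' @param alpha sign-test significance level.
#' @param min_trials minimum trials per stimulus to attempt detection.
#' @param onset_search window in which the response onset may fall (ms).
#' @return list of class `det_params`.
#' @export
det_params <- function(sigma_ms = 10, min_dur_ms = 75, max_gap_ms = 20,
                       thr_sd = 4, thr_floor_hz = 5, thr_window = c(-900, -100),
                       count_window_ms = 500, min_median = 2, base_sd = 5,
                       base_window = c(-700, -200), alpha = 0.01,
                       min_trials = 15, onset_search = c(0, 1000)) {
  structure(as.list(environment()), class = "det_params")
}

#' Trial-averaged instantaneous firing rate
#'
#' Convolves each trial's spike train with a unit-area Gaussian kernel
#' (truncated at 1% amplitude) on a 1-ms grid and averages across trials.
#'
#' @param trains list of numeric vectors of spike times (ms), one per trial.
#' @param sigma_ms kernel width in ms.
#' @param t_range half-open time span of the grid, default `c(-1000, 2000)`.
#' @return list of class `rate_trace` with `t` (ms, left bin edges), `hz`
#'   and `sigma_ms`.
#' @export
instantaneous_rate <- function(trains, sigma_ms = 10, t_range = c(-1000, 2000)) {
  if (length(trains) == 0) stop("instantaneous_rate() needs at least one trial")
  t <- seq(t_range[1], t_range[2] - 1)
  counts <- rate_histogram(trains, t_range)
  hz <- smooth_counts(colSums(counts), sigma_ms) / length(trains)
  structure(list(t = t, hz = hz, sigma_ms = sigma_ms), class = "rate_trace")
}

# 1-ms binned counts, one row per trial.
rate_histogram <- function(trains, t_range = c(-1000, 2000)) {
  n <- t_range[2] - t_range[1]
  out <- matrix(0, nrow = length(trains), ncol = n)
  for (i in seq_along(trains)) {
    ts <- trains[[i]]
    ts <- ts[ts >= t_range[1] & ts < t_range[2]]
    if (length(ts))
      out[i, ] <- tabulate(floor(ts) - t_range[1] + 1L, nbins = n)
  }
  out
}

# Convolve a 1-ms count histogram with the truncated Gaussian; returns Hz.
smooth_counts <- function(counts, sigma_ms = 10) {
  half <- floor(sigma_ms * sqrt(2 * log(100)))  # amplitude >= 1% of peak
  k <- stats::dnorm(-half:half, 0, sigma_ms)    # per-ms density, not renormalized
  n <- length(counts)
  y <- stats::convolve(counts, rev(k), type = "open")
  y[(half + 1):(half + n)] * 1000
}

#' Response-detection rate threshold
#'
#' Mean plus `thr_sd` standard deviations of the per-stimulus average rate
#' traces, pooled across all stimuli over the pre-stimulus window, with a
#' floor (default 5 Hz) for neurons with low baseline firing.
#'
#' @param traces list of `rate_trace` objects, one per stimulus.
#' @param params a [det_params()] list.
#' @return threshold in Hz.
#' @export
response_threshold <- function(traces, params = det_params()) {
  samp <- unlist(lapply(traces, function(tr) {
    tr$hz[tr$t >= params$thr_window[1] & tr$t < params$thr_window[2]]
  }), use.names = FALSE)
  max(mean(samp) + params$thr_sd * stats::sd(samp), params$thr_floor_hz)
}

#' First sustained threshold crossing of a rate trace
#'
#' Finds the first upward crossing within the search window after which the
#' rate stays above threshold for at least `min_dur_ms`, disregarding
#' sub-threshold dips shorter than `max_gap_ms`.
#'
#' @param trace a `rate_trace`.
#' @param threshold rate threshold in Hz.
#' @param params a [det_params()] list.
#' @return onset time in ms, or `NA` if no qualifying crossing.
#' @export
first_crossing <- function(trace, threshold, params = det_params()) {
  keep <- trace$t >= params$onset_search[1]
  t <- trace$t[keep]
  above <- trace$hz[keep] > threshold
  if (!any(above)) return(NA_real_)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  iab <- which(r$values)
  # merge above-runs separated by below-runs shorter than max_gap_ms
  m_start <- m_end <- integer(0)
  i <- 1
  while (i <= length(iab)) {
    s <- starts[iab[i]]; e <- ends[iab[i]]
    while (i < length(iab) &&
           (starts[iab[i + 1]] - e - 1) < params$max_gap_ms) {
      i <- i + 1
      e <- ends[iab[i]]
    }
    m_start <- c(m_start, s); m_end <- c(m_end, e)
    i <- i + 1
  }
  dur <- m_end - m_start + 1
  ok <- which(dur >= params$min_dur_ms & t[m_start] < params$onset_search[2])
  if (!length(ok)) return(NA_real_)
  t[m_start[ok[1]]]
}

# One-sided paired sign test (post > baseline), ties dropped.
paired_sign_test <- function(post, base) {
  d <- post - base
  d <- d[d != 0]
  if (!length(d)) return(1)
  stats::pbinom(sum(d > 0) - 1, length(d), 0.5, lower.tail = FALSE)
}

#' Detect a response of one unit to one stimulus
#'
#' Applies the three-part responsiveness criterion: (i) the trial-averaged
#' instantaneous rate must exceed the session threshold for at least 75 ms
#' (dips < 20 ms disregarded), the first upward crossing defining the onset
#' `t_THR`; (ii) the median spike count across trials in a 500 ms window from
#' `t_THR` must be at least 2 and larger than the mean plus 5 SD (across
#' stimuli) of the baseline medians; (iii) a one-sided paired sign test of
#' post-onset versus baseline counts must give p < 0.01.
#'
#' @param session a `session`.
#' @param unit_id,stimulus_id identifiers.
#' @param params a [det_params()] list.
#' @param context optional precomputed list from [detection_context()]; pass
#'   it when testing many stimuli of the same unit.
#' @return one-row data.frame (onset, strength, baseline, p-value, threshold)
#'   or `NULL` when any criterion fails.
#' @export
detect_response <- function(session, unit_id, stimulus_id,
                            params = det_params(), context = NULL) {
  if (is.null(context)) context <- detection_context(session, unit_id, params)
  trains <- context$trains[[as.character(stimulus_id)]]
  if (length(trains) < params$min_trials)
    stop("detect_response(): fewer than min_trials (", params$min_trials,
         ") trials for stimulus ", stimulus_id)
  onset <- first_crossing(context$traces[[as.character(stimulus_id)]],
                          context$threshold, params)
  if (is.na(onset)) return(NULL)
  w <- c(onset, onset + params$count_window_ms)
  post <- vapply(trains, count_in_window, numeric(1), window = w)
  med <- stats::median(post)
  if (med < params$min_median) return(NULL)
  if (med <= context$base_mean + params$base_sd * context$base_sd_val) return(NULL)
  base <- vapply(trains, count_in_window, numeric(1), window = params$base_window)
  p <- paired_sign_test(post, base)
  if (p >= params$alpha) return(NULL)
  data.frame(unit_id = unit_id, stimulus_id = stimulus_id,
             onset_ms = onset,
             strength_hz = response_strength_counts(
               vapply(trains, count_in_window, numeric(1),
                      window = c(onset, onset + 700))),
             baseline_hz = baseline_strength(session, unit_id),
             p_sign = p, threshold_hz = context$threshold,
             n_trials = length(trains))
}

#' Precompute per-unit detection context
#'
#' Spike trains, per-stimulus rate traces, the pooled rate threshold and the
#' across-stimuli baseline-count statistics for one unit.
#'
#' @inheritParams detect_response
#' @return list used by [detect_response()].
#' @export
detection_context <- function(session, unit_id, params = det_params()) {
  stim_ids <- session$stimuli$stimulus_id
  trains <- lapply(stim_ids, function(s) spike_trains(session, unit_id, s))
  names(trains) <- stim_ids
  traces <- lapply(trains, instantaneous_rate, sigma_ms = params$sigma_ms)
  thr <- response_threshold(traces, params)
  base_meds <- vapply(trains, function(tr) {
    stats::median(vapply(tr, count_in_window, numeric(1),
                         window = params$base_window))
  }, numeric(1))
  list(trains = trains, traces = traces, threshold = thr,
       base_mean = mean(base_meds), base_sd_val = stats::sd(base_meds))
}

#' Detect all responses in a session
#'
#' @param session a `session`.
#' @param unit_ids units to scan (default all).
#' @param params a [det_params()] list.
#' @return data.frame with one row per significant (unit, stimulus) response,
#'   plus `n_responses` (responses of that unit) and `quality` flag.
#' @export
detect_responses <- function(session, unit_ids = NULL, params = det_params()) {
  if (is.null(unit_ids)) unit_ids <- session$units$unit_id
  rows <- list()
  for (u in unit_ids) {
    ctx <- detection_context(session, u, params)
    for (s in session$stimuli$stimulus_id) {
      r <- detect_response(session, u, s, params, context = ctx)
      if (!is.null(r)) rows[[length(rows) + 1]] <- r
    }
  }
  if (!length(rows)) {
    return(data.frame(unit_id = integer(), stimulus_id = integer(),
                      onset_ms = numeric(), strength_hz = numeric(),
                      baseline_hz = numeric(), p_sign = numeric(),
                      threshold_hz = numeric(), n_trials = integer(),
                      n_responses = integer(), quality = character()))
  }
  out <- do.call(rbind, rows)
  out$n_responses <- ave(out$unit_id, out$unit_id, FUN = length)
  out$quality <- vapply(out$unit_id, function(u) flag_unit_quality(session, u),
                        character(1))
  rownames(out) <- NULL
  out
}
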