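# Strength quantification: median spike count across trials in a window,
# normalized by the window length (Hz).

# Counts -> Hz given the default 700 ms strength window.
response_strength_counts <- function(counts, window_s = 0.7) {
  stats::median(counts) / window_s
}

#' Strength of one response
#'
#' Median spike count across trials in a 700 ms window starting at the
#' response onset, divided by the window length.
#'
#' @param session a `session`.
#' @param unit_id,stimulus_id identifiers.
#' @param onset_ms response onset (`t_THR`) in ms.
#' @param window_ms window length, default 700.
#' @param use_mean compute the mean count instead of the median (used by the
#'   correlation and population analyses, where the median gives overly
#'   discrete values).
#' @return strength in Hz.
#' @export
response_strength <- function(session, unit_id, stimulus_id, onset_ms,
                              window_ms = 700, use_mean = FALSE) {
  counts <- spike_counts(session, unit_id, stimulus_id,
                         c(onset_ms, onset_ms + window_ms))
  f <- if (use_mean) mean else stats::median
  f(counts) / (window_ms / 1000)
}

#' Baseline strength of a unit
#'
#' Median spike count over all trials of all stimuli in the pre-stimulus
#' window from -1000 to -300 ms, divided by the window length.
#'
#' @param session a `session`.
#' @param unit_id unit.
#' @param window baseline window, default `c(-1000, -300)` ms.
#' @param use_mean use the mean instead of the median.
#' @return baseline strength in Hz.
#' @export
baseline_strength <- function(session, unit_id, window = c(-1000, -300),
                              use_mean = FALSE) {
  counts <- unlist(lapply(session$stimuli$stimulus_id, function(s)
    spike_counts(session, unit_id, s, window)), use.names = FALSE)
  f <- if (use_mean) mean else stats::median
  f(counts) / ((window[2] - window[1]) / 1000)
}

#' Pooled strength over a unit's multiple responses
#'
#' Pools the trials of all stimuli eliciting a significant response and takes
#' the median count in a 700 ms window starting at the minimum response onset.
#'
#' @param session a `session`.
#' @param unit_id unit.
#' @param responses data.frame (as from [detect_responses()]) with at least
#'   `unit_id`, `stimulus_id`, `onset_ms`; must contain >= 2 responses for
#'   this unit.
#' @param window_ms window length, default 700.
#' @return pooled strength in Hz.
#' @export
pooled_strength <- function(session, unit_id, responses, window_ms = 700) {
  r <- responses[responses$unit_id == unit_id, , drop = FALSE]
  if (nrow(r) < 2) stop("pooled_strength() needs >= 2 responsive stimuli")
  onset <- min(r$onset_ms)
  counts <- unlist(lapply(r$stimulus_id, function(s)
    spike_counts(session, unit_id, s, c(onset, onset + window_ms))),
    use.names = FALSE)
  stats::median(counts) / (window_ms / 1000)
}

#' Normalized strength profile of a unit across all stimuli
#'
#' Per-stimulus median spike count between 100 and 800 ms after onset,
#' corrected by the mean baseline (across all stimuli) and normalized by the
#' maximum across stimuli; stimuli with activity below baseline get strength
#' zero.
#'
#' @param session a `session`.
#' @param unit_id unit.
#' @param window response window, default `c(100, 800)` ms.
#' @param base_window baseline window, default `c(-1000, -300)` ms.
#' @return named numeric vector in `[0, 1]` (names are stimulus ids), with
#'   maximum exactly 1.
#' @export
normalized_strength_profile <- function(session, unit_id,
                                        window = c(100, 800),
                                        base_window = c(-1000, -300)) {
  stim_ids <- session$stimuli$stimulus_id
  med <- vapply(stim_ids, function(s)
    stats::median(spike_counts(session, unit_id, s, window)), numeric(1))
  base <- vapply(stim_ids, function(s)
    stats::median(spike_counts(session, unit_id, s, base_window)), numeric(1))
  corr <- pmax(med - mean(base), 0)
  m <- max(corr)
  if (m == 0)
    stop("normalized_strength_profile(): no stimulus with activity above baseline")
  out <- corr / m
  names(out) <- stim_ids
  out
}
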