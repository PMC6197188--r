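# Spike-LFP theta phase locking: instantaneous phase at spike times, the
# phase-locking index (mean resultant length), Rayleigh significance, and a
# trial-shuffle surrogate test.

#' Length of half a theta cycle, in ms
#'
#' Half a period of the mid frequency of the theta band; with the default
#' 3-6 Hz band the midpoint is 4.5 Hz and the window is 111 ms. Used as the
#' epoch length of the phase-locking analysis.
#'
#' @param band theta band in Hz, default `c(3, 6)`.
#' @return window length in ms (rounded).
#' @export
theta_halfcycle_ms <- function(band = c(3, 6)) {
  round(1000 / (2 * mean(band)))
}

#' Instantaneous theta phase at spike times
#'
#' Evaluates the Hilbert phase of each trial's theta trace at that trial's
#' spike times inside the window and pools the phases across trials
#' (0 deg = oscillation peak, +/-180 deg = trough).
#'
#' @param trains list of per-trial spike-time vectors (ms), aligned with the
#'   rows of `theta`.
#' @param theta matrix of theta-filtered single-trial traces (rows = trials).
#' @param fs sampling rate in Hz.
#' @param t0_ms time of the first sample.
#' @param window half-open window `[a, b)` in ms.
#' @return numeric vector of phases in degrees; attribute `n_skipped` counts
#'   spikes outside the trace extent.
#' @export
spike_phases <- function(trains, theta, fs, t0_ms = -1000, window) {
  stopifnot(length(trains) == nrow(theta))
  n <- ncol(theta)
  out <- numeric(0); skipped <- 0L
  for (i in seq_along(trains)) {
    ts <- trains[[i]]
    ts <- ts[ts >= window[1] & ts < window[2]]
    if (!length(ts)) next
    idx <- round((ts - t0_ms) * fs / 1000) + 1
    ok <- idx >= 1 & idx <= n
    skipped <- skipped + sum(!ok)
    if (any(ok)) {
      ph <- instantaneous_phase(theta[i, ])
      out <- c(out, ph[idx[ok]])
    }
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Phase locking of one response, baseline and response epochs
#'
#' Both epochs are half a theta cycle long (~111 ms with the 3-6 Hz band):
#' the response epoch starts at the spike response latency; the baseline
#' epoch sits at a fixed position in the pre-stimulus period and, to gather
#' enough spikes, pools the trials from all stimuli. Epochs with fewer than
#' `min_spikes` pooled spikes are returned as `NULL`.
#'
#' @param resp_trains,resp_theta spike trains and theta trials (matrix rows
#'   aligned to trains) of the response's stimulus.
#' @param onset_ms spike response latency (ms).
#' @param fs sampling rate in Hz.
#' @param t0_ms time of the first sample.
#' @param base_trains,base_theta spike trains and theta trials pooled over
#'   all stimuli (defaults: the response's own stimulus only).
#' @param band theta band in Hz.
#' @param baseline_start_ms start of the baseline epoch, default -500 ms.
#' @param min_spikes minimum pooled spikes per epoch, default 20.
#' @return list with elements `baseline` and `response`; each is `NULL` or a
#'   list with `n`, `pli`, `mean_deg`, `rayleigh_p`, `window`.
#' @export
phase_lock <- function(resp_trains, resp_theta, onset_ms, fs, t0_ms = -1000,
                       base_trains = resp_trains, base_theta = resp_theta,
                       band = c(3, 6), baseline_start_ms = -500,
                       min_spikes = 20) {
  w <- theta_halfcycle_ms(band)
  epoch <- function(trains, theta, window) {
    ph <- spike_phases(trains, theta, fs, t0_ms, window)
    if (length(ph) < min_spikes) return(NULL)
    r <- mean_resultant(ph)
    list(n = r$n, pli = r$pli, mean_deg = r$mean_deg,
         rayleigh_p = rayleigh_test(ph)$p, window = window, phases = ph)
  }
  list(baseline = epoch(base_trains, base_theta,
                        c(baseline_start_ms, baseline_start_ms + w)),
       response = epoch(resp_trains, resp_theta, c(onset_ms, onset_ms + w)))
}

#' Trial-shuffle surrogate test of a phase-locking index
#'
#' Keeps every spike time unchanged but permutes the assignment of trials to
#' single-trial LFP traces before re-reading the phases, so each surrogate
#' PLI uses the same number of phases as the observed one.
#'
#' @param trains list of per-trial spike-time vectors (>= 2 trials).
#' @param theta matrix of theta trials aligned with `trains`.
#' @param fs sampling rate in Hz.
#' @param t0_ms time of the first sample.
#' @param window epoch `[a, b)` in ms.
#' @param n_surr number of shuffles.
#' @param seed optional integer seed.
#' @return a `perm_result` (observed PLI vs shuffled PLIs, add-one p).
#' @export
surrogate_pli <- function(trains, theta, fs, t0_ms = -1000, window,
                          n_surr = 1000, seed = NULL) {
  if (length(trains) < 2)
    stop("surrogate_pli(): trial shuffling needs >= 2 trials")
  if (!is.null(seed)) set.seed(seed)
  # cache per-trial phase traces once
  ph_tr <- t(apply(theta, 1, instantaneous_phase))
  idx_of <- function(perm) {
    out <- numeric(0)
    for (i in seq_along(trains)) {
      ts <- trains[[i]]
      ts <- ts[ts >= window[1] & ts < window[2]]
      if (!length(ts)) next
      idx <- round((ts - t0_ms) * fs / 1000) + 1
      idx <- idx[idx >= 1 & idx <= ncol(theta)]
      if (length(idx)) out <- c(out, ph_tr[perm[i], idx])
    }
    out
  }
  obs_ph <- idx_of(seq_along(trains))
  if (length(obs_ph) < 2) stop("surrogate_pli(): too few spikes in window")
  obs <- mean_resultant(obs_ph)$pli
  surr <- vapply(seq_len(n_surr), function(b)
    mean_resultant(idx_of(sample(length(trains))))$pli, numeric(1))
  new_perm_result(obs, surr, perm_pvalue(obs, surr), seed)
}

#' Angular difference between the preferred phases of a response pair
#'
#' @param mean_i_deg,mean_j_deg circular means of the two responses, degrees.
#' @return wrapped absolute difference in `[0, 180]`.
#' @export
pair_phase_diff <- function(mean_i_deg, mean_j_deg) {
  circ_diff_deg(mean_i_deg, mean_j_deg)
}
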