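# Shared numeric helpers. Time is always in ms relative to stimulus onset and
# windows are half-open [a, b) so a boundary spike is never counted twice.

#' Count spikes in a half-open time window
#'
#' @param times numeric vector of spike times (ms relative to onset).
#' @param window length-2 numeric, window `[a, b)` in ms.
#' @return integer count.
#' @keywords internal
count_in_window <- function(times, window) {
  sum(times >= window[1] & times < window[2])
}

#' Per-trial spike counts for one (unit, stimulus) in a window
#'
#' @param session a `session` object.
#' @param unit_id,stimulus_id identifiers.
#' @param window half-open window `[a, b)` in ms.
#' @return integer vector, one count per trial (in trial order).
#' @export
spike_counts <- function(session, unit_id, stimulus_id, window) {
  trains <- spike_trains(session, unit_id, stimulus_id)
  vapply(trains, count_in_window, integer(1) + 0, window = window)
}

#' Spike times split by trial for one (unit, stimulus)
#'
#' @inheritParams spike_counts
#' @return named list of numeric vectors, one per trial index (all trials of
#'   the stimulus, including empty ones).
#' @export
spike_trains <- function(session, unit_id, stimulus_id) {
  tr <- session$trials[session$trials$stimulus_id == stimulus_id, , drop = FALSE]
  sp <- session$spikes[session$spikes$unit_id == unit_id &
                         session$spikes$stimulus_id == stimulus_id, , drop = FALSE]
  out <- lapply(sort(tr$trial_index), function(k) {
    sort(sp$time_ms[sp$trial_index == k])
  })
  names(out) <- sort(tr$trial_index)
  out
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns the complex analytic signal `x + i H(x)`; its modulus is the
#' instantaneous amplitude and its argument the instantaneous phase.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a theta-band trace, in degrees
#'
#' Convention: 0 deg at the oscillation peak, +/-180 deg at the trough, and
#' phase increasing with time (so an upward zero-crossing sits at -90 deg).
#'
#' @param x real numeric vector (band-limited trace).
#' @return numeric vector of phases in degrees, in (-180, 180].
#' @export
instantaneous_phase <- function(x) {
  ph <- Arg(analytic_signal(x)) * 180 / pi
  ph[ph <= -180] <- ph[ph <= -180] + 360
  ph
}

## ---- circular statistics (degrees) ----

#' Mean resultant vector of circular data
#'
#' @param phases_deg numeric vector of angles in degrees.
#' @return list with `pli` (resultant length, in `[0, 1]`), `mean_deg`
#'   (circular mean in `(-180, 180]`, `NA` when the resultant length is 0)
#'   and `n`.
#' @export
mean_resultant <- function(phases_deg) {
  stopifnot(length(phases_deg) >= 1)
  z <- mean(exp(1i * phases_deg * pi / 180))
  r <- Mod(z)
  mu <- if (r > .Machine$double.eps^0.5) Arg(z) * 180 / pi else NA_real_
  if (!is.na(mu) && mu <= -180) mu <- mu + 360
  list(pli = r, mean_deg = mu, n = length(phases_deg))
}

#' Rayleigh test of circular uniformity
#'
#' Finite-sample approximation to the p-value of the Rayleigh statistic
#' `Z = n * R^2` against a unimodal alternative.
#'
#' @param phases_deg numeric vector of angles in degrees (n >= 2).
#' @return list with `pli`, `z` and `p`.
#' @export
rayleigh_test <- function(phases_deg) {
  n <- length(phases_deg)
  stopifnot(n >= 2)
  r <- mean_resultant(phases_deg)$pli
  z <- n * r^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * r)^2)) - (1 + 2 * n))
  list(pli = r, z = z, p = min(1, p))
}

#' Absolute circular difference between two angles
#'
#' @param a_deg,b_deg angles in degrees.
#' @return wrapped absolute difference in `[0, 180]`.
#' @export
circ_diff_deg <- function(a_deg, b_deg) {
  d <- abs(((a_deg - b_deg + 180) %% 360) - 180)
  d
}

#' Z-score a column within a session
#'
#' @param x numeric vector with at least two non-missing, non-constant values.
#' @return `(x - mean) / sd`, computed over non-missing entries.
#' @export
session_zscore <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("session_zscore() needs at least 2 non-missing values")
  s <- stats::sd(x[ok])
  if (s == 0) stop("session_zscore(): column is constant")
  (x - mean(x[ok])) / s
}

# Add-one permutation p-value: rank of the observed statistic among surrogates.
perm_pvalue <- function(observed, surrogates, tail = c("greater", "less")) {
  tail <- match.arg(tail)
  k <- if (tail == "greater") sum(surrogates >= observed) else sum(surrogates <= observed)
  (1 + k) / (1 + length(surrogates))
}

# von Mises density ratio helpers used by the generator and the PLI oracle.
besselI0 <- function(kappa) besselI(kappa, 0)
besselI1 <- function(kappa) besselI(kappa, 1)

#' Expected resultant length of a von Mises sample
#'
#' Closed form `I1(kappa) / I0(kappa)`; the large-n limit of the empirical
#' phase-locking index for von Mises distributed phases.
#'
#' @param kappa concentration parameter, `>= 0`.
#' @return numeric in `[0, 1)`.
#' @export
vonmises_pli <- function(kappa) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(0)
  besselI1(kappa) / besselI0(kappa)
}
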