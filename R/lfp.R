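# LFP preprocessing, theta evoked power, latency estimation and the
# latency-corrected grand average.
#
# Filters: 4th-order elliptic band-pass (0.1 dB passband ripple, 40 dB
# stopband), applied forward-backward for zero phase; 2nd-order IIR notches
# at the line frequency and its harmonics; a zero-phase Butterworth
# anti-alias stage before integer-factor downsampling.

.fcache <- new.env(parent = emptyenv())

# Elliptic band-pass designed in zero-pole-gain form and factored into
# second-order sections. The narrow theta band (3-6 Hz at 1500 Hz) makes the
# expanded transfer-function polynomial numerically unstable, so the filter
# is kept as a biquad cascade.
ellip_design <- function(fs, band, n = 4, Rp = 0.1, Rs = 40) {
  key <- sprintf("e_%g_%g_%g", fs, band[1], band[2])
  if (is.null(.fcache[[key]])) {
    W <- tan(pi * band / fs)                     # prewarped analog edges (T = 2)
    zpg <- signal::bilinear(
      signal::sftrans(signal:::ncauer(Rp, Rs, n), W = W, stop = FALSE), T = 2)
    .fcache[[key]] <- zpg_to_sos(zpg)
  }
  .fcache[[key]]
}

# Factor a Zpg into real biquads (conjugate pole/zero pairs matched by
# angle); the overall gain is folded into the first section.
zpg_to_sos <- function(zpg) {
  pair_up <- function(r) {
    r <- r[order(abs(Arg(r)), Im(r))]
    got <- logical(length(r)); out <- list()
    for (i in seq_along(r)) {
      if (got[i]) next
      j <- which(!got & seq_along(r) > i &
                   abs(r - Conj(r[i])) < 1e-8 * (1 + abs(r[i])))[1]
      if (is.na(j)) {  # real root: pair with the nearest remaining real root
        j <- which(!got & seq_along(r) > i & abs(Im(r)) < 1e-8)[1]
      }
      got[c(i, j)] <- TRUE
      out[[length(out) + 1]] <- c(r[i], r[j])
    }
    out
  }
  zp <- pair_up(zpg$zero)
  pp <- pair_up(zpg$pole)
  stopifnot(length(zp) == length(pp))
  sos <- lapply(seq_along(pp), function(k) {
    b <- Re(c(1, -(zp[[k]][1] + zp[[k]][2]), zp[[k]][1] * zp[[k]][2]))
    a <- Re(c(1, -(pp[[k]][1] + pp[[k]][2]), pp[[k]][1] * pp[[k]][2]))
    signal::Arma(b = b, a = a)
  })
  sos[[1]]$b <- sos[[1]]$b * Re(zpg$gain)
  sos
}

# Odd-reflection padding: continuous in value and slope at both edges, which
# suppresses the start-up transient of zero-phase IIR filtering.
reflect_pad <- function(x, p) {
  n <- length(x)
  p <- min(p, n - 1)
  c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
}

# Zero-phase application of a biquad cascade (or a single Arma filter),
# with optional reflection padding (in samples).
filtfilt_sos <- function(flt, x, pad = 0) {
  n <- length(x)
  if (pad > 0) x <- reflect_pad(x, pad)
  p <- length(x) - n
  if (inherits(flt, "Arma")) x <- signal::filtfilt(flt, x)
  else for (s in flt) x <- signal::filtfilt(s, x)
  if (p > 0) x[(p / 2 + 1):(p / 2 + n)] else x
}

# RBJ-style biquad notch at f0 with the given -3 dB bandwidth.
notch_design <- function(fs, f0, bw = 4) {
  key <- sprintf("n_%g_%g_%g", fs, f0, bw)
  if (is.null(.fcache[[key]])) {
    w0 <- 2 * pi * f0 / fs
    alpha <- sin(w0) * sinh(log(2) / 2 * (bw / f0) * w0 / sin(w0))
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    .fcache[[key]] <- signal::Arma(b = b / a[1], a = a / a[1])
  }
  .fcache[[key]]
}

butter_design <- function(fs, cutoff) {
  key <- sprintf("b_%g_%g", fs, cutoff)
  if (is.null(.fcache[[key]]))
    .fcache[[key]] <- signal::butter(4, cutoff / (fs / 2), type = "low")
  .fcache[[key]]
}

apply_rows <- function(x, f) {
  if (is.matrix(x)) t(apply(x, 1, f)) else f(x)
}

#' Preprocess raw wideband LFP trials
#'
#' Band-pass 2-512 Hz (zero-phase elliptic), notch the line frequency and
#' its harmonics (2nd-order IIR), then downsample to `fs_out` after a
#' zero-phase anti-alias stage. The raw rate must exceed twice the upper
#' band edge and be an integer multiple of `fs_out`.
#'
#' @param x numeric vector or matrix (rows = trials) of raw samples.
#' @param fs raw sampling rate in Hz.
#' @param fs_out output rate, default 1500 Hz.
#' @param band pass band in Hz, default `c(2, 512)`.
#' @param line_hz line frequency, default 50; harmonics up to 500 Hz are
#'   notched. Use `NULL` to skip notching.
#' @return vector or matrix of cleaned trials at `fs_out`.
#' @export
lfp_preprocess <- function(x, fs, fs_out = 1500, band = c(2, 512),
                           line_hz = 50) {
  if (fs < 2 * band[2])
    stop("lfp_preprocess(): sampling rate below twice the upper band edge")
  q <- fs / fs_out
  if (abs(q - round(q)) > 1e-9)
    stop("lfp_preprocess(): fs must be an integer multiple of fs_out")
  q <- round(q)
  bp <- ellip_design(fs, band)
  notches <- if (is.null(line_hz)) list() else
    lapply(seq(line_hz, min(500, fs / 2 - 1), by = line_hz),
           function(f0) notch_design(fs, f0))
  aa <- if (q > 1) butter_design(fs, 0.4 * fs_out) else NULL
  pad <- q * ceiling(0.5 * fs / q)       # 0.5 s reflection pad, multiple of q
  clean1 <- function(v) {
    n <- length(v)
    v <- reflect_pad(v, pad)
    v <- filtfilt_sos(bp, v)
    for (nf in notches) v <- signal::filtfilt(nf, v)
    if (q > 1) {
      v <- signal::filtfilt(aa, v)
      v <- v[seq(1, length(v), by = q)]
      v[(pad / q + 1):(pad / q + n / q)]
    } else v[(pad + 1):(pad + n)]
  }
  apply_rows(x, clean1)
}

# Mean power of each trial row in a frequency band, via the periodogram.
band_power <- function(x, fs, band) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- freqs >= band[1] & freqs <= band[2]
  mean(apply(x, 1, function(v) mean(Mod(stats::fft(v))[sel]^2 / n)))
}

#' Screen LFP channels for high-frequency noise
#'
#' Discards channels whose mean power in the high band exceeds a multiple of
#' the session median across channels (an automated stand-in for visual
#' power-spectrum inspection).
#'
#' @param trials_by_channel named list of trial matrices (rows = trials),
#'   all at the same sampling rate.
#' @param fs sampling rate in Hz.
#' @param band high-frequency band, default `c(300, 512)` Hz.
#' @param factor discard multiple, default 10.
#' @return named logical vector: `TRUE` = keep.
#' @export
screen_channels <- function(trials_by_channel, fs, band = c(300, 512),
                            factor = 10) {
  p <- vapply(trials_by_channel, band_power, numeric(1), fs = fs, band = band)
  if (length(p) == 1) {
    warning("screen_channels(): single channel, kept by default")
    return(stats::setNames(TRUE, names(p)))
  }
  keep <- p <= factor * stats::median(p)
  stats::setNames(keep, names(trials_by_channel))
}

#' Theta-band filter
#'
#' @param x vector or matrix (rows = trials).
#' @param fs sampling rate in Hz.
#' @param band theta band, default `c(3, 6)` Hz.
#' @return filtered trace(s), zero phase.
#' @export
theta_filter <- function(x, fs, band = c(3, 6)) {
  f <- ellip_design(fs, band)
  pad <- round(fs)       # 1 s reflection pad: the 3 Hz corner rings long
  apply_rows(x, function(v) filtfilt_sos(f, v, pad = pad))
}

#' Theta-filtered, per-trial RMS-normalized LFP trials
#'
#' Each trial is filtered to the theta band and divided by the root mean
#' square of its post-stimulus segment (0-1000 ms). Trials with zero RMS are
#' excluded with a warning.
#'
#' @param trials matrix of cleaned trials (rows = trials).
#' @param fs sampling rate in Hz.
#' @param t0_ms time of the first sample, default -1000.
#' @param band theta band.
#' @param norm_window normalization window in ms, default `c(0, 1000)`.
#' @return matrix of normalized theta trials; attribute `excluded` lists
#'   dropped row indices.
#' @export
theta_trials <- function(trials, fs, t0_ms = -1000, band = c(3, 6),
                         norm_window = c(0, 1000)) {
  th <- theta_filter(trials, fs, band)
  if (!is.matrix(th)) th <- matrix(th, nrow = 1)
  t_ms <- t0_ms + (seq_len(ncol(th)) - 1) / fs * 1000
  sel <- t_ms >= norm_window[1] & t_ms < norm_window[2]
  if (!is.matrix(trials)) trials <- matrix(trials, nrow = 1)
  rms <- sqrt(rowMeans(th[, sel, drop = FALSE]^2))
  rms_raw <- sqrt(rowMeans(trials[, sel, drop = FALSE]^2))
  # a trial whose theta content is < 1% of its broadband RMS (e.g. DC only)
  # carries no usable phase information
  bad <- which(rms == 0 | rms < 0.01 * rms_raw)
  if (length(bad)) {
    warning("theta_trials(): excluding ", length(bad), " trial(s) with zero RMS")
    th <- th[-bad, , drop = FALSE]
    rms <- rms[-bad]
  }
  out <- th / rms
  attr(out, "excluded") <- bad
  out
}

#' Theta evoked power, onset and peak latency per stimulus
#'
#' The instantaneous power is the squared magnitude of the analytic signal
#' of the trial-averaged theta trace. The onset threshold is the median plus
#' `thr_mad` mean absolute deviations of the power, pooled across all
#' stimuli over the pre-stimulus baseline; the onset is the first
#' supra-threshold time in the search window (absent if none) and the peak
#' is the power argmax in the same window.
#'
#' @param theta_by_stimulus named list (names = stimulus ids) of normalized
#'   theta trial matrices, >= 10 trials each.
#' @param fs sampling rate in Hz.
#' @param t0_ms time of the first sample, default -1000.
#' @param thr_mad number of mean absolute deviations above the median.
#' @param baseline baseline window in ms, default `c(-900, -100)`.
#' @param search onset/peak search window in ms, default `c(0, 700)`.
#' @return list with `latencies` (data.frame `stimulus_id`, `onset_ms`,
#'   `peak_ms`), `power` (list of power traces), `avg` (list of average
#'   theta traces), `threshold`, `t_ms`.
#' @export
evoked_lfp <- function(theta_by_stimulus, fs, t0_ms = -1000, thr_mad = 4,
                       baseline = c(-900, -100), search = c(0, 700)) {
  stopifnot(length(theta_by_stimulus) >= 1)
  n_tr <- vapply(theta_by_stimulus, nrow, integer(1))
  if (any(n_tr < 10)) stop("evoked_lfp() needs >= 10 trials per stimulus")
  avg <- lapply(theta_by_stimulus, colMeans)
  pow <- lapply(avg, function(a) Mod(analytic_signal(a))^2)
  t_ms <- t0_ms + (seq_along(avg[[1]]) - 1) / fs * 1000
  bsel <- t_ms >= baseline[1] & t_ms < baseline[2]
  bs <- unlist(lapply(pow, function(p) p[bsel]), use.names = FALSE)
  mad_mean <- mean(abs(bs - stats::median(bs)))
  thr <- stats::median(bs) + thr_mad * mad_mean
  ssel <- which(t_ms >= search[1] & t_ms <= search[2])
  lat <- do.call(rbind, lapply(names(pow), function(s) {
    p <- pow[[s]][ssel]
    onset <- if (mad_mean == 0) NA_real_ else {
      i <- which(p > thr)[1]
      if (is.na(i)) NA_real_ else t_ms[ssel[i]]
    }
    data.frame(stimulus_id = s, onset_ms = onset,
               peak_ms = t_ms[ssel[which.max(p)]])
  }))
  list(latencies = lat, power = pow, avg = avg, threshold = thr, t_ms = t_ms,
       zero_mad = mad_mean == 0)
}

#' Latency-corrected grand average of LFP power (or rate) traces
#'
#' Each trace is normalized by the area below its curve, shifted so that its
#' spike latency maps to time 0, and averaged. Also splits the responses
#' into early and late halves by the median spike latency and compares the
#' LFP peak latencies of the two halves with a one-sided rank-sum test.
#'
#' @param traces matrix, one row per response, on a common time grid.
#' @param spike_latencies_ms spike response onsets, one per row.
#' @param fs sampling rate in Hz.
#' @param t0_ms time of the first sample.
#' @param search window (ms, stimulus-locked) in which each trace's peak
#'   latency is measured for the early/late comparison.
#' @return list with `t_ms` (relative to the spike latency), `grand_avg`,
#'   `early_avg`, `late_avg`, `median_latency_ms`, `peak_ms` (per response,
#'   stimulus-locked) and `split_p`.
#' @export
latency_corrected_average <- function(traces, spike_latencies_ms, fs,
                                      t0_ms = -1000, search = c(0, 700)) {
  stopifnot(nrow(traces) == length(spike_latencies_ms), nrow(traces) >= 2)
  dt <- 1000 / fs
  n <- ncol(traces)
  t_ms <- t0_ms + (seq_len(n) - 1) * dt
  area <- rowSums(traces) * dt
  norm <- traces / area
  shifts <- round(spike_latencies_ms / dt)
  width <- n + max(shifts) - min(shifts)
  acc <- matrix(NA_real_, nrow(traces), width)
  for (i in seq_len(nrow(traces))) {
    off <- max(shifts) - shifts[i]
    acc[i, off + seq_len(n)] <- norm[i, ]
  }
  t_out <- (seq_len(width) - 1 - max(shifts)) * dt + t0_ms
  med <- stats::median(spike_latencies_ms)
  early <- spike_latencies_ms <= med
  ssel <- t_ms >= search[1] & t_ms <= search[2]
  peaks <- t_ms[ssel][apply(traces[, ssel, drop = FALSE], 1, which.max)]
  split_p <- if (sum(early) >= 2 && sum(!early) >= 2)
    stats::wilcox.test(peaks[early], peaks[!early],
                       alternative = "less", exact = FALSE)$p.value
  else NA_real_
  list(t_ms = t_out, grand_avg = colMeans(acc, na.rm = TRUE),
       early_avg = colMeans(acc[early, , drop = FALSE], na.rm = TRUE),
       late_avg = colMeans(acc[!early, , drop = FALSE], na.rm = TRUE),
       median_latency_ms = med, peak_ms = peaks, split_p = split_p)
}

#' Permutation test for an LFP peak-latency difference
#'
#' Statistic: absolute difference between the theta evoked-power peak
#' latencies of two stimuli, with the peak re-estimated for every surrogate
#' trial grouping (trial labels permuted across the two stimuli).
#'
#' @param theta_i,theta_j normalized theta trial matrices of the two stimuli.
#' @param fs sampling rate in Hz.
#' @param t0_ms time of the first sample.
#' @param n_surr number of surrogates.
#' @param seed optional integer seed.
#' @param search peak search window in ms, default `c(0, 700)`.
#' @return a `perm_result` with extra fields `peak_i`, `peak_j`.
#' @export
lfp_pair_latency_diff <- function(theta_i, theta_j, fs, t0_ms = -1000,
                                  n_surr = 1000, seed = NULL,
                                  search = c(0, 700)) {
  if (!is.null(seed)) set.seed(seed)
  ni <- nrow(theta_i)
  pool <- rbind(theta_i, theta_j)
  t_ms <- t0_ms + (seq_len(ncol(pool)) - 1) / fs * 1000
  ssel <- which(t_ms >= search[1] & t_ms <= search[2])
  peak_of <- function(rows) {
    p <- Mod(analytic_signal(colMeans(pool[rows, , drop = FALSE])))^2
    t_ms[ssel[which.max(p[ssel])]]
  }
  pi_ <- peak_of(seq_len(ni))
  pj <- peak_of(ni + seq_len(nrow(theta_j)))
  obs <- abs(pi_ - pj)
  surr <- vapply(seq_len(n_surr), function(b) {
    idx <- sample(nrow(pool))
    abs(peak_of(idx[seq_len(ni)]) - peak_of(idx[-seq_len(ni)]))
  }, numeric(1))
  new_perm_result(obs, surr, perm_pvalue(obs, surr), seed,
                  extra = list(peak_i = pi_, peak_j = pj))
}
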