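# Shared fixtures and independent oracles, all built in code.

# Minimal hand-built session: explicit spike times, no LFP.
tiny_session <- function(spikes, n_stimuli = 2, n_trials = 3,
                         waveforms = NULL, units = NULL, assoc = NULL) {
  stimuli <- data.frame(stimulus_id = seq_len(n_stimuli),
                        name = sprintf("s%d", seq_len(n_stimuli)),
                        category = "unknown")
  trials <- data.frame(stimulus_id = rep(seq_len(n_stimuli), each = n_trials),
                       trial_index = rep(seq_len(n_trials), n_stimuli))
  if (is.null(units))
    units <- data.frame(unit_id = unique(spikes$unit_id), channel_id = 1L)
  new_session(stimuli, trials, units, spikes, waveforms = waveforms,
              assoc = assoc)
}

# Poisson spike trains on [-1000, 2000) ms at a constant rate.
poisson_trains <- function(n_trials, rate_hz, t_range = c(-1000, 2000)) {
  span_s <- diff(t_range) / 1000
  lapply(seq_len(n_trials), function(i)
    sort(stats::runif(stats::rpois(1, span_s * rate_hz), t_range[1], t_range[2])))
}

# Exact von Mises sampler by rejection from the uniform (fine for kappa <= 4).
rvonmises <- function(n, mu_deg, kappa) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::runif(2 * n, -180, 180)
    acc <- stats::runif(length(cand)) <
      exp(kappa * (cos((cand - mu_deg) * pi / 180) - 1))
    out <- c(out, cand[acc])
  }
  out[seq_len(n)]
}

# Exhaustive-enumeration oracle for a two-group permutation p-value:
# proportion of all C(n, ni) label assignments whose statistic is >= the
# observed one (the observed labeling is one of them).
enum_perm_p <- function(x_i, x_j, stat) {
  pool <- c(x_i, x_j)
  ni <- length(x_i)
  obs <- stat(x_i, x_j)
  sel <- utils::combn(length(pool), ni)
  vals <- apply(sel, 2, function(ix) stat(pool[ix], pool[-ix]))
  mean(vals >= obs - 1e-12)
}

# Synthetic theta trials: cosine at f_hz with per-trial phase offsets, plus
# optional white noise; returns a trials x samples matrix.
cosine_trials <- function(n_trials, fs = 1500, t0_ms = 0, dur_ms = 500,
                          f_hz = 4.5, phase0_deg = NULL, noise_sd = 0) {
  n <- round(dur_ms / 1000 * fs)
  t_ms <- t0_ms + (seq_len(n) - 1) / fs * 1000
  if (is.null(phase0_deg)) phase0_deg <- stats::runif(n_trials, -180, 180)
  m <- t(vapply(phase0_deg, function(p0)
    cos((360 * f_hz * t_ms / 1000 + p0) * pi / 180), numeric(n)))
  if (noise_sd > 0) m <- m + matrix(stats::rnorm(length(m), 0, noise_sd),
                                    nrow = n_trials)
  attr(m, "t_ms") <- t_ms
  attr(m, "phase0_deg") <- phase0_deg
  m
}

# Waveform group: template + iid noise.
wf_group <- function(n, template, noise_sd = 1) {
  matrix(rep(template, each = n), nrow = n) +
    matrix(stats::rnorm(n * length(template), 0, noise_sd), nrow = n)
}
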