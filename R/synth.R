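# Seeded synthetic-session generator with known ground truth.
#
# Spiking is inhomogeneous Poisson: a constant baseline rate everywhere plus
# an added response rate inside [latency, latency + duration). LFP trials are
# 1/f background noise plus a phase-reset theta burst whose envelope starts
# `lead_ms` before the spike latency. During the response window, spike times
# are thinned against the von Mises density of the trial's theta phase, which
# controls phase concentration while preserving the marginal Poisson rate in
# expectation. Waveforms are a per-unit template plus i.i.d. Gaussian noise,
# and the association table is block-structured (high scores inside the
# configured stimulus groups, low outside).

#' Synthetic-session configuration
#'
#' @param n_stimuli number of pictures (default 15, as in a follow-up
#'   session).
#' @param n_trials presentations per picture (default 29, inside the 25-35
#'   range of the experimental protocol).
#' @param units data.frame with `unit_id`, `channel_id`, `baseline_hz`
#'   (low-rate Poisson baseline, about 1-10 Hz) and `wf_amp` (waveform peak,
#'   arbitrary units).
#' @param responses data.frame with `unit_id`, `stimulus_id`, `latency_ms`
#'   (in `[0, 1000)`), `duration_ms`, `rate_hz` (rate added on top of the
#'   baseline), `kappa` (von Mises concentration of spike phases) and
#'   `pref_phase_deg` (preferred theta phase).
#' @param lfp `NULL` to omit LFP, or a list with `theta_hz` (burst frequency,
#'   default 4.5 = the 3-6 Hz midpoint), `lead_ms` (how far the burst onset
#'   precedes the spike latency, default 70), `burst_amp`, `burst_dur_ms`,
#'   `noise_amp` (1/f background SD), `fs_raw` (raw sampling rate, Hz),
#'   `reset_jitter_deg` (SD of the per-trial phase jitter at burst onset;
#'   0 = perfect phase reset).
#' @param assoc_blocks list of integer vectors: groups of stimuli with high
#'   pairwise association scores.
#' @param assoc `NULL` to omit the association table, or a list with
#'   `a_in`/`a_out` (mean raw log2 association score inside/outside blocks)
#'   and `a_sd`.
#' @param wf_n waveform samples per spike (default 32).
#' @param wf_noise_sd waveform noise SD (default 5).
#' @param seed integer seed fixing all randomness.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_stimuli = 15, n_trials = 29,
                         units = data.frame(unit_id = 1L, channel_id = 1L,
                                            baseline_hz = 3, wf_amp = 100),
                         responses = data.frame(unit_id = integer(),
                                                stimulus_id = integer(),
                                                latency_ms = numeric(),
                                                duration_ms = numeric(),
                                                rate_hz = numeric(),
                                                kappa = numeric(),
                                                pref_phase_deg = numeric()),
                         lfp = NULL, assoc_blocks = list(), assoc = NULL,
                         wf_n = 32, wf_noise_sd = 5, seed = 1) {
  if (!is.null(lfp)) {
    defaults <- list(theta_hz = 4.5, lead_ms = 70, burst_amp = 4,
                     burst_dur_ms = 700, noise_amp = 10, fs_raw = 3000,
                     reset_jitter_deg = 20)
    lfp <- utils::modifyList(defaults, lfp)
  }
  cfg <- structure(list(n_stimuli = n_stimuli, n_trials = n_trials,
                        units = units, responses = responses, lfp = lfp,
                        assoc_blocks = assoc_blocks, assoc = assoc,
                        wf_n = wf_n, wf_noise_sd = wf_noise_sd, seed = seed),
                   class = "synth_config")
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  r <- cfg$responses
  if (nrow(r)) {
    stopifnot(all(r$rate_hz >= 0), all(r$kappa >= 0),
              all(r$latency_ms >= 0 & r$latency_ms < 1000))
    if (any(r$latency_ms + r$duration_ms > 2000))
      stop("config error: response window exceeds trial end (2000 ms)")
    if (!all(r$unit_id %in% cfg$units$unit_id))
      stop("config error: response references unknown unit")
    if (!all(r$stimulus_id %in% seq_len(cfg$n_stimuli)))
      stop("config error: response references unknown stimulus")
  }
  stopifnot(all(cfg$units$baseline_hz >= 0))
  cfg
}

#' Ground-truth table of a synthetic configuration
#'
#' @param config a [synth_config()].
#' @return data.frame with one row per configured response: true latency,
#'   total rate (baseline + response), duration, kappa, preferred phase, and
#'   the LFP burst onset (`latency - lead_ms`; `NA` without LFP).
#' @export
ground_truth <- function(config) {
  r <- config$responses
  if (!nrow(r)) {
    return(data.frame(unit_id = integer(), stimulus_id = integer(),
                      latency_ms = numeric(), duration_ms = numeric(),
                      rate_hz = numeric(), rate_eff_hz = numeric(),
                      baseline_hz = numeric(),
                      kappa = numeric(), pref_phase_deg = numeric(),
                      lfp_onset_ms = numeric()))
  }
  base <- config$units$baseline_hz[match(r$unit_id, config$units$unit_id)]
  # the 3 ms refractory dead time makes the realized response-window rate
  # 1 / (ref + 1/rate): the true mean rate of the dead-time renewal process
  tot <- base + r$rate_hz
  data.frame(unit_id = r$unit_id, stimulus_id = r$stimulus_id,
             latency_ms = r$latency_ms, duration_ms = r$duration_ms,
             rate_hz = tot, rate_eff_hz = 1 / (0.003 + 1 / tot),
             baseline_hz = base,
             kappa = r$kappa, pref_phase_deg = r$pref_phase_deg,
             lfp_onset_ms = if (is.null(config$lfp)) NA_real_ else
               r$latency_ms - config$lfp$lead_ms)
}

# Spike-waveform template: biphasic, peak amplitude 1 at around sample 9.
wf_template <- function(n) {
  i <- seq_len(n)
  w <- -exp(-(i - 9)^2 / 10) + 0.45 * exp(-(i - 20)^2 / 30)
  w / max(abs(w))
}

# 1/f background noise of length n with SD = amp, spectrally shaped from
# white noise with a fixed seed-dependent phase draw. The 1/f law is floored
# below floor_hz: the sub-2 Hz content of a real recording is removed by the
# acquisition/preprocessing chain before trials are epoched, and synthesizing
# it into 3 s epochs would only inject spurious edge energy into every
# narrowband filter downstream.
pink_noise <- function(n, amp, fs = n / 3, floor_hz = 2) {
  half <- floor(n / 2)
  f <- seq_len(half) * fs / n
  mag <- 1 / sqrt(pmax(f, floor_hz))
  ph <- stats::runif(half, 0, 2 * pi)
  X <- complex(modulus = mag, argument = ph)
  spec <- c(0, X, Conj(rev(X[seq_len(half - (n %% 2 == 0))])))
  spec <- spec[seq_len(n)]
  x <- Re(stats::fft(spec, inverse = TRUE))
  amp * x / stats::sd(x)
}

# Single units have a refractory period: drop any spike closer than ref_ms
# to the previous accepted spike (the expected loss at tens of Hz is tiny).
enforce_refractory <- function(times, ref_ms = 3) {
  if (length(times) < 2) return(times)
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= ref_ms) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

# Raised-cosine-edged burst envelope on a ms time axis.
burst_envelope <- function(t_ms, onset_ms, dur_ms, ramp_ms = 40) {
  e <- numeric(length(t_ms))
  up <- t_ms >= onset_ms & t_ms < onset_ms + ramp_ms
  on <- t_ms >= onset_ms + ramp_ms & t_ms < onset_ms + dur_ms - ramp_ms
  dn <- t_ms >= onset_ms + dur_ms - ramp_ms & t_ms < onset_ms + dur_ms
  e[up] <- 0.5 * (1 - cos(pi * (t_ms[up] - onset_ms) / ramp_ms))
  e[on] <- 1
  e[dn] <- 0.5 * (1 + cos(pi * (t_ms[dn] - (onset_ms + dur_ms - ramp_ms)) / ramp_ms))
  e
}

#' Generate a synthetic session
#'
#' @param config a [synth_config()].
#' @return a validated `session` with spikes, waveforms and (optionally) LFP
#'   traces and an association table consistent with [ground_truth()].
#' @export
generate_session <- function(config) {
  config <- validate_synth_config(config)
  set.seed(config$seed)
  ns <- config$n_stimuli; nt <- config$n_trials
  stimuli <- data.frame(stimulus_id = seq_len(ns),
                        name = sprintf("stim_%02d", seq_len(ns)),
                        category = rep(STIM_CATEGORIES, length.out = ns))
  trials <- data.frame(stimulus_id = rep(seq_len(ns), each = nt),
                       trial_index = rep(seq_len(nt), ns))
  units <- config$units[, c("unit_id", "channel_id")]
  lfp_cfg <- config$lfp

  # Per-trial theta phase offsets: phase at burst onset is -90 deg (rising
  # toward the peak) plus per-trial reset jitter.
  burst_tab <- NULL
  phase0 <- NULL
  if (!is.null(lfp_cfg)) {
    gt <- ground_truth(config)
    if (nrow(gt)) {
      ch <- config$units$channel_id[match(gt$unit_id, config$units$unit_id)]
      burst_tab <- stats::aggregate(lfp_onset_ms ~ channel + stimulus_id,
                                    data = data.frame(channel = ch,
                                                      stimulus_id = gt$stimulus_id,
                                                      lfp_onset_ms = gt$lfp_onset_ms),
                                    FUN = min)
    }
    channels <- sort(unique(config$units$channel_id))
    phase0 <- array(NA_real_, dim = c(length(channels), ns, nt),
                    dimnames = list(channels, NULL, NULL))
    for (ci in seq_along(channels)) for (s in seq_len(ns)) {
      on <- burst_onset(burst_tab, channels[ci], s)
      if (!is.na(on)) {
        jit <- stats::rnorm(nt, 0, lfp_cfg$reset_jitter_deg)
        # absolute offset so that phase(onset) = -90 + jitter
        phase0[ci, s, ] <- -90 + jit - 360 * lfp_cfg$theta_hz * on / 1000
      }
    }
  }

  theta_phase <- function(t_ms, ph0) (360 * lfp_cfg$theta_hz * t_ms / 1000 + ph0)

  spikes <- list(); wf_rows <- list()
  tmpl <- wf_template(config$wf_n)
  resp_key <- paste(config$responses$unit_id, config$responses$stimulus_id)
  for (ui in seq_len(nrow(config$units))) {
    u <- config$units$unit_id[ui]
    b <- config$units$baseline_hz[ui]
    amp <- config$units$wf_amp[ui]
    uch <- as.character(config$units$channel_id[ui])
    for (s in seq_len(ns)) {
      ri <- match(paste(u, s), resp_key)
      for (k in seq_len(nt)) {
        t_base <- sort(stats::runif(stats::rpois(1, 3 * b), -1000, 2000))
        t_resp <- numeric(0)
        if (!is.na(ri)) {
          r <- config$responses[ri, ]
          win <- c(r$latency_ms, r$latency_ms + r$duration_ms)
          dur_s <- r$duration_ms / 1000
          ph0 <- if (!is.null(phase0)) phase0[uch, s, k] else NA_real_
          if (r$kappa > 0 && !is.na(ph0)) {
            # thinning against the von Mises density of the trial theta phase
            boost <- exp(r$kappa) / besselI0(r$kappa)
            cand <- stats::runif(stats::rpois(1, dur_s * r$rate_hz * boost),
                                 win[1], win[2])
            phc <- theta_phase(cand, ph0) * pi / 180
            acc <- stats::runif(length(cand)) <
              exp(r$kappa * (cos(phc - r$pref_phase_deg * pi / 180) - 1))
            t_resp <- cand[acc]
          } else {
            t_resp <- stats::runif(stats::rpois(1, dur_s * r$rate_hz),
                                   win[1], win[2])
          }
        }
        tt <- enforce_refractory(sort(c(t_base, t_resp)))
        if (length(tt)) {
          spikes[[length(spikes) + 1]] <-
            data.frame(unit_id = u, stimulus_id = s, trial_index = k,
                       time_ms = tt)
          wf_rows[[length(wf_rows) + 1]] <-
            matrix(rep(amp * tmpl, each = length(tt)), nrow = length(tt)) +
            matrix(stats::rnorm(length(tt) * config$wf_n, 0, config$wf_noise_sd),
                   nrow = length(tt))
        }
      }
    }
  }
  spikes <- if (length(spikes)) do.call(rbind, spikes) else
    data.frame(unit_id = integer(), stimulus_id = integer(),
               trial_index = integer(), time_ms = numeric())
  waveforms <- if (length(wf_rows)) do.call(rbind, wf_rows) else NULL

  lfp <- NULL
  if (!is.null(lfp_cfg)) {
    channels <- sort(unique(config$units$channel_id))
    fs <- lfp_cfg$fs_raw
    nsamp <- round(3 * fs)
    t_ms <- -1000 + (seq_len(nsamp) - 1) / fs * 1000
    idx <- list(); rows <- list()
    for (ci in seq_along(channels)) for (s in seq_len(ns)) {
      on <- burst_onset(burst_tab, channels[ci], s)
      for (k in seq_len(nt)) {
        x <- pink_noise(nsamp, lfp_cfg$noise_amp, fs)
        if (!is.na(on)) {
          ph <- theta_phase(t_ms, phase0[ci, s, k]) * pi / 180
          x <- x + lfp_cfg$burst_amp *
            burst_envelope(t_ms, on, lfp_cfg$burst_dur_ms) * cos(ph)
        }
        idx[[length(idx) + 1]] <- data.frame(channel_id = channels[ci],
                                             stimulus_id = s, trial_index = k)
        rows[[length(rows) + 1]] <- x
      }
    }
    lfp <- list(fs = fs, t0_ms = -1000, index = do.call(rbind, idx),
                samples = do.call(rbind, rows))
  }

  assoc <- NULL
  if (!is.null(config$assoc)) {
    a_cfg <- utils::modifyList(list(a_in = -10, a_out = -20, a_sd = 1),
                               config$assoc)
    hits <- round(10^stats::runif(ns, 5, 7))
    in_block <- function(i, j) any(vapply(config$assoc_blocks,
                                          function(b) i %in% b && j %in% b,
                                          logical(1)))
    pr <- utils::combn(ns, 2)
    assoc <- do.call(rbind, lapply(seq_len(ncol(pr)), function(q) {
      i <- pr[1, q]; j <- pr[2, q]
      mu <- if (in_block(i, j)) a_cfg$a_in else a_cfg$a_out
      a_raw <- stats::rnorm(1, mu, a_cfg$a_sd)
      data.frame(id_i = i, id_j = j, hits_i = hits[i], hits_j = hits[j],
                 hits_ij = max(1, round(2^a_raw * hits[i] * hits[j])),
                 personal_score = round(min(10, max(0, 10 + (a_raw - a_cfg$a_out) /
                                                      (a_cfg$a_in - a_cfg$a_out) * 10 - 10))))
    }))
  }

  out <- new_session(stimuli, trials, units, spikes, waveforms = waveforms,
                     lfp = lfp, assoc = assoc,
                     meta = list(session_id = sprintf("synth-%d", config$seed),
                                 seed = config$seed))
  # ground-truth sidecar for tests: per-(channel, stimulus, trial) theta
  # phase offset, so spike phases can be checked against the exact analytic
  # phase rather than through the noisy LFP readout; not persisted by
  # write_session()
  attr(out, "phase0") <- phase0
  out
}

burst_onset <- function(burst_tab, channel, stimulus) {
  if (is.null(burst_tab)) return(NA_real_)
  hit <- burst_tab$channel == channel & burst_tab$stimulus_id == stimulus
  if (!any(hit)) NA_real_ else burst_tab$lfp_onset_ms[hit][1]
}

#' A canonical "unitized" synthetic session configuration
#'
#' The study conditions emulated by default: 15 stimuli shown 29 times;
#' several multi-responsive units whose responses to associated stimuli
#' (grouped in association blocks) share strength, latency and preferred
#' theta phase; one multi-responsive unit with non-associated responses that
#' differ in all three; single-responsive and silent units; spike latencies
#' spanning roughly 110-650 ms; and a theta burst leading each spike latency
#' by 70 ms.
#'
#' @param seed integer seed.
#' @param with_lfp include LFP traces (default TRUE).
#' @return a [synth_config()].
#' @export
synth_unitized_config <- function(seed = 1, with_lfp = TRUE) {
  units <- data.frame(
    unit_id = 1:16,
    channel_id = rep(1:2, 8),
    baseline_hz = c(2, 3, 4, 2, 3, 5, 2, 4, 3, 2, 4, 3, 2, 3, 4, 2),
    wf_amp = seq(80, 155, by = 5))
  # units 1-9: unitized multi-responses inside association blocks
  blocks <- list(c(1L, 2L, 3L), c(4L, 5L), c(6L, 7L))
  resp <- rbind(
    data.frame(unit_id = 1L, stimulus_id = c(1L, 2L, 3L), latency_ms = 180,
               duration_ms = 700, rate_hz = 30),
    data.frame(unit_id = 2L, stimulus_id = c(4L, 5L), latency_ms = 320,
               duration_ms = 700, rate_hz = 35),
    data.frame(unit_id = 3L, stimulus_id = c(6L, 7L), latency_ms = 450,
               duration_ms = 700, rate_hz = 28),
    data.frame(unit_id = 4L, stimulus_id = c(1L, 2L), latency_ms = 150,
               duration_ms = 700, rate_hz = 40),
    data.frame(unit_id = 5L, stimulus_id = c(2L, 3L), latency_ms = 260,
               duration_ms = 700, rate_hz = 32),
    data.frame(unit_id = 6L, stimulus_id = c(4L, 5L), latency_ms = 380,
               duration_ms = 700, rate_hz = 26),
    data.frame(unit_id = 7L, stimulus_id = c(1L, 3L), latency_ms = 210,
               duration_ms = 700, rate_hz = 34),
    data.frame(unit_id = 8L, stimulus_id = c(6L, 7L), latency_ms = 300,
               duration_ms = 700, rate_hz = 30),
    data.frame(unit_id = 9L, stimulus_id = c(4L, 5L), latency_ms = 240,
               duration_ms = 700, rate_hz = 38),
    # unit 10: multi-responsive but NOT associated; responses differ
    data.frame(unit_id = 10L, stimulus_id = c(8L, 9L),
               latency_ms = c(140, 520), duration_ms = 700,
               rate_hz = c(45, 18)),
    # single-responsive units across the latency range
    data.frame(unit_id = 11L, stimulus_id = 10L, latency_ms = 620,
               duration_ms = 700, rate_hz = 25),
    data.frame(unit_id = 12L, stimulus_id = 11L, latency_ms = 480,
               duration_ms = 700, rate_hz = 30),
    data.frame(unit_id = 13L, stimulus_id = 12L, latency_ms = 560,
               duration_ms = 700, rate_hz = 22))
  # concentration kappa = 1 gives response-epoch PLIs ~0.45, the regime of
  # significantly locked human MTL responses
  resp$kappa <- 1
  # associated responses of one unit share the preferred phase; phases
  # cluster around the rising-to-peak phase of the evoked burst (~+20 deg at
  # the spike latency), which is the phase that drives the firing
  pref <- c(0, 40, -20, 20, 70, 10, 60, -10, 50, NA, 30, -15, 25)
  resp$pref_phase_deg <- rep(pref, times = c(3, 2, 2, 2, 2, 2, 2, 2, 2, 2, 1, 1, 1))
  resp$pref_phase_deg[resp$unit_id == 10] <- c(20, 150)  # differing phases
  synth_config(n_stimuli = 15, n_trials = 29, units = units,
               responses = resp,
               lfp = if (with_lfp) list() else NULL,
               assoc_blocks = blocks,
               assoc = list(a_in = -10, a_out = -20, a_sd = 1),
               seed = seed)
}
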