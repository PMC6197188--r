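# Instantaneous rate, response detection and strength quantification.

test_that("instantaneous rate: unit-area kernel peak and trial averaging", {
  tr <- instantaneous_rate(list(0), sigma_ms = 10)
  # single spike: peak = 1/(sigma*sqrt(2*pi)) in Hz at the spike time
  expect_equal(max(tr$hz), 1000 * stats::dnorm(0, 0, 10), tolerance = 1e-6)
  expect_equal(tr$t[which.max(tr$hz)], 0)
  # two identical trials average to the single-trial trace
  tr2 <- instantaneous_rate(list(c(-100, 50), c(-100, 50)), sigma_ms = 10)
  tr1 <- instantaneous_rate(list(c(-100, 50)), sigma_ms = 10)
  expect_equal(tr2$hz, tr1$hz)
  expect_error(instantaneous_rate(list()), "at least one trial")
})

test_that("instantaneous rate recovers a homogeneous Poisson rate", {
  set.seed(3)
  trains <- poisson_trains(100, 20)
  tr <- instantaneous_rate(trains)
  mid <- tr$hz[tr$t > -900 & tr$t < 1900]  # avoid edge roll-off
  # time-averaged trace ~ 20 Hz; SE of the overall mean ~ sqrt(rate/T_total)
  se <- sqrt(20 / (100 * 2.8))
  expect_lt(abs(mean(mid) - 20), 3 * se)
})

test_that("detection recovers onset and strength on a strong response", {
  r <- data.frame(unit_id = 1L, stimulus_id = 2L, latency_ms = 300,
                  duration_ms = 700, rate_hz = 40, kappa = 0,
                  pref_phase_deg = 0)
  cfg <- synth_config(n_stimuli = 6, n_trials = 29,
                      units = data.frame(unit_id = 1L, channel_id = 1L,
                                         baseline_hz = 3, wf_amp = 100),
                      responses = r, seed = 21)
  s <- generate_session(cfg)
  det <- detect_responses(s)
  expect_equal(det$stimulus_id, 2L)
  expect_gte(det$onset_ms, 280)
  expect_lte(det$onset_ms, 320)
  gt <- ground_truth(cfg)
  # strength within 3 SE of the true (dead-time corrected) rate
  se_hz <- 1.25 * sqrt(gt$rate_eff_hz * 0.7 / 29) / 0.7
  expect_lt(abs(det$strength_hz - gt$rate_eff_hz), 3 * se_hz)
})

test_that("criterion (i) rejects sub-75 ms excursions", {
  # build a rate trace above threshold for only 60 ms
  hz <- rep(0, 3000)
  hz[1501:1560] <- 50                          # excursion at t = 500..559
  trace <- structure(list(t = seq(-1000, 1999), hz = hz, sigma_ms = 10),
                     class = "rate_trace")
  expect_true(is.na(first_crossing(trace, 10)))
  hz[1501:1580] <- 50     # 80 ms: passes
  trace$hz <- hz
  expect_equal(first_crossing(trace, 10), 500)
  # sub-20 ms dip is disregarded
  hz2 <- rep(0, 3000)
  hz2[1501:1540] <- 50; hz2[1556:1600] <- 50   # 40 + 45 ms, 15 ms gap
  trace$hz <- hz2
  expect_equal(first_crossing(trace, 10), 500)
  # a 25 ms dip splits the runs: both below 75 ms -> no crossing
  hz3 <- rep(0, 3000)
  hz3[1501:1540] <- 50; hz3[1566:1610] <- 50
  trace$hz <- hz3
  expect_true(is.na(first_crossing(trace, 10)))
})

test_that("no response is detected in pure baseline activity", {
  set.seed(9)
  hits <- 0L; total <- 0L
  for (seed in 1:40) {
    cfg <- synth_config(n_stimuli = 5, n_trials = 29,
                        units = data.frame(unit_id = 1L, channel_id = 1L,
                                           baseline_hz = 5, wf_amp = 100),
                        seed = 3000 + seed)
    det <- detect_responses(generate_session(cfg))
    hits <- hits + nrow(det)
    total <- total + 5L
  }
  # per-(unit, stimulus) false-detection rate stays below 2%
  expect_lt(hits / total, 0.02)
})

test_that("detection is invariant to trial order", {
  r <- data.frame(unit_id = 1L, stimulus_id = 1L, latency_ms = 250,
                  duration_ms = 700, rate_hz = 30, kappa = 0,
                  pref_phase_deg = 0)
  cfg <- synth_config(n_stimuli = 3, n_trials = 20,
                      units = data.frame(unit_id = 1L, channel_id = 1L,
                                         baseline_hz = 3, wf_amp = 100),
                      responses = r, seed = 33)
  s <- generate_session(cfg)
  det1 <- detect_responses(s)
  # reverse the trial indices (a pure relabeling of trials)
  s2 <- s
  nt <- 20
  s2$spikes$trial_index <- nt + 1L - s2$spikes$trial_index
  s2 <- validate_session(s2)
  det2 <- detect_responses(s2)
  expect_equal(det1$onset_ms, det2$onset_ms)
  expect_equal(det1$strength_hz, det2$strength_hz)
  expect_equal(det1$p_sign, det2$p_sign)
})

test_that("strength arithmetic follows the median-count definition", {
  # counts {2,2,2} in the window -> 2/0.7 Hz
  sp <- data.frame(unit_id = 1L, stimulus_id = rep(1L, 6),
                   trial_index = rep(1:3, each = 2),
                   time_ms = rep(c(150, 400), 3))
  s <- tiny_session(sp, n_stimuli = 2, n_trials = 3)
  expect_equal(response_strength(s, 1L, 1L, onset_ms = 100), 2 / 0.7)
  # all-empty trials -> 0
  expect_equal(response_strength(s, 1L, 2L, onset_ms = 100), 0)
  # baseline: 7 spikes in [-1000, -300) in a single trial -> 10 Hz over
  # that trial, 0 in the others -> median 0
  sp2 <- data.frame(unit_id = 1L, stimulus_id = 1L, trial_index = 1L,
                    time_ms = seq(-900, -450, length.out = 7))
  s2 <- tiny_session(sp2, n_stimuli = 1, n_trials = 1)
  expect_equal(baseline_strength(s2, 1L), 10)
})

test_that("pooled strength pools trials across responsive stimuli", {
  # stimulus 1 counts {2,2,2}, stimulus 2 counts {4,4,4}: pooled median 3
  mk <- function(stim, k) data.frame(unit_id = 1L, stimulus_id = stim,
                                     trial_index = rep(1:3, each = k),
                                     time_ms = rep(seq(150, 500, length.out = k), 3))
  sp <- rbind(mk(1L, 2), mk(2L, 4))
  s <- tiny_session(sp, n_stimuli = 2, n_trials = 3)
  resp <- data.frame(unit_id = 1L, stimulus_id = c(1L, 2L),
                     onset_ms = c(100, 100))
  expect_equal(pooled_strength(s, 1L, resp), 3 / 0.7)
  # identical distributions: pooled equals individual strength
  sp2 <- rbind(mk(1L, 2), mk(2L, 2))
  s2 <- tiny_session(sp2, n_stimuli = 2, n_trials = 3)
  expect_equal(pooled_strength(s2, 1L, resp),
               response_strength(s2, 1L, 1L, 100))
  expect_error(pooled_strength(s, 1L, resp[1, ]), ">= 2")
})

test_that("normalized strength profile scales to [0, 1] with a zero floor", {
  # three stimuli with median counts 2, 1, 0 in [100, 800), no baseline
  mk <- function(stim, k) if (k == 0) NULL else
    data.frame(unit_id = 1L, stimulus_id = stim,
               trial_index = rep(1:3, each = k),
               time_ms = rep(seq(150, 500, length.out = k), 3))
  sp <- rbind(mk(1L, 2), mk(2L, 1))
  s <- tiny_session(sp, n_stimuli = 3, n_trials = 3)
  prof <- normalized_strength_profile(s, 1L)
  expect_equal(unname(prof), c(1, 0.5, 0))
  # activity below baseline floors at zero: counts {4, 3, 0} over baseline 1
  sp2 <- rbind(mk(1L, 4), mk(2L, 3))
  base <- do.call(rbind, lapply(1:3, function(st)
    data.frame(unit_id = 1L, stimulus_id = st, trial_index = 1:3,
               time_ms = rep(-900, 3))))
  s2 <- tiny_session(rbind(sp2, base), n_stimuli = 3, n_trials = 3)
  prof2 <- normalized_strength_profile(s2, 1L)
  expect_equal(unname(prof2), c(1, 2 / 3, 0))
})
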