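# One-command orchestration: detection -> pairwise tests -> decoding -> LFP
# -> phase locking -> association scores -> population statistics, with CSV
# outputs and a machine-readable summary.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the full analysis with its default:
#' the detection constants ([det_params()]), the number of surrogates (1000),
#' the decoding window (100-800 ms) and likelihood family, the theta band
#' (3-6 Hz), the phase-locking spike floor (20) and the significance levels.
#'
#' @param det a [det_params()] list.
#' @param n_surr surrogates per permutation test.
#' @param decode_window common spike-count window for decoding (ms).
#' @param decode_family naive-Bayes likelihood family.
#' @param theta_band theta band (Hz).
#' @param pair_alpha significance level for pairwise difference tests.
#' @param min_phase_spikes spike floor per phase-locking epoch.
#' @param lfp_screen_factor channel-screening power multiple.
#' @param shape_window waveform window for the spike-shape test (ms).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(det = det_params(), n_surr = 1000,
                            decode_window = c(100, 800),
                            decode_family = "poisson",
                            theta_band = c(3, 6), pair_alpha = 0.05,
                            min_phase_spikes = 20, lfp_screen_factor = 10,
                            shape_window = c(100, 800)) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on one session
#'
#' Runs response detection, pairwise strength/latency/shape permutation
#' tests, naive-Bayes decoding, LFP preprocessing with theta evoked-power
#' latencies, spike-LFP phase locking, association scoring and population
#' statistics. Writes `responses.csv`, `pairs.csv`, `decode.csv`,
#' `lfp.csv`, `phase.csv`, `assoc.csv`, `popstats.csv`, `run.log` and
#' `summary.json` into `out_dir`. Stages without the required inputs (no
#' LFP, no association table) are skipped and noted. A stage failure leaves
#' the earlier outputs in place and marks the run failed in `summary.json`.
#'
#' @param session a `session`.
#' @param out_dir output directory (created).
#' @param config a [pipeline_config()].
#' @param seed integer seed driving every surrogate test.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(session, out_dir, config = pipeline_config(),
                         seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat(sprintf("pipeline run, seed %d, %s\n", seed,
              format(Sys.time(), "%Y-%m-%d %H:%M:%S")), file = logf)
  summary <- list(session_id = session$meta$session_id %||% "?", seed = seed,
                  status = "ok", skipped = character(0))
  wcsv <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                           row.names = FALSE)
  result <- tryCatch({
    ## 1. detection ------------------------------------------------------
    responses <- detect_responses(session, params = config$det)
    wcsv(responses, "responses.csv")
    log_line("detected %d responses in %d units", nrow(responses),
             length(unique(responses$unit_id)))
    summary$n_responses <- nrow(responses)
    summary$n_responsive_units <- length(unique(responses$unit_id))
    multi <- unique(responses$unit_id[responses$n_responses >= 2])
    summary$n_multiresponsive_units <- length(multi)

    ## 2. pairwise permutation tests --------------------------------------
    pairs <- pair_tests(session, responses, multi, config, seed)
    wcsv(pairs, "pairs.csv")
    summary$n_pairs <- nrow(pairs)
    if (nrow(pairs)) {
      summary$frac_sig_strength <- mean(pairs$p_strength < config$pair_alpha)
      summary$frac_sig_latency <- mean(pairs$p_latency < config$pair_alpha)
      summary$frac_joint_nonsig <- mean(pairs$p_strength >= config$pair_alpha &
                                          pairs$p_latency >= config$pair_alpha)
      summary$frac_sig_shape <- if (all(is.na(pairs$p_shape))) NA else
        mean(pairs$p_shape < config$pair_alpha, na.rm = TRUE)
    }

    ## 3. decoding ---------------------------------------------------------
    dec <- decode_stage(session, responses, multi, config, seed)
    wcsv(dec, "decode.csv")
    if (nrow(dec))
      summary$frac_units_decodable <- mean(dec$p < config$pair_alpha)

    ## 4/5. LFP and phase --------------------------------------------------
    if (!is.null(session$lfp)) {
      lf <- lfp_stage(session, responses, config)
      wcsv(lf$responses, "lfp.csv")
      d <- lf$responses$onset_ms - lf$responses$lfp_onset_ms
      d <- d[!is.na(d)]
      if (length(d) >= 5) {
        dens <- stats::density(d)
        summary$spike_lfp_lag_mode_ms <- dens$x[which.max(dens$y)]
        summary$n_lfp_responses <- length(d)
      }
      ph <- phase_stage(session, responses, lf, config, seed)
      wcsv(ph, "phase.csv")
      if (nrow(ph)) {
        sig <- ph$resp_rayleigh_p < config$pair_alpha & !is.na(ph$resp_rayleigh_p)
        summary$frac_responses_phase_locked <- mean(sig)
      }
      # pairwise phase difference for significantly locked pairs
      pairs <- pair_phase_stage(pairs, ph, config)
      wcsv(pairs, "pairs.csv")
    } else {
      summary$skipped <- c(summary$skipped, "lfp", "phase")
      log_line("no LFP: lfp/phase stages skipped")
    }

    ## 6. association ------------------------------------------------------
    if (!is.null(session$assoc)) {
      tab <- assoc_table(session$assoc)
      all_ids <- session$stimuli$stimulus_id
      arows <- list()
      for (u in multi) {
        rs <- responses$stimulus_id[responses$unit_id == u]
        s <- unit_assoc_summary(tab, rs, all_ids)
        if (!is.null(s))
          arows[[length(arows) + 1]] <-
            data.frame(unit_id = u, as_rr = s$as_rr, as_rnr = s$as_rnr,
                       n_rr = s$n_rr, n_rnr = s$n_rnr)
      }
      assoc_units <- if (length(arows)) do.call(rbind, arows) else
        data.frame(unit_id = integer(), as_rr = numeric(), as_rnr = numeric())
      wcsv(assoc_units, "assoc.csv")
      if (nrow(assoc_units) >= 2) {
        summary$assoc_sign_p <- paired_sign_test(assoc_units$as_rr,
                                                 assoc_units$as_rnr)
        summary$mean_as_rr <- mean(assoc_units$as_rr, na.rm = TRUE)
        summary$mean_as_rnr <- mean(assoc_units$as_rnr, na.rm = TRUE)
      }
      if (nrow(pairs)) {
        pairs$assoc_z <- vapply(seq_len(nrow(pairs)), function(q)
          pair_score(tab, pairs$stimulus_i[q], pairs$stimulus_j[q]),
          numeric(1))
        wcsv(pairs, "pairs.csv")
        ok <- !is.na(pairs$assoc_z)
        if (sum(ok) >= 4) {
          q1 <- stats::quantile(pairs$assoc_z[ok], 0.25)
          hi <- ok & pairs$assoc_z > q1
          summary$frac_high_assoc_joint_nonsig <-
            mean(pairs$p_strength[hi] >= config$pair_alpha &
                   pairs$p_latency[hi] >= config$pair_alpha)
          summary$n_high_assoc_pairs <- sum(hi)
        }
      }
    } else {
      summary$skipped <- c(summary$skipped, "assoc")
      log_line("no association table: assoc stage skipped")
    }

    ## 7. population statistics -------------------------------------------
    if (nrow(responses) >= 10) {
      lat <- latency_vs_nresponses(responses)
      str <- strength_vs_nresponses(responses)
      pop <- data.frame(metric = c("latency_vs_n", "strength_vs_n"),
                        rho = c(lat$rho, str$rho), p = c(lat$p, str$p),
                        n = c(lat$n, str$n))
      wcsv(pop, "popstats.csv")
      summary$latency_vs_n_rho <- lat$rho
      summary$strength_vs_n_rho <- str$rho
    } else summary$skipped <- c(summary$skipped, "popstats")
    summary
  }, error = function(e) {
    summary$status <- "failed"
    summary$error <- conditionMessage(e)
    log_line("FAILED: %s", conditionMessage(e))
    summary
  })
  jsonlite::write_json(result, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

# Pairwise strength/latency/shape permutation tests for the multi-responsive
# units. Seeds are derived deterministically per pair.
pair_tests <- function(session, responses, multi, config, seed) {
  rows <- list()
  pk <- 0L
  for (u in multi) {
    ru <- responses[responses$unit_id == u, , drop = FALSE]
    thr <- ru$threshold_hz[1]
    cmb <- utils::combn(seq_len(nrow(ru)), 2)
    for (q in seq_len(ncol(cmb))) {
      pk <- pk + 1L
      i <- cmb[1, q]; j <- cmb[2, q]
      si <- ru$stimulus_id[i]; sj <- ru$stimulus_id[j]
      ci <- spike_counts(session, u, si, c(ru$onset_ms[i], ru$onset_ms[i] + 700))
      cj <- spike_counts(session, u, sj, c(ru$onset_ms[j], ru$onset_ms[j] + 700))
      ps <- perm_strength_diff(ci, cj, config$n_surr, seed = seed + 7L * pk)
      ti <- spike_trains(session, u, si)
      tj <- spike_trains(session, u, sj)
      pl <- perm_latency_diff(ti, tj, thr, config$det, config$n_surr,
                              seed = seed + 7L * pk + 1L)
      psh <- NA_real_; dshape <- NA_real_
      if (!is.null(session$waveforms)) {
        wfi <- response_waveforms(session, u, si, config$shape_window)
        wfj <- response_waveforms(session, u, sj, config$shape_window)
        if (nrow(wfi) >= 10 && nrow(wfj) >= 10) {
          r <- perm_shape_diff(wfi, wfj, config$n_surr,
                               seed = seed + 7L * pk + 2L)
          psh <- r$p; dshape <- r$observed
        }
      }
      s_i <- ru$strength_hz[i]; s_j <- ru$strength_hz[j]
      rows[[length(rows) + 1]] <- data.frame(
        unit_id = u, stimulus_i = si, stimulus_j = sj,
        delta_strength = ps$observed,
        norm_delta_strength = norm_strength_diff(s_i, s_j),
        delta_latency = pl$observed,
        p_strength = ps$p, p_latency = pl$p,
        p_shape = psh, shape_dist = dshape)
    }
  }
  if (!length(rows))
    return(data.frame(unit_id = integer(), stimulus_i = integer(),
                      stimulus_j = integer(), delta_strength = numeric(),
                      norm_delta_strength = numeric(),
                      delta_latency = numeric(), p_strength = numeric(),
                      p_latency = numeric(), p_shape = numeric(),
                      shape_dist = numeric()))
  do.call(rbind, rows)
}

# Waveforms of a unit's spikes inside the shape window for one stimulus.
response_waveforms <- function(session, unit_id, stimulus_id,
                               window = c(100, 800)) {
  sel <- session$spikes$unit_id == unit_id &
    session$spikes$stimulus_id == stimulus_id &
    session$spikes$time_ms >= window[1] & session$spikes$time_ms < window[2]
  session$waveforms[sel, , drop = FALSE]
}

decode_stage <- function(session, responses, multi, config, seed) {
  rows <- list()
  for (u in multi) {
    rs <- responses$stimulus_id[responses$unit_id == u]
    counts <- lapply(rs, function(s)
      spike_counts(session, u, s, config$decode_window))
    names(counts) <- rs
    r <- decode_significance(counts, config$n_surr, seed = seed + 13L * u,
                             family = config$decode_family)
    rows[[length(rows) + 1]] <- data.frame(unit_id = u,
                                           n_stimuli = length(rs),
                                           performance = r$performance,
                                           chance = 100 / length(rs),
                                           p = r$p,
                                           family = config$decode_family)
  }
  if (!length(rows))
    return(data.frame(unit_id = integer(), n_stimuli = integer(),
                      performance = numeric(), chance = numeric(),
                      p = numeric(), family = character()))
  do.call(rbind, rows)
}

# Preprocess the LFP, screen channels, build per-(channel, stimulus) theta
# trials and attach evoked onset/peak latencies to each spike response.
lfp_stage <- function(session, responses, config) {
  l <- session$lfp
  channels <- sort(unique(l$index$channel_id))
  cleaned <- list()
  for (ch in channels) {
    sel <- l$index$channel_id == ch
    cleaned[[as.character(ch)]] <- lfp_preprocess(
      l$samples[sel, , drop = FALSE], l$fs)
  }
  fs_out <- 1500
  keep <- screen_channels(cleaned, fs_out)
  theta <- list(); evoked <- list()
  for (ch in names(cleaned)) {
    if (!keep[[ch]]) next
    sel <- l$index$channel_id == as.numeric(ch)
    idx <- l$index[sel, , drop = FALSE]
    by_stim <- list()
    for (s in unique(idx$stimulus_id)) {
      m <- cleaned[[ch]][idx$stimulus_id == s, , drop = FALSE]
      # keep trial alignment: rows already ordered by trial_index
      by_stim[[as.character(s)]] <- theta_trials(m, fs_out, l$t0_ms)
    }
    theta[[ch]] <- by_stim
    evoked[[ch]] <- evoked_lfp(by_stim, fs_out, l$t0_ms)
  }
  resp <- responses
  resp$channel_id <- session$units$channel_id[match(resp$unit_id,
                                                    session$units$unit_id)]
  resp$lfp_onset_ms <- NA_real_; resp$lfp_peak_ms <- NA_real_
  for (q in seq_len(nrow(resp))) {
    ch <- as.character(resp$channel_id[q])
    if (is.null(evoked[[ch]])) next
    lt <- evoked[[ch]]$latencies
    hit <- lt$stimulus_id == as.character(resp$stimulus_id[q])
    if (any(hit)) {
      resp$lfp_onset_ms[q] <- lt$onset_ms[hit][1]
      resp$lfp_peak_ms[q] <- lt$peak_ms[hit][1]
    }
  }
  list(responses = resp, theta = theta, evoked = evoked, keep = keep,
       fs = fs_out)
}

phase_stage <- function(session, responses, lf, config, seed) {
  rows <- list()
  for (q in seq_len(nrow(responses))) {
    u <- responses$unit_id[q]
    s <- responses$stimulus_id[q]
    ch <- as.character(session$units$channel_id[match(u, session$units$unit_id)])
    th_all <- lf$theta[[ch]]
    if (is.null(th_all)) next
    th <- th_all[[as.character(s)]]
    trains <- spike_trains(session, u, s)
    # baseline pools all stimuli
    base_trains <- list(); base_theta <- list()
    for (s2 in names(th_all)) {
      tr2 <- spike_trains(session, u, as.numeric(s2))
      base_trains <- c(base_trains, tr2)
      base_theta[[length(base_theta) + 1]] <- th_all[[s2]]
    }
    base_theta <- do.call(rbind, base_theta)
    pr <- phase_lock(trains, th, responses$onset_ms[q], lf$fs,
                     session$lfp$t0_ms, base_trains, base_theta,
                     config$theta_band, min_spikes = config$min_phase_spikes)
    sp <- NA_real_
    if (!is.null(pr$response) &&
        pr$response$rayleigh_p < config$pair_alpha) {
      w <- pr$response$window
      sp <- surrogate_pli(trains, th, lf$fs, session$lfp$t0_ms, w,
                          config$n_surr, seed = seed + 17L * q)$p
    }
    rows[[length(rows) + 1]] <- data.frame(
      unit_id = u, stimulus_id = s,
      base_n = if (is.null(pr$baseline)) NA else pr$baseline$n,
      base_pli = if (is.null(pr$baseline)) NA else pr$baseline$pli,
      base_rayleigh_p = if (is.null(pr$baseline)) NA else pr$baseline$rayleigh_p,
      resp_n = if (is.null(pr$response)) NA else pr$response$n,
      resp_pli = if (is.null(pr$response)) NA else pr$response$pli,
      resp_mean_deg = if (is.null(pr$response)) NA else pr$response$mean_deg,
      resp_rayleigh_p = if (is.null(pr$response)) NA else pr$response$rayleigh_p,
      surrogate_p = sp)
  }
  if (!length(rows))
    return(data.frame(unit_id = integer(), stimulus_id = integer(),
                      base_n = integer(), base_pli = numeric(),
                      base_rayleigh_p = numeric(), resp_n = integer(),
                      resp_pli = numeric(), resp_mean_deg = numeric(),
                      resp_rayleigh_p = numeric(), surrogate_p = numeric()))
  do.call(rbind, rows)
}

pair_phase_stage <- function(pairs, ph, config) {
  if (!nrow(pairs)) return(pairs)
  pairs$delta_phase_deg <- NA_real_
  for (q in seq_len(nrow(pairs))) {
    gi <- ph[ph$unit_id == pairs$unit_id[q] &
               ph$stimulus_id == pairs$stimulus_i[q], , drop = FALSE]
    gj <- ph[ph$unit_id == pairs$unit_id[q] &
               ph$stimulus_id == pairs$stimulus_j[q], , drop = FALSE]
    if (nrow(gi) && nrow(gj) && !is.na(gi$resp_rayleigh_p) &&
        !is.na(gj$resp_rayleigh_p) &&
        gi$resp_rayleigh_p < config$pair_alpha &&
        gj$resp_rayleigh_p < config$pair_alpha)
      pairs$delta_phase_deg[q] <- pair_phase_diff(gi$resp_mean_deg,
                                                  gj$resp_mean_deg)
  }
  pairs
}
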