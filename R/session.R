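# Session container: one follow-up experiment (about 15 pictures shown 25-35
# times each) with sorted spike trains, optional spike waveforms, optional
# per-trial LFP traces and an optional web-hit association table.

STIM_CATEGORIES <- c("musicians", "experimenters", "actors", "sportsmen",
                     "politicians", "places", "objects", "animals")

#' Construct a recording-session object
#'
#' @param stimuli data.frame with columns `stimulus_id` (unique integers),
#'   `name`, `category` (one of the eight fixed picture categories or
#'   `"unknown"`).
#' @param trials data.frame with columns `stimulus_id`, `trial_index`
#'   (1-based presentation order within stimulus).
#' @param units data.frame with columns `unit_id`, `channel_id` (the LFP
#'   channel the unit was recorded on; `NA` allowed).
#' @param spikes data.frame with columns `unit_id`, `stimulus_id`,
#'   `trial_index`, `time_ms` (ms relative to stimulus onset, within
#'   `[-1000, 2000)`).
#' @param waveforms optional numeric matrix with one row per row of `spikes`
#'   (spike-aligned waveform samples, all the same length).
#' @param lfp optional list with elements `fs` (Hz), `t0_ms` (time of the
#'   first sample, normally -1000), `index` (data.frame `channel_id`,
#'   `stimulus_id`, `trial_index`) and `samples` (matrix, one row per index
#'   row).
#' @param assoc optional data.frame with columns `id_i`, `id_j`, `hits_i`,
#'   `hits_j`, `hits_ij` and optionally `personal_score` (0-10).
#' @param meta list of session-level metadata (at least `session_id`).
#' @return object of class `session`.
#' @export
new_session <- function(stimuli, trials, units, spikes,
                        waveforms = NULL, lfp = NULL, assoc = NULL,
                        meta = list(session_id = "session")) {
  s <- structure(list(stimuli = as.data.frame(stimuli),
                      trials = as.data.frame(trials),
                      units = as.data.frame(units),
                      spikes = as.data.frame(spikes),
                      waveforms = waveforms, lfp = lfp, assoc = assoc,
                      meta = meta),
                 class = "session")
  validate_session(s)
}

#' Validate a session's referential integrity
#'
#' Checks id uniqueness, category levels, spike-time range and ordering, and
#' that every spike and LFP row references an existing stimulus and trial.
#'
#' @param session a `session` object.
#' @return the session, invisibly modified (spike times sorted within trial).
#' @export
validate_session <- function(session) {
  st <- session$stimuli
  if (anyDuplicated(st$stimulus_id))
    stop("integrity error: duplicated stimulus_id in stimuli")
  bad_cat <- setdiff(unique(st$category), c(STIM_CATEGORIES, "unknown"))
  if (length(bad_cat))
    stop("integrity error: unknown stimulus category: ", paste(bad_cat, collapse = ", "))
  tr_key <- paste(session$trials$stimulus_id, session$trials$trial_index)
  if (anyDuplicated(tr_key))
    stop("integrity error: duplicated (stimulus, trial) in trials")
  if (!all(session$trials$stimulus_id %in% st$stimulus_id))
    stop("integrity error: trials reference unknown stimulus_id")
  sp <- session$spikes
  if (nrow(sp)) {
    if (!all(sp$stimulus_id %in% st$stimulus_id))
      stop("integrity error: spikes reference unknown stimulus_id")
    if (!all(paste(sp$stimulus_id, sp$trial_index) %in% tr_key))
      stop("integrity error: spikes reference unknown (stimulus, trial)")
    if (!all(sp$unit_id %in% session$units$unit_id))
      stop("integrity error: spikes reference unknown unit_id")
    if (any(sp$time_ms < -1000 | sp$time_ms >= 2000))
      stop("integrity error: spike times outside [-1000, 2000) ms")
    o <- order(sp$unit_id, sp$stimulus_id, sp$trial_index, sp$time_ms)
    session$spikes <- sp[o, , drop = FALSE]
    rownames(session$spikes) <- NULL
    if (!is.null(session$waveforms)) {
      if (nrow(session$waveforms) != nrow(sp))
        stop("integrity error: waveforms rows != spike rows")
      session$waveforms <- session$waveforms[o, , drop = FALSE]
    }
  } else if (!is.null(session$waveforms) && nrow(session$waveforms))
    stop("integrity error: waveforms present without spikes")
  if (!is.null(session$lfp)) {
    l <- session$lfp
    stopifnot(is.numeric(l$fs), l$fs > 0, is.numeric(l$t0_ms))
    if (nrow(l$index) != nrow(l$samples))
      stop("integrity error: lfp index rows != sample rows")
    if (!all(l$index$stimulus_id %in% st$stimulus_id))
      stop("integrity error: lfp references unknown stimulus_id")
  }
  if (!is.null(session$assoc)) {
    a <- session$assoc
    if (!all(c(a$id_i, a$id_j) %in% st$stimulus_id))
      stop("integrity error: associations reference unknown stimulus_id")
    if (any(a$hits_i < 0 | a$hits_j < 0 | a$hits_ij < 0, na.rm = TRUE))
      stop("integrity error: negative hit counts")
  }
  session
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session '%s'> %d stimuli, %d units, %d spikes%s%s\n",
              x$meta$session_id %||% "?", nrow(x$stimuli), nrow(x$units),
              nrow(x$spikes),
              if (!is.null(x$lfp)) sprintf(", LFP @%g Hz (%d traces)",
                                           x$lfp$fs, nrow(x$lfp$index)) else "",
              if (!is.null(x$assoc)) sprintf(", %d association pairs",
                                             nrow(x$assoc)) else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a session to a directory of CSV + JSON files
#'
#' Emits `session.json`, `stimuli.csv`, `trials.csv`, `spikes.csv` and, when
#' present, `waveforms.csv`, `lfp.csv`, `associations.csv`. Two writes of the
#' same session produce byte-identical files.
#'
#' @param session a `session` object.
#' @param path directory (created if absent).
#' @export
write_session <- function(session, path) {
  session <- validate_session(session)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, f) utils::write.csv(df, file.path(path, f), row.names = FALSE)
  wcsv(session$stimuli, "stimuli.csv")
  wcsv(session$trials, "trials.csv")
  wcsv(session$units, "units.csv")
  wcsv(session$spikes, "spikes.csv")
  if (!is.null(session$waveforms)) {
    wf <- as.data.frame(session$waveforms)
    names(wf) <- sprintf("s%03d", seq_len(ncol(wf)))
    wcsv(wf, "waveforms.csv")
  }
  if (!is.null(session$lfp)) {
    l <- session$lfp
    df <- cbind(l$index, as.data.frame(l$samples))
    names(df) <- c(names(l$index), sprintf("s%05d", seq_len(ncol(l$samples))))
    wcsv(df, "lfp.csv")
  }
  if (!is.null(session$assoc)) wcsv(session$assoc, "associations.csv")
  meta <- session$meta
  meta$n_stimuli <- nrow(session$stimuli)
  meta$n_units <- nrow(session$units)
  meta$n_spikes <- nrow(session$spikes)
  if (!is.null(session$lfp)) {
    meta$lfp_fs <- session$lfp$fs
    meta$lfp_t0_ms <- session$lfp$t0_ms
  }
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Read a session from a directory written by [write_session()]
#'
#' @param path session directory.
#' @return a validated `session` object.
#' @export
read_session <- function(path) {
  need <- c("session.json", "stimuli.csv", "trials.csv", "units.csv", "spikes.csv")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      stop("load error: missing mandatory file ", f)
  meta <- jsonlite::read_json(file.path(path, "session.json"), simplifyVector = TRUE)
  rcsv <- function(f) utils::read.csv(file.path(path, f), stringsAsFactors = FALSE)
  stimuli <- rcsv("stimuli.csv")
  trials <- rcsv("trials.csv")
  units <- rcsv("units.csv")
  spikes <- rcsv("spikes.csv")
  waveforms <- NULL
  if (file.exists(file.path(path, "waveforms.csv")))
    waveforms <- as.matrix(rcsv("waveforms.csv"))
  lfp <- NULL
  if (file.exists(file.path(path, "lfp.csv"))) {
    df <- rcsv("lfp.csv")
    key <- c("channel_id", "stimulus_id", "trial_index")
    lfp <- list(fs = meta$lfp_fs, t0_ms = meta$lfp_t0_ms,
                index = df[, key, drop = FALSE],
                samples = unname(as.matrix(df[, setdiff(names(df), key), drop = FALSE])))
  }
  assoc <- NULL
  if (file.exists(file.path(path, "associations.csv")))
    assoc <- rcsv("associations.csv")
  keep <- setdiff(names(meta), c("n_stimuli", "n_units", "n_spikes", "lfp_fs", "lfp_t0_ms"))
  new_session(stimuli, trials, units, spikes, waveforms = waveforms,
              lfp = lfp, assoc = assoc, meta = as.list(meta[keep]))
}

#' Single-unit versus multi-unit quality flag
#'
#' A cluster is flagged `multi_unit` when it violates either quantitative
#' quality criterion: at least 1% of within-trial inter-spike intervals are
#' shorter than 3 ms (no refractory period), or the ratio between the peak of
#' the mean waveform and the standard deviation of its first sample is not
#' larger than 5. Without waveforms the quality is `"unknown"`.
#'
#' @param session a `session` object.
#' @param unit_id unit to flag.
#' @param isi_ms refractory bound in ms (default 3).
#' @param max_violation maximum tolerated ISI-violation fraction (default 0.01).
#' @param min_peak_sd minimum peak-to-first-sample-SD ratio (default 5).
#' @return `"single_unit"`, `"multi_unit"` or `"unknown"`.
#' @export
flag_unit_quality <- function(session, unit_id, isi_ms = 3,
                              max_violation = 0.01, min_peak_sd = 5) {
  idx <- which(session$spikes$unit_id == unit_id)
  if (is.null(session$waveforms) || length(idx) < 2) return("unknown")
  sp <- session$spikes[idx, , drop = FALSE]
  # ISIs within trials only: trials are discontinuous recordings.
  isis <- unlist(lapply(split(sp$time_ms, paste(sp$stimulus_id, sp$trial_index)),
                        function(t) diff(sort(t))), use.names = FALSE)
  if (length(isis) == 0) return("unknown")
  viol <- mean(isis < isi_ms)
  wf <- session$waveforms[idx, , drop = FALSE]
  mw <- colMeans(wf)
  sd1 <- stats::sd(wf[, 1])
  ratio <- if (sd1 > 0) max(abs(mw)) / sd1 else Inf
  if (viol >= max_violation || ratio <= min_peak_sd) "multi_unit" else "single_unit"
}
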