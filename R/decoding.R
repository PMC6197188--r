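# Naive-Bayes single-trial decoding of stimulus identity from spike counts.

#' Leave-one-out naive-Bayes decoding of stimulus identity
#'
#' For each held-out trial, per-stimulus Poisson likelihoods are fitted on
#' the remaining trials (rate = mean training count + `eps` smoothing, so a
#' stimulus with all-zero training counts stays usable) and the trial is
#' assigned to the maximum-posterior stimulus under uniform priors. Ties are
#' broken deterministically in favour of the lowest stimulus id. A Gaussian
#' likelihood (mean/SD of training counts, SD floored at `eps`) is available
#' behind `family = "gaussian"`.
#'
#' @param counts named list (names = stimulus ids) of integer vectors: the
#'   single-trial spike counts in the response period, one vector per
#'   stimulus (>= 2 stimuli, >= 5 trials each).
#' @param eps smoothing constant added to the fitted rate (default 0.1).
#' @param family `"poisson"` (default) or `"gaussian"`.
#' @return list with `performance` (% of trials correctly predicted),
#'   `confusion` (row-normalized, rows sum to 100), `n_trials` and `family`.
#' @export
nb_decode_loo <- function(counts, eps = 0.1, family = c("poisson", "gaussian")) {
  family <- match.arg(family)
  k <- length(counts)
  if (k < 2) stop("nb_decode_loo() needs >= 2 stimuli")
  if (any(vapply(counts, length, integer(1)) < 5))
    stop("nb_decode_loo() needs >= 5 trials per stimulus")
  ids <- names(counts)
  if (is.null(ids)) ids <- as.character(seq_len(k))
  ord <- order(suppressWarnings(as.numeric(ids)), ids)  # lowest id wins ties
  x <- unlist(counts, use.names = FALSE)
  cls <- rep(seq_len(k), vapply(counts, length, integer(1)))
  n_t <- length(x)
  nj <- tabulate(cls, k)
  S1 <- vapply(seq_len(k), function(j) sum(x[cls == j]), numeric(1))
  own <- outer(cls, seq_len(k), "==")                   # trial x class
  # leave-one-out training statistics, vectorized over trials
  n_tr <- matrix(nj, n_t, k, byrow = TRUE) - own
  S1_tr <- matrix(S1, n_t, k, byrow = TRUE) - own * x
  if (family == "poisson") {
    lam <- S1_tr / n_tr + eps
    loglik <- stats::dpois(x, lam, log = TRUE)
  } else {
    S2 <- vapply(seq_len(k), function(j) sum(x[cls == j]^2), numeric(1))
    S2_tr <- matrix(S2, n_t, k, byrow = TRUE) - own * x^2
    mu <- S1_tr / n_tr
    v <- pmax((S2_tr - S1_tr^2 / n_tr) / (n_tr - 1), 0)
    s <- pmax(sqrt(v), eps)
    loglik <- stats::dnorm(x, mu, s, log = TRUE)
  }
  best <- ord[max.col(loglik[, ord, drop = FALSE], ties.method = "first")]
  conf <- matrix(0, k, k, dimnames = list(ids, ids))
  for (q in seq_len(n_t)) conf[cls[q], best[q]] <- conf[cls[q], best[q]] + 1
  list(performance = 100 * mean(best == cls),
       confusion = 100 * conf / rowSums(conf),
       n_trials = n_t, family = family)
}

#' Shuffle significance of a decoding performance
#'
#' Re-runs the leave-one-out decoder on `n_surr` surrogates in which the
#' trial labels (stimulus assignments of the single-trial counts) are
#' randomly shuffled; returns the add-one p-value of the observed
#' performance.
#'
#' @inheritParams nb_decode_loo
#' @param n_surr number of label shuffles (default 1000).
#' @param seed optional integer seed.
#' @return a `perm_result` with extra field `performance`.
#' @export
decode_significance <- function(counts, n_surr = 1000, seed = NULL,
                                eps = 0.1, family = c("poisson", "gaussian")) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  obs <- nb_decode_loo(counts, eps, family)$performance
  sizes <- vapply(counts, length, integer(1))
  pool <- unlist(counts, use.names = FALSE)
  grp <- rep(seq_along(counts), sizes)
  surr <- vapply(seq_len(n_surr), function(b) {
    x <- sample(pool)
    sh <- split(x, grp)
    names(sh) <- names(counts)
    nb_decode_loo(sh, eps, family)$performance
  }, numeric(1))
  new_perm_result(obs, surr, perm_pvalue(obs, surr), seed,
                  extra = list(performance = obs))
}
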