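# Web-hit association, familiarity and visual-similarity scoring, with the
# unit-level R-R vs R-NR summaries and correlation analyses against
# electrophysiological differences. Hit counts are consumed from a cached
# provider table (associations.csv); the pipeline performs no network I/O.

#' Web association score between two concepts
#'
#' `a_ij = log2(hits_ij / (hits_i * hits_j))`: the joint web-hit count
#' normalized by the individual counts, so popularity cancels out. A zero
#' joint count leaves the score undefined (`NA`); such pairs are excluded
#' and counted by the callers.
#'
#' @param hits_i,hits_j individual hit counts (>= 1).
#' @param hits_ij joint hit count (pages containing both concepts).
#' @return numeric score (vectorized), `NA` where `hits_ij` is 0.
#' @export
association_score <- function(hits_i, hits_j, hits_ij) {
  stopifnot(all(hits_i >= 1), all(hits_j >= 1), all(hits_ij >= 0))
  ifelse(hits_ij >= 1, log2(hits_ij / (hits_i * hits_j)), NA_real_)
}

#' Familiarity score of a stimulus pair
#'
#' `f_ij = log2(hits_i * hits_j)`: log product of the individual hit counts.
#'
#' @inheritParams association_score
#' @return numeric score (vectorized).
#' @export
familiarity_score <- function(hits_i, hits_j) {
  stopifnot(all(hits_i >= 1), all(hits_j >= 1))
  log2(hits_i * hits_j)
}

#' Visual similarity between two grayscale images
#'
#' Pearson correlation of the z-score-normalized pixel intensities of two
#' equally sized images (160 x 160 in the experimental stimuli).
#'
#' @param img_a,img_b numeric matrices of equal dimensions.
#' @return correlation in `[-1, 1]`, `NA` when either image is constant.
#' @export
visual_similarity <- function(img_a, img_b) {
  stopifnot(all(dim(img_a) == dim(img_b)))
  a <- as.vector(img_a); b <- as.vector(img_b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

# Symmetric lookup of a pair score in a per-session table.
pair_score <- function(tab, i, j, col = "a_z") {
  hit <- (tab$id_i == i & tab$id_j == j) | (tab$id_i == j & tab$id_j == i)
  if (!any(hit)) NA_real_ else tab[[col]][hit][1]
}

#' Session association table with derived, z-scored columns
#'
#' Computes `a_ij` and `f_ij` from the hit counts and z-scores each derived
#' column (and the optional personal score) within the session.
#'
#' @param assoc data.frame with `id_i`, `id_j`, `hits_i`, `hits_j`,
#'   `hits_ij` and optionally `personal_score`.
#' @return the table with extra columns `a_raw`, `a_z`, `f_raw`, `f_z` (and
#'   `personal_z`), plus attribute `n_excluded` (pairs with undefined
#'   association score).
#' @export
assoc_table <- function(assoc) {
  assoc$a_raw <- association_score(assoc$hits_i, assoc$hits_j, assoc$hits_ij)
  assoc$f_raw <- familiarity_score(assoc$hits_i, assoc$hits_j)
  # a constant or near-empty column cannot be z-scored; mark it undefined
  safe_z <- function(x) {
    ok <- !is.na(x)
    if (sum(ok) < 2 || stats::sd(x[ok]) == 0) return(rep(NA_real_, length(x)))
    session_zscore(x)
  }
  assoc$a_z <- safe_z(assoc$a_raw)
  assoc$f_z <- safe_z(assoc$f_raw)
  if (!is.null(assoc$personal_score))
    assoc$personal_z <- safe_z(assoc$personal_score)
  attr(assoc, "n_excluded") <- sum(is.na(assoc$a_raw))
  assoc
}

#' Unit-level mean association scores: R-R versus R-NR
#'
#' The mean z-scored association score over all pairs of the unit's
#' responsive stimuli (`AS_R-R`) and over all pairs where exactly one
#' stimulus is responsive (`AS_R-NR`).
#'
#' @param tab association table from [assoc_table()].
#' @param responsive_ids stimulus ids with a significant response in the
#'   unit (>= 2).
#' @param all_ids all stimulus ids of the session.
#' @param col score column, default `"a_z"`.
#' @return list with `as_rr`, `as_rnr`, `n_rr`, `n_rnr`; `NULL` when no
#'   valid R-R score exists.
#' @export
unit_assoc_summary <- function(tab, responsive_ids, all_ids, col = "a_z") {
  if (length(responsive_ids) < 2)
    stop("unit_assoc_summary() needs >= 2 responsive stimuli")
  rr <- utils::combn(responsive_ids, 2)
  rr_scores <- vapply(seq_len(ncol(rr)), function(q)
    pair_score(tab, rr[1, q], rr[2, q], col), numeric(1))
  nr <- setdiff(all_ids, responsive_ids)
  rnr_scores <- if (length(nr)) {
    g <- expand.grid(r = responsive_ids, n = nr)
    vapply(seq_len(nrow(g)), function(q)
      pair_score(tab, g$r[q], g$n[q], col), numeric(1))
  } else numeric(0)
  if (all(is.na(rr_scores))) return(NULL)
  list(as_rr = mean(rr_scores, na.rm = TRUE),
       as_rnr = if (all(is.na(rnr_scores))) NA_real_ else
         mean(rnr_scores, na.rm = TRUE),
       n_rr = sum(!is.na(rr_scores)), n_rnr = sum(!is.na(rnr_scores)))
}

#' Category-matched association summary for one unit
#'
#' Restricts the comparison pairs to those whose category pair matches the
#' category pair of the unit's responsive stimuli: the R-R score is
#' unchanged, while the R-NR side is replaced by the scores of all other
#' stimulus pairs with the same (unordered) category pair.
#'
#' @param tab association table from [assoc_table()].
#' @param responsive_ids the unit's responsive stimulus ids (>= 2).
#' @param stimuli data.frame with `stimulus_id` and `category`.
#' @param col score column, default `"a_z"`.
#' @return list with `as_rr` and `as_match` (mean score of category-matched
#'   non-response pairs), or `NULL` when no matching pair exists.
#' @export
category_controls <- function(tab, responsive_ids, stimuli, col = "a_z") {
  cat_of <- function(id) stimuli$category[match(id, stimuli$stimulus_id)]
  rr <- utils::combn(responsive_ids, 2)
  rr_scores <- vapply(seq_len(ncol(rr)), function(q)
    pair_score(tab, rr[1, q], rr[2, q], col), numeric(1))
  rr_cats <- vapply(seq_len(ncol(rr)), function(q)
    paste(sort(c(cat_of(rr[1, q]), cat_of(rr[2, q]))), collapse = "|"),
    character(1))
  all_ids <- stimuli$stimulus_id
  other <- utils::combn(all_ids, 2)
  keep <- logical(ncol(other)); sc <- numeric(ncol(other))
  for (q in seq_len(ncol(other))) {
    i <- other[1, q]; j <- other[2, q]
    if (all(c(i, j) %in% responsive_ids)) next   # R-R pairs stay on their side
    cp <- paste(sort(c(cat_of(i), cat_of(j))), collapse = "|")
    if (cp %in% rr_cats) {
      keep[q] <- TRUE
      sc[q] <- pair_score(tab, i, j, col)
    }
  }
  m <- sc[keep & !is.na(sc)]
  if (!length(m) || all(is.na(rr_scores))) return(NULL)
  list(as_rr = mean(rr_scores, na.rm = TRUE), as_match = mean(m),
       n_match = length(m))
}

#' Correlate an association score with an electrophysiological difference
#'
#' Pearson correlation between the per-pair scores and differences, a split
#' at a score quartile with the correlation recomputed in the
#' high-association group, and a Fisher-Z machinery for comparing two
#' correlations.
#'
#' @param score per-pair association scores.
#' @param ephys_diff per-pair electrophysiological differences (normalized
#'   strength difference, latency difference, ...).
#' @param quartile probability of the split point, default 0.25 (the high
#'   group keeps the 75% of pairs with the largest scores).
#' @return list with `r`, `p`, `n`, `high` (same fields for the
#'   high-association subset) and `split_value`.
#' @export
score_vs_ephys <- function(score, ephys_diff, quartile = 0.25) {
  ok <- !is.na(score) & !is.na(ephys_diff)
  score <- score[ok]; ephys_diff <- ephys_diff[ok]
  if (length(score) < 10) stop("score_vs_ephys() needs >= 10 valid pairs")
  ct <- stats::cor.test(score, ephys_diff)
  q1 <- stats::quantile(score, quartile)
  hi <- score > q1
  high <- if (sum(hi) >= 4) {
    ht <- stats::cor.test(score[hi], ephys_diff[hi])
    list(r = unname(ht$estimate), p = ht$p.value, n = sum(hi))
  } else NULL
  list(r = unname(ct$estimate), p = ct$p.value, n = length(score),
       high = high, split_value = unname(q1))
}

#' Fisher-Z comparison of two Pearson correlations
#'
#' `z = atanh(r)`; the statistic `(z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))` is
#' referred to the standard normal (two-sided).
#'
#' @param r1,n1 first correlation and its sample size (> 3).
#' @param r2,n2 second correlation and its sample size (> 3).
#' @return list with `z_stat` and `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("fisher_z_compare(): needs n > 3 per group")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z_stat = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Spearman correlation between web and personal association scores
#'
#' @param web z-scored web association scores.
#' @param personal z-scored personal (0-10) association rankings.
#' @return list with `rho` and `p`.
#' @export
personal_score_correlation <- function(web, personal) {
  ok <- !is.na(web) & !is.na(personal)
  ct <- suppressWarnings(
    stats::cor.test(web[ok], personal[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
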