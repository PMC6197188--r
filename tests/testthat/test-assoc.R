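# Association, familiarity and visual-similarity scoring with the unit-level
# summaries and correlation machinery.

test_that("association and familiarity score identities", {
  expect_equal(association_score(1, 1, 1), 0)
  expect_equal(association_score(4, 8, 16), -1)
  # hits_ij = hits_i * hits_j -> 0 for any hits
  expect_equal(association_score(37, 91, 37 * 91), 0)
  # symmetry and invariance to a common factor on hits_i and hits_ij
  expect_equal(association_score(5, 9, 22), association_score(9, 5, 22))
  expect_equal(association_score(3 * 5, 9, 3 * 22),
               association_score(5, 9, 22))
  # zero joint hits -> undefined
  expect_true(is.na(association_score(4, 8, 0)))
  expect_error(association_score(0, 8, 2))

  expect_equal(familiarity_score(1, 1), 0)
  expect_equal(familiarity_score(4, 8), 5)
  expect_equal(familiarity_score(2^7, 2^9), 16)
})

test_that("visual similarity is a pixel correlation with degenerate NA", {
  set.seed(21)
  a <- matrix(rnorm(160 * 160), 160)
  expect_equal(visual_similarity(a, a), 1)
  expect_equal(visual_similarity(a, -a), -1)
  b <- matrix(rnorm(160 * 160), 160)
  expect_lt(abs(visual_similarity(a, b)), 0.05)   # null corr, SE ~ 1/160
  expect_true(is.na(visual_similarity(a, matrix(1, 160, 160))))
})

test_that("session z-score: mean 0, sd 1, idempotent, errors on constants", {
  x <- c(0, 1, 2)
  z <- session_zscore(x)
  expect_equal(mean(z), 0)
  expect_equal(stats::sd(z), 1)
  expect_equal(session_zscore(z), z)
  expect_error(session_zscore(5), "2 non-missing")
  expect_error(session_zscore(c(3, 3, 3)), "constant")
})

test_that("unit summary separates R-R from R-NR means", {
  # 4 stimuli; unit responsive to 1, 2; block (1,2) highly associated
  assoc <- data.frame(id_i = c(1, 1, 1, 2, 2, 3),
                      id_j = c(2, 3, 4, 3, 4, 4),
                      hits_i = 2^10, hits_j = 2^10,
                      hits_ij = c(2^12, 2, 2, 2, 2, 2))
  tab <- assoc_table(assoc)
  s <- unit_assoc_summary(tab, c(1, 2), 1:4)
  expect_gt(s$as_rr, s$as_rnr)
  expect_equal(s$n_rr, 1)
  expect_equal(s$n_rnr, 4)
  # all scores equal -> both means equal (use raw column; z-score would be
  # degenerate)
  assoc2 <- assoc; assoc2$hits_ij <- 2^2
  tab2 <- assoc_table(assoc2)
  s2 <- unit_assoc_summary(tab2, c(1, 2), 1:4, col = "a_raw")
  expect_equal(s2$as_rr, s2$as_rnr)
  expect_error(unit_assoc_summary(tab, 1, 1:4), ">= 2")
})

test_that("category controls restrict comparison pairs by category pair", {
  stimuli <- data.frame(stimulus_id = 1:6,
                        category = c("actors", "actors", "actors",
                                     "places", "places", "places"))
  # scores: all pairs defined; actor-actor pairs high, others low
  pr <- t(utils::combn(6, 2))
  a_raw <- ifelse(pr[, 1] <= 3 & pr[, 2] <= 3, -5, -15)
  assoc <- data.frame(id_i = pr[, 1], id_j = pr[, 2],
                      hits_i = 2^10, hits_j = 2^10,
                      hits_ij = pmax(1, round(2^(a_raw + 20))))
  tab <- assoc_table(assoc)
  # unit responds to actors 1 and 2: matching category pair = actor|actor
  r <- category_controls(tab, c(1, 2), stimuli)
  # the only other actor-actor pairs are (1,3) and (2,3): high scores
  direct <- mean(c(pair_score(tab, 1, 3), pair_score(tab, 2, 3)))
  expect_equal(r$as_match, direct)
  expect_equal(r$n_match, 2)
  # all stimuli in one category: restriction equals the unrestricted R-NR +
  # NR-NR pool
  stimuli1 <- data.frame(stimulus_id = 1:6, category = "actors")
  r1 <- category_controls(tab, c(1, 2), stimuli1)
  all_other <- t(utils::combn(6, 2))
  keep <- !(all_other[, 1] %in% c(1, 2) & all_other[, 2] %in% c(1, 2))
  direct1 <- mean(vapply(which(keep), function(q)
    pair_score(tab, all_other[q, 1], all_other[q, 2]), numeric(1)))
  expect_equal(r1$as_match, direct1)
  # no matching pair -> NULL
  stim2 <- data.frame(stimulus_id = 1:3,
                      category = c("actors", "places", "animals"))
  pr2 <- t(utils::combn(3, 2))
  tab2 <- assoc_table(data.frame(id_i = pr2[, 1], id_j = pr2[, 2],
                                 hits_i = 4, hits_j = 4, hits_ij = 2))
  expect_null(category_controls(tab2, c(1, 2), stim2))
})

test_that("score-vs-ephys correlation and Fisher-Z comparison", {
  set.seed(14)
  n <- 139
  score <- rnorm(n)
  # negative coupling: larger associations give smaller differences
  diff <- -0.4 * score + rnorm(n, sd = 0.8)
  r <- score_vs_ephys(score, diff)
  expect_lt(r$r, 0)
  expect_lt(r$p, 0.01)
  expect_equal(r$n, n)
  # independent score: r within 3 SE of 0
  r0 <- score_vs_ephys(rnorm(n), rnorm(n))
  expect_lt(abs(r0$r), 3 / sqrt(n - 3))
  # equal correlations, equal n -> Fisher-Z p = 1
  fz <- fisher_z_compare(0.3, 50, 0.3, 50)
  expect_equal(fz$p, 1)
  expect_error(fisher_z_compare(0.2, 3, 0.1, 50), "n > 3")
  expect_error(score_vs_ephys(rnorm(5), rnorm(5)), ">= 10")
})

test_that("Fisher-Z comparison matches a bootstrap of two correlations", {
  set.seed(99)
  n1 <- 60; n2 <- 80
  mk <- function(n, rho) {
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    cbind(x, y)
  }
  d1 <- mk(n1, 0.5); d2 <- mk(n2, 0.1)
  r1 <- stats::cor(d1)[1, 2]; r2 <- stats::cor(d2)[1, 2]
  fz <- fisher_z_compare(r1, n1, r2, n2)
  boot <- replicate(800, {
    b1 <- d1[sample(n1, replace = TRUE), ]
    b2 <- d2[sample(n2, replace = TRUE), ]
    atanh(stats::cor(b1)[1, 2]) - atanh(stats::cor(b2)[1, 2])
  })
  # the analytic SE of atanh(r1) - atanh(r2) matches the bootstrap SD
  se_analytic <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  expect_lt(abs(stats::sd(boot) - se_analytic) / se_analytic, 0.25)
  # and the implied z-statistic agrees with the bootstrap-normalized one
  z_boot <- (atanh(r1) - atanh(r2)) / stats::sd(boot)
  expect_lt(abs(fz$z_stat - z_boot), 0.5)
})

test_that("personal-score correlation: monotone 1, reversed -1, independent 0", {
  web <- c(0.2, 1.4, -0.5, 0.9, -1.2, 0.1, 2.0, -0.3)
  expect_equal(personal_score_correlation(web, web^3)$rho, 1)
  expect_equal(personal_score_correlation(web, -web)$rho, -1)
  set.seed(8)
  r <- personal_score_correlation(rnorm(200), rnorm(200))
  expect_lt(abs(r$rho), 0.2)
})
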