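# Permutation machinery: degenerate cases, the exhaustive-enumeration
# oracle, power, cross-neuron surrogates and stability curves.

test_that("strength permutation: degenerate and fully separated cases", {
  # identical count multisets: observed 0, p = 1 under the add-one rule
  r <- perm_strength_diff(c(2, 3, 4), c(4, 3, 2), n_surr = 200, seed = 1)
  expect_equal(r$observed, 0)
  expect_equal(r$p, 1)
  # two-valued counts are a degenerate case for the median statistic: every
  # 25/25 split leaves one group median at 10 and the other at 0, so the
  # statistic is constant over permutations and p = 1 (the test is blind to
  # this alternative); confirmed by exhaustive enumeration at 5 trials/side
  r2 <- perm_strength_diff(rep(10, 25), rep(0, 25), n_surr = 1000, seed = 2)
  expect_equal(r2$p, 1)
  stat <- function(a, b) abs(stats::median(a) - stats::median(b)) / 0.7
  expect_equal(enum_perm_p(rep(10, 5), rep(0, 5), stat), 1)
  # with distinct values, only the original labeling and its mirror attain
  # the observed separation -> p = 1/1001
  r3 <- perm_strength_diff(100 + 1:25, 1:25, n_surr = 1000, seed = 2)
  expect_equal(r3$p, 1 / 1001)
  expect_error(perm_strength_diff(1, c(1, 2)), ">= 2 trials")
})

test_that("sampled permutation p matches exhaustive enumeration", {
  stat <- function(a, b) abs(stats::median(a) - stats::median(b)) / 0.7
  set.seed(4)
  for (rep in 1:5) {
    x <- rpois(5, 4); y <- rpois(5, 7)
    p_exact <- enum_perm_p(x, y, stat)
    r <- perm_strength_diff(x, y, n_surr = 2000, seed = 100 + rep)
    # binomial tolerance on the sampled estimate
    tol <- 3 * sqrt(p_exact * (1 - p_exact) / 2000) + 1 / 2000
    expect_lt(abs(r$p - p_exact), tol + 1e-9)
  }
})

test_that("latency permutation: identical trains give 0; distinct latencies detected", {
  set.seed(11)
  tr <- poisson_trains(12, 5)
  r <- perm_latency_diff(tr, tr, threshold = 5, n_surr = 100, seed = 1)
  expect_equal(r$observed, 0)
  expect_equal(r$p, 1)

  # strong responses at 200 vs 500 ms
  mk <- function(lat) lapply(1:20, function(i) {
    sort(c(runif(rpois(1, 6), -1000, 2000),
           runif(rpois(1, 28), lat, lat + 700)))
  })
  power_hits <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    r2 <- perm_latency_diff(mk(200), mk(500), threshold = 8,
                            n_surr = 200, seed = s)
    if (r2$p <= 0.01) power_hits <- power_hits + 1L
  }
  expect_gte(power_hits, 9)
})

test_that("shape permutation: identical sets give 0; separated templates detected", {
  tmpl <- 50 * mtlunitize:::wf_template(20)
  set.seed(5)
  wf <- wf_group(12, tmpl, 1)
  r <- perm_shape_diff(wf, wf, n_surr = 100, seed = 1)
  expect_equal(r$observed, 0, tolerance = 1e-10)
  expect_equal(r$p, 1)
  expect_error(perm_shape_diff(wf[1:5, ], wf, n_surr = 10), ">= 10 spikes")

  # templates separated by 5 noise SD at the peak sample
  tmpl2 <- tmpl
  tmpl2[which.max(abs(tmpl))] <- tmpl2[which.max(abs(tmpl))] + 5
  hits <- 0L
  for (s in 1:10) {
    set.seed(600 + s)
    r2 <- perm_shape_diff(wf_group(15, tmpl, 1), wf_group(15, tmpl2, 1),
                          n_surr = 200, seed = s)
    if (r2$p <= 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 9)
})

test_that("cross-neuron surrogate pairs rank a unitized population first", {
  # 6 units; within-unit strengths identical, across-unit strengths differ
  values <- rep(c(5, 12, 20, 28, 36, 44), each = 2)
  units <- rep(1:6, each = 2)
  r <- surrogate_pairs(values, units, n_sets = 500, seed = 3)
  expect_equal(r$observed_median, 0)
  expect_equal(r$p, 1 / 501)          # below every surrogate median
  expect_true(all(r$surrogate_medians >= 0))
  expect_lt(r$ranksum_p, 0.01)

  # all units identical: observed median equals the surrogate medians
  v2 <- rep(7, 12)
  r2 <- surrogate_pairs(v2, units, n_sets = 200, seed = 4)
  expect_equal(r2$observed_median, stats::median(r2$surrogate_medians))
  expect_error(surrogate_pairs(1:3, c(1, 1, 1)), ">= 2 units")
})

test_that("stability curve plateaus and the sliding sign test is calibrated", {
  # metric constant in n_t -> fitted b ~ 0, plateau at the constant
  fns <- list(function(idx) 4.2, function(idx) 4.2)
  r <- stability_curve(fns, n_trials = 25)
  expect_equal(r$curve$value, rep(4.2, nrow(r$curve)))
  if (!is.null(r$fit)) expect_lt(abs(r$fit$b), 1e-6)

  # stationary Poisson metric: plateau change < 1% beyond some n*, and the
  # trials 1-6 vs 20-25 sign test is non-significant in most seeds
  nonsig <- 0L
  plateau_ok <- 0L
  for (s in 1:20) {
    set.seed(700 + s)
    counts <- matrix(rpois(25 * 8, 10), nrow = 25)   # trials x responses
    fns2 <- lapply(1:8, function(j) function(idx) mean(counts[idx, j]))
    rs <- stability_curve(fns2, n_trials = 25)
    if (rs$sign_p > 0.05) nonsig <- nonsig + 1L
    v <- rs$curve$value
    late <- v[rs$curve$nt >= 18]
    if (max(abs(late - v[length(v)])) / abs(v[length(v)]) < 0.05)
      plateau_ok <- plateau_ok + 1L
  }
  expect_gte(nonsig, 18)       # ~ 90% of seeds
  expect_gte(plateau_ok, 18)
})

test_that("seeded permutation runs are bit-reproducible", {
  x <- rpois(15, 6); y <- rpois(15, 9)
  a <- perm_strength_diff(x, y, n_surr = 300, seed = 42)
  b <- perm_strength_diff(x, y, n_surr = 300, seed = 42)
  expect_identical(a$surrogates, b$surrogates)
  expect_identical(a$p, b$p)
})

test_that("normalized strength difference is the ratio to the pair maximum", {
  expect_equal(norm_strength_diff(10, 5), 0.5)
  expect_equal(norm_strength_diff(5, 10), 0.5)
  expect_equal(norm_strength_diff(7, 7), 0)
  expect_true(is.na(norm_strength_diff(0, 0)))
})
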