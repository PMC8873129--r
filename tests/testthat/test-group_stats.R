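test_that("midranks share averages across ties and sum to n(n+1)/2", {
  expect_equal(rank_with_ties(c(5, 1, 3)), c(3, 1, 2))
  expect_equal(rank_with_ties(c(2, 2, 4)), c(1.5, 1.5, 3))
  expect_equal(rank_with_ties(rep(7, 5)), rep(3, 5))
  set.seed(4)
  for (i in 1:10) {
    x <- sample(0:5, 12, replace = TRUE)
    expect_equal(sum(rank_with_ties(x)), 12 * 13 / 2)
  }
  expect_error(rank_with_ties(numeric(0)), class = "pollenrisk_config_error")
})

test_that("the H statistic matches a first-principles rank-sum oracle", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(round(kw$statistic, 3), 3.857)
  expect_equal(kw$df, 1)
  # chi-square upper tail by numerical integration, independent of pchisq
  quad <- integrate(function(x) dchisq(x, df = 1), kw$statistic, Inf)$value
  expect_equal(kw$p_value, quad, tolerance = 1e-4)

  set.seed(9)
  for (i in 1:20) {
    groups <- lapply(sample(2:5, sample(2:4, 1), replace = TRUE),
                     function(n) sample(0:4, n, replace = TRUE))
    if (length(unique(unlist(groups))) == 1) next
    expect_equal(kruskal_wallis(groups)$statistic, oracle_kw_h(groups),
                 tolerance = 1e-10)
  }
})

test_that("fully tied data give H = 0, p = 1 instead of 0/0", {
  kw <- kruskal_wallis(list(rep(2, 4), rep(2, 5)))
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p_value, 1)
  # heavy zero inflation with a single detection still yields finite H
  kw2 <- kruskal_wallis(list(c(0, 0, 0, 0, 7), c(0, 0, 0, 0)))
  expect_true(is.finite(kw2$statistic))
  expect_error(kruskal_wallis(list(1:3)), class = "pollenrisk_config_error")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), class = "pollenrisk_config_error")
})

test_that("H is invariant under strictly monotone transformations", {
  set.seed(21)
  g <- list(rlnorm(6), rlnorm(5), rlnorm(4))
  h0 <- kruskal_wallis(g)$statistic
  for (f in list(log, sqrt, function(x) 3 * x + 2, function(x) x^3)) {
    expect_equal(kruskal_wallis(lapply(g, f))$statistic, h0, tolerance = 1e-12)
  }
})

test_that("two-group KW agrees with the normal-approximation rank-sum test", {
  set.seed(31)
  x <- rnorm(50)
  y <- rnorm(50, 0.3)
  kw <- kruskal_wallis(list(x, y))
  w <- wilcox.test(x, y, correct = FALSE, exact = FALSE)
  expect_lt(abs(kw$p_value - w$p.value), 0.01)
})

test_that("chi-square p tracks the exact permutation p at small n", {
  cases <- list(
    list(c(1, 2, 3), c(4, 5, 6)),
    list(c(0, 0, 5), c(0, 3, 8)),
    list(c(2.5, 1.1, 9), c(3, 3, 3, 7)),
    list(c(0, 0, 0, 1), c(0, 2, 6, 6))
  )
  for (cs in cases) {
    kw <- kruskal_wallis(cs)
    expect_equal(kw$statistic, oracle_kw_h(cs), tolerance = 1e-10)
    p_exact <- oracle_kw_exact_p(cs[[1]], cs[[2]])
    # loose sanity bound: the chi-square reference is only a rough guide at
    # tiny n (gaps up to ~0.2 observed); the exact oracle is the arbiter
    expect_lt(abs(kw$p_value - p_exact), 0.3)
  }
})

test_that("per-timepoint comparisons test treated vs control per hive", {
  s20 <- example_study_2020()
  res <- per_timepoint_comparison(s20, "tau-fluvalinate") |>
    suppressWarnings() # surplus collections lack a control arm
  expect_equal(res$timepoint, 1:4)
  expect_equal(unique(res$n_treated), 5)
  expect_equal(unique(res$n_control), 4)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # pre-treatment timepoints are all-non-detect: degenerate H = 0
  expect_equal(res$statistic[res$timepoint == 1], 0)

  one <- suppressWarnings(
    per_timepoint_comparison(s20, "tau-fluvalinate", timepoints = 3)
  )
  expect_equal(nrow(one), 1)

  expect_warning(
    skipped <- per_timepoint_comparison(s20, "tau-fluvalinate", timepoints = c(4, 5)),
    "lacks a control arm"
  )
  expect_equal(skipped$timepoint, 4)

  holm <- suppressWarnings(
    per_timepoint_comparison(s20, "tau-fluvalinate", adjust = "holm")
  )
  expect_true(all(holm$adjusted_p >= holm$p_value))
  expect_error(per_timepoint_comparison(s20, "unobtainium"),
               class = "pollenrisk_validation_error")
})

test_that("composition correlation handles monotone, degenerate, and tiny inputs", {
  frac <- c(0.05, 0.1, 0.2, 0.4, 0.6)
  expect_equal(composition_correlation(frac, frac * 10)$estimate, 1)
  expect_equal(composition_correlation(frac, rev(frac))$estimate, -1)
  flat <- composition_correlation(frac, rep(3, 5))
  expect_true(is.na(flat$estimate))
  expect_match(flat$note, "zero variance")
  expect_error(composition_correlation(c(0.1, 0.2), c(1, 2)),
               class = "pollenrisk_config_error")
  set.seed(55)
  r <- composition_correlation(runif(200), runif(200))$estimate
  expect_lt(abs(r), 0.15)
  pear <- composition_correlation(frac, frac * 2 + 1, method = "pearson")
  expect_equal(pear$estimate, 1)
})
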