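test_that("multiyear weights divide two-year weights by the cycle count", {
  tab <- data.frame(wtint2yr = c(12000, 6000), wtmec2yr = c(10000, 5000),
                    wtdr2d = c(9000, 4500))
  out <- build_multiyear_weights(tab, 6)
  expect_equal(out$wtint12yr, c(2000, 1000))
  ident <- build_multiyear_weights(tab, 1)
  expect_equal(ident$wtint12yr, tab$wtint2yr)
  expect_equal(sum(out$wtmec12yr), sum(tab$wtmec2yr) / 6)
  expect_error(build_multiyear_weights(tab, 0), "positive")
})

test_that("the analysis kind selects the matching weight column", {
  expect_equal(select_weight("interview"), "wtint12yr")
  expect_equal(select_weight("mec"), "wtmec12yr")
  expect_equal(select_weight("dietary"), "wtdr2d12yr")
  expect_error(select_weight("household"))
})

test_that("equal weights and a self-representing design give sample fractions", {
  set.seed(21)
  x <- sample(fs_levels, 500, replace = TRUE, prob = c(0.5, 0.3, 0.15, 0.05))
  est <- weighted_prevalence(x, srs_design(500))
  expect_equal(est$proportion,
               as.vector(table(factor(x, sort(unique(x)))) / 500),
               tolerance = 1e-12)
  expect_equal(sum(est$proportion), 1, tolerance = 1e-10)
  expect_true(all(est$ci_lower >= 0 & est$ci_upper <= 1))
})

test_that("a worked 6-record fixture matches hand-computed weighted shares", {
  x <- c("High", "High", "Marginal", "Low", "Low", "High")
  d <- fs_design(strata = c(1, 1, 1, 2, 2, 2), psu = c(1, 2, 1, 1, 2, 2),
                 weights = c(1, 1, 2, 2, 3, 3))
  est <- weighted_prevalence(x, d)
  # total weight 12; High = 1+1+3 = 5, Marginal = 2, Low = 2+3 = 5
  expect_equal(est$proportion[est$category == "High"], 5 / 12)
  expect_equal(est$proportion[est$category == "Marginal"], 2 / 12)
  expect_equal(est$proportion[est$category == "Low"], 5 / 12)
})

test_that("prevalence is invariant to uniform weight rescaling", {
  set.seed(22)
  x <- sample(c("a", "b", "c"), 200, replace = TRUE)
  d1 <- clustered_design(200, seed = 22)
  d2 <- fs_design(d1$strata, sub("^[^:]*:", "", d1$psu), d1$weights * 57.3)
  e1 <- weighted_prevalence(x, d1)
  e2 <- weighted_prevalence(x, d2)
  expect_equal(e1$proportion, e2$proportion, tolerance = 1e-12)
  expect_equal(e1$se, e2$se, tolerance = 1e-10)
  expect_equal(e1$ci_lower, e2$ci_lower, tolerance = 1e-10)
})

test_that("prevalence recovers generating probabilities on a clustered design", {
  set.seed(23)
  n <- 10000
  p_true <- c(0.483, 0.308, 0.136, 0.073)
  x <- sample(fs_levels, n, replace = TRUE, prob = p_true)
  d <- clustered_design(n, n_strata = 15, seed = 23)
  est <- weighted_prevalence(factor(x, fs_levels), d)
  expect_true(all(abs(est$proportion - p_true) <= 3 * est$se))
})

test_that("a lonely PSU errors by default and is tolerated when centered", {
  x <- c("a", "b", "a", "b")
  expect_error(
    weighted_prevalence(x, fs_design(c(1, 1, 2, 2), c(1, 2, 1, 1), rep(1, 4))),
    "single PSU")
  d <- fs_design(c(1, 1, 2, 2), c(1, 2, 1, 1), rep(1, 4), lonely = "center")
  expect_silent(weighted_prevalence(x, d))
})

test_that("Rao-Scott second-order F reduces to Pearson X2/df under SRS", {
  set.seed(31)
  n <- 4000
  r <- sample(c("x", "y"), n, replace = TRUE)
  cc <- sample(fs_levels, n, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  rs <- rao_scott_test(r, cc, srs_design(n))
  pearson <- suppressWarnings(chisq.test(table(r, cc), correct = FALSE))
  d <- 3
  expect_equal(rs$statistic, unname(pearson$statistic) / d, tolerance = 0.01)
  expect_equal(rs$df1, d, tolerance = 0.05)
})

test_that("a perfectly associated 2x2 table gives p near zero", {
  g <- rep(c("a", "b"), each = 100)
  y <- rep(c("u", "v"), each = 100)
  rs <- rao_scott_test(g, y, clustered_design(200, seed = 5))
  expect_lt(rs$p.value, 1e-6)
})

test_that("Rao-Scott type-I error is near nominal under independence", {
  set.seed(77)
  reject <- logical(400)
  for (i in seq_along(reject)) {
    n <- 400
    r <- sample(c("x", "y"), n, replace = TRUE)
    cc <- sample(c("a", "b", "c"), n, replace = TRUE)
    d <- clustered_design(n, n_strata = 8, weight_cv = 0.4)
    reject[i] <- rao_scott_test(r, cc, d)$p.value < 0.05
  }
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("degenerate margins are rejected", {
  expect_error(rao_scott_test(rep("a", 10), sample(c("u", "v"), 10, TRUE),
                              srs_design(10)), "two observed categories")
})

test_that("design t-tests: identical groups give capped p of 1; 4 groups give 6 pairs", {
  set.seed(41)
  y <- rnorm(400)
  g <- sample(fs_levels, 400, replace = TRUE)
  d <- clustered_design(400, seed = 41)
  res <- design_ttest_bonferroni(y, g, d, m = 6)
  expect_equal(nrow(res), 6)  # all pairs of 4 categories
  expect_true(all(res$p_adj >= res$p_raw))
  expect_true(all(res$p_adj <= 1))
  # same outcome duplicated into two labels: difference exactly 0
  y2 <- rep(y, 2)
  g2 <- rep(c("g1", "g2"), each = 400)
  d2 <- fs_design(rep(rep(1:5, length.out = 400), 2),
                  rep(rep(1:2, length.out = 400), 2), rep(1, 800))
  res2 <- design_ttest_bonferroni(y2, g2, d2, m = 6)
  expect_equal(res2$diff, 0)
  expect_equal(res2$p_adj, 1)
  expect_error(design_ttest_bonferroni(y, g, d, pairs = list(c("High", "zzz"))),
               "unknown group")
})

test_that("a planted 2-SD mean shift is detected across all pairs", {
  set.seed(42)
  n_per <- 500
  g <- rep(c("g1", "g2", "g3"), each = n_per)
  y <- rnorm(3 * n_per, mean = c(0, 2, 4)[as.integer(factor(g))], sd = 1)
  d <- clustered_design(3 * n_per, n_strata = 10, seed = 43)
  res <- design_ttest_bonferroni(y, g, d, m = 3)
  expect_true(all(res$p_adj < 0.01))
})

test_that("weighted logistic reduces to ordinary logistic under equal weights", {
  set.seed(51)
  n <- 500
  x <- rnorm(n)
  g <- factor(sample(c("High", "Low"), n, replace = TRUE), c("High", "Low"))
  y <- rbinom(n, 1, plogis(-1 + 1.2 * (g == "Low") + 0.5 * x))
  dat <- data.frame(y = y, g = g, x = x)
  fit <- weighted_logistic(y ~ g + x, dat, srs_design(n))
  oracle <- glm(y ~ g + x, dat, family = binomial())
  expect_equal(fit$results$estimate, unname(coef(oracle)), tolerance = 1e-8)
  expect_equal(fit$results$odds_ratio, exp(fit$results$estimate))
})

test_that("weighted logistic rejects constant outcomes and separation", {
  n <- 100
  dat <- data.frame(y = rep(0, n), x = rnorm(n))
  expect_error(weighted_logistic(y ~ x, dat, srs_design(n)), "constant")
  dat2 <- data.frame(y = rep(c(0, 1), each = 50),
                     g = rep(c("a", "b"), each = 50))
  expect_error(weighted_logistic(y ~ g, dat2, srs_design(n)), "separation")
})

test_that("weighted linear reduces to OLS and its intercept to the weighted mean", {
  set.seed(52)
  n <- 500
  x <- rnorm(n)
  y <- 2 + 3 * x + rnorm(n)
  dat <- data.frame(y = y, x = x)
  fit <- weighted_linear(y ~ x, dat, srs_design(n))
  oracle <- lm(y ~ x, dat)
  expect_equal(fit$results$estimate, unname(coef(oracle)), tolerance = 1e-8)

  d <- clustered_design(n, seed = 52)
  fit0 <- weighted_linear(y ~ 1, dat, d)
  expect_equal(fit0$results$estimate, sum(d$weights * y) / sum(d$weights),
               tolerance = 1e-10)
})

test_that("planted regression coefficients are recovered within 3 design SEs", {
  set.seed(53)
  n <- 5000
  g <- factor(sample(fs_levels, n, replace = TRUE), fs_levels)
  beta <- c(0, -2, -3.5, -4.5)
  y <- 55 + beta[as.integer(g)] + rnorm(n, 0, 8)
  d <- clustered_design(n, n_strata = 12, seed = 53)
  fit <- weighted_linear(y ~ g, data.frame(y = y, g = g), d)
  r <- fit$results[-1, ]
  expect_equal(r$estimate, beta[-1], tolerance = 3 * max(r$se) / 2)
  expect_true(all(abs(r$estimate - beta[-1]) <= 3 * r$se))
})

test_that("a model compared with itself shows zero differences and p near 1", {
  set.seed(54)
  n <- 400
  g <- factor(sample(c("High", "Low"), n, replace = TRUE), c("High", "Low"))
  y <- rbinom(n, 1, plogis(-0.5 + 1 * (g == "Low")))
  d <- clustered_design(n, n_strata = 6, seed = 54)
  fit <- weighted_logistic(y ~ g, data.frame(y = y, g = g), d)
  cmp <- compare_models(fit, fit, reps = 50, seed = 1)
  expect_equal(cmp$diff, 0)
  expect_equal(unname(cmp$ci_lower), 0)
  expect_gte(cmp$p, 0.9)
})

test_that("a planted coefficient gap between two models is detected", {
  set.seed(55)
  n <- 5000
  x1 <- rnorm(n)
  x2 <- x1 + rnorm(n)  # noisier version of the same exposure
  y <- 1 + 1.5 * x1 + rnorm(n)
  d <- clustered_design(n, n_strata = 10, seed = 55)
  dat <- data.frame(y = y, x = x1)
  datb <- data.frame(y = y, x = x2)
  fa <- weighted_linear(y ~ x, dat, d)
  fb <- weighted_linear(y ~ x, datb, d)
  cmp <- compare_models(fa, fb, reps = 120, seed = 2)
  expect_lt(cmp$p[cmp$term == "x"], 0.05)
  expect_gt(cmp$ci_lower[cmp$term == "x"], 0)
})

test_that("models fit on different respondents cannot be compared", {
  n <- 100
  y <- rbinom(n, 1, 0.4)
  dat <- data.frame(y = y, x = rnorm(n))
  fa <- weighted_linear(y ~ x, dat, srs_design(n))
  fb <- weighted_linear(y ~ x, dat[1:50, ], srs_design(50))
  expect_error(compare_models(fa, fb), "same respondents")
})
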