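test_that("Pearson chi-square equals the brute-force oracle", {
  # exhaustive scan of 2x2 tables with entries 1..5
  for (a in 1:5) for (b in 1:5) for (cc in 1:5) for (d in 1:5) {
    m <- matrix(c(a, cc, b, d), 2)
    res <- pearson_chi2(m)
    expect_equal(res$statistic, chi2_brute(m), tolerance = 1e-9)
    # 2x2 shortcut n(ad - bc)^2 / product of marginals
    n <- sum(m)
    short <- n * (a * d - b * cc)^2 /
      ((a + b) * (cc + d) * (a + cc) * (b + d))
    expect_equal(res$statistic, short, tolerance = 1e-9)
    expect_equal(res$df, 1)
  }
  # a handful of random larger tables
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(rpois(12, 8) + 1, 3, 4)
    expect_equal(pearson_chi2(m)$statistic, chi2_brute(m), tolerance = 1e-9)
    expect_equal(pearson_chi2(m)$df, 6)
  }
})

test_that("chi-square reproduces published contingency rows", {
  expect_equal(round(pearson_chi2(matrix(c(19, 6, 123, 131), 2))$statistic, 1), 6.9)
  expect_equal(round(pearson_chi2(matrix(c(36, 19, 106, 118), 2))$statistic, 1), 5.8)
  course <- matrix(c(75, 51, 20, 31, 65, 58, 5, 2, 4, 0), 5, 2, byrow = TRUE)
  res <- pearson_chi2(course)
  expect_equal(round(res$statistic, 1), 10.4)
  expect_equal(res$df, 4)
  expect_match(res$note, "expected count")   # sparse cells flagged, not fatal

  flat <- matrix(c(10, 20, 5, 10), 2)        # identical row proportions
  expect_equal(pearson_chi2(flat)$statistic, 0, tolerance = 1e-12)
  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "marginal")
})

test_that("pooled t-test reproduces published summary rows", {
  t1 <- pooled_t_from_summary(c(mean = 45.3, sd = 13.5, n = 169),
                              c(mean = 53.1, sd = 8.8, n = 55))
  expect_equal(round(t1$statistic, 1), 4.0)
  expect_equal(t1$df, 222)
  t2 <- pooled_t_from_summary(c(mean = 42.8, sd = 14.4, n = 142),
                              c(mean = 58.7, sd = 10.1, n = 137))
  expect_equal(round(t2$statistic, 1), 10.6)
  t3 <- pooled_t_from_summary(c(mean = 22.0, sd = 13.7, n = 142),
                              c(mean = 17.8, sd = 11.2, n = 137))
  expect_equal(round(t3$statistic, 1), -2.8)
  t4 <- pooled_t_from_summary(c(mean = 22.5, sd = 12.8, n = 169),
                              c(mean = 13.5, sd = 8.6, n = 55))
  expect_equal(round(t4$statistic, 1), -4.9)
  # mean onset age, type 1 vs type 2, oriented (first - second) in the text
  t5 <- pooled_t_from_summary(c(mean = 30.6, sd = 12.7, n = 279),
                              c(mean = 26.7, sd = 9.2, n = 224))
  expect_equal(t5$statistic, -3.8, tolerance = 0.1)
})

test_that("pooled t is antisymmetric and consistent between raw and summary routes", {
  g1 <- c(mean = 10, sd = 2, n = 20)
  g2 <- c(mean = 12, sd = 3, n = 30)
  expect_equal(pooled_t_from_summary(g1, g2)$statistic,
               -pooled_t_from_summary(g2, g1)$statistic)

  expect_equal(pooled_t_raw(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(pooled_t_raw(c(1, 2, 3), c(4, 5, 6))$statistic,
               3 / sqrt(2 / 3), tolerance = 1e-9)

  set.seed(8)
  for (i in 1:100) {
    x1 <- rnorm(sample(5:40, 1), 10, 3)
    x2 <- rnorm(sample(5:40, 1), 12, 4)
    a <- pooled_t_raw(x1, x2)
    b <- pooled_t_from_summary(list(mean = mean(x1), sd = sd(x1), n = length(x1)),
                               list(mean = mean(x2), sd = sd(x2), n = length(x2)))
    expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  }
  expect_error(pooled_t_from_summary(c(mean = 1, sd = 0, n = 5),
                                     c(mean = 2, sd = 0, n = 5)), "infinite")
})

test_that("odds ratio matches the cross-product and handles zero cells", {
  # early-onset alcohol dependence: 10/169 (type 1) vs 19/142 (type 2)
  or <- odds_ratio_2x2(matrix(c(10, 19, 159, 123), 2))
  expect_equal(or$or, (10 * 123) / (159 * 19), tolerance = 1e-12)
  expect_equal(round(or$or, 1), 0.4)
  expect_false(or$corrected)
  expect_true(or$ci_lower < or$or && or$or < or$ci_upper)

  expect_equal(odds_ratio_2x2(matrix(c(5, 5, 5, 5), 2))$or, 1)

  z <- odds_ratio_2x2(matrix(c(0, 5, 10, 5), 2))
  expect_true(z$corrected)
  expect_equal(z$or, (0.5 * 5.5) / (10.5 * 5.5), tolerance = 1e-12)
})

test_that("logistic fit reproduces closed forms", {
  # saturated 2x2: coefficient = log cross-product OR
  m <- matrix(c(10, 19, 159, 123), 2)
  grp <- rep(c(0, 1), times = rowSums(m))
  exposed <- c(rep(1, m[1, 1]), rep(0, m[1, 2]), rep(1, m[2, 1]), rep(0, m[2, 2]))
  fit <- logistic_fit(exposed, data.frame(group = grp))
  expect_equal(fit$table$coefficient[fit$table$term == "group"],
               log((m[2, 1] * m[1, 2]) / (m[2, 2] * m[1, 1])),
               tolerance = 1e-6)

  # intercept-only model: intercept = logit(prevalence)
  y <- c(rep(1, 30), rep(0, 70))
  fit0 <- backward_stepwise(y, data.frame(x = rnorm(100)), alpha = 1e-9)
  expect_equal(fit0$table$coefficient[1], qlogis(0.3), tolerance = 1e-6)
  expect_length(fit0$retained, 0)

  expect_error(logistic_fit(y, data.frame(k = rep(1, 100))), "singular")
  x <- c(rnorm(50, -3), rnorm(50, 3))
  expect_error(logistic_fit(as.integer(x > 0), data.frame(x = x)),
               "separation")
  expect_error(logistic_fit(rep(1, 20), data.frame(x = rnorm(20))),
               "two observed classes")
})

test_that("backward stepwise keeps true effects and drops noise", {
  set.seed(99)
  x1 <- rnorm(2000)
  x2 <- rnorm(2000)
  y <- rbinom(2000, 1, plogis(-0.5 + log(3) * x1))
  m <- backward_stepwise(y, data.frame(true = x1, noise = x2))
  expect_equal(m$retained, "true")
  expect_equal(m$trace$removed, "noise")

  # a single significant covariate is returned unchanged
  m1 <- backward_stepwise(y, data.frame(true = x1))
  expect_equal(m1$retained, "true")
  expect_equal(nrow(m1$trace), 0)

  # odds ratios are exp(coefficients) with bracketing CIs
  expect_equal(m$table$odds_ratio, exp(m$table$coefficient), tolerance = 1e-9)
  expect_true(all(m$table$ci_lower < m$table$odds_ratio &
                    m$table$odds_ratio < m$table$ci_upper))

  # likelihood-ratio criterion agrees on this clear-cut case
  mlr <- backward_stepwise(y, data.frame(true = x1, noise = x2),
                           criterion = "lr")
  expect_equal(mlr$retained, "true")
})

test_that("Pearson correlation matches hand computation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$statistic, 1)
  expect_equal(pearson_r(x, -x)$statistic, -1)
  y <- c(2, 1, 4, 3, 6)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y)$statistic, r_hand, tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 5)), "zero variance")
})

test_that("Cohen's kappa follows (po - pe) / (1 - pe)", {
  expect_equal(cohens_kappa(diag(c(12, 8)))$statistic, 1)
  indep <- outer(c(6, 4), c(3, 2))   # independence-structured table
  expect_equal(cohens_kappa(indep)$statistic, 0, tolerance = 1e-12)
  expect_equal(cohens_kappa(matrix(c(20, 10, 5, 15), 2))$statistic, 0.4,
               tolerance = 1e-12)
  expect_error(cohens_kappa(matrix(c(5, 0, 0, 0), 2)), "degenerate")
  expect_error(cohens_kappa(matrix(1:6, 2, 3)), "square")
})
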