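test_that("k = 1 fit equals the closed-form Gaussian MLE", {
  set.seed(4)
  for (x in list(rexp(50) + 20, runif(30, 10, 60), rnorm(200, 30, 8))) {
    x <- pmax(x, 5)
    f <- fit_em(x, 1)
    mu <- mean(x)
    s <- sqrt(mean((x - mu)^2))
    expect_equal(f$components$mean, mu, tolerance = 1e-9)
    expect_equal(f$components$sd, s, tolerance = 1e-9)
    expect_equal(f$components$weight, 1)
    expect_equal(f$loglik, sum(dnorm(x, mu, s, log = TRUE)), tolerance = 1e-9)
  }
})

test_that("BIC follows the 2*logLik - p*log(n) maximization convention", {
  expect_equal(bic_score(0, 1, 1), 0)
  # n = 100 values with maximum-likelihood variance exactly 1:
  # logLik = -(n/2) (log(2 pi) + 1), BIC = 2 logLik - 2 log(100)
  set.seed(11)
  z <- rnorm(100)
  x <- (z - mean(z)) / sqrt(mean((z - mean(z))^2)) + 50
  f <- fit_em(x, 1)
  expect_equal(f$loglik, -(100 / 2) * (log(2 * pi) + 1), tolerance = 1e-6)
  expect_equal(f$bic, -283.7877 - 2 * log(100), tolerance = 1e-3)
  expect_equal(round(f$bic, 3), -292.998)
  # consistency with a published two-component row: n = 224, logLik = -786.2
  expect_equal(bic_score(-786.2, 5, 224), -1599.4, tolerance = 0.5)
})

test_that("EM log-likelihood is monotone and the BIC identity holds", {
  for (s in 1:3) {
    x <- rmix_aao(400, bd2_fit(), seed = 40 + s)
    for (k in 2:3) {
      f <- fit_em(x, k, seed = s)
      expect_true(all(diff(f$loglik_trace) > -1e-8))
      expect_equal(f$bic, bic_score(f$loglik, 3 * k - 1, length(x)),
                   tolerance = 1e-9)
      expect_equal(f$n_params, 3L * k - 1L)
      expect_equal(sum(f$components$weight), 1, tolerance = 1e-9)
      expect_true(all(diff(f$components$mean) > 0))
    }
  }
})

test_that("EM recovers generating two-component parameters at large n", {
  x <- rmix_aao(5000, bd2_fit(), seed = 1)
  f <- fit_em(x, 2, seed = 1)
  expect_equal(f$components$mean, c(20.9, 38.2), tolerance = 0.5 / 20)
  expect_true(all(abs(f$components$mean - c(20.9, 38.2)) < 0.5))
  expect_true(all(abs(f$components$sd - c(4.1, 11.8)) < 0.5))
  expect_true(all(abs(f$components$weight - c(0.44, 0.56)) < 0.03))
  expect_true(f$converged)
})

test_that("fits are invariant to permutations of the input order", {
  x <- rmix_aao(300, bd2_fit(), seed = 5)
  f1 <- fit_em(x, 2, seed = 3)
  f2 <- fit_em(sample(x), 2, seed = 3)
  expect_equal(f1$components, f2$components, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("degenerate and undersized inputs raise errors", {
  expect_error(fit_em(rep(10, 6), 2), "degenerate")
  expect_error(fit_em(rep(10, 6), 1), "degenerate")
  expect_error(fit_em(c(10, 20, 30, 40, 50), 2), "too few")
  expect_error(fit_em(c(10, -5, 20, 30, 40, 50), 2), "positive")
  expect_error(fit_em(c(10, NA, 20, 30, 40, 50), 2), "missing")
})

test_that("mixture pdf, cdf and responsibilities behave as distributions", {
  std <- mixture_fit(0.0, 1.0, 1.0)
  expect_equal(mixture_cdf(std, 0), 0.5)
  sym <- mixture_fit(c(-3, 3), c(1, 1), c(0.5, 0.5))
  expect_equal(mixture_cdf(sym, 0), 0.5)
  expect_equal(as.numeric(posterior_responsibilities(sym, 0)), c(0.5, 0.5),
               tolerance = 1e-12)

  b1 <- bd1_fit()
  expect_equal(mixture_cdf(b1, 32),
               0.669 * pnorm((32 - 22.6) / 4.8) +
                 0.331 * pnorm((32 - 35.1) / 10.1), tolerance = 1e-12)
  expect_equal(mixture_cdf(b1, 32), 0.778, tolerance = 5e-4)

  b2 <- bd2_fit()
  r <- posterior_responsibilities(b2, c(27, 28))
  expect_true(r[1, 1] > 0.5)   # 27 still favours the early component
  expect_true(r[2, 1] < 0.5)   # 28 favours the late component
  expect_equal(rowSums(r), c(1, 1), tolerance = 1e-12)

  # deep in one component's core, far in the other's tail, the
  # responsibility saturates
  apart <- mixture_fit(c(0.5, 10), c(1, 1), c(0.5, 0.5))
  expect_gt(posterior_responsibilities(apart, 0.5)[1, 1], 0.999)

  g <- seq(-40, 120, length.out = 4001)
  expect_true(all(mixture_pdf(b2, g) >= 0))
  expect_true(all(diff(mixture_cdf(b2, g)) >= 0))
  expect_equal(integrate(function(x) mixture_pdf(b2, x), -Inf, Inf)$value, 1,
               tolerance = 1e-6)
})

test_that("model scan selects by BIC with parsimony tie-break", {
  set.seed(2)
  x <- pmax(5, rnorm(500, 30, 5))
  sc <- scan_components(x, 1, 3, seed = 1)
  expect_equal(sc$best_k, 1L)
  expect_equal(sc$best_k, seq.int(1, 3)[which.max(sc$bic)])

  x2 <- rmix_aao(300, bd2_fit(), seed = 8)
  sc2 <- scan_components(x2, 2, 2, seed = 1)
  expect_length(Filter(Negate(is.null), sc2$fits), 1)
  expect_equal(sc2$best_k, 2L)

  expect_error(scan_components(x2, 0, 2), "k_min")
  # a failing k is dropped with a warning, selection proceeds on the rest
  small <- rmix_aao(8, bd2_fit(), seed = 3)
  w <- capture_warnings(sc3 <- scan_components(small, 1, 4, seed = 1))
  expect_match(w, "failed", all = TRUE)
  expect_true(is.null(sc3$fits[["3"]]) && is.null(sc3$fits[["4"]]))
  expect_true(sc3$best_k %in% 1:2)
})

test_that("EM is at least as good as an independent mixture fitter", {
  suppressPackageStartupMessages(library(mclust))   # Mclust needs attachment
  x <- rmix_aao(1000, bd2_fit(), seed = 13)
  f <- fit_em(x, 2, seed = 1)
  m <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  # the restarted EM must reach at least the reference log-likelihood
  expect_gte(f$loglik, m$loglik - 1e-3)
  expect_equal(sort(f$components$mean),
               sort(as.numeric(m$parameters$mean)), tolerance = 0.05)
})

test_that("JSON serialization round-trips fits and scans losslessly", {
  x <- rmix_aao(200, bd2_fit(), seed = 12)
  f <- fit_em(x, 2, seed = 1)
  f2 <- mixture_from_json(mixture_to_json(f))
  expect_equal(f2$components, f$components)
  expect_equal(f2$loglik, f$loglik)
  expect_equal(f2$bic, f$bic)
  expect_equal(f2$n, f$n)
  expect_equal(f2$converged, f$converged)

  sc <- scan_components(x, 1, 2, seed = 1)
  sc2 <- scan_from_json(scan_to_json(sc))
  expect_equal(sc2$best_k, sc$best_k)
  expect_equal(unname(sc2$bic), unname(sc$bic))
  expect_equal(sc2$fits[["2"]]$components, sc$fits[["2"]]$components)
})
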