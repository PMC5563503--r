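# Clinical-correlates battery: Pearson chi-square, pooled two-sample t,
# 2x2 odds ratios, logistic regression with backward stepwise elimination,
# Pearson correlation and Cohen's kappa.
#
# Conventions mirror the clinical literature these tables come from: the
# chi-square carries no continuity correction, the t-test pools variances
# (df = n1 + n2 - 2) and is oriented as (group 2 - group 1), p-values are
# two-sided, and no multiple-testing adjustment is applied.

#' Pearson chi-square test on a contingency table
#'
#' Computes the uncorrected Pearson statistic `sum (O - E)^2 / E` with
#' `df = (r - 1)(c - 1)`. Tables with a sparse cell (any expected count < 5)
#' are flagged in `note` but still tested, as is conventional for the
#' course-type tables this battery reproduces.
#'
#' @param counts matrix of non-negative counts, at least 2 x 2.
#' @return an `onsetmix_test` (statistic, df, p_value).
#' @examples
#' pearson_chi2(matrix(c(19, 6, 123, 131), 2))   # 6.9 on 1 df
#' @export
pearson_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("table must be at least 2 x 2", call. = FALSE)
  }
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal row or column", call. = FALSE)
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  low <- any(expected < 5)
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  test_result(unname(ct$statistic), df = unname(ct$parameter),
              p_value = ct$p.value, method = "Pearson chi-square",
              n = sum(counts),
              note = if (low) "expected count < 5 in at least one cell")
}

#' Pooled (equal-variance) two-sample t-test from summary statistics
#'
#' Student's t with pooled variance, oriented as
#' `(mean2 - mean1) / SE_pooled` with `df = n1 + n2 - 2`, so swapping the
#' groups flips the sign.
#'
#' @param g1,g2 group summaries: numeric vectors or lists with elements
#'   `mean`, `sd` (sample SD) and `n`.
#' @return an `onsetmix_test` (statistic, df, two-sided p_value).
#' @examples
#' pooled_t_from_summary(c(mean = 45.3, sd = 13.5, n = 169),
#'                       c(mean = 53.1, sd = 8.8, n = 55))   # t = 4.0
#' @export
pooled_t_from_summary <- function(g1, g2) {
  g1 <- as.list(g1); g2 <- as.list(g2)
  for (g in list(g1, g2)) {
    if (is.null(g$mean) || is.null(g$sd) || is.null(g$n)) {
      stop("each group needs mean, sd and n", call. = FALSE)
    }
    if (g$sd < 0 || g$n < 2) stop("need sd >= 0 and n >= 2", call. = FALSE)
  }
  n1 <- g1$n; n2 <- g2$n
  df <- n1 + n2 - 2
  if (df < 1) stop("need n1 + n2 >= 3", call. = FALSE)
  sp2 <- ((n1 - 1) * g1$sd^2 + (n2 - 1) * g2$sd^2) / df
  if (sp2 == 0) {
    if (g1$mean != g2$mean) {
      stop("zero pooled variance with unequal means: t is infinite",
           call. = FALSE)
    }
    return(test_result(0, df = df, p_value = 1,
                       method = "Pooled two-sample t-test", n = c(n1, n2)))
  }
  t <- (g2$mean - g1$mean) / sqrt(sp2 * (1 / n1 + 1 / n2))
  test_result(t, df = df, p_value = 2 * stats::pt(-abs(t), df),
              method = "Pooled two-sample t-test", n = c(n1, n2))
}

#' Pooled two-sample t-test from raw data
#'
#' Computes each group's sample mean, SD and size and delegates to
#' [pooled_t_from_summary()], so the two routes agree exactly.
#'
#' @param x1,x2 numeric vectors, each with at least 2 values (NAs dropped).
#' @return an `onsetmix_test`.
#' @export
pooled_t_raw <- function(x1, x2) {
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  if (length(x1) < 2L || length(x2) < 2L) {
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  }
  pooled_t_from_summary(
    list(mean = mean(x1), sd = stats::sd(x1), n = length(x1)),
    list(mean = mean(x2), sd = stats::sd(x2), n = length(x2)))
}

#' Odds ratio with Wald confidence interval from a 2x2 table
#'
#' Cross-product odds ratio `(a d) / (b c)` for a table laid out as rows =
#' groups, columns = (exposed, unexposed). If any cell is zero, the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied and flagged.
#'
#' @param counts 2x2 matrix of counts.
#' @param conf_level confidence level for the log-scale Wald interval.
#' @return list of class `odds_ratio_result`: `or`, `log_or`, `se`,
#'   `ci_lower`, `ci_upper`, `p_value` (Wald), `corrected` flag.
#' @examples
#' odds_ratio_2x2(matrix(c(10, 19, 159, 123), 2))   # OR = 0.41
#' @export
odds_ratio_2x2 <- function(counts, conf_level = 0.95) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("need a 2 x 2 table", call. = FALSE)
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  corrected <- any(counts == 0)
  cc <- if (corrected) counts + 0.5 else counts
  log_or <- log(cc[1, 1]) + log(cc[2, 2]) - log(cc[1, 2]) - log(cc[2, 1])
  se <- sqrt(sum(1 / cc))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(or = exp(log_or), log_or = log_or, se = se,
         ci_lower = exp(log_or - z * se), ci_upper = exp(log_or + z * se),
         p_value = 2 * stats::pnorm(-abs(log_or / se)),
         conf_level = conf_level, corrected = corrected,
         counts = counts),
    class = "odds_ratio_result"
  )
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR = %.3f, %d%% CI %.3f-%.3f, p = %s\n",
              x$or, round(100 * x$conf_level), x$ci_lower, x$ci_upper,
              format.pval(x$p_value, digits = 3)))
  if (x$corrected) cat("note: Haldane-Anscombe +0.5 applied (zero cell)\n")
  invisible(x)
}

# Shared builder of the coefficient table used by logistic_fit and the
# stepwise wrapper.
.logistic_summary <- function(glm_fit, conf_level = 0.95) {
  sm <- summary(glm_fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(
    term = rownames(sm),
    coefficient = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    odds_ratio = exp(sm[, "Estimate"]),
    ci_lower = exp(sm[, "Estimate"] - z * sm[, "Std. Error"]),
    ci_upper = exp(sm[, "Estimate"] + z * sm[, "Std. Error"]),
    p_value = sm[, "Pr(>|z|)"],
    row.names = NULL
  )
}

#' Binary logistic regression with Wald inference
#'
#' Maximum-likelihood fit (iteratively reweighted least squares via
#' [stats::glm()]) of `outcome ~ covariates`, returning coefficients on the
#' log-odds scale with Wald standard errors, odds ratios and 95% CIs.
#' Singular designs (aliased columns) and perfect separation raise errors.
#'
#' @param outcome binary vector (0/1, logical, or two-level factor).
#' @param covariates data.frame (or matrix) of covariate columns.
#' @param conf_level confidence level for Wald intervals.
#' @return an object of class `logistic_model`: list with `table` (term,
#'   coefficient, se, odds_ratio, ci bounds, p_value), `covariate_names`,
#'   `retained`, `n_used`, `fit` (the glm object).
#' @export
logistic_fit <- function(outcome, covariates, conf_level = 0.95) {
  f <- factor(outcome)
  if (nlevels(f) != 2L) {
    stop("outcome must have exactly two observed classes", call. = FALSE)
  }
  y <- as.integer(f) - 1L
  X <- as.data.frame(covariates)
  if (nrow(X) != length(y)) stop("outcome/covariate length mismatch", call. = FALSE)
  cc <- if (ncol(X) > 0L) stats::complete.cases(X) & !is.na(y) else !is.na(y)
  X <- X[cc, , drop = FALSE]
  y <- y[cc]
  if (length(y) <= ncol(X) + 1L) {
    stop("too few observations for the number of covariates", call. = FALSE)
  }
  dat <- cbind(.y = y, X)
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (anyNA(stats::coef(fit))) {
    stop("singular design: aliased covariate(s) ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  if (any(abs(stats::coef(fit)[-1]) > 15)) {
    stop("perfect separation detected: divergent coefficient(s)", call. = FALSE)
  }
  structure(
    list(table = .logistic_summary(fit, conf_level),
         covariate_names = names(X),
         retained = names(X),
         n_used = length(y),
         conf_level = conf_level,
         fit = fit),
    class = "logistic_model"
  )
}

#' @export
print.logistic_model <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic regression (n = %d)\n", x$n_used))
  tab <- x$table
  tab$odds_ratio <- round(tab$odds_ratio, digits)
  tab$ci_lower <- round(tab$ci_lower, digits)
  tab$ci_upper <- round(tab$ci_upper, digits)
  tab$p_value <- signif(tab$p_value, digits)
  print(tab[, c("term", "odds_ratio", "ci_lower", "ci_upper", "p_value")],
        row.names = FALSE)
  if (!is.null(x$trace) && nrow(x$trace) > 0) {
    cat("removed:", paste(x$trace$removed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Backward stepwise logistic regression
#'
#' Repeatedly refits the logistic model, removing the covariate with the
#' largest removal p-value until every remaining covariate is significant at
#' `alpha`. The removal criterion is the Wald p-value by default; a
#' likelihood-ratio criterion (single-term deletion chi-square) is available
#' via `criterion = "lr"`.
#'
#' @inheritParams logistic_fit
#' @param alpha significance level for retention (default 0.05).
#' @param criterion `"wald"` (default) or `"lr"`.
#' @return a `logistic_model` for the final model, with `retained` (possibly
#'   empty) and a `trace` data.frame (step, removed, p_removed). If every
#'   covariate is eliminated, an intercept-only model is returned.
#' @export
backward_stepwise <- function(outcome, covariates, alpha = 0.05,
                              criterion = c("wald", "lr"),
                              conf_level = 0.95) {
  criterion <- match.arg(criterion)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  X <- as.data.frame(covariates)
  keep <- names(X)
  trace <- data.frame(step = integer(0), removed = character(0),
                      p_removed = numeric(0))
  step <- 0L
  repeat {
    if (length(keep) == 0L) {
      model <- logistic_fit(outcome, data.frame(row.names = seq_along(outcome)),
                            conf_level = conf_level)
      break
    }
    model <- logistic_fit(outcome, X[, keep, drop = FALSE],
                          conf_level = conf_level)
    p <- .removal_pvalues(model, keep, criterion)
    if (max(p) < alpha) break
    step <- step + 1L
    worst <- names(p)[which.max(p)]
    trace <- rbind(trace, data.frame(step = step, removed = worst,
                                     p_removed = max(p)))
    keep <- setdiff(keep, worst)
  }
  model$retained <- keep
  model$covariate_names <- names(X)
  model$trace <- trace
  model$alpha <- alpha
  model$criterion <- criterion
  model
}

# Per-covariate removal p-values; for factors the Wald route takes the
# smallest term p (conservative against removal), the LR route tests the
# whole covariate.
.removal_pvalues <- function(model, keep, criterion) {
  if (criterion == "lr") {
    d1 <- stats::drop1(model$fit, test = "Chisq")
    p <- d1[["Pr(>Chi)"]][-1]
    names(p) <- rownames(d1)[-1]
    return(p[keep])
  }
  tab <- model$table[model$table$term != "(Intercept)", ]
  p <- vapply(keep, function(v) {
    rows <- tab$term == v | startsWith(tab$term, v)
    min(tab$p_value[rows])
  }, numeric(1))
  p
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (pairwise-complete, n >= 3).
#' @return an `onsetmix_test` with `statistic` = r, `df` = n - 2, two-sided
#'   `p_value`.
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  test_result(unname(ct$estimate), df = unname(ct$parameter),
              p_value = ct$p.value, method = "Pearson correlation",
              n = length(x))
}

#' Cohen's kappa for two-rater agreement
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` from a square agreement table (raters in
#' rows/columns, categories matched).
#'
#' @param counts square matrix of agreement counts.
#' @return an `onsetmix_test` with `statistic` = kappa (no p-value).
#' @examples
#' cohens_kappa(matrix(c(20, 10, 5, 15), 2))   # 0.4
#' @export
cohens_kappa <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) {
    stop("agreement table must be square", call. = FALSE)
  }
  n <- sum(counts)
  if (n < 1) stop("empty table", call. = FALSE)
  po <- sum(diag(counts)) / n
  pe <- sum(rowSums(counts) * colSums(counts)) / n^2
  if (abs(1 - pe) < 1e-12) {
    stop("degenerate marginals: expected agreement is 1", call. = FALSE)
  }
  test_result((po - pe) / (1 - pe), method = "Cohen's kappa", n = n)
}
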