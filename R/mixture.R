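# Univariate Gaussian mixture fitting by EM with BIC model selection.
#
# This is the admixture-analysis engine: age-at-onset (AAO) distributions in
# clinical cohorts are modelled as finite mixtures of normal components with
# per-component (unequal) variances, the number of components is chosen by
# maximizing the BIC in the 2*logLik - p*log(n) convention, and posterior
# responsibilities of the fitted model drive the downstream subgrouping.

#' Construct a Gaussian mixture fit object
#'
#' Builds a `mixture_fit` from known component parameters, e.g. values
#' published in a report table. Components are sorted by ascending mean and
#' weights must sum to 1 (they are renormalized if off by less than 1e-6).
#'
#' @param mean numeric vector of component means (years).
#' @param sd numeric vector of component standard deviations (years), all > 0.
#' @param weight numeric vector of mixing proportions in (0, 1].
#' @param n number of observations behind the fit, if known.
#' @param loglik log-likelihood of the fit, if known.
#' @param converged logical convergence flag.
#' @param n_iter,n_restarts EM bookkeeping, if applicable.
#' @return an object of class `mixture_fit` with elements `components`
#'   (data.frame of mean, sd, weight), `k`, `n_params`, `loglik`, `bic`, `n`,
#'   and convergence metadata.
#' @examples
#' bd2 <- mixture_fit(mean = c(20.9, 38.2), sd = c(4.1, 11.8),
#'                    weight = c(0.44, 0.56), n = 279)
#' mixture_cdf(bd2, 28)
#' @export
mixture_fit <- function(mean, sd, weight, n = NA_integer_,
                        loglik = NA_real_, converged = NA,
                        n_iter = NA_integer_, n_restarts = NA_integer_) {
  k <- length(mean)
  if (length(sd) != k || length(weight) != k) {
    stop("mean, sd and weight must have equal length", call. = FALSE)
  }
  if (any(sd <= 0)) stop("component sd must be > 0", call. = FALSE)
  if (any(weight <= 0) || any(weight > 1)) {
    stop("component weights must lie in (0, 1]", call. = FALSE)
  }
  s <- sum(weight)
  if (abs(s - 1) > 1e-6) {
    stop("component weights must sum to 1 (got ", format(s), ")", call. = FALSE)
  }
  weight <- weight / s
  ord <- order(mean)
  fit <- structure(
    list(
      components = data.frame(mean = mean[ord], sd = sd[ord],
                              weight = weight[ord]),
      k = k,
      n_params = 3L * k - 1L,
      loglik = loglik,
      bic = if (is.na(loglik) || is.na(n)) NA_real_ else
        bic_score(loglik, 3L * k - 1L, n),
      n = n,
      converged = converged,
      n_iter = n_iter,
      n_restarts = n_restarts,
      floor_hit = FALSE
    ),
    class = "mixture_fit"
  )
  fit
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: k = %d component%s", x$k,
              if (x$k > 1) "s" else ""), "\n")
  print(round(x$components, 4))
  if (!is.na(x$loglik)) {
    cat(sprintf("logLik = %.3f, BIC = %.3f (n = %s, params = %d)\n",
                x$loglik, x$bic, x$n, x$n_params))
  }
  if (isTRUE(x$floor_hit)) cat("note: variance floor reached\n")
  invisible(x)
}

#' BIC in the maximization convention
#'
#' `2 * loglik - n_params * log(n)`: larger is better, matching the
#' model-based-clustering convention in which the selected model is the one
#' with the highest BIC.
#'
#' @param loglik log-likelihood of the fitted model.
#' @param n_params number of free parameters (for a k-component univariate
#'   Gaussian mixture with unequal variances, `3k - 1`).
#' @param n number of observations.
#' @return the BIC value.
#' @export
bic_score <- function(loglik, n_params, n) {
  stopifnot(is.finite(loglik), n_params >= 1, n >= 1)
  2 * loglik - n_params * log(n)
}

# Per-observation log mixture density contributions: n x k matrix of
# log(w_j) + log phi(x; mu_j, sd_j).
.component_logdens <- function(x, comp) {
  k <- nrow(comp)
  m <- matrix(0, length(x), k)
  for (j in seq_len(k)) {
    m[, j] <- log(comp$weight[j]) +
      stats::dnorm(x, comp$mean[j], comp$sd[j], log = TRUE)
  }
  m
}

.mixture_loglik <- function(x, comp) {
  sum(log_row_sum_exp(.component_logdens(x, comp)))
}

# One EM run from a given parameter start; returns parameters, loglik trace
# and convergence info. sd_floor guards against spike components.
#
# Convergence: relative log-likelihood change below tol, or the Aitken
# estimate of the asymptotic log-likelihood within tol * |loglik| of the
# current value (EM improves geometrically near a solution, so the Aitken
# limit detects convergence long before the raw increments vanish).
.em_run <- function(x, comp, tol, max_iter, sd_floor) {
  n <- length(x)
  k <- nrow(comp)
  mu <- comp$mean
  sd_ <- comp$sd
  w <- comp$weight
  half_l2pi <- 0.5 * log(2 * pi)
  ll_trace <- numeric(max_iter)
  converged <- FALSE
  iter <- 0L
  floor_hit <- FALSE
  for (iter in seq_len(max_iter)) {
    dev <- outer(x, mu, "-")                               # n x k
    ld <- sweep(-0.5 * sweep(dev, 2L, sd_, "/")^2, 2L,
                log(w) - log(sd_) - half_l2pi, "+")
    lse <- log_row_sum_exp(ld)
    ll <- sum(lse)
    ll_trace[iter] <- ll
    if (iter >= 2L) {
      d1 <- ll - ll_trace[iter - 1L]
      if (abs(d1) < tol * (abs(ll) + .Machine$double.eps)) {
        converged <- TRUE
        break
      }
      if (iter >= 3L) {
        d0 <- ll_trace[iter - 1L] - ll_trace[iter - 2L]
        if (d0 > 0 && d1 > 0 && d1 < d0) {
          a <- d1 / d0
          ll_inf <- ll_trace[iter - 1L] + d1 / (1 - a)
          if (abs(ll_inf - ll) < tol * abs(ll)) {
            converged <- TRUE
            break
          }
        }
      }
    }
    r <- exp(ld - lse)                                     # responsibilities
    nk <- colSums(r)
    w <- nk / n
    mu <- colSums(r * x) / nk
    v <- colSums(r * (outer(x, mu, "-")^2)) / nk
    low <- v < sd_floor^2
    floor_hit <- floor_hit || any(low)
    sd_ <- sqrt(pmax(v, sd_floor^2))
  }
  ord <- order(mu)
  list(components = data.frame(mean = mu[ord], sd = sd_[ord],
                               weight = w[ord]),
       loglik = ll_trace[iter],
       loglik_trace = ll_trace[seq_len(iter)],
       converged = converged, n_iter = iter, floor_hit = floor_hit)
}

# Deterministic start: contiguous quantile blocks of the sorted data.
.init_quantile <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  idx <- cut(seq_len(n), breaks = k, labels = FALSE)
  mu <- tapply(xs, idx, mean)
  s <- tapply(xs, idx, function(v) stats::sd(v))
  s[!is.finite(s) | s == 0] <- stats::sd(x) / k
  data.frame(mean = as.numeric(mu), sd = as.numeric(s),
             weight = as.numeric(table(idx)) / n)
}

# Random start that depends on the data only through its order statistics,
# so that fits are invariant to permutations of the input.
.init_random <- function(x, k) {
  q <- sort(stats::runif(k))
  mu <- stats::quantile(sort(x), probs = q, names = FALSE, type = 7)
  data.frame(mean = mu,
             sd = rep(stats::sd(x) * stats::runif(1, 0.5, 1.5), k),
             weight = rep(1 / k, k))
}

#' Fit a k-component univariate Gaussian mixture by EM
#'
#' Runs expectation-maximization with unequal per-component variances from a
#' deterministic quantile-based start plus `n_restarts - 1` seeded random
#' starts, and returns the restart with the highest log-likelihood. A
#' variance floor of `1e-3` times the sample SD prevents degenerate spike
#' components; a fit that ends on the floor is flagged via `floor_hit`.
#'
#' @param x numeric vector of onset ages (positive, finite).
#' @param k number of components (>= 1). Requires `length(x) >= 3k`.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per restart.
#' @param n_restarts total number of starts (first is deterministic).
#' @param seed integer seed controlling the random restarts.
#' @return a `mixture_fit`; the element `loglik_trace` holds the
#'   per-iteration log-likelihood of the winning restart.
#' @examples
#' x <- simulate_mixture(500, mean = c(21, 38), sd = c(4, 12),
#'                       weight = c(0.45, 0.55), seed = 1)
#' fit_em(x, k = 2)
#' @export
fit_em <- function(x, k, tol = 1e-8, max_iter = 1000L, n_restarts = 10L,
                   seed = 1L) {
  x <- check_aao(x, min_n = 2L)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  n <- length(x)
  if (n < 3L * k) {
    stop("too few observations: need n >= 3k = ", 3L * k, ", got ", n,
         call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("degenerate data: all values identical (zero variance)",
         call. = FALSE)
  }

  if (k == 1L) {
    mu <- mean(x)
    s <- sqrt(mean((x - mu)^2))          # maximum-likelihood SD
    ll <- sum(stats::dnorm(x, mu, s, log = TRUE))
    fit <- mixture_fit(mu, s, 1, n = n, loglik = ll, converged = TRUE,
                       n_iter = 0L, n_restarts = 1L)
    fit$loglik_trace <- ll
    return(fit)
  }

  sd_floor <- 1e-3 * stats::sd(x)
  runs <- with_seed(seed, {
    starts <- c(list(.init_quantile(x, k)),
                lapply(seq_len(max(0L, n_restarts - 1L)),
                       function(i) .init_random(x, k)))
    lapply(starts, function(st) .em_run(x, st, tol, max_iter, sd_floor))
  })
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
  comp <- best$components
  fit <- mixture_fit(comp$mean, comp$sd, comp$weight, n = n,
                     loglik = best$loglik, converged = best$converged,
                     n_iter = best$n_iter, n_restarts = as.integer(n_restarts))
  fit$floor_hit <- best$floor_hit
  fit$loglik_trace <- best$loglik_trace
  fit
}

#' Scan candidate component counts and select by BIC
#'
#' Fits `fit_em` for each k in `k_min:k_max` and selects the k maximizing the
#' BIC; exact ties are broken toward the smaller k (parsimony). A k whose fit
#' fails is recorded as missing, excluded from the selection, and reported
#' with a warning.
#'
#' @inheritParams fit_em
#' @param k_min,k_max inclusive range of component counts (default 1 to 9).
#' @return an object of class `model_scan`: list with `fits` (one
#'   `mixture_fit` or NULL per k), `best_k`, `k_range`, and a `bic` vector.
#' @export
scan_components <- function(x, k_min = 1L, k_max = 9L, tol = 1e-8,
                            max_iter = 1000L, n_restarts = 10L, seed = 1L) {
  if (k_min < 1L || k_min > k_max) stop("need 1 <= k_min <= k_max", call. = FALSE)
  ks <- seq.int(k_min, k_max)
  fits <- vector("list", length(ks))
  names(fits) <- as.character(ks)
  for (i in seq_along(ks)) {
    fits[[i]] <- tryCatch(
      fit_em(x, ks[i], tol = tol, max_iter = max_iter,
             n_restarts = n_restarts, seed = seed + ks[i]),
      error = function(e) {
        warning("fit for k = ", ks[i], " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  }
  bic <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$bic,
                numeric(1))
  if (all(is.na(bic))) stop("all component counts failed to fit", call. = FALSE)
  best_k <- ks[which.max(bic)]   # which.max returns the first (smallest k) tie
  structure(list(fits = fits, bic = bic, best_k = best_k,
                 k_range = c(k_min, k_max)),
            class = "model_scan")
}

#' @export
print.model_scan <- function(x, ...) {
  ks <- seq.int(x$k_range[1], x$k_range[2])
  cat("Mixture model scan, k =", x$k_range[1], "to", x$k_range[2], "\n")
  tab <- data.frame(k = ks, BIC = round(x$bic, 1),
                    best = ifelse(ks == x$best_k, "*", ""))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Mixture density, distribution function and posterior responsibilities
#'
#' @param fit a `mixture_fit`.
#' @param x numeric vector of evaluation points (ages in years).
#' @return `mixture_pdf` and `mixture_cdf` return a numeric vector;
#'   `posterior_responsibilities` returns a `length(x)` by `k` matrix whose
#'   rows sum to 1, column j giving the posterior probability that the
#'   observation arose from component j.
#' @examples
#' f <- mixture_fit(c(-2, 2), c(1, 1), c(0.5, 0.5))
#' mixture_cdf(f, 0)                       # 0.5 by symmetry
#' posterior_responsibilities(f, 0)        # (0.5, 0.5)
#' @export
mixture_pdf <- function(fit, x) {
  stopifnot(inherits(fit, "mixture_fit"))
  comp <- fit$components
  out <- numeric(length(x))
  for (j in seq_len(fit$k)) {
    out <- out + comp$weight[j] * stats::dnorm(x, comp$mean[j], comp$sd[j])
  }
  out
}

#' @rdname mixture_pdf
#' @export
mixture_cdf <- function(fit, x) {
  stopifnot(inherits(fit, "mixture_fit"))
  comp <- fit$components
  out <- numeric(length(x))
  for (j in seq_len(fit$k)) {
    out <- out + comp$weight[j] * stats::pnorm(x, comp$mean[j], comp$sd[j])
  }
  out
}

#' @rdname mixture_pdf
#' @export
posterior_responsibilities <- function(fit, x) {
  stopifnot(inherits(fit, "mixture_fit"))
  ld <- .component_logdens(x, fit$components)
  r <- exp(ld - log_row_sum_exp(ld))
  dimnames(r) <- list(NULL, paste0("comp", seq_len(fit$k)))
  r
}

#' Serialize and restore mixture fits as JSON
#'
#' Round-trip lossless serialization of a `mixture_fit` (or a whole
#' `model_scan`) including component parameters, log-likelihood, BIC and
#' convergence metadata.
#'
#' @param fit a `mixture_fit`.
#' @param scan a `model_scan`.
#' @param json a JSON string produced by the corresponding `*_to_json`.
#' @return `*_to_json` return a JSON string; `*_from_json` the restored object.
#' @export
mixture_to_json <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  jsonlite::toJSON(unclass(fit), digits = NA, auto_unbox = TRUE,
                   na = "null", dataframe = "columns")
}

#' @rdname mixture_to_json
#' @export
mixture_from_json <- function(json) {
  o <- jsonlite::fromJSON(json)
  fit <- mixture_fit(o$components$mean, o$components$sd, o$components$weight,
                     n = o$n %||% NA_integer_,
                     loglik = o$loglik %||% NA_real_,
                     converged = o$converged %||% NA,
                     n_iter = o$n_iter %||% NA_integer_,
                     n_restarts = o$n_restarts %||% NA_integer_)
  fit$floor_hit <- isTRUE(o$floor_hit)
  if (!is.null(o$loglik_trace)) fit$loglik_trace <- o$loglik_trace
  fit
}

#' @rdname mixture_to_json
#' @export
scan_to_json <- function(scan) {
  stopifnot(inherits(scan, "model_scan"))
  jsonlite::toJSON(
    list(fits = lapply(scan$fits, function(f)
           if (is.null(f)) NULL else unclass(f)),
         bic = scan$bic, best_k = scan$best_k, k_range = scan$k_range),
    digits = NA, auto_unbox = TRUE, na = "null", dataframe = "columns")
}

#' @rdname mixture_to_json
#' @export
scan_from_json <- function(json) {
  o <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  fits <- lapply(o$fits, function(f) {
    if (is.null(f)) return(NULL)
    mixture_from_json(jsonlite::toJSON(f, digits = NA, auto_unbox = TRUE,
                                       na = "null"))
  })
  structure(list(fits = fits, bic = unlist(o$bic), best_k = o$best_k,
                 k_range = o$k_range),
            class = "model_scan")
}

#' Draw samples from a Gaussian mixture
#'
#' @param n number of draws.
#' @param mean,sd,weight component parameters (equal-length vectors).
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
simulate_mixture <- function(n, mean, sd, weight, seed = 1L) {
  stopifnot(length(mean) == length(sd), length(mean) == length(weight))
  with_seed(seed, {
    z <- sample.int(length(mean), n, replace = TRUE, prob = weight)
    stats::rnorm(n, mean[z], sd[z])
  })
}
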