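# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the caller's RNG state
#' so that seeded package functions never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Validate a vector of onset ages: positive, finite, at least `min_n` values.
check_aao <- function(x, min_n = 2L, what = "aao") {
  if (!is.numeric(x)) stop(what, " must be numeric", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    stop(what, " contains missing or non-finite values", call. = FALSE)
  }
  if (any(x <= 0)) stop(what, " values must be positive (ages in years)", call. = FALSE)
  if (length(x) < min_n) {
    stop(what, " needs at least ", min_n, " observations, got ", length(x),
         call. = FALSE)
  }
  as.numeric(x)
}

# Numerically stable log(sum(exp(v))) over rows of a matrix.
log_row_sum_exp <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

# Lightweight container for test statistics (t, chi-square, KS D, r, kappa).
test_result <- function(statistic, df = NULL, p_value = NULL, method,
                        n = NULL, note = NULL) {
  if (!is.null(p_value) && !is.na(p_value) &&
      (p_value < 0 || p_value > 1)) {
    stop("p-value outside [0, 1]", call. = FALSE)
  }
  structure(
    list(statistic = as.numeric(statistic), df = df, p_value = p_value,
         method = method, n = n, note = note),
    class = "onsetmix_test"
  )
}

#' @export
print.onsetmix_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic =", format(x$statistic, digits = 6))
  if (!is.null(x$df)) cat(", df =", x$df)
  if (!is.null(x$p_value)) cat(", p =", format.pval(x$p_value, digits = 4))
  cat("\n")
  if (!is.null(x$n)) cat("  n =", paste(x$n, collapse = " / "), "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
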