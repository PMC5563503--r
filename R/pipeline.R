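# End-to-end orchestration: per-diagnosis admixture analysis (model scan,
# best fit, cut-off, labelling) and the clinical-correlates battery on the
# labelled cohort, with report tables mirroring the published layout.

# Default variable-role map for the association battery.
.default_roles <- function() {
  list(
    binary = c(female = "sex", fh_any = "fh_any", fh_mood = "fh_mood",
               fh_bd = "fh_bd", substance_dep = "substance_dep",
               alcohol_dep = "alcohol_dep", suicidal = "suicidal"),
    continuous = c(age_at_interview = "age_at_interview",
                   illness_duration = "illness_duration",
                   n_manic = "n_manic", n_depressive = "n_depressive",
                   n_mixed = "n_mixed"),
    multinomial = c(course = "course")
  )
}

#' Per-diagnosis admixture analysis of age at onset
#'
#' For each requested diagnosis (plus, optionally, the pooled sample) runs a
#' BIC model scan over `k_min:k_max` components, derives the integer
#' early/late-onset cut-off from the best two-component solution, and labels
#' the patients. Produces a BIC report table (one row per candidate k) with
#' the best model flagged.
#'
#' @param cohort cohort data.frame with columns `diagnosis` and `aao`.
#' @param diagnoses character vector of diagnosis values to analyse;
#'   defaults to the observed values. Use `"all"` for the pooled sample
#'   (always included by default).
#' @param k_min,k_max component-count range for the scan.
#' @param n_restarts,tol,max_iter EM settings, see [fit_em()].
#' @param seed integer seed for the EM restarts.
#' @return list of class `admixture_result`, one element per analysed group:
#'   `scan` (a `model_scan`), `best_fit`, `boundaries`, `cutoff`,
#'   `subgroups` (an `onset_subgrouping`, NULL when the best fit has a
#'   single component), and `report` (data.frame of k, loglik, BIC,
#'   parameters).
#' @export
run_admixture <- function(cohort, diagnoses = NULL, k_min = 1L, k_max = 9L,
                          n_restarts = 10L, tol = 1e-8, max_iter = 1000L,
                          seed = 1L) {
  for (col in c("diagnosis", "aao")) {
    if (!col %in% names(cohort)) {
      stop("cohort is missing required column '", col, "'", call. = FALSE)
    }
  }
  diagnoses <- diagnoses %||% c(unique(as.character(cohort$diagnosis)), "all")
  out <- list()
  for (dg in diagnoses) {
    sub <- if (dg == "all") cohort else cohort[cohort$diagnosis == dg, ]
    scan <- scan_components(sub$aao, k_min = k_min, k_max = k_max, tol = tol,
                            max_iter = max_iter, n_restarts = n_restarts,
                            seed = seed)
    best <- scan$fits[[as.character(scan$best_k)]]
    cutoff <- NULL
    boundaries <- NULL
    sg <- NULL
    if (best$k >= 2L) {
      boundaries <- posterior_boundaries(best)
      cutoff <- integer_cutoff(best)[1L]
      sg <- assign_subgroups(sub, cutoff)
    }
    rows <- lapply(scan$fits, function(f) {
      if (is.null(f)) return(NULL)
      data.frame(diagnosis = dg, k = f$k, loglik = f$loglik, bic = f$bic,
                 best = f$k == scan$best_k,
                 components = paste(
                   sprintf("%.1f/%.1f/%.0f%%", f$components$mean,
                           f$components$sd, 100 * f$components$weight),
                   collapse = "; "))
    })
    out[[dg]] <- list(scan = scan, best_fit = best, boundaries = boundaries,
                      cutoff = cutoff, subgroups = sg,
                      report = do.call(rbind, rows))
  }
  class(out) <- "admixture_result"
  out
}

#' @export
print.admixture_result <- function(x, ...) {
  for (dg in names(x)) {
    r <- x[[dg]]
    cat(sprintf("== %s (n = %d): best k = %d", dg, r$best_fit$n,
                r$best_fit$k))
    if (!is.null(r$cutoff)) {
      cat(sprintf(", cut-off = %d y (EO %d / LO %d)", r$cutoff,
                  r$subgroups$counts[1], r$subgroups$counts[2]))
    }
    cat("\n")
  }
  invisible(x)
}

# One univariate battery row. Returns NULL when the variable is absent or
# degenerate in this cohort.
.univariate_row <- function(cohort, name, col, type, alpha) {
  g <- cohort$onset_group
  v <- cohort[[col]]
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2L) return(NULL)
  res <- tryCatch({
    if (type == "continuous") {
      tr <- pooled_t_raw(v[g == "EO"], v[g == "LO"])
      data.frame(variable = name, type = type,
                 summary_EO = sprintf("%.1f (%.1f)", mean(v[g == "EO"]),
                                      stats::sd(v[g == "EO"])),
                 summary_LO = sprintf("%.1f (%.1f)", mean(v[g == "LO"]),
                                      stats::sd(v[g == "LO"])),
                 statistic = tr$statistic, df = tr$df, p = tr$p_value,
                 n = length(v))
    } else {
      vv <- if (type == "binary") {
        pres <- if (col == "sex") v == "F" else v == 1 | v == TRUE
        factor(pres, levels = c(TRUE, FALSE))   # "present" category first
      } else {
        factor(v)
      }
      tab <- table(vv, g)
      if (nrow(tab) < 2L) return(NULL)
      ct <- pearson_chi2(t(tab))   # rows = groups, cols = categories
      lead <- tab[1L, ]            # first category count per group
      data.frame(variable = name, type = type,
                 summary_EO = sprintf("%d (%.1f%%)", lead["EO"],
                                      100 * lead["EO"] / sum(tab[, "EO"])),
                 summary_LO = sprintf("%d (%.1f%%)", lead["LO"],
                                      100 * lead["LO"] / sum(tab[, "LO"])),
                 statistic = ct$statistic, df = ct$df, p = ct$p_value,
                 n = length(v))
    }
  }, error = function(e) NULL)
  res
}

#' Clinical-correlates battery on a labelled cohort
#'
#' Runs the univariate screen (pooled t for continuous variables,
#' uncorrected Pearson chi-square for binary and multinomial ones) of every
#' mapped variable against the EO/LO label, then forwards the variables
#' significant at `alpha` to a backward stepwise logistic regression of
#' early-onset membership. Missing values are deleted pairwise per variable
#' and the effective n is reported per row. Age at interview is excluded
#' from the multivariate model whenever illness duration qualifies, since
#' the two are near-collinear by construction (duration = interview age -
#' onset age); multinomial variables are screened univariately only.
#'
#' @param cohort labelled cohort (must contain `onset_group`).
#' @param roles variable-role map: list with character vectors `binary`,
#'   `continuous`, `multinomial` (names = report labels, values = column
#'   names). Defaults to the generated-cohort dictionary.
#' @param alpha significance level for the univariate screen and for
#'   stepwise retention.
#' @param criterion stepwise removal criterion, `"wald"` or `"lr"`.
#' @return list of class `correlates_result`: `univariate` (report
#'   data.frame), `screened` (variables entering the model), `model` (a
#'   `logistic_model`, or NULL with `notice` when no variable passes the
#'   screen), `alpha`.
#' @export
run_correlates <- function(cohort, roles = .default_roles(), alpha = 0.05,
                           criterion = "wald") {
  if (!"onset_group" %in% names(cohort)) {
    stop("cohort is missing 'onset_group' labels; run the admixture step first",
         call. = FALSE)
  }
  cohort$onset_group <- factor(cohort$onset_group, levels = c("EO", "LO"))
  rows <- list()
  for (type in c("binary", "continuous", "multinomial")) {
    vars <- roles[[type]]
    for (i in seq_along(vars)) {
      nm <- names(vars)[i] %||% vars[i]
      if (!vars[i] %in% names(cohort)) next
      rows[[length(rows) + 1L]] <-
        .univariate_row(cohort, nm, vars[i], type, alpha)
    }
  }
  uni <- do.call(rbind, rows)
  if (is.null(uni)) {
    stop("no mapped variables found in the cohort", call. = FALSE)
  }
  elig <- uni$variable[uni$p < alpha & uni$type != "multinomial"]
  # drop interview age when illness duration qualifies: the two are
  # near-collinear (r ~ 1 by construction)
  if (all(c("age_at_interview", "illness_duration") %in% elig)) {
    elig <- setdiff(elig, "age_at_interview")
  }
  model <- NULL
  notice <- NULL
  if (length(elig) == 0L) {
    notice <- "no variable passed the univariate screen; multivariate analysis skipped"
  } else {
    allroles <- c(roles$binary, roles$continuous)
    cols <- allroles[match(elig, names(allroles))]
    X <- cohort[, cols, drop = FALSE]
    names(X) <- elig
    if ("female" %in% names(X)) X$female <- as.integer(cohort$sex == "F")
    y <- as.integer(cohort$onset_group == "EO")
    model <- tryCatch(
      backward_stepwise(y, X, alpha = alpha, criterion = criterion),
      error = function(e) {
        notice <<- paste("multivariate fit failed:", conditionMessage(e))
        NULL
      })
  }
  structure(list(univariate = uni, screened = elig, model = model,
                 notice = notice, alpha = alpha),
            class = "correlates_result")
}

#' @export
print.correlates_result <- function(x, ...) {
  cat("Univariate screen (alpha =", x$alpha, ")\n")
  u <- x$univariate
  u$statistic <- round(u$statistic, 1)
  u$p <- signif(u$p, 2)
  print(u, row.names = FALSE)
  if (!is.null(x$notice)) cat("\n", x$notice, "\n", sep = "")
  if (!is.null(x$model)) {
    cat("\nBackward stepwise logistic model (outcome: early onset)\n")
    print(x$model)
  }
  invisible(x)
}

#' Write pipeline report tables
#'
#' `write_admixture_report` emits the per-diagnosis BIC table as TSV plus a
#' JSON file of the full fit objects; `write_correlates_report` emits the
#' univariate battery table as TSV.
#'
#' @param result an `admixture_result` or `correlates_result`.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_admixture_report <- function(result, dir) {
  stopifnot(inherits(result, "admixture_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rep <- do.call(rbind, lapply(result, `[[`, "report"))
  rep$loglik <- round(rep$loglik, 1)
  rep$bic <- round(rep$bic, 1)
  utils::write.table(rep, file.path(dir, "admixture_bic.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fits <- lapply(result, function(r) {
    jsonlite::fromJSON(mixture_to_json(r$best_fit))
  })
  cut <- lapply(result, function(r)
    list(cutoff = r$cutoff,
         counts = if (is.null(r$subgroups)) NULL else r$subgroups$counts))
  jsonlite::write_json(list(best_fits = fits, cutoffs = cut),
                       file.path(dir, "admixture_fits.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' @rdname write_admixture_report
#' @export
write_correlates_report <- function(result, dir) {
  stopifnot(inherits(result, "correlates_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  u <- result$univariate
  u$statistic <- round(u$statistic, 1)
  utils::write.table(u, file.path(dir, "correlates_univariate.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$model)) {
    utils::write.table(result$model$table,
                       file.path(dir, "correlates_model.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
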