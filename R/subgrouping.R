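# Onset subgrouping: posterior crossing points of a fitted mixture, the
# integer early/late-onset (EO/LO) cut-off, and patient labelling.
#
# For two normal components with unequal variances the weighted densities
# cross at the real roots of a quadratic; the crossing above the lower
# component's mean is the classification boundary. The printed cut-off is an
# integer age: the smallest integer at which the later component's posterior
# responsibility strictly exceeds 0.5, and that age itself belongs to the
# late-onset group (EO strictly below the cut-off, LO at or above).

#' Crossing ages of adjacent weighted component densities
#'
#' For each pair of adjacent components (sorted by mean) solves
#' `w_i phi_i(x) = w_j phi_j(x)`. With unequal SDs this is a quadratic in x
#' and can have two real roots: besides the classification boundary between
#' the means, a second low-age crossing exists where the wider component
#' dominates again. All real roots are returned, sorted ascending.
#'
#' @param fit a `mixture_fit` with k >= 2.
#' @return numeric vector of crossing ages with attribute `pair` giving the
#'   (lower) component index of the adjacent pair each root comes from.
#' @examples
#' f <- mixture_fit(c(-10, 10), c(1, 1), c(0.5, 0.5))
#' posterior_boundaries(f)   # 0
#' @export
posterior_boundaries <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (fit$k < 2L) {
    stop("no boundaries: the fit has a single component", call. = FALSE)
  }
  comp <- fit$components
  roots <- numeric(0)
  pair <- integer(0)
  for (i in seq_len(fit$k - 1L)) {
    j <- i + 1L
    m1 <- comp$mean[i]; s1 <- comp$sd[i]; w1 <- comp$weight[i]
    m2 <- comp$mean[j]; s2 <- comp$sd[j]; w2 <- comp$weight[j]
    # log w1 - log s1 - (x-m1)^2/(2 s1^2) = log w2 - log s2 - (x-m2)^2/(2 s2^2)
    A <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
    B <- m1 / s1^2 - m2 / s2^2
    C <- log(w1 / w2) + log(s2 / s1) - m1^2 / (2 * s1^2) + m2^2 / (2 * s2^2)
    if (abs(A) < 1e-14) {
      r <- if (abs(B) < 1e-14) numeric(0) else -C / B
    } else {
      disc <- B^2 - 4 * A * C
      r <- if (disc < 0) numeric(0) else
        (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
    }
    roots <- c(roots, r)
    pair <- c(pair, rep.int(i, length(r)))
  }
  ord <- order(roots)
  structure(roots[ord], pair = pair[ord])
}

#' Integer early/late-onset cut-off from a two-component mixture
#'
#' Returns the smallest integer age, strictly greater than the lower-mean
#' component's mean, at which the higher-mean component's posterior
#' responsibility strictly exceeds 0.5. By convention that age belongs to
#' the late-onset group (EO < cutoff, LO >= cutoff); an integer age at which
#' the responsibility is exactly 0.5 is therefore not yet late-onset and the
#' cut-off falls at the next integer.
#'
#' For fits with k > 2 a cut-off is derived per adjacent component pair by
#' the same rule applied to the pair's two components; the main pipeline only
#' uses k = 2.
#'
#' @param fit a `mixture_fit` with k >= 2.
#' @return integer cut-off age in years (a vector of length k - 1 when k > 2).
#' @examples
#' bd2 <- mixture_fit(c(20.9, 38.2), c(4.1, 11.8), c(0.44, 0.56))
#' integer_cutoff(bd2)   # 28
#' @export
integer_cutoff <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (fit$k < 2L) {
    stop("no boundaries: the fit has a single component", call. = FALSE)
  }
  comp <- fit$components
  out <- integer(fit$k - 1L)
  for (i in seq_len(fit$k - 1L)) {
    j <- i + 1L
    pairfit <- mixture_fit(comp$mean[c(i, j)], comp$sd[c(i, j)],
                           comp$weight[c(i, j)] / sum(comp$weight[c(i, j)]))
    b <- posterior_boundaries(pairfit)
    upper <- b[b > comp$mean[i]]
    if (length(upper) == 0) {
      stop("no posterior crossing above the mean of component ", i,
           call. = FALSE)
    }
    ages <- seq.int(floor(comp$mean[i]) + 1L,
                    ceiling(max(upper)) + 2L)
    r2 <- posterior_responsibilities(pairfit, ages)[, 2L]
    hit <- which(r2 > 0.5)
    if (length(hit) == 0) {
      stop("no integer age with late-component responsibility > 0.5",
           call. = FALSE)
    }
    out[i] <- ages[hit[1L]]
  }
  if (fit$k == 2L) out[1L] else out
}

#' Label a cohort into early/late-onset subgroups
#'
#' Applies an integer cut-off to the `aao` column: ages strictly below the
#' cut-off are early onset (EO), ages at or above it late onset (LO). The
#' labels are written back into the cohort as an `onset_group` column.
#'
#' @param cohort data.frame with at least columns `subject_id` and `aao`.
#' @param cutoff integer cut-off age in years.
#' @return an object of class `onset_subgrouping`: list with `cutoff`,
#'   `labels` (factor EO/LO), `counts`, `proportions`, and `cohort` (the
#'   input with `onset_group` added).
#' @export
assign_subgroups <- function(cohort, cutoff) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    stop("cohort is empty", call. = FALSE)
  }
  if (!"aao" %in% names(cohort)) stop("cohort lacks an 'aao' column", call. = FALSE)
  cutoff <- as.integer(cutoff)
  miss <- is.na(cohort$aao)
  if (any(miss)) {
    ids <- if ("subject_id" %in% names(cohort)) {
      cohort$subject_id[miss]
    } else {
      which(miss)
    }
    stop("missing aao for subjects: ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  labels <- factor(ifelse(cohort$aao < cutoff, "EO", "LO"),
                   levels = c("EO", "LO"))
  cohort$onset_group <- labels
  counts <- table(labels)
  structure(
    list(cutoff = cutoff,
         labels = labels,
         counts = as.integer(counts),
         proportions = as.numeric(counts) / nrow(cohort),
         cohort = cohort),
    class = "onset_subgrouping"
  )
}

#' @export
print.onset_subgrouping <- function(x, ...) {
  cat(sprintf("Onset subgroups at cut-off %d years (EO < %d <= LO)\n",
              x$cutoff, x$cutoff))
  cat(sprintf("  EO: %d (%.1f%%)   LO: %d (%.1f%%)\n",
              x$counts[1], 100 * x$proportions[1],
              x$counts[2], 100 * x$proportions[2]))
  invisible(x)
}

#' Write a subgroup summary as TSV
#'
#' @param sg an `onset_subgrouping`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_subgroup_tsv <- function(sg, path) {
  stopifnot(inherits(sg, "onset_subgrouping"))
  df <- data.frame(group = c("EO", "LO"), cutoff = sg$cutoff,
                   n = sg$counts, proportion = sg$proportions)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
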