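#' The four robustness/evolvability classes
#'
#' Class labels, in the fixed order used throughout the package. A mutant is
#' *robust* when it preserves every attractor of the original network and
#' *evolvable* when it exhibits at least one new attractor; the four
#' combinations partition all possible attractor-set changes.
#'
#' @return character vector of the four class labels.
#' @export
robustness_classes <- function() {
  c("not_robust_not_evolvable", "not_robust_evolvable",
    "robust_not_evolvable", "robust_evolvable")
}

#' Classify an attractor-set change into a robustness/evolvability class
#'
#' Given the attractor sets of an original network (`A`) and of a mutant
#' (`A'`), with attractor identity defined by equality of state sets (cycle
#' rotation irrelevant), the class is:
#' * `A' = A` — `robust_not_evolvable` (everything preserved, nothing new);
#' * `A'` a proper subset of `A` — `not_robust_not_evolvable`;
#' * `A` a proper subset of `A'` — `robust_evolvable`;
#' * incomparable (each side has an attractor the other lacks) —
#'   `not_robust_evolvable`.
#'
#' These four relations are exhaustive and mutually exclusive for nonempty
#' finite sets, so exactly one class is always returned.
#'
#' @param A,A_prime `state_space_analysis` objects (from [find_attractors()]
#'   on networks of the same size), or plain character vectors of attractor
#'   keys.
#' @return one of [robustness_classes()].
#' @export
classify_change <- function(A, A_prime) {
  if (inherits(A, "state_space_analysis") &&
      inherits(A_prime, "state_space_analysis")) {
    if (A$N != A_prime$N)
      stop(sprintf("incomparable networks: N=%d vs N=%d", A$N, A_prime$N))
    a <- attractor_key_set(A)
    b <- attractor_key_set(A_prime)
  } else {
    a <- as.character(A)
    b <- as.character(A_prime)
  }
  if (length(a) == 0L || length(b) == 0L)
    stop("attractor sets must be nonempty")
  a_in_b <- all(a %in% b)
  b_in_a <- all(b %in% a)
  if (a_in_b && b_in_a) "robust_not_evolvable"
  else if (b_in_a) "not_robust_not_evolvable"
  else if (a_in_b) "robust_evolvable"
  else "not_robust_evolvable"
}

#' Class distribution of a mutant cohort
#'
#' Classifies every mutant of a cohort against the original network by
#' exhaustive attractor comparison and tabulates the percentage frequency of
#' the four classes.
#'
#' @param net the original [boolean_network()].
#' @param mutants a cohort from [sample_mutants()], or a list of
#'   [boolean_network()] objects.
#' @param cap exhaustive-enumeration cap passed to [find_attractors()].
#' @return an object of class `class_distribution`: a list with
#'   `percentages` (named, summing to 100), `counts`, `classes` (per-mutant
#'   labels) and `n_mutants`.
#' @export
class_distribution <- function(net, mutants, cap = 26L) {
  if (length(mutants) == 0L) stop("empty mutant cohort")
  nets <- lapply(mutants, function(m)
    if (inherits(m, "boolean_network")) m else m$network)
  A <- find_attractors(net, cap = cap)
  cls <- vapply(nets, function(mut)
    classify_change(A, find_attractors(mut, cap = cap)), character(1))
  counts <- table(factor(cls, levels = robustness_classes()))
  structure(list(percentages = 100 * as.vector(counts) / length(cls),
                 counts = counts, classes = cls, n_mutants = length(cls)),
            class = "class_distribution")
}

#' @export
print.class_distribution <- function(x, ...) {
  cat(sprintf("Class distribution over %d mutants:\n", x$n_mutants))
  for (i in seq_along(x$counts))
    cat(sprintf("  %-26s %5d  (%.1f%%)\n", names(x$counts)[i],
                x$counts[i], x$percentages[i]))
  invisible(x)
}

#' Cramer's V association between two categorical variables
#'
#' `V = sqrt(chi^2 / (n * min(r - 1, c - 1)))` with the standard Pearson
#' chi-squared statistic on an r-by-c contingency table of counts. `V`
#' ranges from 0 (independence) to 1 (perfect association) and is invariant
#' under row/column permutation and under scaling all counts by a positive
#' integer. All-zero rows and columns are dropped before the computation; the
#' reduced table must still be at least 2 x 2.
#'
#' @param table matrix of nonnegative counts with at least 2 rows and 2
#'   columns (after dropping empty margins) and a positive total.
#' @return Cramer's V in `[0, 1]`.
#' @examples
#' cramers_v(diag(50, 2))  # 1: perfect association
#' @export
cramers_v <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("contingency table must contain nonnegative integer counts")
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("degenerate contingency table: need >= 2 nonempty rows and columns")
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected)
  sqrt(chi2 / (n * min(nrow(tab) - 1L, ncol(tab) - 1L)))
}
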