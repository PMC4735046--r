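#' Cross-tabulate two binary vectors
#'
#' Counts the four logical states of a pair of binary variables: `a` joint
#' presence, `b` present on the first only, `c` present on the second only,
#' `d` joint absence.
#'
#' @param x,y Binary (0/1) vectors of equal length.
#' @return An object of class `agreement_counts`: list with integer fields
#'   `a`, `b`, `c`, `d` and `n = a + b + c + d`.
#' @export
#' @examples
#' cross_tabulate(c(1, 1, 0, 0), c(1, 0, 1, 0))
cross_tabulate <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length (", length(x), " vs ", length(y), ")")
  check_binary(x, "x"); check_binary(y, "y")
  x <- as.logical(x); y <- as.logical(y)
  a <- sum(x & y)
  counts <- list(a = a, b = sum(x) - a, c = sum(y) - a,
                 d = sum(!x & !y), n = length(x))
  structure(counts, class = "agreement_counts")
}

#' @export
print.agreement_counts <- function(x, ...) {
  cat(sprintf("a=%d b=%d c=%d d=%d (n=%d)\n", x$a, x$b, x$c, x$d, x$n))
  invisible(x)
}

#' Jaccard agreement from a 2x2 cross-classification
#'
#' `a / (a + b + c)`: the proportion of subjects positive on either variable
#' who are positive on both. Joint absences (`d`) are ignored, which keeps the
#' measure meaningful for low-prevalence traits where `d` dominates by design.
#'
#' @param counts An [cross_tabulate()] result, or a list with fields
#'   `a`, `b`, `c`.
#' @return Numeric in `[0, 1]`, or `NA_real_` when `a + b + c = 0` (agreement
#'   undefined; the caller decides how to treat it, it is never coerced to 0).
#' @export
#' @examples
#' jaccard(cross_tabulate(c(1, 1, 0), c(1, 0, 1)))
jaccard <- function(counts) {
  denom <- counts$a + counts$b + counts$c
  if (denom == 0) return(NA_real_)
  counts$a / denom
}

#' Diagnostic persistence across waves
#'
#' The conditional probability of diagnosing at Wave 2 given a Wave-1
#' diagnosis: `sum(dx1 & dx2) / sum(dx1)`.
#'
#' @param dx1,dx2 Binary diagnosis vectors of equal length.
#' @return Numeric in `[0, 1]`, or `NA_real_` when no subject diagnoses at
#'   Wave 1.
#' @export
persistence <- function(dx1, dx2) {
  if (length(dx1) != length(dx2))
    stop("dx1 and dx2 must have equal length")
  check_binary(dx1, "dx1"); check_binary(dx2, "dx2")
  n1 <- sum(dx1 == 1)
  if (n1 == 0) return(NA_real_)
  sum(dx1 == 1 & dx2 == 1) / n1
}

# Jaccard of dx1 against every column of a binary matrix, vectorized.
# col_sums may be precomputed; n1 = sum(dx1).
jaccard_columns <- function(dx1, mat, col_sums = colSums(mat), n1 = sum(dx1)) {
  a <- as.vector(crossprod(mat, as.numeric(dx1)))
  denom <- n1 + col_sums - a
  out <- a / denom
  out[denom == 0] <- NA_real_
  out
}

#' Axis I comorbidity of a diagnosis
#'
#' The median, over the Axis I symptom disorders, of the Jaccard agreement
#' between the Wave-1 diagnosis and each disorder indicator. With an even
#' number of disorders the median is the mean of the two middle order
#' statistics.
#'
#' @param dx1 Binary Wave-1 diagnosis vector.
#' @param axis1 `N x M` binary matrix of disorder indicators (columns are
#'   disorders).
#' @return Numeric in `[0, 1]`; `NA_real_` if any constituent Jaccard is
#'   undefined.
#' @export
comorbidity_axis1 <- function(dx1, axis1) {
  axis1 <- as.matrix(axis1)
  if (length(dx1) != nrow(axis1))
    stop("dx1 length must equal the number of rows of axis1")
  if (ncol(axis1) < 1) stop("axis1 must contain at least one disorder")
  j <- jaccard_columns(dx1, axis1)
  if (anyNA(j)) return(NA_real_)
  stats::median(j)
}

#' Axis II comorbidity of a diagnosis
#'
#' A weighted combination of per-cluster median Jaccard agreements between the
#' Wave-1 diagnosis and the personality disorders of clusters A, B and C. The
#' default weights (.1, .7, .2) reflect the stronger association of the
#' dramatic/erratic cluster B disorders with AUD, with cluster C slightly
#' ahead of cluster A.
#'
#' @param dx1 Binary Wave-1 diagnosis vector.
#' @param cluster_a,cluster_b,cluster_c Binary disorder matrices for the three
#'   clusters.
#' @param weights Nonnegative cluster weights `(wA, wB, wC)` summing to 1.
#' @return Numeric in `[0, 1]`; `NA_real_` if any constituent Jaccard is
#'   undefined.
#' @export
comorbidity_axis2 <- function(dx1, cluster_a, cluster_b, cluster_c,
                              weights = c(.1, .7, .2)) {
  check_cluster_weights(weights)
  meds <- vapply(list(cluster_a, cluster_b, cluster_c), function(m) {
    m <- as.matrix(m)
    if (ncol(m) < 1) stop("each cluster must contain at least one disorder")
    j <- jaccard_columns(dx1, m)
    if (anyNA(j)) NA_real_ else stats::median(j)
  }, numeric(1))
  if (anyNA(meds)) return(NA_real_)
  sum(weights * meds)
}

check_cluster_weights <- function(weights) {
  if (length(weights) != 3 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("cluster weights must be three nonnegative values summing to 1")
  invisible(weights)
}

#' Validity profile of a diagnostic rule
#'
#' Applies a rule at both waves and computes the four per-rule metrics used by
#' the optimizer: Wave-1 prevalence, persistence, Axis I comorbidity and
#' Axis II comorbidity. Metrics are unweighted subject counts; survey weights
#' enter only at external validation.
#'
#' @param rule A [diagnostic_rule()].
#' @param panel A [criterion_panel()].
#' @param comorbidity A [comorbidity_panel()].
#' @param cluster_weights Axis II cluster weights, see [comorbidity_axis2()].
#' @return An object of class `validity_profile`: list with
#'   `prevalence_w1`, `persistence`, `comorbidity_ax1`, `comorbidity_ax2`,
#'   `valid`. When no subject diagnoses at Wave 1 the rule is flagged
#'   `valid = FALSE` and the three validity metrics are `NA` (absent, not 0).
#' @export
validity_profile <- function(rule, panel, comorbidity,
                             cluster_weights = c(.1, .7, .2)) {
  stopifnot(inherits(panel, "criterion_panel"),
            inherits(comorbidity, "comorbidity_panel"))
  dx1 <- apply_rule(rule, panel$wave1)
  prev <- mean(dx1)
  if (prev == 0) {
    return(structure(list(prevalence_w1 = 0, persistence = NA_real_,
                          comorbidity_ax1 = NA_real_,
                          comorbidity_ax2 = NA_real_, valid = FALSE),
                     class = "validity_profile"))
  }
  dx2 <- apply_rule(rule, panel$wave2)
  structure(list(
    prevalence_w1 = prev,
    persistence = persistence(dx1, dx2),
    comorbidity_ax1 = comorbidity_axis1(dx1, comorbidity$axis1),
    comorbidity_ax2 = comorbidity_axis2(dx1, comorbidity$cluster_a,
                                        comorbidity$cluster_b,
                                        comorbidity$cluster_c,
                                        weights = cluster_weights),
    valid = TRUE
  ), class = "validity_profile")
}

#' @export
print.validity_profile <- function(x, ...) {
  if (!x$valid) {
    cat("Validity profile: invalid (no Wave-1 diagnoses)\n")
  } else {
    cat(sprintf(
      "Validity profile: P(AUD1)=%.4f  P(AUD2|AUD1)=%.4f  C(AxI)=%.4f  C(AxII)=%.4f\n",
      x$prevalence_w1, x$persistence, x$comorbidity_ax1, x$comorbidity_ax2))
  }
  invisible(x)
}
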