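# External validation: overlap cross-classification and survey-weighted
# planned comparisons among diagnosis subgroups.

#' Cross-classify two diagnoses
#'
#' Partitions subjects into the four cells of the 2x2 table comparing two
#' diagnostic rules' diagnosis vectors.
#'
#' @param dxA,dxB Binary diagnosis vectors of equal length.
#' @return An object of class `overlap_table`: counts `both`, `a_only`,
#'   `b_only`, `neither` plus the corresponding subject index lists (`ids`).
#' @export
#' @examples
#' cross_classify(c(1, 1, 0, 0), c(1, 0, 1, 0))
cross_classify <- function(dxA, dxB) {
  if (length(dxA) != length(dxB))
    stop("dxA and dxB must have equal length")
  check_binary(dxA, "dxA"); check_binary(dxB, "dxB")
  A <- dxA == 1; B <- dxB == 1
  ids <- list(both = which(A & B), a_only = which(A & !B),
              b_only = which(!A & B), neither = which(!A & !B))
  structure(list(both = length(ids$both), a_only = length(ids$a_only),
                 b_only = length(ids$b_only), neither = length(ids$neither),
                 n = length(dxA), ids = ids),
            class = "overlap_table")
}

#' @export
print.overlap_table <- function(x, ...) {
  cat(sprintf("Overlap: both=%d  A-only=%d  B-only=%d  neither=%d  (n=%d)\n",
              x$both, x$a_only, x$b_only, x$neither, x$n))
  invisible(x)
}

weighted_moments <- function(x, w) {
  keep <- !is.na(x) & !is.na(w)
  x <- x[keep]; w <- w[keep]
  sw <- sum(w)
  if (sw <= 0 || !length(x))
    return(list(mean = NA_real_, var = NA_real_, n_eff = 0))
  m <- sum(w * x) / sw
  n_eff <- sw^2 / sum(w^2)
  v <- if (n_eff > 1) sum(w * (x - m)^2) / sw * n_eff / (n_eff - 1)
       else NA_real_
  list(mean = m, var = v, n_eff = n_eff)
}

#' Survey-weighted two-group comparison
#'
#' Welch-type comparison of weighted group means using effective sample sizes
#' `n_eff = (sum w)^2 / sum(w^2)`: the statistic is the difference of weighted
#' means over the square root of `s1^2/n_eff1 + s2^2/n_eff2` with
#' Welch-Satterthwaite degrees of freedom. With unit weights this is exactly
#' the ordinary Welch two-sample t test. Missing values are dropped pairwise.
#'
#' @param values Numeric vector over all subjects (0/1 for binary validators;
#'   the comparison is then a difference of weighted proportions).
#' @param weights Survey weights (positive on group members).
#' @param group1,group2 Subject index vectors for the two groups.
#' @param label Optional validator label carried into the output.
#' @return A one-row data frame of class `comparison_row`: `validator`,
#'   `diff` (group1 minus group2), `t`, `df`, `p` (two-sided), `n_eff1`,
#'   `n_eff2`, `estimable`. A group with effective size below 2 makes the row
#'   non-estimable.
#' @export
#' @examples
#' weighted_comparison(c(1, 2, 3, 4, 5, 6), rep(1, 6), 1:3, 4:6)
weighted_comparison <- function(values, weights, group1, group2,
                                label = NA_character_) {
  if (!length(group1) || !length(group2)) {
    return(comparison_row(label, NA, NA, NA, NA, 0, 0, FALSE))
  }
  g1 <- weighted_moments(values[group1], weights[group1])
  g2 <- weighted_moments(values[group2], weights[group2])
  if (g1$n_eff < 2 || g2$n_eff < 2 || is.na(g1$var) || is.na(g2$var)) {
    return(comparison_row(label, g1$mean - g2$mean, NA, NA, NA,
                          g1$n_eff, g2$n_eff, FALSE))
  }
  d <- g1$mean - g2$mean
  se2 <- g1$var / g1$n_eff + g2$var / g2$n_eff
  if (se2 == 0) {
    tstat <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else 0
    df <- NA_real_
  } else {
    tstat <- d / sqrt(se2)
    df <- se2^2 / ((g1$var / g1$n_eff)^2 / (g1$n_eff - 1) +
                     (g2$var / g2$n_eff)^2 / (g2$n_eff - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  comparison_row(label, d, tstat, df, p, g1$n_eff, g2$n_eff, TRUE)
}

comparison_row <- function(label, d, tstat, df, p, n1, n2, estimable) {
  out <- data.frame(validator = label, diff = d, t = tstat, df = df, p = p,
                    n_eff1 = n1, n_eff2 = n2, estimable = estimable,
                    stringsAsFactors = FALSE)
  class(out) <- c("comparison_row", class(out))
  out
}

#' External validation report for two competing rules
#'
#' Cross-classifies the Wave-1 diagnoses of two rules and runs the three
#' planned contrasts — A-only vs B-only, A-only vs Both, B-only vs Both — on
#' every external validator, using survey-weighted Welch comparisons
#' ([weighted_comparison()]). Binary validators go through the same machinery
#' as differences of weighted proportions.
#'
#' @param ruleA,ruleB [diagnostic_rule()]s to compare (A is typically the
#'   newly derived rule, B the conventional one).
#' @param panel A [criterion_panel()] (its `weights` are used).
#' @param external An [external_panel()].
#' @param wave Wave at which diagnoses are formed (1 or 2; default 1).
#' @param adjust_p If `TRUE`, add Benjamini-Hochberg adjusted p-values per
#'   contrast (off by default; the planned comparisons are reported
#'   unadjusted).
#' @return An object of class `validation_report`: list with `overlap`
#'   ([cross_classify()] result) and `comparisons`, a data frame with one row
#'   per validator per contrast.
#' @export
validation_report <- function(ruleA, ruleB, panel, external, wave = 1,
                              adjust_p = FALSE) {
  stopifnot(inherits(panel, "criterion_panel"),
            inherits(external, "external_panel"))
  if (external$n != panel$n)
    stop("external panel row count does not match criterion panel")
  W <- if (wave == 1) panel$wave1 else panel$wave2
  dxA <- apply_rule(ruleA, W)
  dxB <- apply_rule(ruleB, W)
  overlap <- cross_classify(dxA, dxB)
  groups <- overlap$ids
  contrasts <- list(
    a_only_vs_b_only = c("a_only", "b_only"),
    a_only_vs_both = c("a_only", "both"),
    b_only_vs_both = c("b_only", "both")
  )
  vals <- list()
  if (!is.null(external$scales))
    for (v in colnames(external$scales))
      vals[[v]] <- list(x = external$scales[, v], type = "scale")
  if (!is.null(external$binary_validators))
    for (v in colnames(external$binary_validators))
      vals[[v]] <- list(x = external$binary_validators[, v], type = "binary")
  if (!length(vals)) stop("external panel has no validators")
  rows <- list()
  for (v in names(vals)) {
    for (cn in names(contrasts)) {
      g <- contrasts[[cn]]
      row <- weighted_comparison(vals[[v]]$x, panel$weights,
                                 groups[[g[1]]], groups[[g[2]]], label = v)
      row$type <- vals[[v]]$type
      row$contrast <- cn
      rows[[length(rows) + 1L]] <- row
    }
  }
  comparisons <- do.call(rbind, rows)
  class(comparisons) <- "data.frame"
  if (adjust_p) {
    comparisons$p_adj <- NA_real_
    for (cn in names(contrasts)) {
      i <- comparisons$contrast == cn
      comparisons$p_adj[i] <- stats::p.adjust(comparisons$p[i],
                                              method = "BH")
    }
  }
  structure(list(overlap = overlap, comparisons = comparisons,
                 ruleA = ruleA, ruleB = ruleB, wave = wave),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, digits = 2, ...) {
  cat("External validation of rule A vs rule B\n")
  cat("  A: ", format(x$ruleA), "\n  B: ", format(x$ruleB), "\n", sep = "")
  print(x$overlap)
  cmp <- x$comparisons
  for (cn in unique(cmp$contrast)) {
    cat("\nContrast ", cn, ":\n", sep = "")
    sub <- cmp[cmp$contrast == cn, c("validator", "diff", "t", "p")]
    sub$diff <- round(sub$diff, digits)
    sub$t <- round(sub$t, digits)
    sub$p <- signif(sub$p, 2)
    print(sub, row.names = FALSE)
  }
  invisible(x)
}
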