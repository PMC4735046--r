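#' Select an optimal diagnostic criterion set
#'
#' The central fitting function: exhaustively enumerates every
#' (criterion subset, threshold) diagnostic rule, scores each candidate on
#' persistence and Axis I / Axis II Jaccard comorbidity via rank-based
#' inverse-normal composites over a grid of persistence/comorbidity weights,
#' runs the optimization independently in `k` random folds, and selects final
#' rules two ways: min-max (least-worst percentile) cross-validation across
#' folds, and consensus voting on criterion membership across all per-fold,
#' per-alpha optima.
#'
#' @param panel A [criterion_panel()].
#' @param comorbidity A [comorbidity_panel()].
#' @param k Number of cross-validation folds (default 5).
#' @param alpha_step Alpha grid step (default .10, an 11-point grid).
#' @param cutoff Consensus vote cutoff (default .60).
#' @param min_threshold Endorsement threshold of the consensus rule
#'   (default 2: no single-criterion diagnosis).
#' @param seed Mandatory seed for the fold split.
#' @param cluster_weights Axis II cluster weights (default `(.1, .7, .2)`).
#' @param min_fold_n Minimum fold size for a fold to be optimized.
#' @return An object of class `criterion_select` with components `solutions`
#'   (the [discover_solutions()] result), `crossval` ([cross_validate()]),
#'   `consensus` ([consensus_rule()] result), `votes`, `minmax_rule`,
#'   `consensus_rule`, plus the call and configuration. Methods: `print`,
#'   `summary`, `coef` (the vote vector), `plot` (vote profile with cutoff)
#'   and `predict` (apply a selected rule to new data).
#' @export
#' @examples
#' sim <- make_fixture("tiny", n = 400)
#' fit <- criterion_select(sim$panel, sim$comorbidity, k = 2, seed = 7,
#'                         min_fold_n = 50, min_threshold = 1, cutoff = 0.5)
#' fit
criterion_select <- function(panel, comorbidity, k = 5L, alpha_step = 0.1,
                             cutoff = 0.60, min_threshold = 2L, seed,
                             cluster_weights = c(.1, .7, .2),
                             min_fold_n = 100L) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  cl <- match.call()
  grid <- alpha_grid(alpha_step)
  lattice <- enumerate_rules(panel$k)
  solutions <- discover_solutions(panel, comorbidity, k = k, grid = grid,
                                  seed = seed, lattice = lattice,
                                  cluster_weights = cluster_weights,
                                  min_fold_n = min_fold_n)
  cv <- cross_validate(solutions)
  cons <- consensus(solutions, cutoff = cutoff,
                    min_threshold = min_threshold,
                    criterion_names = panel$criterion_names)
  structure(list(call = cl, solutions = solutions, crossval = cv,
                 consensus = cons, votes = cons$votes,
                 minmax_rule = cv$winner_rule,
                 consensus_rule = cons$final_rule,
                 k = k, grid = grid, cutoff = cutoff,
                 min_threshold = min_threshold, seed = seed,
                 n = panel$n, n_criteria = panel$k,
                 n_rules = nrow(lattice$rules),
                 criterion_names = panel$criterion_names),
            class = "criterion_select")
}

#' @export
print.criterion_select <- function(x, ...) {
  cat("Diagnostic criterion-set optimization\n")
  cat(sprintf("  %d subjects, %d criteria, %d candidate rules, %d folds, %d alpha points\n",
              x$n, x$n_criteria, x$n_rules, x$k, nrow(x$grid)))
  cat("  Min-max (least-worst) rule:  ", format(x$minmax_rule), "\n", sep = "")
  cat("  Consensus rule (cutoff ", sprintf("%.2f", x$cutoff), "): ",
      format(x$consensus_rule), "\n", sep = "")
  invisible(x)
}

#' @export
summary.criterion_select <- function(object, ...) {
  structure(list(fit = object), class = "summary.criterion_select")
}

#' @export
print.summary.criterion_select <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nCriterion votes (proportion of ", nrow(f$solutions$entries),
      " solutions):\n", sep = "")
  v <- sort(f$votes, decreasing = TRUE)
  for (nm in names(v))
    cat(sprintf("  %-20s %.2f%s\n", nm, v[[nm]],
                if (v[[nm]] >= f$cutoff) "  *" else ""))
  cat("  (* retained at cutoff)\n\n")
  cat("Cross-validation (percentile of each discovered rule per fold,\n")
  cat("lower is better; NA on the discovery fold):\n")
  rows <- f$crossval$rows
  disp <- rows[, c("fold", "alpha1_hi", "alpha1_lo", "threshold", "size",
                   colnames(f$crossval$pct), "max_pct")]
  disp[, -(1:5)] <- round(disp[, -(1:5)], 1)
  print(disp, row.names = FALSE)
  cat(sprintf("Least-worst rule: row %d, maximum percentile %.1f%%\n",
              f$crossval$winner, rows$max_pct[f$crossval$winner]))
  invisible(x)
}

#' @export
coef.criterion_select <- function(object, ...) {
  object$votes
}

#' @export
plot.criterion_select <- function(x, ...) {
  v <- x$votes
  op <- graphics::par(mar = c(8, 4, 2, 1))
  on.exit(graphics::par(op))
  bp <- graphics::barplot(v, las = 2, ylim = c(0, 1),
                          ylab = "Vote (proportion of solutions)",
                          main = "Consensus criterion votes",
                          col = ifelse(v >= x$cutoff, "steelblue", "grey80"),
                          ...)
  graphics::abline(h = x$cutoff, lty = 2)
  invisible(bp)
}

#' Apply a selected rule to (new) panel data
#'
#' @param object A [criterion_select()] fit.
#' @param newdata A [criterion_panel()] (or a bare binary matrix) with the
#'   same criteria.
#' @param rule Which selected rule to apply: `"consensus"` (default) or
#'   `"minmax"`, or a [diagnostic_rule()].
#' @param wave Wave to diagnose at when `newdata` is a panel (default 1).
#' @param ... Unused.
#' @return Integer 0/1 diagnosis vector.
#' @export
predict.criterion_select <- function(object, newdata,
                                     rule = c("consensus", "minmax"),
                                     wave = 1, ...) {
  r <- if (inherits(rule, "diagnostic_rule")) rule
       else switch(match.arg(rule),
                   consensus = object$consensus_rule,
                   minmax = object$minmax_rule)
  m <- if (inherits(newdata, "criterion_panel")) {
    if (wave == 1) newdata$wave1 else newdata$wave2
  } else as.matrix(newdata)
  apply_rule(r, m)
}
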