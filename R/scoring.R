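# Rank-based inverse-normal scoring of validity metrics and composite
# optimization over the alpha grid.

#' Alpha weighting grid
#'
#' The grid of persistence/comorbidity weights: `alpha1` from 0 to 1 in fixed
#' steps (default .10, giving 11 points), with `alpha2 = 1 - alpha1`.
#'
#' @param step Grid step in `(0, 1]`.
#' @return Data frame with columns `alpha1`, `alpha2`.
#' @export
alpha_grid <- function(step = 0.1) {
  if (!is.numeric(step) || step <= 0 || step > 1)
    stop("step must be in (0, 1]")
  a1 <- seq(0, 1, by = step)
  if (abs(a1[length(a1)] - 1) > 1e-12) a1 <- c(a1, 1)
  data.frame(alpha1 = a1, alpha2 = 1 - a1)
}

#' Rank-based inverse normal transformation
#'
#' Replaces each value by the standard-normal quantile of its rank percentile:
#' ascending ranks with average ties, percentile `r / (n_valid + 1)` (which
#' keeps quantiles finite at the extremes), then `qnorm`. Entries excluded by
#' `valid_mask` (or `NA`) receive no score.
#'
#' @param values Numeric vector.
#' @param valid_mask Logical vector; `FALSE` entries are excluded from ranking.
#' @return Numeric vector of z-scores, `NA` where excluded. When all valid
#'   values are identical every tie sits at the middle rank, so all z are 0.
#' @export
#' @examples
#' rank_inverse_normal(c(3, 1, 2))  # ~ 0.674, -0.674, 0
rank_inverse_normal <- function(values, valid_mask = NULL) {
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, length(values))
  valid <- valid_mask & !is.na(values)
  nv <- sum(valid)
  if (nv < 2) stop("rank_inverse_normal needs at least 2 valid values")
  r <- rank(values[valid], ties.method = "average")
  z <- rep(NA_real_, length(values))
  z[valid] <- stats::qnorm(r / (nv + 1))
  z
}

#' Composite validity score
#'
#' `S = alpha1 * z_p + (1 - alpha1) * (.5 * z_ax1 + .5 * z_ax2)`: a convex
#' combination of the persistence score and the equally weighted Axis I /
#' Axis II comorbidity scores.
#'
#' @param z_p,z_ax1,z_ax2 Normal scores of persistence and the two
#'   comorbidity metrics (vectors recycle as usual).
#' @param alpha1 Persistence weight in `[0, 1]`.
#' @return Numeric composite score(s).
#' @export
composite_score <- function(z_p, z_ax1, z_ax2, alpha1) {
  if (!is.numeric(alpha1) || any(alpha1 < 0 | alpha1 > 1))
    stop("alpha1 must lie in [0, 1]")
  alpha1 * z_p + (1 - alpha1) * (0.5 * z_ax1 + 0.5 * z_ax2)
}

#' Validity profiles for every rule in a lattice
#'
#' Computes Wave-1 prevalence, persistence and the Axis I / Axis II Jaccard
#' comorbidity metrics for every `(subset, threshold)` rule, sharing the
#' per-subset endorsement counts across thresholds so the full 11-criterion
#' lattice (11,264 rules) profiles in seconds.
#'
#' @param lattice A [enumerate_rules()] lattice matching the panel's `K`.
#' @param panel A [criterion_panel()].
#' @param comorbidity A [comorbidity_panel()].
#' @param cluster_weights Axis II cluster weights.
#' @return Data frame with one row per rule: `rule_id`, `subset_id`, `mask`,
#'   `size`, `threshold`, `prevalence_w1`, `persistence`, `comorbidity_ax1`,
#'   `comorbidity_ax2`, `valid`. Invalid rules (no Wave-1 diagnoses) carry
#'   `NA` metrics.
#' @export
profile_rules <- function(lattice, panel, comorbidity,
                          cluster_weights = c(.1, .7, .2)) {
  stopifnot(inherits(lattice, "rule_lattice"),
            inherits(panel, "criterion_panel"),
            inherits(comorbidity, "comorbidity_panel"))
  if (lattice$n_criteria != panel$k)
    stop("lattice K (", lattice$n_criteria, ") does not match panel K (",
         panel$k, ")")
  if (comorbidity$n != panel$n)
    stop("comorbidity panel row count does not match criterion panel")
  check_cluster_weights(cluster_weights)

  W1 <- panel$wave1; W2 <- panel$wave2; N <- panel$n
  D <- cbind(comorbidity$axis1, comorbidity$cluster_a,
             comorbidity$cluster_b, comorbidity$cluster_c)
  storage.mode(D) <- "double"
  csD <- colSums(D)
  m1 <- ncol(comorbidity$axis1)
  ia <- m1 + seq_len(ncol(comorbidity$cluster_a))
  ib <- m1 + ncol(comorbidity$cluster_a) + seq_len(ncol(comorbidity$cluster_b))
  ic <- m1 + ncol(comorbidity$cluster_a) + ncol(comorbidity$cluster_b) +
    seq_len(ncol(comorbidity$cluster_c))

  rules <- lattice$rules
  nr <- nrow(rules)
  prev <- pers <- com1 <- com2 <- rep(NA_real_, nr)
  valid <- rep(FALSE, nr)

  row <- 0L
  for (s in seq_along(lattice$subsets)) {
    idx <- lattice$subsets[[s]]
    cnt1 <- if (length(idx) == 1L) W1[, idx] else
      rowSums(W1[, idx, drop = FALSE])
    cnt2 <- if (length(idx) == 1L) W2[, idx] else
      rowSums(W2[, idx, drop = FALSE])
    for (t in seq_along(idx)) {
      row <- row + 1L
      dx1 <- cnt1 >= t
      n1 <- sum(dx1)
      prev[row] <- n1 / N
      if (n1 == 0) next
      valid[row] <- TRUE
      pers[row] <- sum(dx1 & (cnt2 >= t)) / n1
      a <- as.vector(crossprod(D, dx1))
      j <- a / (n1 + csD - a)
      com1[row] <- stats::median(j[seq_len(m1)])
      com2[row] <- cluster_weights[1] * stats::median(j[ia]) +
        cluster_weights[2] * stats::median(j[ib]) +
        cluster_weights[3] * stats::median(j[ic])
    }
  }
  data.frame(rule_id = seq_len(nr), subset_id = rules$subset_id,
             mask = rules$mask, size = rules$size,
             threshold = rules$threshold, prevalence_w1 = prev,
             persistence = pers, comorbidity_ax1 = com1,
             comorbidity_ax2 = com2, valid = valid)
}

#' Score table over the alpha grid
#'
#' Rank-inverse-normal transforms the three validity metrics across valid
#' rules and computes the composite `S` and its within-dataset rank percentile
#' (in percent, smaller is better) at every grid point.
#'
#' @param profiles Output of [profile_rules()].
#' @param grid An [alpha_grid()].
#' @return An object of class `score_table`: list with `profiles`, `grid`,
#'   `z` (n_rules x 3 matrix), `S` and `pct` (n_rules x n_alpha matrices, `NA`
#'   rows for invalid rules), and `n_valid`.
#' @export
score_table <- function(profiles, grid = alpha_grid()) {
  valid <- profiles$valid
  if (sum(valid) < 2) stop("fewer than 2 valid rules; cannot rank")
  z <- cbind(
    z_persistence = rank_inverse_normal(profiles$persistence, valid),
    z_ax1 = rank_inverse_normal(profiles$comorbidity_ax1, valid),
    z_ax2 = rank_inverse_normal(profiles$comorbidity_ax2, valid)
  )
  na <- nrow(grid)
  S <- matrix(NA_real_, nrow(profiles), na)
  pct <- matrix(NA_real_, nrow(profiles), na)
  nv <- sum(valid)
  for (j in seq_len(na)) {
    S[, j] <- composite_score(z[, 1], z[, 2], z[, 3], grid$alpha1[j])
    pct[valid, j] <- 100 * rank(-S[valid, j], ties.method = "average") / nv
  }
  colnames(S) <- colnames(pct) <- format_alpha(grid$alpha1)
  structure(list(profiles = profiles, grid = grid, z = z, S = S, pct = pct,
                 n_valid = nv),
            class = "score_table")
}

format_alpha <- function(a) sprintf("a%.2f", a)

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("Score table: %d rules (%d valid) x %d alpha points\n",
              nrow(x$profiles), x$n_valid, nrow(x$grid)))
  invisible(x)
}

# Deterministic argmax of S with parsimony tie-breaking:
# fewer criteria, then lower threshold, then lexicographic bitmask.
pick_winner <- function(S_col, profiles) {
  s_max <- max(S_col, na.rm = TRUE)
  cand <- which(!is.na(S_col) & S_col == s_max)
  if (length(cand) > 1L) {
    o <- order(profiles$size[cand], profiles$threshold[cand],
               profiles$mask[cand])
    cand <- cand[o]
  }
  cand[1L]
}

#' Per-alpha optimal rules for one dataset
#'
#' Enumerates (or reuses) the rule lattice, profiles every rule, scores the
#' composite over the alpha grid, and for each alpha returns the valid rule
#' maximizing `S`. Ties (e.g. rules producing identical diagnosis vectors) are
#' broken parsimony-first: fewer criteria, then lower threshold, then
#' lexicographic bitmask.
#'
#' @param panel A [criterion_panel()].
#' @param comorbidity A [comorbidity_panel()].
#' @param lattice Optional precomputed [enumerate_rules()] lattice.
#' @param grid An [alpha_grid()].
#' @param cluster_weights Axis II cluster weights.
#' @param min_n Minimum subjects required (guards against vacuous optima on
#'   tiny samples); default 100.
#' @return An object of class `optimal_rules`: list with `winners` (data frame
#'   with one row per alpha: `alpha1`, `rule_id`, `mask`, `size`, `threshold`,
#'   the four validity metrics, `S`, `percentile`) and the underlying
#'   `score_table`.
#' @export
optimize_dataset <- function(panel, comorbidity, lattice = NULL,
                             grid = alpha_grid(),
                             cluster_weights = c(.1, .7, .2),
                             min_n = 100L) {
  if (panel$n < min_n)
    stop("panel has ", panel$n, " subjects; minimum is ", min_n)
  if (is.null(lattice)) lattice <- enumerate_rules(panel$k)
  profiles <- profile_rules(lattice, panel, comorbidity, cluster_weights)
  if (!any(profiles$valid))
    stop("no valid rules: no rule diagnoses anyone at Wave 1")
  st <- score_table(profiles, grid)
  idx <- vapply(seq_len(nrow(grid)),
                function(j) pick_winner(st$S[, j], profiles), integer(1))
  winners <- data.frame(
    alpha1 = grid$alpha1,
    rule_id = profiles$rule_id[idx],
    mask = profiles$mask[idx],
    size = profiles$size[idx],
    threshold = profiles$threshold[idx],
    prevalence_w1 = profiles$prevalence_w1[idx],
    persistence = profiles$persistence[idx],
    comorbidity_ax1 = profiles$comorbidity_ax1[idx],
    comorbidity_ax2 = profiles$comorbidity_ax2[idx],
    S = st$S[cbind(idx, seq_len(nrow(grid)))],
    percentile = st$pct[cbind(idx, seq_len(nrow(grid)))]
  )
  structure(list(winners = winners, score_table = st,
                 n_criteria = lattice$n_criteria),
            class = "optimal_rules")
}

#' @export
print.optimal_rules <- function(x, ...) {
  cat("Per-alpha optimal rules:\n")
  w <- x$winners
  for (i in seq_len(nrow(w))) {
    cat(sprintf(
      "  alpha1=%.2f  %d-of-{%s}  P(W1)=%.3f  P(W2|W1)=%.3f\n",
      w$alpha1[i], w$threshold[i],
      paste(mask_to_subset(w$mask[i]), collapse = ","),
      w$prevalence_w1[i], w$persistence[i]))
  }
  invisible(x)
}

#' Extract the winning rule at one alpha
#'
#' @param x An `optimal_rules` object.
#' @param alpha1 Grid point to extract.
#' @param labels Optional criterion dictionary for the returned rule.
#' @return A [diagnostic_rule()].
#' @export
winning_rule <- function(x, alpha1, labels = NULL) {
  stopifnot(inherits(x, "optimal_rules"))
  i <- which(abs(x$winners$alpha1 - alpha1) < 1e-9)
  if (!length(i)) stop("alpha1 = ", alpha1, " is not on the grid")
  diagnostic_rule(mask_to_subset(x$winners$mask[i]),
                  x$winners$threshold[i], labels = labels)
}
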