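# k-fold discovery, min-max cross-validation, and consensus voting.

#' Seeded k-fold partition
#'
#' Randomly partitions `N` subjects into `k` folds whose sizes differ by at
#' most one (the last `N mod k` folds receive the extra subject).
#'
#' @param N Number of subjects.
#' @param k Number of folds, `2 <= k <= N`.
#' @param seed Mandatory integer seed; the same seed reproduces the partition.
#' @return Integer fold assignment vector of length `N` with values in `1..k`.
#' @export
#' @examples
#' table(kfold_split(15773, 5, seed = 1))  # sizes 3154,3154,3155,3155,3155
kfold_split <- function(N, k, seed) {
  N <- as.integer(N); k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be at least 2")
  if (is.na(N) || N < k) stop("N must be at least k")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  sizes <- rep(N %/% k, k)
  extra <- N %% k
  if (extra > 0) sizes[(k - extra + 1):k] <- sizes[(k - extra + 1):k] + 1L
  set.seed(as.integer(seed))
  fold <- integer(N)
  fold[sample.int(N)] <- rep.int(seq_len(k), times = sizes)
  fold
}

subset_panels <- function(panel, comorbidity, rows) {
  list(
    panel = criterion_panel(panel$wave1[rows, , drop = FALSE],
                            panel$wave2[rows, , drop = FALSE],
                            criterion_names = panel$criterion_names,
                            subject_ids = panel$subject_ids[rows],
                            weights = panel$weights[rows]),
    comorbidity = comorbidity_panel(
      comorbidity$axis1[rows, , drop = FALSE],
      comorbidity$cluster_a[rows, , drop = FALSE],
      comorbidity$cluster_b[rows, , drop = FALSE],
      comorbidity$cluster_c[rows, , drop = FALSE])
  )
}

#' Discover per-fold, per-alpha optimal rules
#'
#' Splits the sample into `k` folds and runs the exhaustive optimization
#' ([optimize_dataset()]) independently on each fold at every alpha grid
#' point, yielding `k * nrow(grid)` candidate solutions (55 for five folds and
#' the default 11-point grid).
#'
#' @param panel A [criterion_panel()].
#' @param comorbidity A [comorbidity_panel()].
#' @param k Number of folds (default 5).
#' @param grid An [alpha_grid()].
#' @param seed Mandatory seed for the fold split.
#' @param lattice Optional precomputed lattice (built once and shared).
#' @param cluster_weights Axis II cluster weights.
#' @param min_fold_n Minimum fold size passed to [optimize_dataset()].
#' @return An object of class `solution_set`: list with `entries` (data frame:
#'   `fold`, `alpha1`, `mask`, `size`, `threshold`, validity metrics,
#'   `percentile`), `k`, `grid`, `fold_assignment`, `score_tables` (per-fold
#'   [score_table()]s, kept for cross-validation), `n_criteria`, `seed`.
#'   Folds in which no rule is valid are skipped with a warning.
#' @export
discover_solutions <- function(panel, comorbidity, k = 5L,
                               grid = alpha_grid(), seed,
                               lattice = NULL,
                               cluster_weights = c(.1, .7, .2),
                               min_fold_n = 100L) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (is.null(lattice)) lattice <- enumerate_rules(panel$k)
  fold <- kfold_split(panel$n, k, seed)
  entries <- list(); tables <- vector("list", k)
  for (f in seq_len(k)) {
    sub <- subset_panels(panel, comorbidity, which(fold == f))
    opt <- tryCatch(
      optimize_dataset(sub$panel, sub$comorbidity, lattice = lattice,
                       grid = grid, cluster_weights = cluster_weights,
                       min_n = min_fold_n),
      error = function(e) {
        warning("fold ", f, " skipped: ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(opt)) next
    tables[[f]] <- opt$score_table
    w <- opt$winners
    entries[[length(entries) + 1L]] <- data.frame(
      fold = f, alpha1 = w$alpha1, mask = w$mask, size = w$size,
      threshold = w$threshold, prevalence_w1 = w$prevalence_w1,
      persistence = w$persistence, comorbidity_ax1 = w$comorbidity_ax1,
      comorbidity_ax2 = w$comorbidity_ax2, percentile = w$percentile)
  }
  if (!length(entries)) stop("no fold produced any valid solution")
  structure(list(entries = do.call(rbind, entries), k = k, grid = grid,
                 fold_assignment = fold, score_tables = tables,
                 n_criteria = panel$k, seed = seed),
            class = "solution_set")
}

#' @export
print.solution_set <- function(x, ...) {
  cat(sprintf("Solution set: %d entries (%d folds x %d alpha points)\n",
              nrow(x$entries), x$k, nrow(x$grid)))
  invisible(x)
}

# Collapse per-alpha entries of one fold into runs of consecutive alpha values
# sharing the same (mask, threshold) rule, as candidate rows for
# cross-validation.
collapse_entries <- function(entries) {
  rows <- list()
  for (f in unique(entries$fold)) {
    e <- entries[entries$fold == f, , drop = FALSE]
    e <- e[order(-e$alpha1), , drop = FALSE]  # display order: alpha1 high->low
    key <- paste(e$mask, e$threshold)
    run <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
    for (r in unique(run)) {
      er <- e[run == r, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f, alpha1_hi = max(er$alpha1), alpha1_lo = min(er$alpha1),
        mask = er$mask[1], size = er$size[1], threshold = er$threshold[1])
    }
  }
  do.call(rbind, rows)
}

#' Min-max selection on a percentile matrix
#'
#' Given a matrix of percentile ranks (rows = candidate rules, columns =
#' evaluation datasets, `NA` where a rule is not evaluated, e.g. its own
#' discovery fold), scores each row by its maximum (worst) percentile and
#' selects the row that minimizes it — the least-worst rule. Ties are broken
#' parsimony-first when `size`/`threshold`/`mask` are supplied, otherwise by
#' row order.
#'
#' @param pct Numeric matrix of percentiles in `(0, 100]`; each row must have
#'   at least one non-`NA` cell.
#' @param size,threshold,mask Optional per-row rule descriptors for
#'   tie-breaking.
#' @return List with `winner` (row index), `row_max` (per-row maximum
#'   percentile).
#' @export
#' @examples
#' cv <- aud_crossval_percentiles()
#' cand <- cv[!cv$reference, ]
#' minmax_select(as.matrix(cand[, c("D1", "D2", "D3", "D4", "D5")]))
minmax_select <- function(pct, size = NULL, threshold = NULL, mask = NULL) {
  pct <- as.matrix(pct)
  if (any(rowSums(!is.na(pct)) == 0))
    stop("every row must be evaluated in at least one dataset")
  row_max <- apply(pct, 1, max, na.rm = TRUE)
  cand <- which(row_max == min(row_max))
  if (length(cand) > 1L && !is.null(size)) {
    o <- order(size[cand],
               if (!is.null(threshold)) threshold[cand] else cand,
               if (!is.null(mask)) mask[cand] else cand)
    cand <- cand[o]
  }
  list(winner = cand[1L], row_max = row_max)
}

#' Cross-validate discovered rules across folds
#'
#' Each unique discovered rule (one row per run of consecutive alpha values
#' within its discovery fold) is re-scored in every other fold: its composite
#' percentile is read from that fold's full score table at each alpha in the
#' rule's range and averaged. A rule that is invalid (diagnoses no one) in an
#' evaluation fold receives the worst percentile, 100. The final rule is the
#' min-max (least-worst) row.
#'
#' @param solutions A [discover_solutions()] result (its per-fold score tables
#'   are reused; no recomputation).
#' @return An object of class `crossval_matrix`: list with `rows` (data frame:
#'   fold, alpha range, rule descriptors, per-fold percentiles, `max_pct`),
#'   `pct` (rows x folds matrix, `NA` on the discovery fold), `winner` (row
#'   index) and `winner_rule` (a [diagnostic_rule()]).
#' @export
cross_validate <- function(solutions) {
  stopifnot(inherits(solutions, "solution_set"))
  rows <- collapse_entries(solutions$entries)
  k <- solutions$k
  grid_a <- solutions$grid$alpha1
  pct <- matrix(NA_real_, nrow(rows), k,
                dimnames = list(NULL, paste0("D", seq_len(k))))
  for (i in seq_len(nrow(rows))) {
    a_in <- grid_a >= rows$alpha1_lo[i] - 1e-9 &
      grid_a <= rows$alpha1_hi[i] + 1e-9
    for (f in seq_len(k)) {
      if (f == rows$fold[i]) next
      st <- solutions$score_tables[[f]]
      if (is.null(st)) next
      j <- which(st$profiles$mask == rows$mask[i] &
                   st$profiles$threshold == rows$threshold[i])
      cell <- st$pct[j, a_in]
      cell[is.na(cell)] <- 100  # invalid in this fold: worst possible
      pct[i, f] <- mean(cell)
    }
  }
  sel <- minmax_select(pct, size = rows$size, threshold = rows$threshold,
                       mask = rows$mask)
  rows$max_pct <- sel$row_max
  winner_rule <- diagnostic_rule(mask_to_subset(rows$mask[sel$winner]),
                                 rows$threshold[sel$winner])
  structure(list(rows = cbind(rows, pct), pct = pct, winner = sel$winner,
                 winner_rule = winner_rule),
            class = "crossval_matrix")
}

#' @export
print.crossval_matrix <- function(x, ...) {
  cat(sprintf("Cross-validation matrix: %d candidate rules x %d folds\n",
              nrow(x$pct), ncol(x$pct)))
  cat(sprintf("Least-worst rule (row %d, max percentile %.1f%%): %s\n",
              x$winner, x$rows$max_pct[x$winner], format(x$winner_rule)))
  invisible(x)
}

#' Consensus rule from criterion votes
#'
#' Retains every criterion whose vote (proportion of discovered solutions
#' containing it) meets the cutoff and fixes the diagnosis threshold at a
#' configured minimum — by default 2, so no single criterion can carry a
#' diagnosis alone.
#'
#' @param votes Named numeric vector of per-criterion vote proportions in
#'   `[0, 1]`.
#' @param cutoff Retention cutoff (default .60, markedly above chance).
#' @param min_threshold Endorsement threshold of the final rule (default 2).
#' @param criterion_names Labels when `votes` is unnamed.
#' @return An object of class `consensus_result`: list with `votes`, `cutoff`,
#'   `retained` (criterion indices), `retained_names`, `final_rule`.
#' @export
#' @examples
#' consensus_rule(aud_consensus_votes(), cutoff = 0.60)
consensus_rule <- function(votes, cutoff = 0.60, min_threshold = 2L,
                           criterion_names = names(votes)) {
  if (any(votes < 0 | votes > 1)) stop("votes must lie in [0, 1]")
  retained <- which(votes >= cutoff)
  if (length(retained) < min_threshold)
    stop("only ", length(retained), " criteria reach the ", cutoff,
         " cutoff; lower the cutoff or the minimum threshold")
  if (is.null(criterion_names))
    criterion_names <- paste0("C", seq_along(votes))
  final <- diagnostic_rule(retained, threshold = min_threshold,
                           labels = criterion_names)
  structure(list(votes = stats::setNames(votes, criterion_names),
                 cutoff = cutoff, retained = retained,
                 retained_names = criterion_names[retained],
                 final_rule = final),
            class = "consensus_result")
}

#' Consensus voting over a solution set
#'
#' Computes each criterion's vote as the proportion of the discovered
#' solutions (one per fold x alpha combination; duplicates within a fold count
#' once per alpha) whose optimal rule contains it, then forms the consensus
#' rule via [consensus_rule()].
#'
#' @param solutions A [discover_solutions()] result.
#' @param cutoff,min_threshold See [consensus_rule()].
#' @param criterion_names Labels (default `aud_criteria()` when `K = 11`).
#' @return A `consensus_result`; see [consensus_rule()].
#' @export
consensus <- function(solutions, cutoff = 0.60, min_threshold = 2L,
                      criterion_names = NULL) {
  stopifnot(inherits(solutions, "solution_set"))
  K <- solutions$n_criteria
  if (is.null(criterion_names))
    criterion_names <- if (K == 11) aud_criteria() else paste0("C", seq_len(K))
  masks <- solutions$entries$mask
  votes <- vapply(seq_len(K), function(j) {
    mean(bitwAnd(masks, bitwShiftL(1L, j - 1L)) != 0L)
  }, numeric(1))
  consensus_rule(votes, cutoff = cutoff, min_threshold = min_threshold,
                 criterion_names = criterion_names)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus votes:\n")
  v <- sort(x$votes, decreasing = TRUE)
  for (nm in names(v)) cat(sprintf("  %-20s %.2f\n", nm, v[[nm]]))
  cat(sprintf("Retained at cutoff %.2f: %s\n", x$cutoff,
              paste(x$retained_names, collapse = ", ")))
  cat("Final rule: ", format(x$final_rule), "\n", sep = "")
  invisible(x)
}
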