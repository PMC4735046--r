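#' Construct a diagnostic rule
#'
#' A diagnostic rule is a nonempty subset of criterion indices together with an
#' endorsement threshold `T`: a subject is diagnosed when at least `T` of the
#' criteria in the subset are endorsed.
#'
#' @param subset Integer vector of criterion indices (1-based), nonempty,
#'   without duplicates.
#' @param threshold Integer `T` with `1 <= T <= length(subset)`.
#' @param labels Optional character vector naming the criteria in `subset`
#'   (same length), or a full criterion dictionary from which labels are taken.
#' @return An object of class `diagnostic_rule`: a list with elements
#'   `subset` (sorted indices), `threshold` and `labels`.
#' @export
#' @examples
#' diagnostic_rule(c(1, 2, 7), threshold = 2, labels = aud_criteria())
diagnostic_rule <- function(subset, threshold, labels = NULL) {
  subset <- as.integer(subset)
  if (length(subset) < 1L || anyNA(subset) || any(subset < 1L))
    stop("`subset` must be a nonempty set of positive criterion indices")
  if (anyDuplicated(subset))
    stop("`subset` must not contain duplicate indices")
  ord <- order(subset)
  subset <- subset[ord]
  threshold <- as.integer(threshold)
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 1L || threshold > length(subset))
    stop("`threshold` must satisfy 1 <= T <= |subset| (got T = ", threshold,
         " for a set of ", length(subset), ")")
  if (!is.null(labels)) {
    if (length(labels) == length(subset)) {
      lab <- labels[ord]
    } else if (length(labels) >= max(subset)) {
      lab <- labels[subset]
    } else {
      stop("`labels` must match the subset or cover all its indices")
    }
  } else {
    lab <- NULL
  }
  structure(list(subset = subset, threshold = threshold, labels = lab),
            class = "diagnostic_rule")
}

#' @export
print.diagnostic_rule <- function(x, ...) {
  what <- if (!is.null(x$labels)) paste(x$labels, collapse = ", ")
          else paste(x$subset, collapse = ", ")
  cat(sprintf("Diagnostic rule: %d of {%s}\n", x$threshold, what))
  invisible(x)
}

#' @export
format.diagnostic_rule <- function(x, ...) {
  sprintf("%d-of-%d [%s]", x$threshold, length(x$subset),
          paste(x$subset, collapse = ","))
}

rule_mask <- function(subset) {
  # bit j-1 set iff criterion j in subset; valid for K <= 30
  sum(bitwShiftL(1L, subset - 1L))
}

mask_to_subset <- function(mask) {
  which(bitwAnd(bitwShiftR(mask, 0:29), 1L) == 1L)
}

#' Enumerate the full rule lattice
#'
#' Enumerates every diagnostic rule on `K` criteria: all `2^K - 1` nonempty
#' criterion subsets, each paired with every threshold from 1 to the subset
#' size, giving `K * 2^(K-1)` rules in total. Rules are listed in a fixed
#' canonical order (subset size, then lexicographic subset, then threshold) so
#' downstream results are reproducible.
#'
#' @param K Number of criteria, `1 <= K <= max_k`.
#' @param max_k Guard against combinatorial blow-up (default 24).
#' @return An object of class `rule_lattice`: a list with `n_criteria`,
#'   `subsets` (list of index vectors in canonical order), and `rules`, a data
#'   frame with one row per rule (`subset_id`, `mask`, `size`, `threshold`).
#' @export
#' @examples
#' lat <- enumerate_rules(4)
#' nrow(lat$rules)  # 4 * 2^3 = 32
enumerate_rules <- function(K, max_k = 24L) {
  K <- as.integer(K)
  if (length(K) != 1L || is.na(K) || K < 1L || K > max_k)
    stop("K must be an integer in [1, ", max_k, "]")
  subsets <- vector("list", 2^K - 1)
  pos <- 0L
  for (size in seq_len(K)) {
    comb <- utils::combn(K, size)
    for (j in seq_len(ncol(comb))) {
      pos <- pos + 1L
      subsets[[pos]] <- comb[, j]
    }
  }
  sizes <- lengths(subsets)
  n_rules <- sum(sizes)
  rules <- data.frame(
    subset_id = rep.int(seq_along(subsets), sizes),
    mask = rep.int(vapply(subsets, rule_mask, integer(1)), sizes),
    size = rep.int(sizes, sizes),
    threshold = sequence(sizes)
  )
  structure(list(n_criteria = K, subsets = subsets, rules = rules),
            class = "rule_lattice")
}

#' @export
print.rule_lattice <- function(x, ...) {
  cat(sprintf("Rule lattice on %d criteria: %d subsets, %d (subset, threshold) rules\n",
              x$n_criteria, length(x$subsets), nrow(x$rules)))
  invisible(x)
}

#' Apply a diagnostic rule to an endorsement matrix
#'
#' @param rule A [diagnostic_rule()].
#' @param wave_matrix `N x K` binary matrix of criterion endorsements.
#' @return Integer 0/1 vector of length `N`; entry `i` is 1 iff subject `i`
#'   endorses at least `rule$threshold` of the criteria in `rule$subset`.
#' @export
#' @examples
#' w <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0))
#' apply_rule(diagnostic_rule(1:2, 2), w)
apply_rule <- function(rule, wave_matrix) {
  stopifnot(inherits(rule, "diagnostic_rule"))
  wave_matrix <- as.matrix(wave_matrix)
  if (max(rule$subset) > ncol(wave_matrix))
    stop("rule refers to criterion ", max(rule$subset), " but the matrix has ",
         ncol(wave_matrix), " columns")
  cnt <- rowSums(wave_matrix[, rule$subset, drop = FALSE])
  as.integer(cnt >= rule$threshold)
}

#' Conventional DSM reference rules
#'
#' The two conventional diagnostic algorithms used as comparators:
#' DSM-IV alcohol dependence (3 of the 7 dependence criteria) and the DSM-5
#' AUD 2-of-11 rule over the full criterion set.
#'
#' @return Named list of [diagnostic_rule()] objects `dsm4_dependence` and
#'   `dsm5_aud_2of11`, indexed against [aud_criteria()].
#' @export
#' @examples
#' dsm_reference_rules()$dsm4_dependence
dsm_reference_rules <- function() {
  labs <- aud_criteria()
  dep <- match(c("Tolerance", "Cut Down", "Larger/Longer", "Give Up",
                 "Time Drinking", "Continue", "Withdrawal"), labs)
  list(
    dsm4_dependence = diagnostic_rule(dep, threshold = 3L, labels = labs),
    dsm5_aud_2of11 = diagnostic_rule(seq_along(labs), threshold = 2L,
                                     labels = labs)
  )
}
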