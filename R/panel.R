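# Input containers and validation for two-wave criterion panels,
# comorbidity indicators and external validators.

check_binary <- function(x, what, rows = NULL) {
  v <- x[!is.na(x)]
  if (length(v) && !all(v == 0 | v == 1)) {
    bad <- which(!(x %in% c(0, 1)) & !is.na(x))
    where <- if (!is.null(rows)) paste0(" (rows: ",
                 paste(utils::head(rows[bad], 5), collapse = ", "), ")")
             else paste0(" (positions: ",
                 paste(utils::head(bad, 5), collapse = ", "), ")")
    stop("non-binary value in ", what, where, call. = FALSE)
  }
  invisible(x)
}

as_binary_matrix <- function(x, what, allow_na = FALSE) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (!allow_na && anyNA(m))
    stop("missing values are not allowed in ", what, call. = FALSE)
  check_binary(as.vector(m), what)
  m
}

#' Two-wave criterion endorsement panel
#'
#' Holds per-subject binary endorsement of `K` diagnostic criteria at two
#' survey waves, plus subject identifiers and survey weights.
#'
#' @param wave1,wave2 `N x K` binary matrices (criterion endorsed in the past
#'   year at each wave). Must share dimensions.
#' @param criterion_names Length-`K` labels; defaults to [aud_criteria()] when
#'   `K = 11`, otherwise `C1..CK`.
#' @param subject_ids Unique identifiers (default `1..N`).
#' @param weights Nonnegative survey weights with at least one positive
#'   (default all 1).
#' @return An object of class `criterion_panel`.
#' @export
criterion_panel <- function(wave1, wave2, criterion_names = NULL,
                            subject_ids = NULL, weights = NULL) {
  wave1 <- as_binary_matrix(wave1, "wave1")
  wave2 <- as_binary_matrix(wave2, "wave2")
  if (!identical(dim(wave1), dim(wave2)))
    stop("wave1 and wave2 must share dimensions")
  n <- nrow(wave1); k <- ncol(wave1)
  if (k < 1) stop("panel must contain at least one criterion")
  if (is.null(criterion_names))
    criterion_names <- if (k == 11) aud_criteria() else paste0("C", seq_len(k))
  if (length(criterion_names) != k)
    stop("criterion_names must have length K = ", k)
  if (is.null(subject_ids)) subject_ids <- seq_len(n)
  if (length(subject_ids) != n || anyDuplicated(subject_ids))
    stop("subject_ids must be unique and of length N")
  if (is.null(weights)) weights <- rep(1, n)
  weights <- as.numeric(weights)
  if (length(weights) != n || anyNA(weights) || any(weights < 0) ||
      !any(weights > 0))
    stop("weights must be N nonnegative values with at least one positive")
  colnames(wave1) <- colnames(wave2) <- criterion_names
  structure(list(subject_ids = subject_ids, wave1 = wave1, wave2 = wave2,
                 criterion_names = criterion_names, weights = weights,
                 n = n, k = k),
            class = "criterion_panel")
}

#' @export
print.criterion_panel <- function(x, ...) {
  cat(sprintf("Criterion panel: %d subjects x %d criteria, two waves\n",
              x$n, x$k))
  cat("  Wave-1 endorsement (%):",
      paste(sprintf("%s %.1f", x$criterion_names,
                    100 * colMeans(x$wave1)), collapse = ", "), "\n")
  invisible(x)
}

#' Comorbid-disorder indicator panel
#'
#' Binary lifetime indicators for Axis I symptom disorders and for Axis II
#' personality disorders grouped into clusters A, B and C.
#'
#' @param axis1 `N x M1` binary matrix (default labels [axis1_disorders()]).
#' @param cluster_a,cluster_b,cluster_c Binary matrices for the three Axis II
#'   clusters, each with at least one disorder.
#' @return An object of class `comorbidity_panel`.
#' @export
comorbidity_panel <- function(axis1, cluster_a, cluster_b, cluster_c) {
  axis1 <- as_binary_matrix(axis1, "axis1")
  cluster_a <- as_binary_matrix(cluster_a, "cluster_a")
  cluster_b <- as_binary_matrix(cluster_b, "cluster_b")
  cluster_c <- as_binary_matrix(cluster_c, "cluster_c")
  n <- nrow(axis1)
  for (m in list(cluster_a, cluster_b, cluster_c)) {
    if (nrow(m) != n) stop("all comorbidity matrices must share row count")
    if (ncol(m) < 1) stop("each cluster must contain at least one disorder")
  }
  if (ncol(axis1) < 1) stop("axis1 must contain at least one disorder")
  defaults <- axis2_clusters()
  if (is.null(colnames(axis1)) && ncol(axis1) == 7)
    colnames(axis1) <- axis1_disorders()
  if (is.null(colnames(cluster_a)) && ncol(cluster_a) == 3)
    colnames(cluster_a) <- defaults$cluster_a
  if (is.null(colnames(cluster_b)) && ncol(cluster_b) == 4)
    colnames(cluster_b) <- defaults$cluster_b
  if (is.null(colnames(cluster_c)) && ncol(cluster_c) == 3)
    colnames(cluster_c) <- defaults$cluster_c
  structure(list(axis1 = axis1, cluster_a = cluster_a, cluster_b = cluster_b,
                 cluster_c = cluster_c, n = n),
            class = "comorbidity_panel")
}

#' @export
print.comorbidity_panel <- function(x, ...) {
  cat(sprintf(
    "Comorbidity panel: %d subjects; %d Axis I disorders; clusters A/B/C: %d/%d/%d\n",
    x$n, ncol(x$axis1), ncol(x$cluster_a), ncol(x$cluster_b),
    ncol(x$cluster_c)))
  invisible(x)
}

#' External validator panel
#'
#' Continuous scales (health indices, consumption measures) and binary Wave-2
#' disorder indicators used only for external validation of competing rules.
#' Missing values are allowed and handled pairwise per comparison.
#'
#' @param scales `N x V` numeric matrix with column labels; values finite or
#'   `NA`.
#' @param binary_validators `N x B` binary matrix with column labels; `NA`
#'   allowed.
#' @return An object of class `external_panel`.
#' @export
external_panel <- function(scales = NULL, binary_validators = NULL) {
  n <- NULL
  if (!is.null(scales)) {
    scales <- as.matrix(scales)
    storage.mode(scales) <- "double"
    if (any(!is.finite(scales) & !is.na(scales)))
      stop("scale values must be finite or NA")
    n <- nrow(scales)
  }
  if (!is.null(binary_validators)) {
    binary_validators <- as_binary_matrix(binary_validators,
                                          "binary_validators", allow_na = TRUE)
    if (!is.null(n) && nrow(binary_validators) != n)
      stop("scales and binary_validators must share row count")
    n <- nrow(binary_validators)
  }
  if (is.null(n)) stop("external panel needs at least one validator block")
  structure(list(scales = scales, binary_validators = binary_validators,
                 n = n),
            class = "external_panel")
}

#' @export
print.external_panel <- function(x, ...) {
  cat(sprintf("External panel: %d subjects; %d scales, %d binary validators\n",
              x$n,
              if (is.null(x$scales)) 0L else ncol(x$scales),
              if (is.null(x$binary_validators)) 0L
              else ncol(x$binary_validators)))
  invisible(x)
}

#' Read a subject-level CSV/TSV into validated panels
#'
#' Reads one row per subject and maps columns to roles through a schema (a
#' YAML/JSON file or an equivalent list). Rows with any missing value among
#' the optimization columns (both waves of criteria and all comorbidity
#' indicators) are dropped and counted, mirroring a complete-case rule on the
#' optimization variables only; missingness in external validators is left in
#' place and handled pairwise at comparison time.
#'
#' The schema maps roles to column names:
#' \preformatted{
#' subject_id: id            # optional
#' weight: wt                # optional
#' wave1: {Tolerance: w1_tol, ...}
#' wave2: {Tolerance: w2_tol, ...}
#' axis1: {Major Depression: mdd, ...}
#' cluster_a: {...}; cluster_b: {...}; cluster_c: {...}
#' scales: {...}             # optional
#' binary_validators: {...}  # optional
#' }
#'
#' @param path CSV (comma) or TSV (tab, by `.tsv`/`.txt` extension) file.
#' @param schema Path to a YAML or JSON schema file, or a named list.
#' @return A list with elements `panel` ([criterion_panel()]), `comorbidity`
#'   ([comorbidity_panel()]), `external` ([external_panel()] or `NULL`),
#'   `n_input`, `n_dropped`.
#' @export
read_panel <- function(path, schema) {
  if (!file.exists(path)) stop("input file not found: ", path)
  schema <- load_schema(schema)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  need_maps <- c("wave1", "wave2", "axis1", "cluster_a", "cluster_b",
                 "cluster_c")
  for (role in need_maps)
    if (is.null(schema[[role]]) || !length(schema[[role]]))
      stop("schema is missing the '", role, "' column mapping")
  if (!identical(names(schema$wave1), names(schema$wave2)))
    stop("wave1 and wave2 schema blocks must list the same criteria")
  all_maps <- schema[intersect(names(schema),
                               c(need_maps, "scales", "binary_validators"))]
  wanted <- unlist(all_maps, use.names = FALSE)
  wanted <- c(wanted, unlist(schema[intersect(names(schema),
                                              c("subject_id", "weight"))],
                             use.names = FALSE))
  missing_cols <- setdiff(wanted, names(df))
  if (length(missing_cols))
    stop("schema names columns absent from the file: ",
         paste(missing_cols, collapse = ", "))

  ids <- if (!is.null(schema$subject_id)) df[[schema$subject_id]]
         else seq_len(nrow(df))
  opt_cols <- unlist(schema[need_maps], use.names = FALSE)
  for (col in opt_cols)
    check_binary(df[[col]], paste0("column '", col, "'"), rows = ids)
  keep <- stats::complete.cases(df[, opt_cols, drop = FALSE])
  n_input <- nrow(df)
  df2 <- df[keep, , drop = FALSE]
  ids <- ids[keep]

  block <- function(role) {
    m <- as.matrix(df2[, unlist(schema[[role]], use.names = FALSE),
                       drop = FALSE])
    colnames(m) <- names(schema[[role]])
    m
  }
  panel <- criterion_panel(
    wave1 = block("wave1"), wave2 = block("wave2"),
    criterion_names = names(schema$wave1),
    subject_ids = ids,
    weights = if (!is.null(schema$weight)) df2[[schema$weight]] else NULL)
  comorbidity <- comorbidity_panel(block("axis1"), block("cluster_a"),
                                   block("cluster_b"), block("cluster_c"))
  external <- NULL
  if (!is.null(schema$scales) || !is.null(schema$binary_validators)) {
    for (col in unlist(schema["binary_validators"], use.names = FALSE))
      check_binary(df2[[col]], paste0("column '", col, "'"), rows = ids)
    external <- external_panel(
      scales = if (!is.null(schema$scales)) block("scales"),
      binary_validators = if (!is.null(schema$binary_validators))
        block("binary_validators"))
  }
  list(panel = panel, comorbidity = comorbidity, external = external,
       n_input = n_input, n_dropped = n_input - sum(keep))
}

load_schema <- function(schema) {
  if (is.character(schema) && length(schema) == 1L) {
    if (!file.exists(schema)) stop("schema file not found: ", schema)
    schema <- if (grepl("\\.json$", schema, ignore.case = TRUE))
      jsonlite::read_json(schema, simplifyVector = FALSE)
    else yaml::read_yaml(schema)
  }
  if (!is.list(schema)) stop("schema must be a list or a YAML/JSON file path")
  for (role in c("wave1", "wave2", "axis1", "cluster_a", "cluster_b",
                 "cluster_c", "scales", "binary_validators"))
    if (!is.null(schema[[role]])) schema[[role]] <- unlist(schema[[role]])
  for (role in c("subject_id", "weight"))
    if (!is.null(schema[[role]])) schema[[role]] <- as.character(schema[[role]])
  schema
}

#' Serialize a diagnostic rule to JSON
#'
#' The serialized form records criterion names (not only indices) so rules can
#' be interpreted without the originating panel.
#'
#' @param rule A [diagnostic_rule()].
#' @param criterion_names Dictionary used to label the subset when the rule
#'   carries no labels (default [aud_criteria()] when all indices fit).
#' @param path Optional file to write; when `NULL` the JSON text is returned.
#' @return JSON text (invisibly when written to `path`).
#' @export
#' @examples
#' r <- diagnostic_rule(c(2, 7), 2, labels = aud_criteria())
#' json_to_rule(rule_to_json(r))
rule_to_json <- function(rule, criterion_names = NULL, path = NULL) {
  stopifnot(inherits(rule, "diagnostic_rule"))
  labs <- rule$labels
  if (is.null(labs)) {
    if (is.null(criterion_names) && max(rule$subset) <= 11)
      criterion_names <- aud_criteria()
    labs <- if (!is.null(criterion_names)) criterion_names[rule$subset]
            else as.character(rule$subset)
  }
  txt <- jsonlite::toJSON(list(criteria = labs,
                               indices = rule$subset,
                               threshold = rule$threshold),
                          auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' @rdname rule_to_json
#' @param text JSON text or a path to a JSON file.
#' @export
json_to_rule <- function(text, criterion_names = NULL) {
  obj <- if (length(text) == 1L && file.exists(text)) jsonlite::read_json(text)
         else jsonlite::fromJSON(text, simplifyVector = FALSE)
  threshold <- obj$threshold
  if (is.null(threshold)) stop("serialized rule lacks a threshold")
  idx <- unlist(obj$indices)
  if (is.null(idx)) {
    crit <- unlist(obj$criteria)
    if (is.null(crit)) stop("serialized rule lacks criteria")
    dict <- if (!is.null(criterion_names)) criterion_names else aud_criteria()
    idx <- match(crit, dict)
    if (anyNA(idx))
      stop("unknown criterion name(s): ",
           paste(crit[is.na(idx)], collapse = ", "))
  }
  diagnostic_rule(idx, threshold,
                  labels = if (!is.null(obj$criteria)) unlist(obj$criteria))
}
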