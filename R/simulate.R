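# Synthetic two-wave criterion panels with planted latent-severity structure.
#
# Subjects carry a stable severity factor theta correlated across waves;
# informative criteria load on theta while noise criteria load on a transient
# factor redrawn each wave, so noise criteria specifically damage persistence
# and carry no comorbidity signal -- which is what gives the optimizer its
# pruning signal. Comorbid disorders are thresholded liabilities correlated
# with Wave-1 severity; external scales are linear in Wave-2 severity.

#' Configuration of the synthetic panel generator
#'
#' @param N Number of subjects.
#' @param K Number of criteria.
#' @param difficulties Target marginal endorsement rates in `(0, 1)` (length
#'   `K`); default the published Wave-1 endorsement percentages when `K = 11`.
#' @param discriminations Positive slopes on the latent factor; default 1.5
#'   for informative criteria and 0.8 for noise criteria.
#' @param informative Indices of criteria loading on the stable severity
#'   factor; the rest load on the wave-specific transient factor. Default:
#'   the six-criterion consensus set when `K = 11`, else the first
#'   `ceiling(K/2)`.
#' @param rho Cross-wave latent correlation in `[0, 1]` (drives persistence).
#' @param disorder_prevalences,disorder_loadings Named lists with components
#'   `axis1`, `cluster_a`, `cluster_b`, `cluster_c`: per-disorder lifetime
#'   prevalence targets and loadings on Wave-1 severity.
#' @param scale_loadings Named numeric vector: per-scale loading on Wave-2
#'   severity; scales are scored to mean 50, SD 10 (health indices load
#'   negatively, consumption measures positively).
#' @param binary_validator_prevalences,binary_validator_loadings Named
#'   vectors for Wave-2 binary validators (disorder indicators, craving).
#' @param weight_distribution `"gamma"` (unit-mean gamma, shape 4, mimicking
#'   survey-weight dispersion) or `"unit"`.
#' @param wave_coupling `"independent"` (endorsement noise redrawn each wave)
#'   or `"comonotone"` (uniform draws and the transient factor shared across
#'   waves, so `rho = 1` reproduces Wave 1 exactly at Wave 2).
#' @param seed Mandatory integer seed.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(N, K = 11L,
                             difficulties = NULL,
                             discriminations = NULL,
                             informative = NULL,
                             rho = 0.75,
                             disorder_prevalences = NULL,
                             disorder_loadings = NULL,
                             scale_loadings = NULL,
                             binary_validator_prevalences = NULL,
                             binary_validator_loadings = NULL,
                             weight_distribution = c("gamma", "unit"),
                             wave_coupling = c("independent", "comonotone"),
                             seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  N <- as.integer(N); K <- as.integer(K)
  if (N < 1 || K < 1) stop("N and K must be positive")
  if (is.null(informative)) {
    informative <- if (K == 11)
      match(c("Cut Down", "Time Drinking", "Continue", "Withdrawal",
              "Home/Job", "Fight/Trouble"), aud_criteria())
    else seq_len(ceiling(K / 2))
  }
  informative <- sort(as.integer(informative))
  if (length(informative) < 1 || any(informative < 1 | informative > K))
    stop("informative must be a nonempty subset of 1..K")
  if (is.null(difficulties)) {
    difficulties <- if (K == 11) aud_endorsement_rates()$wave1 / 100
                    else seq(0.30, 0.05, length.out = K)
  }
  if (length(difficulties) != K || any(difficulties <= 0 | difficulties >= 1))
    stop("difficulties must be K rates strictly inside (0, 1)")
  if (is.null(discriminations)) {
    discriminations <- rep(0.8, K)
    discriminations[informative] <- 1.5
  }
  if (length(discriminations) != K || any(discriminations <= 0))
    stop("discriminations must be K positive values")
  if (!is.numeric(rho) || rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  if (is.null(disorder_prevalences)) {
    disorder_prevalences <- list(
      axis1 = stats::setNames(c(.20, .05, .03, .06, .06, .10, .05),
                              axis1_disorders()),
      cluster_a = stats::setNames(c(.04, .03, .04), axis2_clusters()$cluster_a),
      cluster_b = stats::setNames(c(.05, .06, .02, .06),
                                  axis2_clusters()$cluster_b),
      cluster_c = stats::setNames(c(.03, .005, .08), axis2_clusters()$cluster_c)
    )
  }
  if (is.null(disorder_loadings)) {
    disorder_loadings <- lapply(disorder_prevalences, function(p) {
      stats::setNames(rep(0.40, length(p)), names(p))
    })
    disorder_loadings$cluster_a[] <- 0.30
    disorder_loadings$cluster_b[] <- 0.50
    disorder_loadings$cluster_c[] <- 0.35
  }
  for (blk in c("axis1", "cluster_a", "cluster_b", "cluster_c")) {
    p <- disorder_prevalences[[blk]]
    if (is.null(p) || !length(p)) stop("disorder_prevalences$", blk,
                                       " must be nonempty")
    if (any(abs(stats::qnorm(p)) > 6))
      stop("unreachable prevalence target in ", blk,
           " (|probit| > 6)")
    l <- disorder_loadings[[blk]]
    if (length(l) != length(p) || any(abs(l) >= 1))
      stop("disorder_loadings$", blk, " must match prevalences, |loading| < 1")
  }
  if (is.null(scale_loadings)) {
    sf <- c("Phys. Hlth.", "Ment. Hlth.", "Phys. Health (Sub)", "Role Phys.",
            "Bodily Pain", "Gen. Hlth.", "Vitality", "Social",
            "Role Emotional", "Ment. Hlth. (Sub)")
    scale_loadings <- c(stats::setNames(rep(-3, length(sf)), sf),
                        "Ethanol Consump." = 4, "5+ Drinks" = 4)
  }
  if (any(abs(scale_loadings) >= 10))
    stop("scale loadings must satisfy |loading| < 10 (total SD is 10)")
  if (is.null(binary_validator_prevalences)) {
    binary_validator_prevalences <- c(
      stats::setNames(c(.22, .06, .04, .07, .07, .11, .06),
                      paste0(axis1_disorders(), " (W2)")),
      "Craving" = .05)
  }
  if (is.null(binary_validator_loadings)) {
    binary_validator_loadings <- stats::setNames(
      rep(0.40, length(binary_validator_prevalences)),
      names(binary_validator_prevalences))
    binary_validator_loadings["Craving"] <- 0.60
  }
  if (any(abs(stats::qnorm(binary_validator_prevalences)) > 6))
    stop("unreachable binary-validator prevalence target (|probit| > 6)")
  structure(list(
    N = N, K = K, difficulties = difficulties,
    discriminations = discriminations, informative = informative,
    rho = rho, disorder_prevalences = disorder_prevalences,
    disorder_loadings = disorder_loadings, scale_loadings = scale_loadings,
    binary_validator_prevalences = binary_validator_prevalences,
    binary_validator_loadings = binary_validator_loadings,
    weight_distribution = match.arg(weight_distribution),
    wave_coupling = match.arg(wave_coupling),
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Solve the criterion intercept b so that E[plogis(a * (theta - b))] over
# theta ~ N(0,1) equals the target marginal rate.
solve_difficulty <- function(p_target, a) {
  f <- function(b) {
    stats::integrate(function(th) stats::plogis(a * (th - b)) *
                       stats::dnorm(th),
                     -Inf, Inf, rel.tol = 1e-9)$value - p_target
  }
  stats::uniroot(f, c(-12, 12), tol = 1e-9)$root
}

#' Generate synthetic two-wave panels
#'
#' Draws the latent structure described in [generator_config()]: stable
#' severity `theta1 ~ N(0,1)` with
#' `theta2 = rho * theta1 + sqrt(1 - rho^2) * noise`, a transient factor per
#' wave for noise criteria, logistic criterion endorsements, thresholded
#' disorder liabilities correlated with Wave-1 severity, scales linear in
#' Wave-2 severity (mean 50, SD 10), and survey weights. Deterministic given
#' the config seed.
#'
#' @param config A [generator_config()].
#' @return List with `panel` ([criterion_panel()]), `comorbidity`
#'   ([comorbidity_panel()]), `external` ([external_panel()]) and `truth`, a
#'   record of the latent draws and solved parameters.
#' @export
#' @examples
#' sim <- generate_panels(generator_config(N = 200, K = 3, seed = 1))
#' sim$panel
generate_panels <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  N <- config$N; K <- config$K
  theta1 <- stats::rnorm(N)
  theta2 <- config$rho * theta1 +
    sqrt(1 - config$rho^2) * stats::rnorm(N)
  u1 <- stats::rnorm(N)
  u2 <- if (config$wave_coupling == "comonotone") u1 else stats::rnorm(N)

  b <- vapply(seq_len(K), function(j) {
    solve_difficulty(config$difficulties[j], config$discriminations[j])
  }, numeric(1))

  is_inf <- seq_len(K) %in% config$informative
  eff1 <- outer(theta1, rep(1, K)); eff1[, !is_inf] <- u1
  eff2 <- outer(theta2, rep(1, K)); eff2[, !is_inf] <- u2
  p1 <- stats::plogis(sweep(sweep(eff1, 2, b), 2, config$discriminations, `*`))
  p2 <- stats::plogis(sweep(sweep(eff2, 2, b), 2, config$discriminations, `*`))
  if (config$wave_coupling == "comonotone") {
    U <- matrix(stats::runif(N * K), N, K)
    wave1 <- (U < p1) * 1; wave2 <- (U < p2) * 1
  } else {
    wave1 <- (matrix(stats::runif(N * K), N, K) < p1) * 1
    wave2 <- (matrix(stats::runif(N * K), N, K) < p2) * 1
  }
  crit_names <- if (K == 11) aud_criteria() else paste0("C", seq_len(K))
  colnames(wave1) <- colnames(wave2) <- crit_names

  draw_block <- function(prev, load, theta) {
    m <- matrix(0, N, length(prev), dimnames = list(NULL, names(prev)))
    for (j in seq_along(prev)) {
      liab <- load[j] * theta + sqrt(1 - load[j]^2) * stats::rnorm(N)
      m[, j] <- (liab > stats::qnorm(1 - prev[j])) * 1
    }
    m
  }
  com <- comorbidity_panel(
    axis1 = draw_block(config$disorder_prevalences$axis1,
                       config$disorder_loadings$axis1, theta1),
    cluster_a = draw_block(config$disorder_prevalences$cluster_a,
                           config$disorder_loadings$cluster_a, theta1),
    cluster_b = draw_block(config$disorder_prevalences$cluster_b,
                           config$disorder_loadings$cluster_b, theta1),
    cluster_c = draw_block(config$disorder_prevalences$cluster_c,
                           config$disorder_loadings$cluster_c, theta1))

  sl <- config$scale_loadings
  scales <- matrix(0, N, length(sl), dimnames = list(NULL, names(sl)))
  for (j in seq_along(sl)) {
    scales[, j] <- 50 + sl[j] * theta2 +
      stats::rnorm(N, sd = sqrt(100 - sl[j]^2))
  }
  bv <- draw_block(config$binary_validator_prevalences,
                   config$binary_validator_loadings, theta2)
  external <- external_panel(scales = scales, binary_validators = bv)

  weights <- switch(config$weight_distribution,
                    gamma = stats::rgamma(N, shape = 4, rate = 4),
                    unit = rep(1, N))
  panel <- criterion_panel(wave1, wave2, criterion_names = crit_names,
                           weights = weights)
  truth <- list(theta1 = theta1, theta2 = theta2,
                informative = config$informative, intercepts = b,
                config = config)
  list(panel = panel, comorbidity = com, external = external, truth = truth)
}

#' Named fixture presets
#'
#' Deterministic small datasets used throughout the test-suite:
#' * `"tiny"`: N = 20, K = 3 toy panel for oracle tests.
#' * `"table2_like"`: K = 11 with difficulties calibrated to the published
#'   Wave-1 endorsement percentages, N = 500.
#' * `"planted6"`: K = 11 with exactly the six consensus criteria informative
#'   (stable-severity loadings) and five noise criteria (transient loadings),
#'   N = 10,000 by default.
#'
#' @param name Preset label.
#' @param n Optional subject-count override.
#' @param seed Optional seed override.
#' @return As [generate_panels()].
#' @export
make_fixture <- function(name, n = NULL, seed = NULL) {
  presets <- list(
    tiny = function() generator_config(
      N = n %||% 20L, K = 3L, difficulties = c(.35, .25, .15),
      informative = 1:2, rho = 0.8, seed = seed %||% 101L),
    table2_like = function() generator_config(
      N = n %||% 500L, K = 11L, seed = seed %||% 202L),
    planted6 = function() generator_config(
      N = n %||% 10000L, K = 11L, seed = seed %||% 11L)
  )
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  generate_panels(presets[[name]]())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

slugify <- function(x) {
  s <- tolower(gsub("[^A-Za-z0-9]+", "_", x))
  gsub("^_|_$", "", s)
}

#' Write generated panels to CSV with a matching schema
#'
#' Emits `panel.csv`, `schema.yaml` and (when a truth record is present)
#' `truth.json` into `dir`, in the layout [read_panel()] expects — useful for
#' round-trip tests and for driving the command-line pipeline.
#'
#' @param panels A list as returned by [generate_panels()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the schema list.
#' @export
write_panels <- function(panels, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- panels$panel; com <- panels$comorbidity; ext <- panels$external
  df <- data.frame(id = p$subject_ids, wt = p$weights)
  schema <- list(subject_id = "id", weight = "wt")
  add_block <- function(df, m, prefix, role) {
    cols <- paste0(prefix, "_", slugify(colnames(m)))
    df[cols] <- as.data.frame(m)
    schema[[role]] <<- stats::setNames(as.list(cols), colnames(m))
    df
  }
  df <- add_block(df, p$wave1, "w1", "wave1")
  df <- add_block(df, p$wave2, "w2", "wave2")
  df <- add_block(df, com$axis1, "ax1", "axis1")
  df <- add_block(df, com$cluster_a, "ca", "cluster_a")
  df <- add_block(df, com$cluster_b, "cb", "cluster_b")
  df <- add_block(df, com$cluster_c, "cc", "cluster_c")
  if (!is.null(ext)) {
    if (!is.null(ext$scales)) df <- add_block(df, ext$scales, "sc", "scales")
    if (!is.null(ext$binary_validators))
      df <- add_block(df, ext$binary_validators, "bv", "binary_validators")
  }
  utils::write.csv(df, file.path(dir, "panel.csv"), row.names = FALSE)
  yaml::write_yaml(schema, file.path(dir, "schema.yaml"))
  if (!is.null(panels$truth)) {
    tr <- panels$truth
    jsonlite::write_json(
      list(informative = tr$informative, intercepts = tr$intercepts,
           seed = tr$config$seed, rho = tr$config$rho,
           N = tr$config$N, K = tr$config$K),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(schema)
}
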