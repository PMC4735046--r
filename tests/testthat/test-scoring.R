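# Rank-based inverse-normal transform, composite scoring, and per-dataset
# optimization against the brute-force oracle.

test_that("rank_inverse_normal maps rank percentiles to normal quantiles", {
  z <- rank_inverse_normal(c(3, 1, 2))
  expect_equal(z, qnorm(c(3, 1, 2) / 4), tolerance = 1e-12)
  expect_equal(z[1], 0.6744898, tolerance = 1e-6)
  expect_equal(z[2], -0.6744898, tolerance = 1e-6)
  expect_equal(z[3], 0)
  # ties share the average rank
  expect_equal(rank_inverse_normal(c(5, 5)), c(0, 0))
  expect_equal(rank_inverse_normal(c(7, 7, 7, 7)), rep(0, 4))
  # masked and NA entries receive no score and don't shift others
  z2 <- rank_inverse_normal(c(3, 1, 2, 100), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(z2[1:3], z, tolerance = 1e-12)
  expect_true(is.na(z2[4]))
  expect_error(rank_inverse_normal(c(1, NA), c(TRUE, TRUE)), "2 valid")
})

test_that("normal scores are antisymmetric about the median rank", {
  set.seed(9)
  for (n in c(5, 8, 13)) {
    v <- sample(seq_len(100), n)  # tie-free
    z <- rank_inverse_normal(v)
    zo <- z[order(v)]
    expect_equal(zo, -rev(zo), tolerance = 1e-12)
  }
})

test_that("composite score is the stated convex combination", {
  expect_equal(composite_score(1.0, 0.5, -0.5, alpha1 = 0.6), 0.6)
  expect_equal(composite_score(2.3, 1, -1, alpha1 = 1), 2.3)
  expect_equal(composite_score(9, 1.2, 1.2, alpha1 = 0), 1.2)
  expect_error(composite_score(1, 1, 1, alpha1 = 1.2), "alpha1")
  # monotone nondecreasing in each z input
  base <- composite_score(0.3, 0.1, -0.2, 0.4)
  expect_gte(composite_score(0.4, 0.1, -0.2, 0.4), base)
  expect_gte(composite_score(0.3, 0.2, -0.2, 0.4), base)
  expect_gte(composite_score(0.3, 0.1, -0.1, 0.4), base)
})

test_that("the alpha grid spans 0..1 with alpha2 the complement", {
  g <- alpha_grid()
  expect_equal(nrow(g), 11)
  expect_equal(g$alpha1, seq(0, 1, .1))
  expect_equal(g$alpha1 + g$alpha2, rep(1, 11))
})

test_that("profile_rules agrees with per-rule oracle metrics on the fixture", {
  fx <- tiny_fixture()
  ps <- make_panels(fx)
  lat <- enumerate_rules(3)
  prof <- profile_rules(lat, ps$panel, ps$comorbidity)
  expect_equal(nrow(prof), 12)
  for (i in seq_len(nrow(prof))) {
    subset <- lat$subsets[[prof$subset_id[i]]]
    om <- oracle_metrics(subset, prof$threshold[i], fx$w1, fx$w2,
                         fx$ax1, fx$ca, fx$cb, fx$cc)
    expect_equal(prof$valid[i], om$valid)
    expect_equal(prof$prevalence_w1[i], om$prev)
    if (om$valid) {
      expect_equal(prof$persistence[i], om$pers)
      expect_equal(prof$comorbidity_ax1[i], om$c1)
      expect_equal(prof$comorbidity_ax2[i], om$c2)
    }
  }
})

test_that("optimizer winner matches brute-force recomputation at every alpha", {
  for (cfg in list(list(K = 3, seed = 31), list(K = 4, seed = 41))) {
    sim <- generate_panels(generator_config(N = 250, K = cfg$K,
                                            rho = 0.7, seed = cfg$seed))
    opt <- optimize_dataset(sim$panel, sim$comorbidity, min_n = 10)
    oracle <- oracle_optimize(sim$panel$wave1, sim$panel$wave2,
                              sim$comorbidity$axis1, sim$comorbidity$cluster_a,
                              sim$comorbidity$cluster_b,
                              sim$comorbidity$cluster_c,
                              alphas = alpha_grid()$alpha1)
    expect_equal(opt$winners$mask, oracle$mask)
    expect_equal(opt$winners$threshold, oracle$threshold)
  }
})

test_that("a rule dominating all three metrics wins at every alpha", {
  # wave matrices engineered so rule {1}, T=1 has the best persistence and
  # the best comorbidity with every disorder
  set.seed(5)
  n <- 120
  good <- rbinom(n, 1, 0.4)
  noise1 <- rbinom(n, 1, 0.3); noise2 <- rbinom(n, 1, 0.3)
  w1 <- cbind(good, noise1, noise2)
  w2 <- cbind(good, rbinom(n, 1, 0.3), rbinom(n, 1, 0.3))
  dis <- function() ifelse(good == 1, rbinom(n, 1, .8), rbinom(n, 1, .02))
  com <- comorbidity_panel(cbind(dis(), dis(), dis()),
                           cbind(dis()), cbind(dis()), cbind(dis()))
  opt <- optimize_dataset(criterion_panel(w1, w2), com, min_n = 10)
  expect_true(all(opt$winners$mask == 1 & opt$winners$threshold == 1))
})

test_that("equal-S ties break toward the smaller subset", {
  # criterion 3 duplicates criterion 1, so {1} and {1,3} with T matched
  # produce identical diagnoses; parsimony must prefer {1}
  fx <- tiny_fixture()
  w1 <- cbind(fx$w1[, 1], fx$w1[, 2], fx$w1[, 1])
  w2 <- cbind(fx$w2[, 1], fx$w2[, 2], fx$w2[, 1])
  ps <- list(panel = criterion_panel(w1, w2),
             comorbidity = comorbidity_panel(fx$ax1, fx$ca, fx$cb, fx$cc))
  opt <- optimize_dataset(ps$panel, ps$comorbidity, min_n = 5)
  st <- opt$score_table
  dup <- which(st$profiles$mask == 5 & st$profiles$threshold == 2)  # {1,3},T=2
  single <- which(st$profiles$mask == 1 & st$profiles$threshold == 1)  # {1},T=1
  expect_equal(st$S[dup, ], st$S[single, ])
  for (j in seq_len(nrow(opt$winners))) {
    if (opt$winners$S[j] == st$S[single, j])
      expect_equal(opt$winners$mask[j], 1)
  }
})

test_that("normal scores are order-preserving transforms of the raw metrics", {
  sim <- generate_panels(generator_config(N = 300, K = 3, seed = 77))
  opt <- optimize_dataset(sim$panel, sim$comorbidity, min_n = 10)
  prof <- opt$score_table$profiles
  z <- opt$score_table$z
  val <- prof$valid
  raws <- list(prof$persistence, prof$comorbidity_ax1, prof$comorbidity_ax2)
  for (m in 1:3) {
    o <- order(raws[[m]][val])
    zo <- z[val, m][o]
    expect_true(all(diff(zo) >= -1e-12))           # nondecreasing in the raw
    ties <- diff(raws[[m]][val][o]) == 0
    expect_true(all(diff(zo)[!ties] > 0))          # strictly so off ties
  }
  # single-metric weighting at alpha = 1: the winner attains the maximum raw
  # persistence among valid rules
  w1 <- opt$winners[abs(opt$winners$alpha1 - 1) < 1e-9, ]
  expect_equal(w1$persistence, max(prof$persistence[val]))
  # alpha = 0: the winner attains the maximum equal-weighted comorbidity
  # composite
  w0 <- opt$winners[abs(opt$winners$alpha1) < 1e-9, ]
  comp <- 0.5 * z[, 2] + 0.5 * z[, 3]
  i0 <- which(prof$mask == w0$mask & prof$threshold == w0$threshold)
  expect_equal(comp[i0], max(comp[val]))
})

test_that("winner percentile is the minimum percentile at its alpha", {
  sim <- generate_panels(generator_config(N = 300, K = 4, seed = 55))
  opt <- optimize_dataset(sim$panel, sim$comorbidity, min_n = 10)
  for (j in seq_len(nrow(opt$winners))) {
    expect_equal(opt$winners$percentile[j],
                 min(opt$score_table$pct[, j], na.rm = TRUE))
  }
})
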