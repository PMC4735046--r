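# Agreement counts, Jaccard, persistence, and the three validity metrics.

test_that("cross_tabulate partitions subjects into the four logical states", {
  ct <- cross_tabulate(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(ct[c("a", "b", "c", "d")]), c(a = 1, b = 1, c = 1, d = 1))
  ct2 <- cross_tabulate(c(1, 0), c(1, 0))
  expect_equal(unlist(ct2[c("a", "b", "c", "d")]),
               c(a = 1, b = 0, c = 0, d = 1))
  ct3 <- cross_tabulate(rep(0, 3), rep(0, 3))
  expect_equal(ct3$d, 3)
  expect_equal(ct3$a + ct3$b + ct3$c + ct3$d, ct3$n)
  expect_error(cross_tabulate(c(1, 0), c(1, 0, 1)), "length")
  expect_error(cross_tabulate(c(1, 2), c(1, 0)), "non-binary")
})

test_that("jaccard matches a/(a+b+c), ignores d, is NA when undefined", {
  # counts from the published consensus/DSM-IV cross-classification
  expect_equal(jaccard(list(a = 536, b = 145, c = 189, d = 14906)),
               536 / 870, tolerance = 1e-12)
  expect_equal(jaccard(list(a = 5, b = 0, c = 0, d = 99)), 1)
  expect_equal(jaccard(list(a = 0, b = 2, c = 3, d = 0)), 0)
  expect_identical(jaccard(list(a = 0, b = 0, c = 0, d = 7)), NA_real_)
  # symmetric in (b, c); invariant to d
  for (i in 1:20) {
    ct <- as.list(sample(0:10, 3, replace = TRUE))
    names(ct) <- c("a", "b", "c")
    if (ct$a + ct$b + ct$c == 0) next
    swapped <- list(a = ct$a, b = ct$c, c = ct$b)
    expect_equal(jaccard(ct), jaccard(swapped))
    expect_equal(jaccard(c(ct, d = 0)), jaccard(c(ct, d = 1e6)))
  }
})

test_that("persistence is the Wave-2 rate among Wave-1 diagnoses", {
  expect_equal(persistence(c(1, 1, 0, 1), c(1, 0, 0, 1)), 2 / 3)
  dx <- c(1, 0, 1, 1, 0)
  expect_equal(persistence(dx, dx), 1)
  expect_identical(persistence(c(0, 0, 0), c(1, 0, 1)), NA_real_)
  expect_error(persistence(c(1, 0), c(1, 0, 0)), "length")
})

test_that("axis-1 comorbidity is the median disorder Jaccard", {
  dx <- c(1, 1, 0, 0, 1)
  identical7 <- matrix(rep(dx, 7), ncol = 7)
  expect_equal(comorbidity_axis1(dx, identical7), 1)
  # construct columns whose Jaccards with dx are known, then check medians
  fx <- tiny_fixture()
  dx1 <- oracle_diagnose(fx$w1, 1:2, 1)
  js <- vapply(1:7, function(j) oracle_jaccard(dx1, fx$ax1[, j]), numeric(1))
  expect_equal(comorbidity_axis1(dx1, fx$ax1), oracle_median(js))
})

test_that("median conventions: odd takes the middle, even averages the pair", {
  expect_equal(oracle_median(c(.1, .2, .3, .4, .5, .6, .7)), .4)
  expect_equal(oracle_median(c(.1, .3)), .2)
  expect_equal(stats::median(c(.1, .2, .3, .4, .5, .6, .7)), .4)
  expect_equal(stats::median(c(.1, .3)), .2)
})

test_that("axis-2 comorbidity is the weighted cluster-median combination", {
  fx <- tiny_fixture()
  dx1 <- oracle_diagnose(fx$w1, c(1, 3), 1)
  medA <- oracle_median(vapply(1:3, function(j)
    oracle_jaccard(dx1, fx$ca[, j]), numeric(1)))
  medB <- oracle_median(vapply(1:4, function(j)
    oracle_jaccard(dx1, fx$cb[, j]), numeric(1)))
  medC <- oracle_median(vapply(1:3, function(j)
    oracle_jaccard(dx1, fx$cc[, j]), numeric(1)))
  got <- comorbidity_axis2(dx1, fx$ca, fx$cb, fx$cc)
  expect_equal(got, .1 * medA + .7 * medB + .2 * medC)
  # convexity: lies between min and max cluster medians
  expect_gte(got, min(medA, medB, medC))
  expect_lte(got, max(medA, medB, medC))
  # degenerate weights
  expect_equal(comorbidity_axis2(dx1, fx$ca, fx$cb, fx$cc,
                                 weights = c(1, 0, 0)), medA)
  expect_error(comorbidity_axis2(dx1, fx$ca, fx$cb, fx$cc,
                                 weights = c(.5, .4, .2)), "sum")
})

test_that("validity_profile matches a hand recount on the 10-subject fixture", {
  fx <- tiny_fixture()
  ps <- make_panels(fx)
  for (case in list(list(s = 1:2, t = 1), list(s = c(1, 3), t = 2),
                    list(s = 1:3, t = 2))) {
    r <- diagnostic_rule(case$s, case$t)
    vp <- validity_profile(r, ps$panel, ps$comorbidity)
    om <- oracle_metrics(case$s, case$t, fx$w1, fx$w2, fx$ax1,
                         fx$ca, fx$cb, fx$cc)
    expect_equal(vp$prevalence_w1, om$prev)
    expect_equal(vp$persistence, om$pers)
    expect_equal(vp$comorbidity_ax1, om$c1)
    expect_equal(vp$comorbidity_ax2, om$c2)
    expect_true(vp$valid)
  }
})

test_that("rules diagnosing everyone or no one at Wave 1 behave as specified", {
  n <- 8
  w_all <- matrix(1, n, 2); w_none <- matrix(0, n, 2)
  com <- comorbidity_panel(matrix(rep(c(1, 0), n), ncol = 1)[1:n, , drop = FALSE],
                           matrix(1, n, 1), matrix(0, n, 1), matrix(1, n, 1))
  p_all <- criterion_panel(w_all, w_all)
  vp <- validity_profile(diagnostic_rule(1:2, 1), p_all, com)
  expect_equal(vp$persistence, 1)
  expect_equal(vp$prevalence_w1, 1)
  p_none <- criterion_panel(w_none, w_none)
  vp0 <- validity_profile(diagnostic_rule(1:2, 1), p_none, com)
  expect_false(vp0$valid)
  expect_identical(vp0$persistence, NA_real_)
  expect_identical(vp0$comorbidity_ax1, NA_real_)
})

test_that("nested diagnoses: stricter rules never gain joint presences", {
  fx <- tiny_fixture()
  other <- fx$ax1[, 1]
  for (t in 1:3) {
    loose <- oracle_diagnose(fx$w1, 1:3, max(t - 1, 1))
    strict <- oracle_diagnose(fx$w1, 1:3, t)
    a_loose <- cross_tabulate(loose, other)$a
    a_strict <- cross_tabulate(strict, other)$a
    expect_lte(a_strict, a_loose)
  }
})
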