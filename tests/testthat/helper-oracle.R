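# Independent brute-force oracle for the optimization pipeline, written with
# plain loops and no calls into the package's computational path. Used to
# freeze expected values for small problems.

oracle_counts <- function(x, y) {
  a <- b <- c2 <- d <- 0L
  for (i in seq_along(x)) {
    if (x[i] == 1 && y[i] == 1) a <- a + 1L
    else if (x[i] == 1 && y[i] == 0) b <- b + 1L
    else if (x[i] == 0 && y[i] == 1) c2 <- c2 + 1L
    else d <- d + 1L
  }
  list(a = a, b = b, c = c2, d = d)
}

oracle_jaccard <- function(x, y) {
  ct <- oracle_counts(x, y)
  den <- ct$a + ct$b + ct$c
  if (den == 0) NA_real_ else ct$a / den
}

oracle_median <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
}

oracle_diagnose <- function(w, subset, t) {
  out <- integer(nrow(w))
  for (i in seq_len(nrow(w))) {
    cnt <- 0L
    for (j in subset) cnt <- cnt + w[i, j]
    out[i] <- as.integer(cnt >= t)
  }
  out
}

oracle_metrics <- function(subset, t, w1, w2, ax1, ca, cb, cc,
                           cw = c(.1, .7, .2)) {
  dx1 <- oracle_diagnose(w1, subset, t)
  if (sum(dx1) == 0)
    return(list(valid = FALSE, prev = 0, pers = NA, c1 = NA, c2 = NA))
  dx2 <- oracle_diagnose(w2, subset, t)
  pers <- sum(dx1 == 1 & dx2 == 1) / sum(dx1)
  jac_block <- function(m) {
    vapply(seq_len(ncol(m)), function(j) oracle_jaccard(dx1, m[, j]),
           numeric(1))
  }
  c1 <- oracle_median(jac_block(ax1))
  c2v <- cw[1] * oracle_median(jac_block(ca)) +
    cw[2] * oracle_median(jac_block(cb)) +
    cw[3] * oracle_median(jac_block(cc))
  list(valid = TRUE, prev = mean(dx1), pers = pers, c1 = c1, c2 = c2v)
}

# Full exhaustive optimization on a small panel: every nonempty subset of
# 1..K at every threshold, rank-inverse-normal scoring with the r/(n+1)
# percentile convention, composite S, parsimony-first tie-breaking.
oracle_optimize <- function(w1, w2, ax1, ca, cb, cc, alphas,
                            cw = c(.1, .7, .2)) {
  K <- ncol(w1)
  rows <- list()
  for (size in 1:K) {
    combs <- utils::combn(K, size)
    for (ci in seq_len(ncol(combs))) {
      subset <- combs[, ci]
      mask <- sum(2^(subset - 1))
      for (t in 1:size) {
        met <- oracle_metrics(subset, t, w1, w2, ax1, ca, cb, cc, cw)
        rows[[length(rows) + 1L]] <- data.frame(
          mask = mask, size = size, threshold = t, valid = met$valid,
          prev = met$prev, pers = met$pers, c1 = met$c1, c2 = met$c2)
      }
    }
  }
  tab <- do.call(rbind, rows)
  val <- which(tab$valid)
  nv <- length(val)
  zcol <- function(v) {
    z <- rep(NA_real_, nrow(tab))
    z[val] <- qnorm(rank(v[val], ties.method = "average") / (nv + 1))
    z
  }
  zp <- zcol(tab$pers); z1 <- zcol(tab$c1); z2 <- zcol(tab$c2)
  winners <- data.frame(alpha1 = alphas, mask = NA_real_,
                        threshold = NA_integer_)
  for (ai in seq_along(alphas)) {
    a <- alphas[ai]
    S <- a * zp + (1 - a) * (.5 * z1 + .5 * z2)
    best <- max(S[val])
    cand <- val[S[val] == best]
    cand <- cand[order(tab$size[cand], tab$threshold[cand], tab$mask[cand])]
    winners$mask[ai] <- tab$mask[cand[1]]
    winners$threshold[ai] <- tab$threshold[cand[1]]
  }
  winners
}

# Hand-built 10-subject two-wave panel with known overlap structure,
# used for frozen-value checks of the validity metrics.
tiny_fixture <- function() {
  w1 <- matrix(c(
    1, 1, 0,
    1, 0, 1,
    0, 1, 1,
    1, 1, 1,
    0, 0, 0,
    1, 0, 0,
    0, 1, 0,
    0, 0, 1,
    1, 1, 0,
    0, 0, 0), ncol = 3, byrow = TRUE)
  w2 <- matrix(c(
    1, 1, 0,
    0, 0, 1,
    0, 1, 0,
    1, 1, 1,
    0, 0, 0,
    0, 0, 0,
    1, 1, 0,
    0, 0, 0,
    1, 0, 0,
    0, 1, 0), ncol = 3, byrow = TRUE)
  ax1 <- matrix(c(
    1, 0, 1, 0, 0, 1, 0,
    0, 1, 0, 0, 0, 0, 0,
    1, 1, 0, 1, 0, 0, 0,
    1, 0, 0, 0, 1, 1, 1,
    0, 0, 0, 0, 0, 0, 0,
    0, 0, 1, 0, 0, 0, 0,
    1, 0, 0, 0, 0, 1, 0,
    0, 0, 0, 1, 0, 0, 0,
    1, 1, 0, 0, 1, 0, 1,
    0, 0, 0, 0, 0, 0, 0), ncol = 7, byrow = TRUE)
  ca <- matrix(c(
    1, 0, 0,
    0, 0, 0,
    0, 1, 0,
    1, 0, 1,
    0, 0, 0,
    0, 0, 0,
    0, 1, 0,
    0, 0, 0,
    1, 0, 0,
    0, 0, 0), ncol = 3, byrow = TRUE)
  cb <- matrix(c(
    1, 1, 0, 0,
    0, 0, 0, 0,
    1, 0, 1, 0,
    1, 1, 0, 1,
    0, 0, 0, 0,
    0, 1, 0, 0,
    0, 0, 0, 0,
    0, 0, 1, 0,
    1, 0, 0, 1,
    0, 0, 0, 0), ncol = 4, byrow = TRUE)
  cc <- matrix(c(
    0, 0, 1,
    0, 0, 0,
    1, 0, 0,
    0, 1, 1,
    0, 0, 0,
    0, 0, 1,
    0, 0, 0,
    0, 0, 0,
    1, 0, 1,
    0, 0, 0), ncol = 3, byrow = TRUE)
  list(w1 = w1, w2 = w2, ax1 = ax1, ca = ca, cb = cb, cc = cc)
}

make_panels <- function(fx) {
  list(panel = criterion_panel(fx$w1, fx$w2),
       comorbidity = comorbidity_panel(fx$ax1, fx$ca, fx$cb, fx$cc))
}
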