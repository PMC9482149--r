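test_that("Wilson intervals match the score-equation roots and behave at the edges", {
  ci <- wilson_interval(0, 40)
  expect_equal(ci$lower, 0)
  expect_equal(ci$upper, 0.088, tolerance = 5e-3)
  expect_equal(wilson_interval(40, 40)$upper, 1)
  ci <- wilson_interval(20, 40)
  expect_equal(ci$point, 0.5)
  expect_equal(ci$upper - ci$point, ci$point - ci$lower, tolerance = 1e-12)
  # independent oracle: bounds are roots of (p_hat - p)^2 = z^2 p(1-p)/n
  z <- qnorm(0.975)
  for (case in list(c(3, 17), c(8, 40), c(25, 40), c(1, 5))) {
    k <- case[1]; n <- case[2]; ph <- k / n
    ci <- wilson_interval(k, n)
    score <- function(p) (ph - p)^2 - z^2 * p * (1 - p) / n
    lo <- uniroot(score, c(1e-12, ph), tol = 1e-12)$root
    hi <- uniroot(score, c(ph, 1 - 1e-12), tol = 1e-12)$root
    expect_equal(ci$lower, lo, tolerance = 1e-8)
    expect_equal(ci$upper, hi, tolerance = 1e-8)
    expect_true(ci$lower <= ph && ph <= ci$upper)
  }
  # width shrinks with n at fixed proportion
  w <- function(k, n) { ci <- wilson_interval(k, n); ci$upper - ci$lower }
  expect_lt(w(20, 40), w(10, 20))
  expect_error(wilson_interval(1, 0), "n must be")
})

test_that("Spearman rho hits the deterministic anchors and its exact p matches enumeration", {
  x <- c(0.05, 0.07, 0.10, 0.12, 0.19)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  # brute-force permutation oracle at n = 5 (120 orderings)
  y <- c(2, 1, 4, 3, 5)
  got <- spearman_cor(1:5, y)
  rho_obs <- cor(rank(1:5), rank(y))
  perms <- asplit(as.matrix(expand.grid(rep(list(1:5), 5))), 1)
  perms <- Filter(function(p) !anyDuplicated(p), perms)
  expect_length(perms, 120)
  rhos <- vapply(perms, function(p) cor(1:5, y[p]), numeric(1))
  p_oracle <- min(1, 2 * min(mean(rhos >= rho_obs - 1e-12),
                             mean(rhos <= rho_obs + 1e-12)))
  expect_equal(got$p_value, p_oracle)
  expect_equal(got$method, "exact permutation")
  # constant vector flagged
  expect_warning(out <- spearman_cor(rep(1, 5), y), "constant")
  expect_true(is.na(out$rho))
})

test_that("Fisher's exact test agrees with exhaustive hypergeometric enumeration", {
  # identical columns give p = 1
  expect_equal(fisher_exact(8, 40, 8, 40)$p_value, 1)
  expect_equal(fisher_exact(0, 0, 0, 0)$p_value, 1)
  # one-sided tail of (8/40 vs 0/40) is the direct product
  tail_prod <- prod((40 - 0:7) / (80 - 0:7))
  expect_equal(dhyper(0, 40, 40, 8), tail_prod, tolerance = 1e-12)
  expect_equal(fisher_exact(8, 40, 0, 40)$p_value,
               fisher_oracle_p(8, 40, 0, 40), tolerance = 1e-9)
  # full sweep over small margins
  for (n1 in c(3, 5, 12)) for (n2 in c(4, 12)) {
    for (k1 in 0:n1) for (k2 in 0:n2) {
      expect_equal(fisher_exact(k1, n1, k2, n2)$p_value,
                   fisher_oracle_p(k1, n1, k2, n2), tolerance = 1e-9,
                   label = sprintf("FET %d/%d vs %d/%d", k1, n1, k2, n2))
    }
  }
})

test_that("Bonferroni adjustment multiplies and clips", {
  expect_equal(bonferroni(0.01, m = 9), 0.09)
  expect_equal(bonferroni(0.5, m = 9), 1)
  expect_equal(bonferroni(c(0.2, 0.04)), c(0.4, 0.08))
  expect_equal(bonferroni(0.03, m = 1), 0.03)
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "m must be")
})

test_that("Wilcoxon signed-rank matches sign-flip enumeration and is antisymmetric", {
  expect_equal(wilcoxon_signed_rank_paired(1:5, 1:5),
               list(V = 0, p_value = 1, n_nonzero = 0L, method = "degenerate"))
  a <- c(0.90, 0.50, 0.37, 0.33, 0.21, 0.09)
  b <- c(0.80, 0.55, 0.25, 0.30, 0.28, 0.11)  # distinct |differences|
  got <- wilcoxon_signed_rank_paired(a, b)
  # oracle: all 2^6 sign assignments of the ranked |differences|
  d <- a - b
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  Vs <- signs %*% r
  v_obs <- sum(r[d > 0])
  expect_equal(got$V, v_obs)
  p_oracle <- min(1, 2 * min(mean(Vs <= v_obs), mean(Vs >= v_obs)))
  expect_equal(got$p_value, p_oracle)
  # swapping the arms reflects V about n(n+1)/2
  swapped <- wilcoxon_signed_rank_paired(b, a)
  expect_equal(swapped$V, 6 * 7 / 2 - got$V)
  expect_equal(swapped$p_value, got$p_value)
})

test_that("the threshold rule finds the lowest significant level against control", {
  # constructed table with a known break at 0.53 deg
  tab <- data.frame(level = c(0, 0.3, 0.4, 0.53, 0.8),
                    k = c(1L, 1L, 2L, 30L, 34L), n = 38L,
                    p_hat = c(1, 1, 2, 30, 34) / 38,
                    is_control = c(TRUE, rep(FALSE, 4)))
  class(tab) <- c("response_table", "data.frame")
  th <- determine_threshold(tab, experiment = "resolution")
  expect_equal(th$threshold_level, 0.53)
  expect_equal(th$alpha_min_deg, 1.06)
  # verified against direct FET computation at any family size m
  for (m in c(4, 8, 20)) {
    th_m <- determine_threshold(tab, m = m, experiment = "resolution")
    direct <- vapply(2:5, function(i)
      min(1, m * fisher.test(matrix(c(tab$k[i], 38 - tab$k[i],
                                      1, 37), 2, byrow = TRUE))$p.value),
      numeric(1))
    expect_equal(th_m$levels$adj_p, direct, tolerance = 1e-12)
    expect_equal(th_m$threshold_level, 0.53)
  }
  # all-flat table yields the no-threshold outcome
  flat <- tab; flat$k <- 2L; flat$p_hat <- 2 / 38
  th0 <- determine_threshold(flat, experiment = "resolution")
  expect_true(is.na(th0$threshold_level))
  # monotone: adding responders above the threshold never raises it
  more <- tab; more$k[more$level == 0.8] <- 38L
  expect_equal(determine_threshold(more, experiment = "resolution")$threshold_level,
               0.53)
  expect_error(determine_threshold(tab[-1, ]), "control")
})
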