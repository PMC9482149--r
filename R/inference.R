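#' Wilson score interval for a binomial proportion
#'
#' The score interval inverts the normal test on the score scale and keeps
#' good coverage at small n and extreme proportions, which is why it is the
#' interval of choice for per-level response probabilities with n around 40:
#' `(p_hat + z^2/2n +/- z * sqrt(p_hat(1-p_hat)/n + z^2/4n^2)) / (1 + z^2/n)`.
#'
#' @param k Number of responders, `0 <= k <= n`.
#' @param n Number of trials (> 0).
#' @param confidence Confidence level (default 0.95).
#' @return List with `point` (k/n), `lower`, `upper`, `confidence`.
#' @examples
#' wilson_interval(0, 40)   # upper bound ~0.088
#' @export
wilson_interval <- function(k, n, confidence = 0.95) {
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  if (k < 0 || k > n) stop("need 0 <= k <= n", call. = FALSE)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  hw <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  list(point = p, lower = max(0, centre - hw), upper = min(1, centre + hw),
       confidence = confidence)
}

# exact two-sided permutation p for Spearman's rho (no ties), by full
# enumeration of permutations; two-sided as 2 * min(tail) capped at 1
spearman_exact_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  # all permutations of 1..n by iterative insertion, as an integer matrix
  P <- matrix(1L, 1, 1)
  for (k in 2:n) {
    m <- nrow(P)
    out <- matrix(0L, m * k, k)
    for (j in seq_len(k)) {
      rows <- ((j - 1) * m + 1):(j * m)
      if (j > 1) out[rows, seq_len(j - 1)] <- P[, seq_len(j - 1), drop = FALSE]
      out[rows, j] <- k
      if (j < k) out[rows, (j + 1):k] <- P[, j:(k - 1), drop = FALSE]
    }
    P <- out
  }
  # untied ranks are 1..n, so rho = 1 - 6 * sum(d^2) / (n(n^2-1)) with
  # sum(d^2) = 2 * sum(k^2) - 2 * crossproduct
  cp <- as.vector(matrix(ry[P], nrow(P)) %*% rx)
  sumsq <- n * (n + 1) * (2 * n + 1) / 6
  rhos <- 1 - 6 * (2 * sumsq - 2 * cp) / (n * (n^2 - 1))
  eps <- 1e-12
  p_ge <- mean(rhos >= rho_obs - eps)
  p_le <- mean(rhos <= rho_obs + eps)
  min(1, 2 * min(p_ge, p_le))
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation with average ranks for ties. The p-value is computed by
#' exact permutation enumeration for n <= 9 without ties (feasible: at most
#' 9! orderings) and by the t-approximation through [stats::cor.test()]
#' otherwise. A constant input vector leaves rho undefined (returned as NA
#' with a warning).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n` and `method`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant vector: Spearman's rho undefined", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, method = "undefined"))
  }
  rho <- stats::cor(rank(x), rank(y))
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 9 && !has_ties) {
    list(rho = rho, p_value = spearman_exact_p(x, y), n = n,
         method = "exact permutation")
  } else {
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
         method = "t approximation")
  }
}

#' Fisher's exact test between two responder counts
#'
#' Compares k1/n1 responders with k2/n2 (typically a stimulus level against
#' the control) on the 2x2 table of responders and non-responders, using the
#' conventional two-sided rule: the p-value sums the probabilities of all
#' tables with fixed margins whose hypergeometric probability does not
#' exceed that of the observed table.
#'
#' @param k1,n1 Responders and trials in group 1.
#' @param k2,n2 Responders and trials in group 2.
#' @return List with `p_value`, `odds_ratio` (conditional MLE) and the table.
#' @export
fisher_exact <- function(k1, n1, k2, n2) {
  if (any(c(k1, n1, k2, n2) < 0) || k1 > n1 || k2 > n2)
    stop("need 0 <= k <= n in both groups", call. = FALSE)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (sum(tab) == 0) return(list(p_value = 1, odds_ratio = NA_real_, table = tab))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(p_value = ft$p.value,
       odds_ratio = if (is.null(ft$estimate)) NA_real_ else unname(ft$estimate),
       table = tab)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for each p-value; `m` defaults to the number of p-values
#' but may be larger when the comparison family is wider than the vector
#' supplied.
#'
#' @param p Numeric vector of p-values.
#' @param m Size of the comparison family, `m >= length(p)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) stop("m must be >= number of tests", call. = FALSE)
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Paired Wilcoxon signed-rank test
#'
#' Drops zero differences, ranks the absolute differences, and reports
#' V = sum of ranks of positive differences, with an exact p-value for up to
#' 15 non-zero pairs (normal approximation with continuity correction
#' beyond, or whenever tied ranks make the exact distribution unavailable).
#' All-zero differences give V = 0, p = 1.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return List with `V`, `p_value`, `n_nonzero` and `method`.
#' @export
wilcoxon_signed_rank_paired <- function(a, b) {
  if (length(a) != length(b)) stop("a and b lengths differ", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(V = 0, p_value = 1, n_nonzero = 0L, method = "degenerate"))
  exact <- n <= 15 && !anyDuplicated(abs(d))
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = TRUE))
  list(V = unname(wt$statistic), p_value = wt$p.value, n_nonzero = n,
       method = if (exact) "exact" else "normal approximation")
}

#' Determine the behavioural threshold from a response table
#'
#' Tests each stimulus level against the control with [fisher_exact()],
#' applies a Bonferroni correction over the m comparisons (m defaults to the
#' number of non-control levels: nine for the contrast series, eight for the
#' resolution series), and takes the threshold as the smallest level whose
#' adjusted p-value is at or below `alpha` - i.e. the lowest contrast, or
#' finest checkerboard, with responding significantly above control. For the
#' resolution experiment the minimum resolvable angle is twice the threshold
#' check width (one check is half a grating period). When no level is
#' significant the outcome is "no threshold" (`threshold_level = NA`).
#'
#' @param table A `response_table` from [build_response_table()], with its
#'   control row.
#' @param alpha Significance level (default 0.05).
#' @param m Comparison-family size; default `NULL` means the number of
#'   non-control levels.
#' @param experiment `"contrast"` or `"resolution"`; controls whether
#'   `alpha_min` is reported.
#' @return List of class `threshold_result`: `experiment`,
#'   `threshold_level`, `alpha_min_deg` (resolution only, else NA), `alpha`,
#'   `m`, and `levels`, a data frame of per-level p-values and adjusted
#'   p-values.
#' @export
determine_threshold <- function(table, alpha = 0.05, m = NULL,
                                experiment = c("contrast", "resolution")) {
  experiment <- match.arg(experiment)
  if (sum(table$is_control) != 1)
    stop("response table must contain exactly one control row", call. = FALSE)
  ctrl <- table[table$is_control, ]
  lev <- table[!table$is_control, , drop = FALSE]
  lev <- lev[order(lev$level), , drop = FALSE]
  if (is.null(m)) m <- nrow(lev)
  p <- vapply(seq_len(nrow(lev)), function(i)
    fisher_exact(lev$k[i], lev$n[i], ctrl$k, ctrl$n)$p_value, numeric(1))
  adj <- bonferroni(p, m)
  sig <- adj <= alpha
  threshold <- if (any(sig)) min(lev$level[sig]) else NA_real_
  structure(
    list(experiment = experiment,
         threshold_level = threshold,
         alpha_min_deg = if (experiment == "resolution") 2 * threshold else NA_real_,
         alpha = alpha, m = m,
         levels = data.frame(level = lev$level, k = lev$k, n = lev$n,
                             p_value = p, adj_p = adj, significant = sig)),
    class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("Behavioural threshold (", x$experiment, " experiment)\n", sep = "")
  cat("  Fisher's exact vs control, Bonferroni m =", x$m,
      ", alpha =", x$alpha, "\n")
  if (is.na(x$threshold_level)) {
    cat("  No level significantly above control: no threshold.\n")
  } else {
    cat("  Threshold level:", x$threshold_level, "\n")
    if (x$experiment == "resolution")
      cat("  Minimum resolvable angle (2 x threshold):",
          x$alpha_min_deg, "deg\n")
  }
  invisible(x)
}
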