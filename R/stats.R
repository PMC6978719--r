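# Nonparametric cohort statistics, implemented from their defining formulas:
# Spearman and covariate-adjusted (partial) Spearman rank correlation,
# Friedman test with tie correction, Wilcoxon signed-rank post-hoc with
# Bonferroni adjustment (Conover post-hoc available), Pearson chi-square,
# and Cohen's kappa. Base R equivalents serve as independent cross-checks in
# the test suite, not as the implementation.

stat_result <- function(method, statistic = NA_real_, df = NA_real_,
                        p_value = NA_real_, adjusted_p = NA_real_,
                        r_s = NA_real_, n = NA_integer_, extra = list()) {
  structure(c(list(method = method, statistic = statistic, df = df,
                   p_value = p_value, adjusted_p = adjusted_p, r_s = r_s,
                   n = n), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: ", x$method))
  if (!is.na(x$r_s)) cat(sprintf("r_s = %.4f, ", x$r_s))
  if (!is.na(x$statistic)) cat(sprintf("statistic = %.4g, ", x$statistic))
  if (!is.na(x$df)) cat(sprintf("df = %g, ", x$df))
  cat(sprintf("p = %.4g", x$p_value))
  if (!is.na(x$adjusted_p)) cat(sprintf(" (adjusted %.4g)", x$adjusted_p))
  cat(sprintf(", n = %d\n", x$n))
  invisible(x)
}

# average ranks (midranks) — the tie convention used throughout
midrank <- function(x) rank(x, ties.method = "average")

pearson_r <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) NA_real_ else sum(a * b) / den
}

#' Spearman's rank correlation
#'
#' Rank both vectors with average ranks for ties, compute the Pearson
#' correlation of the ranks, and take the two-sided p-value from the t
#' approximation `t = r * sqrt((n-2)/(1-r^2))` with `n - 2` degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @return a `stat_result` with `r_s`, `statistic` (t), `df` and `p_value`.
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y)) {
    icas_stop("icasflow_stats_error", "x and y must have equal length")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) icas_stop("icasflow_stats_error", "need n >= 3")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    icas_stop("icasflow_undefined_correlation_error",
              "correlation undefined for a constant input vector")
  }
  r <- pearson_r(midrank(x), midrank(y))
  tp <- t_two_sided(r, n - 2)
  stat_result("Spearman rank correlation", statistic = tp$t, df = n - 2,
              p_value = tp$p, r_s = r, n = n)
}

t_two_sided <- function(r, df) {
  if (abs(r) >= 1) return(list(t = sign(r) * Inf, p = 0))
  t <- r * sqrt(df / (1 - r^2))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

#' Covariate-adjusted (partial) Spearman correlation
#'
#' Rank-transforms every variable (average ranks; a binary covariate such as
#' sex, coded 0/1, is ranked like any other), residualises the x- and
#' y-ranks on the covariate ranks by least squares (with intercept), and
#' correlates the residuals. The two-sided p-value uses the t approximation
#' with `n - 2 - k` degrees of freedom for `k` covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame or matrix of adjustment covariates; factor
#'   or character columns are converted to integer codes before ranking.
#' @return a `stat_result`.
#' @export
partial_spearman <- function(x, y, covariates) {
  covariates <- as.data.frame(covariates)
  n <- length(x)
  if (length(y) != n || nrow(covariates) != n) {
    icas_stop("icasflow_stats_error", "x, y and covariates must align")
  }
  Z <- vapply(covariates, function(col) {
    if (is.character(col) || is.factor(col)) col <- as.integer(factor(col))
    as.numeric(col)
  }, numeric(n))
  Z <- matrix(Z, nrow = n)
  ok <- is.finite(x) & is.finite(y) & apply(is.finite(Z), 1, all)
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  n <- length(x)
  k <- ncol(Z)
  if (n <= k + 2) icas_stop("icasflow_stats_error", "need n > k + 2")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    icas_stop("icasflow_undefined_correlation_error",
              "correlation undefined for a constant input vector")
  }
  rx <- midrank(x); ry <- midrank(y)
  RZ <- apply(Z, 2, midrank)
  RZ <- matrix(RZ, nrow = n)
  keep <- apply(RZ, 2, function(col) length(unique(col)) > 1)
  RZ <- RZ[, keep, drop = FALSE]
  k_eff <- ncol(RZ)
  if (k_eff == 0) {
    # constant covariates adjust nothing: plain Spearman (df unchanged)
    r <- pearson_r(rx, ry)
    tp <- t_two_sided(r, n - 2)
    return(stat_result("partial Spearman (no effective covariates)",
                       statistic = tp$t, df = n - 2, p_value = tp$p,
                       r_s = r, n = n))
  }
  X <- cbind(1, RZ)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    icas_stop("icasflow_degenerate_adjustment_error",
              "collinear covariates: adjustment is degenerate")
  }
  ex <- stats::residuals(stats::lm.fit(X, rx))
  ey <- stats::residuals(stats::lm.fit(X, ry))
  # a variable lying in the covariate span leaves only rounding noise:
  # its partial correlation is zero, not noise/noise
  explained <- function(e, r0) sum(e^2) <= 1e-20 * sum((r0 - mean(r0))^2)
  r <- if (explained(ex, rx) || explained(ey, ry)) 0 else pearson_r(ex, ey)
  if (is.na(r)) r <- 0
  df <- n - 2 - k_eff
  tp <- t_two_sided(r, df)
  stat_result("partial Spearman (rank residualisation)",
              statistic = tp$t, df = df, p_value = tp$p, r_s = r, n = n)
}

#' Friedman test for repeated measurements
#'
#' Within-block average ranks, tie-corrected chi-square statistic
#' `Q = (k-1) * sum_j (R_j - n(k+1)/2)^2 / (A - C)` with `A = sum r_ij^2`
#' and `C = n k (k+1)^2 / 4`, referred to the chi-square distribution with
#' `k - 1` degrees of freedom (reduces to the classic `12/(nk(k+1)) ...`
#' form when there are no ties).
#'
#' @param block_matrix numeric matrix, `n` blocks (rows) by `k` repeated
#'   locations (columns), no missing cells.
#' @return a `stat_result`.
#' @export
friedman_test <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  if (any(!is.finite(m))) {
    icas_stop("icasflow_stats_error", "missing cells are not allowed")
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) icas_stop("icasflow_stats_error", "need n >= 2, k >= 2")
  r <- t(apply(m, 1, midrank))
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  Q <- if (A - C <= 0) 0 else num / (A - C)  # all columns tied in every block
  p <- stats::pchisq(Q, k - 1, lower.tail = FALSE)
  stat_result("Friedman test", statistic = Q, df = k - 1, p_value = p, n = n,
              extra = list(rank_sums = Rj))
}

#' Bonferroni multiple-comparison adjustment
#'
#' Each p-value is multiplied by the number of comparisons and capped at 1.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param m number of comparisons (defaults to `length(p_values)`).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    icas_stop("icasflow_stats_error", "p-values must lie in [0, 1]")
  }
  pmin(1, p_values * m)
}

# exact null distribution of the Wilcoxon signed-rank statistic W+ for
# (possibly tied) positive rank values, by dynamic programming over the
# 2^n equiprobable sign assignments; ranks are doubled so midranks become
# integers
signed_rank_exact_p <- function(w, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (rk in r2) {
    g <- f
    g[(rk + 1):(total + 1)] <- g[(rk + 1):(total + 1)] + f[1:(total - rk + 1)]
    f <- g
  }
  f <- f / sum(f)
  w2 <- round(2 * w)
  p_le <- sum(f[seq_len(w2 + 1)])
  p_ge <- sum(f[(w2 + 1):(total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test for one paired comparison
#'
#' Paired differences with zeros dropped (Wilcoxon's original convention)
#' and average ranks for tied magnitudes. The null distribution is exact
#' (enumeration over sign assignments, valid with ties) for `n <= 25`
#' non-zero pairs and a normal approximation with tie-corrected variance
#' otherwise.
#'
#' @param a,b paired observations.
#' @param exact_limit largest number of non-zero pairs for which the exact
#'   null is used.
#' @return a `stat_result` (`statistic` is W+, the positive-rank sum).
#' @export
wilcoxon_signed_rank <- function(a, b, exact_limit = 25L) {
  if (length(a) != length(b)) {
    icas_stop("icasflow_stats_error", "paired vectors must align")
  }
  d <- a - b
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  if (n == 0) {
    return(stat_result("Wilcoxon signed-rank", statistic = 0, p_value = 1,
                       n = 0L))
  }
  rk <- midrank(abs(d))
  w <- sum(rk[d > 0])
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(w, rk)
    method <- "Wilcoxon signed-rank (exact)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Wilcoxon signed-rank (normal approximation)"
  }
  stat_result(method, statistic = w, p_value = p, n = as.integer(n))
}

#' Pairwise post-hoc comparisons after a Friedman test
#'
#' Runs the Friedman test, then compares location pairs with the Wilcoxon
#' signed-rank test and adjusts the pairwise p-values by Bonferroni
#' correction across the pairs (Conover's rank-sum post-hoc is available via
#' `method = "conover"`).
#'
#' @param block_matrix numeric `n x k` matrix as in [friedman_test()].
#' @param pairs list of 2-element integer/character vectors naming column
#'   pairs; defaults to all `k(k-1)/2` pairs.
#' @param alpha significance level the Friedman pre-test must meet.
#' @param method `"wilcoxon"` (default) or `"conover"`.
#' @param force run the post-hoc even when the Friedman test is not
#'   significant at `alpha`.
#' @return list with the `friedman` result and `pairwise`, a data.frame of
#'   per-pair statistics, raw and Bonferroni-adjusted p-values.
#' @export
pairwise_posthoc <- function(block_matrix, pairs = NULL, alpha = 0.05,
                             method = c("wilcoxon", "conover"),
                             force = FALSE) {
  method <- match.arg(method)
  m <- as.matrix(block_matrix)
  fr <- friedman_test(m)
  if (!force && fr$p_value > alpha) {
    icas_stop("icasflow_stats_error", sprintf(
      "Friedman test not significant at alpha = %g (p = %.4g); no post-hoc",
      alpha, fr$p_value))
  }
  k <- ncol(m)
  cols <- colnames(m)
  if (is.null(cols)) cols <- paste0("C", seq_len(k))
  colnames(m) <- cols
  if (is.null(pairs)) {
    pairs <- utils::combn(k, 2, simplify = FALSE)
  }
  rows <- lapply(pairs, function(pr) {
    i <- if (is.character(pr[1])) match(pr[1], cols) else as.integer(pr[1])
    j <- if (is.character(pr[2])) match(pr[2], cols) else as.integer(pr[2])
    if (method == "wilcoxon") {
      wt <- wilcoxon_signed_rank(m[, i], m[, j])
      data.frame(a = cols[i], b = cols[j], statistic = wt$statistic,
                 p_value = wt$p_value, stringsAsFactors = FALSE)
    } else {
      ct <- conover_pair(m, i, j, fr)
      data.frame(a = cols[i], b = cols[j], statistic = ct$t,
                 p_value = ct$p, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni_adjust(out$p_value, nrow(out))
  list(friedman = fr, pairwise = out, method = method)
}

# Conover's post-hoc t comparison on Friedman rank sums
conover_pair <- function(m, i, j, fr) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, midrank))
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  T1 <- fr$statistic
  df <- (n - 1) * (k - 1)
  se2 <- 2 * n * (A - C) * (1 - T1 / (n * (k - 1))) / df
  if (se2 <= 0) return(list(t = Inf, p = 0))
  t <- (Rj[i] - Rj[j]) / sqrt(se2)
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test of independence
#'
#' `X^2 = sum (O - E)^2 / E` with expected counts from the margins and
#' `(r-1)(c-1)` degrees of freedom; no continuity correction.
#'
#' @param table r x c matrix of non-negative counts with positive margins.
#' @return a `stat_result`.
#' @export
chi_square_independence <- function(table) {
  m <- as.matrix(table)
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
    icas_stop("icasflow_stats_error", "counts must be non-negative integers")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    icas_stop("icasflow_stats_error", "zero margin in contingency table")
  }
  N <- sum(m)
  E <- outer(rowSums(m), colSums(m)) / N
  X2 <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  p <- stats::pchisq(X2, df, lower.tail = FALSE)
  stat_result("Pearson chi-square", statistic = X2, df = df, p_value = p,
              n = as.integer(N))
}

#' Cohen's kappa for a 2 x 2 (or k x k) agreement table
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` (diagonal
#' proportion) and chance agreement `p_e` from the marginal products. The
#' p-value is the large-sample z test of `kappa = 0`.
#'
#' @param agreement_table square matrix of counts (rater A rows, rater B
#'   columns).
#' @return a `stat_result` (`statistic` is kappa).
#' @export
cohen_kappa <- function(agreement_table) {
  m <- as.matrix(agreement_table)
  if (nrow(m) != ncol(m)) {
    icas_stop("icasflow_stats_error", "agreement table must be square")
  }
  N <- sum(m)
  if (N <= 0) icas_stop("icasflow_stats_error", "empty agreement table")
  p <- m / N
  po <- sum(diag(p))
  pi_ <- rowSums(p); pj <- colSums(p)
  pe <- sum(pi_ * pj)
  if (1 - pe <= .Machine$double.eps) {
    icas_stop("icasflow_undefined_kappa_error",
              "chance agreement is 1: kappa undefined")
  }
  kappa <- (po - pe) / (1 - pe)
  se0 <- sqrt((pe + pe^2 - sum(pi_ * pj * (pi_ + pj))) / (N * (1 - pe)^2))
  z <- if (se0 > 0) kappa / se0 else Inf
  stat_result("Cohen's kappa", statistic = kappa,
              p_value = 2 * stats::pnorm(-abs(z)), n = as.integer(N),
              extra = list(p_observed = po, p_expected = pe))
}

#' Stenosis-threshold split correlations
#'
#' Splits the cohort at a percent-stenosis cutoff (default 50%) and runs the
#' covariate-adjusted Spearman correlation between percent stenosis and an
#' index within each subgroup.
#'
#' @param table cohort index table containing `percent_stenosis`, the index
#'   column and the covariate columns.
#' @param index_column name of the index column.
#' @param cutoff percent-stenosis cutoff (default 50).
#' @param adjust character vector of covariate column names
#'   (default `c("age_years", "sex")`), or `NULL` for unadjusted Spearman.
#' @param min_n smallest admissible subgroup size (default 5).
#' @return list with `below` and `at_or_above` `stat_result`s.
#' @export
threshold_split_correlation <- function(table, index_column, cutoff = 50,
                                        adjust = c("age_years", "sex"),
                                        min_n = 5L) {
  if (!index_column %in% names(table)) {
    icas_stop("icasflow_stats_error",
              sprintf("no column '%s' in the table", index_column))
  }
  hi <- table$percent_stenosis >= cutoff
  run <- function(sub) {
    if (nrow(sub) < min_n) {
      icas_stop("icasflow_subgroup_size_error", sprintf(
        "subgroup has %d lesions; need at least %d", nrow(sub), min_n))
    }
    if (is.null(adjust)) {
      spearman_rank(sub$percent_stenosis, sub[[index_column]])
    } else {
      partial_spearman(sub$percent_stenosis, sub[[index_column]],
                       sub[, adjust, drop = FALSE])
    }
  }
  list(below = run(table[!hi, , drop = FALSE]),
       at_or_above = run(table[hi, , drop = FALSE]))
}
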