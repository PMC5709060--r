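#' @title Statistical kernel
#' @name stats-kernel
#' @description
#' Two-group rank-sum tests with a direction convention (sign of the median
#' difference, group1 minus group2), Benjamini-Hochberg q-values, Spearman
#' and Pearson correlation, and the hypergeometric enrichment tail. These
#' are the primitives every association stage is built on; each has an
#' exhaustive-enumeration oracle in the test suite.
NULL

#' Wilcoxon rank-sum test with direction
#'
#' Exact tail probabilities (via the Wilcoxon distribution) are used when
#' `n1 + n2 <= exact_max` and the pooled data are tie-free; otherwise the
#' normal approximation with midrank tie correction and continuity
#' correction. Direction is the sign of `median(x) - median(y)` — under the
#' convention used throughout, x is the mutated (or tumor) group, so
#' direction `+1` means higher values with the mutation.
#'
#' @param x,y numeric vectors (each non-empty, finite)
#' @param alternative `"two_sided"`, `"greater"` (x tends larger) or `"less"`
#' @param exact_max pooled-size bound for the exact branch (default 20)
#' @return list with `p_value`, `direction` (-1/0/+1), `effect`
#'   (median(x) - median(y)), `n1`, `n2`, `statistic` (Mann-Whitney U of x)
#' @export
rank_sum_test <- function(x, y, alternative = c("two_sided", "greater", "less"),
                          exact_max = 20L) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("empty group in rank_sum_test")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  n1 <- length(x); n2 <- length(y)
  eff <- median(x) - median(y)
  dir <- sign(eff)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)          # all values identical: no evidence
    return(list(p_value = 1, direction = 0, effect = 0, n1 = n1, n2 = n2,
                statistic = n1 * n2 / 2))
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U of x
  ties <- any(duplicated(pooled))
  if (!ties && (n1 + n2) <= exact_max) {
    p <- switch(alternative,
      greater   = pwilcox(u - 1, n1, n2, lower.tail = FALSE),
      less      = pwilcox(u, n1, n2),
      two_sided = {
        if (u > n1 * n2 / 2)
          min(1, 2 * pwilcox(u - 1, n1, n2, lower.tail = FALSE))
        else
          min(1, 2 * pwilcox(u, n1, n2))
      })
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0)
      return(list(p_value = 1, direction = dir, effect = eff, n1 = n1, n2 = n2,
                  statistic = u))
    s <- sqrt(sigma2)
    p <- switch(alternative,
      greater   = pnorm((u - mu - 0.5) / s, lower.tail = FALSE),
      less      = pnorm((u - mu + 0.5) / s),
      two_sided = {
        z <- (u - mu - sign(u - mu) * 0.5) / s
        min(1, 2 * pnorm(-abs(z)))
      })
  }
  list(p_value = p, direction = dir, effect = eff, n1 = n1, n2 = n2, statistic = u)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up q-values mapped back to input order: `q_(i) = min_(j>=i)
#' p_(j) * m / j`, capped at 1. NA p-values yield NA q-values and do not
#' count toward the family size.
#'
#' @param p numeric vector of p-values in \[0,1\]
#' @return numeric vector of q-values aligned to `p`
#' @export
bh_qvalues <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0,1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Spearman rank correlation with p-value
#'
#' rho is the Pearson correlation of midranks; the p-value uses the
#' t-approximation with n-2 degrees of freedom. Pairs with missing values
#' are dropped first.
#'
#' @param x,y paired numeric vectors
#' @return list with `rho` and `p_value` (and `n` used)
#' @export
spearman_correlation <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0)
    stop("undefined correlation: constant vector after rank transform")
  rho <- cor(rx, ry)
  p <- cor_t_pvalue(rho, n)
  list(rho = rho, p_value = p, n = n)
}

#' Pearson product-moment correlation with p-value
#'
#' @param x,y paired numeric vectors (>= 3 complete pairs, non-constant)
#' @return list with `r` and `p_value` (and `n` used)
#' @export
pearson_correlation <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) stop("zero variance in pearson_correlation")
  r <- cor(x, y)
  list(r = r, p_value = cor_t_pvalue(r, n), n = n)
}

# two-sided p for a correlation under the t approximation, df = n - 2
cor_t_pvalue <- function(r, n) {
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Hypergeometric enrichment tail probability
#'
#' Upper-tail probability `P(X >= hits)` of observing at least `hits`
#' members of a set of size `set_size` in a draw of `draw_size` from a
#' universe of `universe_size`.
#'
#' @param hits,draw_size,set_size,universe_size non-negative counts with
#'   `hits <= min(draw_size, set_size)` and `max(draw_size, set_size) <=
#'   universe_size`
#' @return p-value in \[0,1\]
#' @export
hypergeometric_enrichment <- function(hits, draw_size, set_size, universe_size) {
  if (any(c(hits, draw_size, set_size, universe_size) < 0) ||
      hits > min(draw_size, set_size) ||
      draw_size > universe_size || set_size > universe_size)
    stop("inconsistent hypergeometric counts")
  phyper(hits - 1, set_size, universe_size - set_size, draw_size,
         lower.tail = FALSE)
}

# ---- vectorized rank-sum scan ---------------------------------------------

#' Matrix rank-sum scan: many features against many binary groupings
#'
#' Computes the two-sided normal-approximation rank-sum p-value (midrank
#' tie correction, continuity correction — the same approximation branch as
#' [rank_sum_test]) for every (feature, grouping) pair in one pass. Features
#' are rows of `values`; each column of `groups` is a 0/1 membership vector
#' over the samples (columns of `values`). The workhorse behind the
#' gene-by-probe scan, where calling a scalar test 10^5 times would
#' dominate the runtime.
#'
#' Features containing missing values fall back to a per-pair scalar path;
#' for a given pair the test is skipped (NA p) when more than
#' `max_missing_frac` of either group is missing.
#'
#' @param values numeric matrix, features x samples
#' @param groups 0/1 matrix, samples x groupings (colnames = grouping ids)
#' @param alternative `"two_sided"` (default), `"greater"` (member group
#'   tends larger) or `"less"`
#' @param max_missing_frac per-group missingness above which a pair is
#'   skipped (default 0.5)
#' @return list of matrices (features x groupings): `p`, `median_diff`
#'   (member-group median minus rest), `direction` (sign of median_diff)
#' @export
rank_sum_scan <- function(values, groups,
                          alternative = c("two_sided", "greater", "less"),
                          max_missing_frac = 0.5) {
  alternative <- match.arg(alternative)
  values <- as.matrix(values); groups <- as.matrix(groups)
  stopifnot(ncol(values) == nrow(groups))
  n <- ncol(values)
  n1 <- colSums(groups)
  if (any(n1 == 0 | n1 == n))
    stop("each grouping needs at least one member and one non-member")
  has_na <- rowSums(is.na(values)) > 0
  p <- matrix(NA_real_, nrow(values), ncol(groups),
              dimnames = list(rownames(values), colnames(groups)))
  md <- p
  if (any(!has_na)) {
    v <- values[!has_na, , drop = FALSE]
    rk <- matrixStats::rowRanks(v, ties.method = "average")
    w1 <- rk %*% groups                         # rank sums of member group
    u <- sweep(w1, 2, n1 * (n1 + 1) / 2)        # Mann-Whitney U
    mu <- n1 * (n - n1) / 2
    # per-feature tie correction: sum over tied groups of t^3 - t
    tie_term <- apply(rk, 1, function(r) { t <- table(r); sum(t^3 - t) })
    sigma2 <- outer((n + 1) - tie_term / (n * (n - 1)), n1 * (n - n1) / 12)
    s <- sqrt(sigma2)
    d <- sweep(u, 2, mu)
    pv <- switch(alternative,
      two_sided = pmin(1, 2 * pnorm(-abs((d - sign(d) * 0.5) / s))),
      greater   = pnorm((d - 0.5) / s, lower.tail = FALSE),
      less      = pnorm((d + 0.5) / s))
    pv[sigma2 <= 0] <- 1                        # fully tied feature
    p[!has_na, ] <- pv
    for (g in seq_len(ncol(groups))) {
      ing <- groups[, g] == 1
      md[!has_na, g] <- matrixStats::rowMedians(v[, ing, drop = FALSE]) -
        matrixStats::rowMedians(v[, !ing, drop = FALSE])
    }
  }
  if (any(has_na)) {
    alt <- alternative
    for (i in which(has_na)) for (g in seq_len(ncol(groups))) {
      ing <- groups[, g] == 1
      xv <- values[i, ing]; yv <- values[i, !ing]
      if (mean(is.na(xv)) > max_missing_frac || mean(is.na(yv)) > max_missing_frac)
        next
      res <- rank_sum_test(xv[!is.na(xv)], yv[!is.na(yv)], alt)
      p[i, g] <- res$p_value
      md[i, g] <- median(xv, na.rm = TRUE) - median(yv, na.rm = TRUE)
    }
  }
  list(p = p, median_diff = md, direction = sign(md))
}
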