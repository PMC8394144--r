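#' Fisher's exact test on a 2x2 table with the sample odds ratio
#'
#' The two-sided p-value is the usual conditional exact p: the sum of
#' hypergeometric probabilities (margins fixed) of all tables at most as
#' probable as the observed one. Unlike [stats::fisher.test()]'s
#' conditional-MLE estimate, the odds ratio reported here is the plain
#' sample odds ratio `(a/b) / (c/d)`; when any cell is zero the point
#' estimate uses the Haldane correction (+0.5 to every cell) while the
#' test itself is unmodified.
#'
#' @param table 2x2 matrix of non-negative counts (rows = groups,
#'   columns = outcomes), or a length-4 vector `c(a, b, c, d)` read
#'   row-wise.
#' @return List with `odds_ratio`, `p`, and `or_defined` (FALSE when a
#'   margin is zero, in which case `p = 1`).
#' @export
fisher_exact <- function(table) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2, 2)))
    a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  } else {
    stopifnot(length(table) == 4)
    a <- table[1]; b <- table[2]; c <- table[3]; d <- table[4]
  }
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(odds_ratio = NA_real_, p = 1, or_defined = FALSE))
  }
  or <- if (any(c(a, b, c, d) == 0)) {
    ((a + 0.5) / (b + 0.5)) / ((c + 0.5) / (d + 0.5))
  } else {
    (a / b) / (c / d)
  }
  p <- fisher.test(m)$p.value
  list(odds_ratio = unname(or), p = unname(p), or_defined = TRUE)
}

# exact two-sided Mann-Whitney p by enumeration over all group assignments
# of the pooled sample (handles ties); feasible for small n
mwu_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  combs <- combn(length(pooled), n1)
  u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For small samples (both sides <= 8) the exact
#' p-value is computed by enumerating all assignments of the pooled values
#' to the two groups, which remains valid under ties; larger samples use
#' the tie-corrected normal approximation with continuity correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact_max Largest per-side size for the exact path. Default 8.
#' @return List with `U` (statistic for `x`) and two-sided `p`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(c(x, y))) == 1) {
    return(list(U = u, p = 1))
  }
  if (n1 <= exact_max && n2 <= exact_max) {
    return(list(U = u, p = mwu_exact_p(x, y)))
  }
  n <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  mu <- n1 * n2 / 2
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(U = u, p = min(1, 2 * pnorm(-abs(z))))
}

#' One-sample Kolmogorov-Smirnov test against a fitted normal
#'
#' Tests a sample against Normal(mean(x), sd(x)) with the asymptotic
#' Kolmogorov distribution for the p-value. Estimating the parameters from
#' the same sample makes the test conservative (the Lilliefors bias): true
#' normal samples yield p-values stochastically larger than uniform, so a
#' non-rejection is the expected outcome for normal data and rejections
#' are strong signals.
#'
#' @param x Numeric sample with n >= 5.
#' @return List with `D`, `p`, and `degenerate` (TRUE with `p = 0` when
#'   the sample SD is zero).
#' @export
ks_normal <- function(x) {
  if (length(x) < 5) stop("need at least 5 observations")
  s <- sd(x)
  if (s == 0) return(list(D = 1, p = 0, degenerate = TRUE))
  kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), s, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment, order-preserving and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in the input order.
#' @export
bh_qvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}
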