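#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test used throughout the package for group comparisons
#' (transcript panels and electrophysiology features). The null
#' distribution is exact (via the Wilcoxon rank-sum distribution) when both
#' samples have at most `exact_max_n` observations and there are no ties;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. When every observation is tied across both samples
#' the test is degenerate and p = 1.
#'
#' @param x,y Numeric vectors (the two groups).
#' @param exact_max_n Largest per-group size for which the exact null is
#'   used (default 8).
#' @return A list with `statistic` (U, counting pairs where `x` precedes
#'   `y`), `p.value`, and `exact` (logical).
#' @examples
#' mwu_test(c(1, 2, 3), c(4, 5, 6))$p.value # exact: 0.1
#' @export
mwu_test <- function(x, y, exact_max_n = 8L) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n <- length(x)
  m <- length(y)
  if (n == 0L || m == 0L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  nm <- as.numeric(n) * m
  ties <- table(r)
  has_ties <- any(ties > 1L)

  if (!has_ties && n <= exact_max_n && m <= exact_max_n) {
    lower <- stats::pwilcox(U, n, m)
    upper <- 1 - stats::pwilcox(U - 1, n, m)
    p <- min(1, 2 * min(lower, upper))
    return(list(statistic = U, p.value = p, exact = TRUE))
  }

  N <- n + m
  sigma2 <- nm / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(list(statistic = U, p.value = 1, exact = FALSE))
  }
  z <- U - nm / 2
  # continuity correction toward the null
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = U, p.value = p, exact = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper around [stats::p.adjust()] with `method = "BH"`, kept as
#' the package's single multiple-testing surface so every module adjusts
#' p-values identically.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

# Significance stars on adjusted p-values: * < 0.05, ** < 0.01.
sig_stars <- function(p_adj) {
  ifelse(is.na(p_adj), "", ifelse(p_adj < 0.01, "**", ifelse(p_adj < 0.05, "*", "")))
}
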