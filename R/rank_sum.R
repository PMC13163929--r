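#' Two-sample Wilcoxon rank-sum test
#'
#' Mann-Whitney form of the two-sided rank-sum test used for per-probe
#' differential methylation. When the combined sample size is at most
#' `exact_max` and the data are tie-free, the p-value comes from the exact
#' null distribution of the rank-sum statistic; otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used (mid-ranks for ties). Completely tied data give p = 1.
#'
#' @param a,b Numeric vectors of beta-values (or any continuous scores);
#'   `NA`s are dropped. Each group needs at least one non-missing value.
#' @param exact_max Largest combined n for which the exact distribution is
#'   used (default 12).
#' @return List with `statistic` (Mann-Whitney U for group `a`), `p_value`,
#'   and `method` (`"exact"` or `"normal"`).
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # exact, 0.1
#' @export
rank_sum_test <- function(a, b, exact_max = 12L) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  na <- length(a)
  nb <- length(b)
  if (na == 0 || nb == 0) stop("each group needs >= 1 non-missing value",
                               call. = FALSE)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  N <- na + nb
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = U, p_value = 1, method = "degenerate"))
  }
  if (!ties && N <= exact_max) {
    # exact two-sided p: twice the smaller tail of the U distribution
    p <- 2 * min(stats::pwilcox(U, na, nb),
                 1 - stats::pwilcox(U - 1, na, nb))
    p <- min(1, p)
    return(list(statistic = U, p_value = p, method = "exact"))
  }
  tab <- table(pooled)
  tie_term <- sum(tab^3 - tab) / (N * (N - 1))
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(statistic = U, p_value = 1, method = "normal"))
  z <- max(abs(U - na * nb / 2) - 0.5, 0) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-z)
  p <- min(1, max(p, .Machine$double.xmin))
  list(statistic = U, p_value = p, method = "normal")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, capped at 1, in the original input order.
#' Inputs must lie in (0, 1].
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric", call. = FALSE)
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
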