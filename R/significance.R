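#' t-statistic p-value for a distance correlation
#'
#' `t = dCor * sqrt(n-2) / sqrt(1 - dCor^2)` referred to the Student t
#' distribution with n-2 degrees of freedom; the two-sided p-value is
#' `2 * (1 - F_t(t))`, clamped to `[0, 1]`. Since dCor >= 0 the statistic is
#' always non-negative; dCor = 1 yields t = Inf and p = 0.
#'
#' @param dcor Distance correlation in `[0, 1]` (vectorized).
#' @param n Number of samples (>= 3).
#' @return A list with `t_stat` and `p_value`.
#' @export
dcor_t_pvalue <- function(dcor, n) {
  if (n < 3) stop("p-value requires n >= 3 samples (df = n - 2 >= 1)",
                  call. = FALSE)
  stopifnot(all(dcor >= 0 & dcor <= 1))
  t_stat <- ifelse(dcor >= 1, Inf, dcor * sqrt(n - 2) / sqrt(1 - dcor^2))
  p <- 2 * (1 - stats::pt(t_stat, df = n - 2))
  list(t_stat = t_stat, p_value = pmin(pmax(p, 0), 1))
}

#' Companion Pearson and Spearman statistics for a feature pair
#'
#' Conventional product-moment and rank correlations with their two-sided
#' t-based p-values (ranks use the average-tie method, as in
#' [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length n >= 3, non-constant.
#' @return A list with `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`.
#' @export
pearson_spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  pe <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  sp <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = "two.sided"))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
}

#' Sign a distance correlation by the Pearson trend
#'
#' Distance correlation is non-negative; directionality is restored by taking
#' the sign of the Pearson correlation of the same pair. Tie rule: a Pearson
#' correlation of zero (|r| < 1e-15) resolves to +1, so the signed value is
#' deterministic.
#'
#' @param dcor Distance correlation in `[0, 1]` (vectorized).
#' @param pearson_r Pearson correlation of the same pair (vectorized).
#' @return A list with `sign` (+1/-1) and `signed_dcor`.
#' @export
attach_sign <- function(dcor, pearson_r) {
  sgn <- ifelse(pearson_r < -1e-15, -1, 1)
  list(sign = sgn, signed_dcor = sgn * dcor)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment; offered as an option for edge
#' filtering (off by default: raw p thresholds are the default contract).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length, monotone and <= 1.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}
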