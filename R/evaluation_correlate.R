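#' Correlation of intensity ratios with onset time
#'
#' Pearson for normally distributed ratios, Spearman or Kendall otherwise;
#' two-tailed p values throughout (rank methods use the asymptotic
#' approximation so tied ratios are handled).
#'
#' @param x,y paired numeric vectors without missing values, n >= 3.
#' @param method `"pearson"`, `"spearman"` or `"kendall"`.
#' @return list with `estimate`, `p_value`, `method`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman", "kendall")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_strokeclock("bad_input", "x and y must be paired")
  if (anyNA(x) || anyNA(y)) stop_strokeclock("bad_input", "missing pairs are not allowed")
  if (length(x) < 3L) stop_strokeclock("bad_input", "need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_strokeclock("constant_input", "correlation is undefined for constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(estimate = unname(ct$estimate), p_value = ct$p.value, method = method,
       n = length(x))
}
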