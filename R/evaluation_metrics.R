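#' Confusion table of classification counts
#'
#' @param tp,fp,fn,tn non-negative integer counts; total must be positive.
#' @return object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  cts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cts < 0) || any(cts != round(cts)))
    stop_strokeclock("bad_counts", "confusion counts must be non-negative integers")
  if (sum(cts) <= 0) stop_strokeclock("bad_counts", "confusion table is empty")
  structure(as.list(cts), class = "confusion_table")
}

prop_ci <- function(p, n, conf_level = 0.95) {
  if (n == 0) return(c(value = NA_real_, se = NA_real_, lower = NA_real_, upper = NA_real_))
  se <- sqrt(p * (1 - p) / n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  c(value = p, se = se, lower = max(0, p - z * se), upper = min(1, p + z * se))
}

#' Diagnostic accuracy metrics with confidence intervals
#'
#' Accuracy, sensitivity (recall), specificity, positive and negative
#' predictive values as proportions in `[0, 1]`, each with a 95% CI computed
#' as +/- 1.96 standard errors of a proportion (clamped to `[0, 1]`).
#' A metric whose denominator is zero is returned as NA (undefined), not an
#' error for the remaining metrics.
#'
#' @param ct a [confusion_table()].
#' @param conf_level confidence level (default 0.95).
#' @return data.frame with columns metric, value, se, lower, upper and a
#'   logical `undefined` flag.
#' @export
diagnostic_metrics <- function(ct, conf_level = 0.95) {
  if (!inherits(ct, "confusion_table")) stop_strokeclock("bad_input", "need a confusion_table")
  tot <- ct$tp + ct$fp + ct$fn + ct$tn
  defs <- list(
    accuracy = c(ct$tp + ct$tn, tot),
    sensitivity = c(ct$tp, ct$tp + ct$fn),
    specificity = c(ct$tn, ct$tn + ct$fp),
    ppv = c(ct$tp, ct$tp + ct$fp),
    npv = c(ct$tn, ct$tn + ct$fn)
  )
  rows <- lapply(names(defs), function(nm) {
    num <- defs[[nm]][1]; den <- defs[[nm]][2]
    if (den == 0) {
      data.frame(metric = nm, value = NA_real_, se = NA_real_,
                 lower = NA_real_, upper = NA_real_, undefined = TRUE)
    } else {
      ci <- prop_ci(num / den, den, conf_level)
      data.frame(metric = nm, value = ci[["value"]], se = ci[["se"]],
                 lower = ci[["lower"]], upper = ci[["upper"]], undefined = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' F1 score with confidence interval
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`, the harmonic mean of precision and recall,
#' appropriate for imbalanced cohorts because it ignores true negatives. The
#' 95% CI is a normal approximation +/- 1.96 SE with
#' `SE = sqrt(F1 (1 - F1) / n)` over the `n` classified items.
#'
#' @param ct a [confusion_table()].
#' @param conf_level confidence level (default 0.95).
#' @return list with `f1`, `se`, `ci`; `f1` is NA (undefined) when
#'   `2 TP + FP + FN = 0`.
#' @export
f1_score <- function(ct, conf_level = 0.95) {
  if (!inherits(ct, "confusion_table")) stop_strokeclock("bad_input", "need a confusion_table")
  den <- 2 * ct$tp + ct$fp + ct$fn
  if (den == 0)
    return(list(f1 = NA_real_, se = NA_real_, ci = c(lower = NA_real_, upper = NA_real_),
                undefined = TRUE))
  f1 <- 2 * ct$tp / den
  n <- ct$tp + ct$fp + ct$fn + ct$tn
  se <- sqrt(f1 * (1 - f1) / n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(f1 = f1, se = se,
       ci = c(lower = max(0, f1 - z * se), upper = min(1, f1 + z * se)),
       undefined = FALSE)
}
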