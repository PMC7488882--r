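# Precision-recall-gain analysis for class-imbalanced subcohorts.

#' Precision gain and recall gain
#'
#' Gain transforms of precision and recall relative to the always-positive
#' baseline at prevalence `pi`: `gain(v) = (v - pi) / ((1 - pi) * v)`. A
#' trivial classifier sits at gain 0, a perfect one at gain 1.
#'
#' @param v precision or recall in (0, 1].
#' @param pi positive-class prevalence in (0, 1).
#' @return the gain value (<= 1; negative for performance below baseline).
#' @export
precision_gain <- function(v, pi) (v - pi) / ((1 - pi) * v)

#' @rdname precision_gain
#' @export
recall_gain <- function(v, pi) (v - pi) / ((1 - pi) * v)

#' Precision-recall-gain curve and its area
#'
#' Operating points are taken at every distinct score threshold; precision
#' and recall are mapped into gain space and the curve is traced over
#' recall-gain in `[0, 1]`. The entry point at recall-gain 0 (recall equal to
#' the prevalence) is located by linear interpolation of the classification
#' counts between the two adjacent operating points. AUPRG is the trapezoidal
#' area of the polyline over recall-gain in `[0, 1]`; segments with negative
#' precision gain contribute negatively, so a random ranking scores about 0
#' and a perfect ranking exactly 1.
#'
#' @inheritParams roc_auc
#' @return object of class `prg_result`: `prevalence`, `points` data.frame
#'   (recall_gain, precision_gain, tp, fp) and `auprg`.
#' @export
prg_curve <- function(scores, labels, direction = c("below", "above")) {
  direction <- match.arg(direction)
  labels <- check_two_classes(labels)
  s <- orient_scores(scores, direction)
  P <- sum(labels == 1); N <- sum(labels == 0)
  pi0 <- P / (P + N)
  ord <- order(s, decreasing = TRUE)
  lab <- labels[ord]
  # cumulative counts at each distinct-threshold boundary
  sv <- s[ord]
  boundary <- which(diff(sv) != 0)
  cuts <- c(boundary, length(sv))
  tp <- cumsum(lab)[cuts]
  fp <- cuts - tp
  tp_star <- P * pi0  # recall == prevalence, i.e. recall gain 0
  i <- which(tp >= tp_star)[1]
  if (is.na(i)) stop_strokeclock("bad_input", "no operating point reaches the prevalence recall")
  tp_prev <- if (i == 1) 0 else tp[i - 1]
  fp_prev <- if (i == 1) 0 else fp[i - 1]
  lambda <- (tp_star - tp_prev) / (tp[i] - tp_prev)
  fp_star <- fp_prev + lambda * (fp[i] - fp_prev)
  prec_star <- tp_star / (tp_star + fp_star)

  keep <- seq(i, length(tp))
  rec <- tp[keep] / P
  prec <- tp[keep] / (tp[keep] + fp[keep])
  rg <- c(0, recall_gain(rec, pi0))
  pg <- c(precision_gain(prec_star, pi0), precision_gain(prec, pi0))
  auprg <- sum(diff(rg) * (pg[-1] + pg[-length(pg)]) / 2)
  structure(
    list(prevalence = pi0,
         points = data.frame(recall_gain = rg, precision_gain = pg,
                             tp = c(tp_star, tp[keep]), fp = c(fp_star, fp[keep])),
         auprg = auprg, direction = direction),
    class = "prg_result"
  )
}
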