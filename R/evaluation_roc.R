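# ROC analysis: AUC by the Mann-Whitney statistic, DeLong variance components
# for tests and paired comparisons, Youden-index operating points.

# Orient scores so that larger values indicate the positive class.
orient_scores <- function(scores, direction = c("below", "above")) {
  direction <- match.arg(direction)
  if (direction == "below") -scores else scores
}

check_two_classes <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop_strokeclock("bad_labels", "labels must be 0/1")
  if (length(unique(labels)) < 2L)
    stop_strokeclock("single_class", "both classes must be present")
  labels
}

# DeLong placement components; scores already oriented (higher = positive).
delong_components <- function(oriented, labels) {
  x <- oriented[labels == 1]; y <- oriented[labels == 0]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
       m = length(x), n = length(y))
}

delong_se <- function(cmp) {
  sqrt(stats::var(cmp$v10) / cmp$m + stats::var(cmp$v01) / cmp$n)
}

#' ROC curve and AUC
#'
#' The AUC equals the Mann-Whitney probability that a randomly chosen
#' within-window patient scores more extreme, in the stated direction, than a
#' randomly chosen beyond-window patient (ties counted 1/2). `direction =
#' "below"` declares low scores positive (the convention for T2-family
#' ratios, which rise with onset time); `"above"` declares high scores
#' positive (ADC ratios). The default CI is an exact binomial
#' (Clopper-Pearson) interval on the concordant-pair count; `"delong"` gives
#' the asymptotic-normal interval from the DeLong variance. The p value tests
#' AUC = 0.5 with the DeLong standard error.
#'
#' @param scores numeric classifier scores (e.g. intensity ratios).
#' @param labels 0/1 with 1 = within the treatment window; both classes
#'   required.
#' @param direction `"below"` or `"above"` (which extreme is positive).
#' @param conf_level confidence level (default 0.95).
#' @param ci_method `"binomial_exact"` (default) or `"delong"`.
#' @return object of class `roc_result`: `auc`, `ci`, `p_value`, `direction`,
#'   and a `curve` data.frame (threshold, sensitivity, fpr).
#' @export
roc_auc <- function(scores, labels, direction = c("below", "above"),
                    conf_level = 0.95, ci_method = c("binomial_exact", "delong")) {
  direction <- match.arg(direction)
  ci_method <- match.arg(ci_method)
  labels <- check_two_classes(labels)
  if (anyNA(scores)) stop_strokeclock("bad_input", "scores contain missing values")
  s <- orient_scores(scores, direction)
  cmp <- delong_components(s, labels)
  auc <- cmp$auc
  m <- cmp$m; n <- cmp$n
  alpha <- 1 - conf_level
  if (ci_method == "binomial_exact") {
    npair <- m * n
    x <- auc * npair
    lo <- if (x <= 0) 0 else stats::qbeta(alpha / 2, x, npair - x + 1)
    hi <- if (x >= npair) 1 else stats::qbeta(1 - alpha / 2, x + 1, npair - x)
  } else {
    se <- delong_se(cmp)
    z <- stats::qnorm(1 - alpha / 2)
    lo <- max(0, auc - z * se); hi <- min(1, auc + z * se)
  }
  se0 <- max(delong_se(cmp), 1e-10)
  p <- 2 * stats::pnorm(-abs(auc - 0.5) / se0)

  thr <- c(-Inf, sort(unique(s)), Inf)
  curve <- t(vapply(thr, function(t0) {
    pred <- s >= t0
    c(sens = sum(pred & labels == 1) / m, fpr = sum(pred & labels == 0) / n)
  }, numeric(2)))
  structure(
    list(auc = auc, ci = c(lower = lo, upper = hi), conf_level = conf_level,
         ci_method = ci_method, p_value = p, direction = direction,
         n_pos = m, n_neg = n,
         curve = data.frame(threshold = thr, sensitivity = curve[, 1], fpr = curve[, 2])),
    class = "roc_result"
  )
}

#' Pairwise nonparametric comparison of AUCs
#'
#' Paired DeLong test for the difference between correlated AUCs measured on
#' the same patients (covariance-aware placement-value test), with Bonferroni
#' adjustment across all pairs. A classifier compared with itself gives
#' p = 1.
#'
#' @param scores_list named list of score vectors, all on the same patients.
#' @param labels common 0/1 labels.
#' @param directions character vector (recycled) of per-classifier
#'   directions, `"below"`/`"above"`.
#' @return data.frame with one row per unordered pair: AUCs, difference, z,
#'   raw and Bonferroni-adjusted p values.
#' @export
compare_aucs <- function(scores_list, labels, directions = "below") {
  if (length(scores_list) < 2L)
    stop_strokeclock("bad_input", "need at least two classifiers")
  labels <- check_two_classes(labels)
  len <- vapply(scores_list, length, integer(1))
  if (any(len != length(labels)))
    stop_strokeclock("unpaired", "all score vectors must cover the same patients")
  directions <- rep(directions, length.out = length(scores_list))
  cmps <- Map(function(s, d) delong_components(orient_scores(s, d), labels),
              scores_list, directions)
  nm <- names(scores_list) %||% paste0("clf", seq_along(scores_list))
  pairs <- utils::combn(length(cmps), 2)
  rows <- apply(pairs, 2, function(idx) {
    a <- cmps[[idx[1]]]; b <- cmps[[idx[2]]]
    v <- stats::var(a$v10 - b$v10) / a$m + stats::var(a$v01 - b$v01) / a$n
    diff <- a$auc - b$auc
    if (v <= 0) {
      p <- if (abs(diff) < .Machine$double.eps^0.5) 1 else 0
      z <- if (p == 1) 0 else Inf
    } else {
      z <- diff / sqrt(v)
      p <- 2 * stats::pnorm(-abs(z))
    }
    data.frame(classifier_a = nm[idx[1]], classifier_b = nm[idx[2]],
               auc_a = a$auc, auc_b = b$auc, diff = diff, z = z, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "bonferroni")
  rownames(out) <- NULL
  out
}

#' Optimal cutoff by the maximum Youden J index
#'
#' Exhaustive search over the midpoints of adjacent sorted unique scores for
#' the cutoff maximizing J = sensitivity + specificity - 1 (equal weight to
#' both error types). With `direction = "below"` a patient is called within
#' the window when the score is at or below the cutoff. Ties in J are broken
#' toward the cutoff that classifies more patients as beyond the window
#' (favoring specificity, hence treatment safety).
#'
#' @inheritParams roc_auc
#' @param tie_break `"specificity"` (default, as above) or `"sensitivity"`.
#' @return object of class `cutoff_result`: `cutoff`, `j`, the
#'   `confusion` table at the cutoff and its [diagnostic_metrics()].
#' @export
youden_cutoff <- function(scores, labels, direction = c("below", "above"),
                          tie_break = c("specificity", "sensitivity")) {
  direction <- match.arg(direction)
  tie_break <- match.arg(tie_break)
  labels <- check_two_classes(labels)
  u <- sort(unique(scores))
  if (length(u) < 2L)
    stop_strokeclock("bad_input", "scores are constant; no cutoff exists")
  # midpoints of adjacent unique scores, plus the two boundary cutoffs that
  # classify everyone into one class (J = 0): J must never fall below the
  # trivial operating points of the ROC curve
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  pred_pos <- function(c0) if (direction == "below") scores <= c0 else scores >= c0
  stats_at <- vapply(cand, function(c0) {
    pred <- pred_pos(c0)
    tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
    fp <- sum(pred & labels == 0); tn <- sum(!pred & labels == 0)
    c(j = tp / (tp + fn) + tn / (tn + fp) - 1, npos = sum(pred))
  }, numeric(2))
  jmax <- max(stats_at["j", ])
  ties <- which(stats_at["j", ] >= jmax - 1e-12)
  best <- if (tie_break == "specificity") ties[which.min(stats_at["npos", ties])]
          else ties[which.max(stats_at["npos", ties])]
  c0 <- cand[best]
  pred <- pred_pos(c0)
  ct <- confusion_table(
    tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
    fn = sum(!pred & labels == 1), tn = sum(!pred & labels == 0)
  )
  structure(
    list(cutoff = c0, j = jmax, direction = direction,
         confusion = ct, metrics = diagnostic_metrics(ct)),
    class = "cutoff_result"
  )
}
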