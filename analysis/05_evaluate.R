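#!/usr/bin/env Rscript
# Stage 5 — statistical evaluation of the timing classifiers.
#
# Correlations with onset time, ROC/AUC with exact binomial CIs and pairwise
# DeLong comparisons, Youden cutoffs with diagnostic metrics, logistic
# models ranked by AICc, and — on the FLAIR subcohort — PRG/AUPRG, F1 and
# the mismatch-rating kappa. Summary tables land under results/.

source("analysis/00_config.R")
cfg <- analysis_config()
`%||%` <- function(a, b) if (is.null(a)) b else a

stage_evaluate(cfg)
res <- jsonlite::read_json(file.path(cfg$out_dir, "evaluation.json"),
                           simplifyVector = TRUE)

auc_tab <- do.call(rbind, lapply(names(res$roc), function(nm) {
  r <- res$roc[[nm]]
  data.frame(ratio = sub("ratio_", "", nm), auc = r$auc,
             auc_lo = r$auc_ci$lower, auc_hi = r$auc_ci$upper, p = r$auc_p,
             cutoff = r$cutoff, youden_j = r$youden_j,
             accuracy = r$metrics$value[r$metrics$metric == "accuracy"],
             sensitivity = r$metrics$value[r$metrics$metric == "sensitivity"],
             specificity = r$metrics$value[r$metrics$metric == "specificity"])
}))
write.csv(auc_tab, "results/roc_summary.csv", row.names = FALSE)

logit_tab <- do.call(rbind, lapply(names(res$logistic), function(nm) {
  m <- res$logistic[[nm]]
  if (!identical(m$status, "ok")) {
    return(data.frame(model = nm, status = m$status, chisq = NA, df = NA,
                      p = NA, aicc = NA))
  }
  data.frame(model = nm, status = "ok", chisq = m$chisq, df = m$df,
             p = m$p, aicc = m$aicc)
}))
write.csv(logit_tab, "results/logistic_summary.csv", row.names = FALSE)

cor_tab <- do.call(rbind, lapply(names(res$correlations), function(nm) {
  k <- res$correlations[[nm]]
  data.frame(ratio = sub("ratio_", "", nm),
             pearson_r = k$pearson$estimate, pearson_p = k$pearson$p,
             spearman_r = k$spearman$estimate, spearman_p = k$spearman$p)
}))
write.csv(cor_tab, "results/correlation_summary.csv", row.names = FALSE)

message("ROC summary (all patients):")
print(auc_tab, digits = 3)
message("Logistic models by AICc:")
print(logit_tab[order(logit_tab$aicc), ], digits = 4)

if (!is.null(res$subcohort)) {
  sc <- res$subcohort
  prg_tab <- data.frame(
    ratio = sub("ratio_", "", names(sc$prg)),
    auprg = vapply(sc$prg, function(x) x$auprg %||% NA_real_, numeric(1)),
    f1 = vapply(sc$f1, function(x) x$f1 %||% NA_real_, numeric(1))
  )
  write.csv(prg_tab, "results/subcohort_prg_f1.csv", row.names = FALSE)
  message("FLAIR subcohort (AUPRG / F1):")
  print(prg_tab, digits = 3)
  if (!is.null(sc$kappa))
    message(sprintf("Mismatch raters: Po = %.3f, free-marginal kappa = %.2f; mismatch F1 = %.2f",
                    sc$kappa$po, sc$kappa$kappa, sc$mismatch$f1))
}
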