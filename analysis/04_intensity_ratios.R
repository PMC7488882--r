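#!/usr/bin/env Rscript
# Stage 4 — ischemic / reference intensity ratios per map type.
#
# Each patient's ratio is the mean map value over the ischemic VOI divided
# by the mean over the mirrored reference VOI, per map (ADC, DWI, T2w, T2,
# FLAIR where acquired). The cohort table is the input of every classifier
# analysis.

source("analysis/00_config.R")
cfg <- analysis_config()

stage_ratios(cfg)
tab <- read.csv(file.path(cfg$out_dir, "cohort.csv"))

message(sprintf("Cohort table: %d rows; T2 ratio %.3f-%.3f, ADC ratio %.3f-%.3f",
                nrow(tab), min(tab$ratio_t2), max(tab$ratio_t2),
                min(tab$ratio_adc), max(tab$ratio_adc)))
write.csv(tab, "results/cohort_table.csv", row.names = FALSE)
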