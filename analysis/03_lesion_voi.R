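#!/usr/bin/env Rscript
# Stage 3 — ischemic VOI and mirrored non-ischemic reference.
#
# Threshold rules: 0.30 < ADC < 0.55 um^2/ms, ADC more than one HWHM below
# the non-ischemic median, 30 < T2 < 200 ms; largest 26-connected cluster(s)
# kept; reference = reflection about the mid-sagittal plane with the same T2
# limits editing out CSF.

source("analysis/00_config.R")
cfg <- analysis_config()

stage_voi(cfg)

vols <- vapply(list.files(file.path(cfg$out_dir, "voi"), pattern = "voi.json",
                          recursive = TRUE, full.names = TRUE),
               function(p) {
                 j <- jsonlite::read_json(p)
                 if (identical(j$status, "ok")) j$volume_ml else NA_real_
               }, numeric(1))
message(sprintf("Lesion VOIs for %d/%d patients; volumes %.2f-%.2f mL (median %.2f)",
                sum(!is.na(vols)), length(vols),
                min(vols, na.rm = TRUE), max(vols, na.rm = TRUE),
                median(vols, na.rm = TRUE)))

write.csv(data.frame(patient = basename(dirname(names(vols))), lesion_ml = vols,
                     row.names = NULL),
          "results/lesion_volumes.csv", row.names = FALSE)
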