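# Shared configuration for the analysis scripts: one 35-patient synthetic
# hyperacute cohort (16 within / 19 beyond the 270-minute window, 17 with
# FLAIR), glasgow-style protocol, 3% Rician noise, staged outputs under
# scratch/run/ and tables under results/.

library(strokeclock)

analysis_config <- function() {
  run_config(out_dir = "scratch/run", n = 35L, preset = "full", seed = 7L,
             window_min = 270)
}

dir.create("results", showWarnings = FALSE)
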