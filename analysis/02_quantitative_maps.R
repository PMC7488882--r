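#!/usr/bin/env Rscript
# Stage 2 — quantitative and weighted maps per patient.
#
# Voxelwise mono-exponential T2 (signal^2-weighted log-linear fit),
# echo-summed T2w, mean-diffusivity ADC from the 20-direction tensor fit,
# effective b = 1000 DWI from S0 and ADC; FLAIR passes through. Maps land
# under scratch/run/maps/.

source("analysis/00_config.R")
cfg <- analysis_config()

files <- stage_maps(cfg)
message(sprintf("Computed map sets for %d patients (%d files)",
                length(list.dirs(file.path(cfg$out_dir, "maps"), recursive = FALSE)),
                length(files)))
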