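#!/usr/bin/env Rscript
# Stage 1: generate the synthetic silver-nanoform study table.
#
# Emulates the measured design: 6 ERM-identified nanoforms, A549 lung
# exposures (MTT, Alamar blue) over 0.1-100 ppm and HCT-116 intestinal
# exposures (WST-1, digested / non-digested) over 1.25-100 ppm,
# triplicates, with 47% missingness on the DLS columns and 19% on the
# spherical surface area.

suppressMessages(library(hazardbn))
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(seed = 42L)
dataset <- generate_dataset(cfg)
write_dataset(dataset, "results/01_dataset.csv")

cls <- table(classify_viability(dataset$viability))
miss <- vapply(dataset, function(v) mean(is.na(v)), 0)
cat(sprintf("generated %d exposure records for %d nanoforms\n",
            nrow(dataset), length(unique(dataset$erm_id))))
cat("hazard classes:",
    paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
cat("missing fractions (DLS t0/t24, PdI t0/t24, surface area):",
    paste(round(miss[c("hydro_size_t0", "hydro_size_t24", "pdi_t0",
                       "pdi_t24", "spherical_surface_area")], 3),
          collapse = ", "), "\n")
stopifnot(length(validate_dataset(dataset)) == 0)
cat("schema invariants hold; table written to results/01_dataset.csv\n")
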