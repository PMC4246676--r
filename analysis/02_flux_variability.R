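#!/usr/bin/env Rscript
# Stage 2: FBA/FVA on the two toy-model parameterizations and T/S/N
# responsiveness classification. Run after analysis/01_simulate.R.
# Writes results/fva/.

library(fluxcord)

indir <- file.path("results", "simulated")
outdir <- file.path("results", "fva")
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- scenario_config(seed = 42)
pair <- make_model_pair(cfg)

fa <- fva(pair$model_a, pair$ratio_constraints_a, accession = "A")
fb <- fva(pair$model_b, pair$ratio_constraints_b, accession = "B")
write_flux_bounds(fa, file.path(outdir, "toy_fva_A.tsv"))
write_flux_bounds(fb, file.path(outdir, "toy_fva_B.tsv"))

calls <- classify_responsiveness(fa, fb)
fluxcord:::.write_tsv(calls, file.path(outdir, "toy_responsiveness.tsv"))
cat("toy-model responsiveness:\n")
print(table(calls$combined_call))

fcv <- flux_change_value(fa, fb)
fluxcord:::.write_tsv(fcv, file.path(outdir, "toy_flux_change_values.tsv"))
cat(sprintf("%d of %d toy reactions flux-responsive\n",
            sum(fcv$responsive), nrow(fcv)))
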