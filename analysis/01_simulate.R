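#!/usr/bin/env Rscript
# Stage 1: generate every input the pipeline consumes, at the study's design
# scale (two accessions, 3 biological replicates, ~4.7 transcripts per gene,
# 200 reactions with an 80% planted flux-response quota and a planted
# concordance fraction of 0.8). Writes results/simulated/.

library(fluxcord)

outdir <- file.path("results", "simulated")
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- scenario_config(seed = 42)

# toy network: two biomass parameterizations (A high lipid, B high starch)
pair <- make_model_pair(cfg)
write_model_json(pair$model_a, file.path(outdir, "model_A.json"))
write_model_json(pair$model_b, file.path(outdir, "model_B.json"))
cat(sprintf("biomass optima: A = %.6f, B = %.6f umol/h\n",
            pair$objective_a, pair$objective_b))

# scaled synthetic FVA bound sets + planted flux-direction truth
sim <- simulate_flux_bounds(cfg)
write_flux_bounds(sim$bounds_a, file.path(outdir, "flux_bounds_A.tsv"))
write_flux_bounds(sim$bounds_b, file.path(outdir, "flux_bounds_B.tsv"))
fluxcord:::.write_tsv(sim$truth, file.path(outdir, "flux_truth.tsv"))

# GPR association tables and the planted expression truth
gpr <- make_gpr(cfg, sim$truth$reaction_id)
write_gpr(gpr, file.path(outdir, "transcript_gene.tsv"),
          file.path(outdir, "gene_reaction.tsv"))
truth <- plant_concordance(sim$truth, cfg$concordance_fraction, gpr, cfg)
fluxcord:::.write_tsv(truth, file.path(outdir, "planted_truth.tsv"))

# NB count matrix
counts <- simulate_counts(gpr, truth, cfg)
write_counts(counts$counts, file.path(outdir, "counts.tsv"))
cat(sprintf("counts: %d transcripts x %d samples\n",
            nrow(counts$counts$counts), ncol(counts$counts$counts)))

# metabolite replicates: one single-compound pool per first 20 reactions,
# shifts planted for the pools linked to T-direction reactions among them
pools <- data.frame(pool_id = sprintf("P%03d", 1:20),
                    compound = sprintf("cmp%03d", 1:20),
                    reaction_id = sim$truth$reaction_id[1:20],
                    stringsAsFactors = FALSE)
shifted <- pools$pool_id[sim$truth$direction[1:20] == "T"]
metab <- simulate_metabolites(pools, cfg, shifted_pools = shifted, fold = 4)
fluxcord:::.write_tsv(pools, file.path(outdir, "pools.tsv"))
write_metabolites(metab, file.path(outdir, "metabolites.tsv"))
cat("simulated inputs written to", outdir, "\n")
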