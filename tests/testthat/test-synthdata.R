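test_that("scenario_config validates its invariants", {
  cfg <- scenario_config(seed = 1)
  expect_s3_class(cfg, "scenario_config")
  expect_error(scenario_config(concordance_fraction = 1.2),
               "concordance_fraction")
  expect_error(scenario_config(lipid_fraction_a = 0.7, starch_fraction_a = 0.5),
               "<= 1")
  expect_error(scenario_config(dispersion = -0.1))
  expect_error(scenario_config(n_reactions = 0))
})

test_that("make_model_pair: high-lipid variant raises TAG flux, B raises starch", {
  cfg <- scenario_config(seed = 1)
  pair <- make_model_pair(cfg)
  expect_gt(pair$objective_a, 0)
  expect_gt(pair$objective_b, 0)
  fa <- fva(pair$model_a, pair$ratio_constraints_a, accession = "A")
  fb <- fva(pair$model_b, pair$ratio_constraints_b, accession = "B")
  tag_a <- fa[fa$reaction_id == "TAGS_c", ]
  tag_b <- fb[fb$reaction_id == "TAGS_c", ]
  expect_gt(tag_a$vmin, tag_b$vmax + 1e-7)
  st_a <- fa[fa$reaction_id == "SS_p", ]
  st_b <- fb[fb$reaction_id == "SS_p", ]
  expect_gt(st_b$vmin, st_a$vmax + 1e-7)
  # at least one reaction responsive beyond tolerance
  calls <- classify_responsiveness(fa, fb)
  expect_true(any(calls$combined_call %in% c("T", "S")))
  # the MFA-style ratio constraint holds at the FBA optimum
  va <- fba(pair$model_a, pair$ratio_constraints_a)$fluxes
  expect_equal(unname(va["OPP_p"]), 0.25 * unname(va["GLYC_p"]),
               tolerance = 1e-8)
})

test_that("make_model_pair: identical compositions classify everything N", {
  cfg <- scenario_config(seed = 1, lipid_fraction_a = 0.3,
                         starch_fraction_a = 0.2, lipid_fraction_b = 0.3,
                         starch_fraction_b = 0.2)
  pair <- make_model_pair(cfg)
  fa <- fva(pair$model_a, pair$ratio_constraints_a)
  fb <- fva(pair$model_b, pair$ratio_constraints_a)  # same constraints too
  calls <- classify_responsiveness(fa, fb)
  expect_true(all(calls$combined_call == "N"))
})

test_that("make_model_pair: zero lipid demand zeroes the TAG pathway", {
  cfg <- scenario_config(seed = 1, lipid_fraction_a = 0, starch_fraction_a = 0.3,
                         lipid_fraction_b = 0, starch_fraction_b = 0.5)
  pair <- make_model_pair(cfg)
  for (mv in list(list(pair$model_a, pair$ratio_constraints_a),
                  list(pair$model_b, pair$ratio_constraints_b))) {
    fbnds <- fva(mv[[1]], mv[[2]])
    tag <- fbnds[fbnds$reaction_id %in% c("TAGS_c", "FAS_p", "FAX_pc"), ]
    expect_true(all(abs(tag$vmin) < 1e-7 & abs(tag$vmax) < 1e-7))
  }
})

test_that("an infeasible parameterization errors naming the blocking constraint", {
  cfg <- scenario_config(seed = 1)
  m <- toy_model()
  i <- match("EX_glc", reaction_ids(m))
  m$reactions[[i]]$upper_bound <- 0
  expect_error(make_model_pair(cfg, base_model = m), "EX_glc")
})

test_that("make_gpr hits the configured transcripts-per-gene mean", {
  cfg <- scenario_config(seed = 1, n_reactions = 500,
                         n_genes_per_reaction = c(2, 3))
  gpr <- make_gpr(cfg, sprintf("R%04d", 1:500))
  n_genes <- nrow(gpr$reaction_map)
  expect_gte(n_genes, 1000)
  with_tx <- setdiff(gpr$reaction_map$gene_id, gpr$missing_genes)
  realized <- nrow(gpr$transcript_map) / length(with_tx)
  expect_gte(realized, 4.2)
  expect_lte(realized, 5.2)
  # structural contracts
  expect_false(anyDuplicated(gpr$transcript_map$transcript_id) > 0)
  expect_true(all(gpr$transcript_map$gene_id %in% gpr$reaction_map$gene_id))
  # missing genes carry the X marker downstream: they have no transcripts
  expect_false(any(gpr$missing_genes %in% gpr$transcript_map$gene_id))
  expect_gt(length(gpr$missing_genes), 0)
})

test_that("one transcript per gene makes transcript->gene aggregation identity", {
  cfg <- scenario_config(seed = 3, n_reactions = 30,
                         transcripts_per_gene_mean = 1,
                         missing_gene_fraction = 0)
  gpr <- make_gpr(cfg, sprintf("R%04d", 1:30))
  expect_equal(nrow(gpr$transcript_map), length(unique(gpr$reaction_map$gene_id)))
  tcalls <- data.frame(transcript_id = gpr$transcript_map$transcript_id,
                       call = "T", mean_A = 10, mean_B = 1,
                       stringsAsFactors = FALSE)
  g <- aggregate_to_genes(tcalls, gpr)
  expect_true(all(g$call == "T"))
  expect_equal(nrow(g), nrow(tcalls))
})

test_that("plant_concordance uses exact quota assignment", {
  cfg <- scenario_config(seed = 1, n_reactions = 100)
  sim <- simulate_flux_bounds(cfg)
  gpr <- make_gpr(cfg, sim$truth$reaction_id)
  for (beta in c(0, 0.8, 1)) {
    truth <- plant_concordance(sim$truth, beta, gpr, cfg)
    per_rxn <- unique(truth[truth$flux_direction %in% c("T", "S"),
                            c("reaction_id", "congruent")])
    k <- nrow(per_rxn)
    expect_equal(sum(per_rxn$congruent), floor(beta * k))
    # genes of non-responsive reactions are planted N
    expect_true(all(truth$direction[!truth$flux_direction %in% c("T", "S")]
                    == "N"))
    # congruent genes point in the flux direction, discordant opposite
    resp <- truth[truth$flux_direction %in% c("T", "S"), ]
    expect_true(all(resp$direction[resp$congruent] ==
                      resp$flux_direction[resp$congruent]))
    disc <- resp[!resp$congruent, ]
    expect_true(all(disc$direction != disc$flux_direction))
  }
  expect_error(plant_concordance(sim$truth, 1.3, gpr, cfg), "\\[0, 1\\]")
})

test_that("simulate_flux_bounds plants the responsive quota", {
  cfg <- scenario_config(seed = 4, n_reactions = 200)
  sim <- simulate_flux_bounds(cfg)
  expect_equal(sum(sim$truth$direction %in% c("T", "S")),
               floor(0.8 * 200))
  calls <- classify_responsiveness(sim$bounds_a, sim$bounds_b)
  # the planted direction is recovered exactly by classification
  expect_identical(calls$combined_call, sim$truth$direction)
})

test_that("simulate_counts is seed-deterministic down to the written file", {
  cfg <- scenario_config(seed = 9, n_reactions = 20)
  sim <- simulate_flux_bounds(cfg)
  gpr <- make_gpr(cfg, sim$truth$reaction_id)
  truth <- plant_concordance(sim$truth, 0.8, gpr, cfg)
  one <- simulate_counts(gpr, truth, cfg)
  two <- simulate_counts(gpr, truth, cfg)
  expect_identical(one$counts$counts, two$counts$counts)
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_counts(one$counts, p1)
  write_counts(two$counts, p2)
  expect_identical(readLines(p1), readLines(p2))
  # and the TSV round-trips bit-exactly
  back <- read_counts(p1)
  expect_identical(back$counts, one$counts$counts)
  expect_identical(as.character(back$accession),
                   as.character(one$counts$accession))
})

test_that("alpha = 0 counts are Poisson: variance/mean ratio about 1", {
  cfg <- scenario_config(seed = 6, n_reactions = 200, dispersion = 0,
                         depth_spread = 0, effect_log2fc = 0,
                         n_replicates = 30)
  sim <- simulate_flux_bounds(cfg)
  gpr <- make_gpr(cfg, sim$truth$reaction_id)
  truth <- plant_concordance(sim$truth, 0.8, gpr, cfg)
  truth$effect_log2fc <- 0
  counts <- simulate_counts(gpr, truth, cfg)$counts$counts
  counts <- counts[seq_len(min(400, nrow(counts))), ]
  ratio <- apply(counts, 1, stats::var) / rowMeans(counts)
  expect_equal(mean(ratio), 1, tolerance = 0.05)
})

test_that("zero planted effect gives mean log2fc about 0", {
  cfg <- scenario_config(seed = 7, n_reactions = 50, effect_log2fc = 0)
  sim <- simulate_flux_bounds(cfg)
  gpr <- make_gpr(cfg, sim$truth$reaction_id)
  truth <- plant_concordance(sim$truth, 0.8, gpr, cfg)
  truth$effect_log2fc <- 0
  counts <- simulate_counts(gpr, truth, cfg)
  de <- de_test(counts$counts)
  expect_lt(abs(mean(de$log2fc)), 0.1)
  expect_error(simulate_counts(gpr, transform(truth, effect_log2fc = -1), cfg),
               "negative effect")
})

test_that("GPR tables round-trip through their TSV readers", {
  cfg <- scenario_config(seed = 8, n_reactions = 25)
  gpr <- make_gpr(cfg, sprintf("R%04d", 1:25))
  tp <- tempfile(fileext = ".tsv"); rp <- tempfile(fileext = ".tsv")
  write_gpr(gpr, tp, rp)
  back <- read_gpr(tp, rp)
  expect_identical(back$transcript_map, gpr$transcript_map)
  expect_identical(back$reaction_map, gpr$reaction_map)
})
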