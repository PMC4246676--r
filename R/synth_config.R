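#' Scenario configuration for the synthetic-data generators
#'
#' Bundles every knob of the simulated two-accession study design. Defaults
#' mirror the study conditions: 3 biological replicates per accession, a mean
#' of 4.7 transcripts per gene identifier (polyploid homeolog structure), a
#' high-lipid variant A (40% lipid / 10% starch) against a high-starch
#' variant B (25% / 25%), and a planted concordance fraction of 0.8 between
#' flux direction and transcript direction.
#'
#' @param seed integer RNG seed; every generator is a pure function of it.
#' @param n_reactions number of reactions for the scaled flux-bounds
#'   generator ([simulate_flux_bounds()]).
#' @param n_genes_per_reaction integer range (length 2) of genes per reaction.
#' @param transcripts_per_gene_mean mean of the transcripts-per-gene
#'   distribution (1 + Poisson(mean - 1)).
#' @param n_replicates biological replicates per accession.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2); 0 gives
#'   Poisson counts.
#' @param depth_spread sdlog of the log-normal per-sample sequencing-depth
#'   factors (normalized to geometric mean 1).
#' @param concordance_fraction fraction beta of flux-responsive reactions
#'   whose genes are planted differentially expressed in the congruent
#'   direction (quota assignment: exactly `floor(beta * K)` congruent).
#' @param effect_log2fc planted effect size (log2 fold change).
#' @param mean_count_range range of baseline transcript means (log-uniform).
#' @param responsive_fraction fraction of reactions given a planted flux
#'   response in [simulate_flux_bounds()].
#' @param missing_gene_fraction fraction of genes emitted without transcripts
#'   (the "(X)" situation: gene in the model, no transcript found).
#' @param lipid_fraction_a,starch_fraction_a,lipid_fraction_b,starch_fraction_b
#'   biomass composition of the two accession variants (fractions in \[0,1\],
#'   lipid + starch <= 1; the remainder is protein).
#' @param n_tech_replicates technical replicates per biological replicate in
#'   the metabolite generator.
#' @param metab_cv coefficient of variation of metabolite replicate noise
#'   (log-normal).
#' @return validated list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_reactions = 200L,
                            n_genes_per_reaction = c(1L, 3L),
                            transcripts_per_gene_mean = 4.7,
                            n_replicates = 3L,
                            dispersion = 0.05,
                            depth_spread = 0.15,
                            concordance_fraction = 0.8,
                            effect_log2fc = 2,
                            mean_count_range = c(20, 2000),
                            responsive_fraction = 0.8,
                            missing_gene_fraction = 0.02,
                            lipid_fraction_a = 0.40, starch_fraction_a = 0.10,
                            lipid_fraction_b = 0.25, starch_fraction_b = 0.25,
                            n_tech_replicates = 5L,
                            metab_cv = 0.1) {
  cfg <- list(seed = as.integer(seed), n_reactions = as.integer(n_reactions),
              n_genes_per_reaction = as.integer(n_genes_per_reaction),
              transcripts_per_gene_mean = transcripts_per_gene_mean,
              n_replicates = as.integer(n_replicates),
              dispersion = dispersion, depth_spread = depth_spread,
              concordance_fraction = concordance_fraction,
              effect_log2fc = effect_log2fc,
              mean_count_range = mean_count_range,
              responsive_fraction = responsive_fraction,
              missing_gene_fraction = missing_gene_fraction,
              lipid_fraction_a = lipid_fraction_a,
              starch_fraction_a = starch_fraction_a,
              lipid_fraction_b = lipid_fraction_b,
              starch_fraction_b = starch_fraction_b,
              n_tech_replicates = as.integer(n_tech_replicates),
              metab_cv = metab_cv)
  with(cfg, {
    stopifnot(n_reactions > 0, n_replicates > 0, n_tech_replicates > 0,
              length(n_genes_per_reaction) == 2,
              all(n_genes_per_reaction >= 1),
              n_genes_per_reaction[1] <= n_genes_per_reaction[2],
              transcripts_per_gene_mean >= 1,
              dispersion >= 0, depth_spread >= 0,
              concordance_fraction >= 0, concordance_fraction <= 1,
              effect_log2fc >= 0,
              responsive_fraction >= 0, responsive_fraction <= 1,
              missing_gene_fraction >= 0, missing_gene_fraction < 1,
              metab_cv >= 0)
  })
  for (comp in list(c(cfg$lipid_fraction_a, cfg$starch_fraction_a),
                    c(cfg$lipid_fraction_b, cfg$starch_fraction_b))) {
    if (any(comp < 0) || any(comp > 1) || sum(comp) > 1)
      stop("biomass compositions must lie in [0,1] with lipid + starch <= 1",
           call. = FALSE)
  }
  structure(cfg, class = "scenario_config")
}
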