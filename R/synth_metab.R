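#' Simulate replicate metabolite measurements with planted pool shifts
#'
#' Every compound gets a log-uniform baseline level; replicate values are
#' log-normal around it with the configured coefficient of variation, for
#' `n_replicates` biological x `n_tech_replicates` technical replicates per
#' accession. Pools named in `shifted_pools` have all their member compounds
#' multiplied by `fold` in accession A (`fold < 1` plants a B-upward shift).
#'
#' @param pools data.frame with `pool_id`, `compound` (and optionally
#'   `reaction_id` links, carried along untouched).
#' @param config a [scenario_config()].
#' @param shifted_pools character vector of pool ids given a planted shift.
#' @param fold multiplicative shift applied in accession A (default 4).
#' @return long data.frame: `compound`, `accession`, `bio_rep`, `tech_rep`,
#'   `value`.
#' @export
simulate_metabolites <- function(pools, config, shifted_pools = character(0),
                                 fold = 4) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + 505L)
  compounds <- unique(pools$compound)
  base <- stats::setNames(
    exp(stats::runif(length(compounds), log(1), log(100))), compounds)
  shifted <- unique(pools$compound[pools$pool_id %in% shifted_pools])
  sdlog <- sqrt(log(1 + config$metab_cv^2))
  grid <- expand.grid(compound = compounds,
                      accession = c("A", "B"),
                      bio_rep = seq_len(config$n_replicates),
                      tech_rep = seq_len(config$n_tech_replicates),
                      stringsAsFactors = FALSE)
  mu <- base[grid$compound] *
    ifelse(grid$compound %in% shifted & grid$accession == "A", fold, 1)
  grid$value <- mu * exp(stats::rnorm(nrow(grid), 0, sdlog))
  grid[order(grid$compound, grid$accession, grid$bio_rep, grid$tech_rep), ]
}
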