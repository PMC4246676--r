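#' Generate transcript-gene and gene-reaction association tables
#'
#' Each reaction receives a number of genes drawn uniformly from the
#' configured range (genes are reaction-specific, giving an unambiguous
#' planted truth); each gene receives `1 + Poisson(mean - 1)` transcripts,
#' matching the polyploid's many-transcripts-per-gene structure. A configured
#' fraction of genes is emitted with no transcripts at all (the "(X)" case:
#' the gene exists in the model but no transcript was found for it).
#'
#' @param config a [scenario_config()].
#' @param reaction_ids character vector of reaction ids to annotate.
#' @return GPR map: list with `transcript_map` (`transcript_id`, `gene_id`),
#'   `reaction_map` (`gene_id`, `reaction_id`), and `missing_genes`
#'   (genes present in `reaction_map` but absent from `transcript_map`).
#' @export
make_gpr <- function(config, reaction_ids) {
  stopifnot(inherits(config, "scenario_config"), length(reaction_ids) > 0)
  set.seed(config$seed + 202L)
  rng <- config$n_genes_per_reaction
  n_genes_per <- sample(rng[1]:rng[2], length(reaction_ids), replace = TRUE)
  n_genes <- sum(n_genes_per)
  # Arabidopsis-style identifiers: ATxGyyyyy
  gene_ids <- sprintf("AT%dG%05d", sample(1:5, n_genes, replace = TRUE),
                      sample.int(89999, n_genes))
  gene_ids <- make.unique(gene_ids, sep = "0")
  reaction_map <- data.frame(
    gene_id = gene_ids,
    reaction_id = rep(reaction_ids, n_genes_per),
    stringsAsFactors = FALSE)
  missing <- rep(FALSE, n_genes)
  if (config$missing_gene_fraction > 0)
    missing[sample.int(n_genes,
                       floor(config$missing_gene_fraction * n_genes))] <- TRUE
  n_tx_per <- ifelse(missing, 0L,
                     1L + stats::rpois(n_genes,
                                       config$transcripts_per_gene_mean - 1))
  transcript_map <- data.frame(
    transcript_id = sprintf("BnaT%06d", seq_len(sum(n_tx_per))),
    gene_id = rep(gene_ids, n_tx_per),
    stringsAsFactors = FALSE)
  validate_gpr(list(transcript_map = transcript_map,
                    reaction_map = reaction_map,
                    missing_genes = gene_ids[missing]))
}

#' Plant a concordance truth over flux-responsive reactions
#'
#' Quota assignment: among the K flux-responsive reactions (direction `T` or
#' `S`), exactly `floor(beta * K)` (a seeded sample) get all their genes
#' planted differentially expressed in the *congruent* direction (gene
#' direction = flux direction); the remainder get the opposite direction.
#' Genes of non-responsive reactions are planted `N`. Genes with no
#' transcripts keep their planted direction but contribute no counts.
#'
#' @param flux_calls data.frame with `reaction_id` and a direction column
#'   (`combined_call` from [classify_responsiveness()] or `direction` from
#'   [simulate_flux_bounds()] truth); `T`/`S` count as responsive.
#' @param beta concordance fraction in \[0, 1\].
#' @param gpr GPR map from [make_gpr()].
#' @param config a [scenario_config()] (seed and effect size).
#' @return data.frame with `gene_id`, `reaction_id`, `flux_direction`,
#'   `congruent` (logical, NA for N), `direction` (planted gene-level call),
#'   `effect_log2fc`.
#' @export
plant_concordance <- function(flux_calls, beta, gpr, config) {
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]", call. = FALSE)
  dir_col <- if ("combined_call" %in% names(flux_calls)) "combined_call"
             else "direction"
  set.seed(config$seed + 303L)
  fd <- stats::setNames(flux_calls[[dir_col]], flux_calls$reaction_id)
  rmap <- gpr$reaction_map
  flux_direction <- fd[rmap$reaction_id]
  resp_rxns <- flux_calls$reaction_id[fd[flux_calls$reaction_id] %in% c("T", "S")]
  k <- length(resp_rxns)
  congruent_rxns <- if (k > 0)
    resp_rxns[sample.int(k)][seq_len(floor(beta * k))] else character(0)
  congruent <- ifelse(flux_direction %in% c("T", "S"),
                      rmap$reaction_id %in% congruent_rxns, NA)
  flip <- c(T = "S", S = "T", N = "N", X = "N")
  direction <- ifelse(is.na(congruent) | !(flux_direction %in% c("T", "S")),
                      "N",
                      ifelse(congruent, flux_direction,
                             flip[flux_direction]))
  data.frame(gene_id = rmap$gene_id, reaction_id = rmap$reaction_id,
             flux_direction = unname(flux_direction), congruent = congruent,
             direction = unname(direction),
             effect_log2fc = ifelse(direction == "N", 0, config$effect_log2fc),
             stringsAsFactors = FALSE)
}

#' Simulate an NB count matrix with planted differential expression
#'
#' Per-transcript baseline means are log-uniform over the configured range;
#' per-sample depth factors are log-normal with the configured spread,
#' normalized to geometric mean 1. Counts are NB with
#' `variance = mu + alpha mu^2` (Poisson when `alpha = 0`), where the mean of
#' transcript i in sample j is `base_i * depth_j * 2^(+-effect/2)`: the
#' planted effect is split symmetrically, up in the accession the gene's
#' direction points to (`T` = higher in A). All transcripts of a gene share
#' the gene's planted direction. Identical seeds reproduce identical
#' matrices.
#'
#' @param gpr GPR map ([make_gpr()]).
#' @param truth planted truth ([plant_concordance()]), or any data.frame with
#'   `gene_id`, `direction`, `effect_log2fc`.
#' @param config a [scenario_config()].
#' @return list with `counts` (a `count_matrix`, accession levels `A`, `B`)
#'   and `truth` (per-transcript: `transcript_id`, `gene_id`, `direction`,
#'   `effect_log2fc`, `base_mean`).
#' @export
simulate_counts <- function(gpr, truth, config) {
  stopifnot(inherits(config, "scenario_config"))
  if (any(truth$effect_log2fc < 0))
    stop("negative effect size", call. = FALSE)
  if (config$depth_spread < 0) stop("negative depth spread", call. = FALSE)
  set.seed(config$seed + 404L)
  tm <- gpr$transcript_map
  g_idx <- match(tm$gene_id, truth$gene_id)
  direction <- truth$direction[g_idx]
  effect <- truth$effect_log2fc[g_idx]
  direction[is.na(direction)] <- "N"
  effect[is.na(effect)] <- 0
  n_tx <- nrow(tm)
  base <- exp(stats::runif(n_tx, log(config$mean_count_range[1]),
                           log(config$mean_count_range[2])))
  m <- config$n_replicates
  samples <- c(sprintf("A_%d", seq_len(m)), sprintf("B_%d", seq_len(m)))
  accession <- rep(c("A", "B"), each = m)
  depth <- exp(stats::rnorm(2 * m, 0, config$depth_spread))
  depth <- depth / exp(mean(log(depth)))
  shift <- ifelse(direction == "T", 1, ifelse(direction == "S", -1, 0))
  half <- 2^(shift * effect / 2)   # applied up in A, down in B
  mu <- outer(base, depth) *
    outer(half, ifelse(accession == "A", 1, -1), `^`)
  counts <- matrix(0L, n_tx, 2 * m, dimnames = list(tm$transcript_id, samples))
  if (config$dispersion == 0) {
    counts[] <- stats::rpois(length(mu), mu)
  } else {
    counts[] <- stats::rnbinom(length(mu), mu = mu,
                               size = 1 / config$dispersion)
  }
  list(counts = count_matrix(counts, accession),
       truth = data.frame(transcript_id = tm$transcript_id,
                          gene_id = tm$gene_id, direction = direction,
                          effect_log2fc = effect, base_mean = base,
                          stringsAsFactors = FALSE))
}
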