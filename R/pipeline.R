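#' Pipeline configuration
#'
#' Collects inputs and thresholds for a full run. Inputs may be given as
#' in-memory objects (as produced by the synthetic generators) or as paths to
#' the corresponding TSV/JSON files; paths are loaded by [run_pipeline()].
#'
#' @param bounds_a,bounds_b per-accession FVA bounds (`flux_bounds` or TSV
#'   path).
#' @param counts transcript counts (`count_matrix` or TSV path).
#' @param gpr GPR map (list, or character vector of the two TSV paths:
#'   transcript map, reaction map).
#' @param model optional `stoich_model` (or JSON path) used for the map
#'   export.
#' @param categories optional gene-category table (data.frame or TSV path)
#'   for the per-BIN tabulation.
#' @param metabolites,pools,links optional metabolite table, pool definitions
#'   and pool-to-reaction links (data.frames or TSV paths).
#' @param accessions the two accession labels, A first.
#' @param high_lipid which accession is the high-lipid direction anchor.
#' @param padj_threshold,fold_threshold,eps,p_threshold,metab_alpha analysis
#'   thresholds: adjusted-p and fold cutoffs for transcript calls, flux
#'   tolerance (umol/h), raw-p cutoff for congruence pairing, metabolite
#'   t-test level.
#' @param seed integer seed recorded in the run log.
#' @param outdir output directory for the report bundle.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(bounds_a, bounds_b, counts, gpr,
                            model = NULL, categories = NULL,
                            metabolites = NULL, pools = NULL, links = NULL,
                            accessions = c("A", "B"), high_lipid = accessions[1],
                            padj_threshold = 0.01, fold_threshold = 2,
                            eps = 1e-7, p_threshold = 0.01,
                            metab_alpha = 0.05, seed = 1L,
                            outdir = tempfile("fluxcord_run_")) {
  if (length(accessions) != 2)
    stop("exactly two accessions are required", call. = FALSE)
  if (!high_lipid %in% accessions)
    stop("high_lipid must be one of the accessions", call. = FALSE)
  for (th in c(padj_threshold, fold_threshold, eps, p_threshold, metab_alpha))
    if (!is.numeric(th) || th <= 0)
      stop("thresholds must be positive", call. = FALSE)
  structure(list(bounds_a = bounds_a, bounds_b = bounds_b, counts = counts,
                 gpr = gpr, model = model, categories = categories,
                 metabolites = metabolites, pools = pools, links = links,
                 accessions = accessions, high_lipid = high_lipid,
                 padj_threshold = padj_threshold,
                 fold_threshold = fold_threshold, eps = eps,
                 p_threshold = p_threshold, metab_alpha = metab_alpha,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

.load_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1 && !is.data.frame(x)) reader(x) else x
}

#' Study-design summary in the style of the published statistics table
#'
#' @param transcript_calls,gene_calls,reaction_calls call tables at the three
#'   levels.
#' @param responsiveness flux responsiveness calls
#'   ([classify_responsiveness()] output).
#' @return data.frame with `statistic`, `value`: transcript T/S counts,
#'   gene-level T/S counts with summed-expression agreement sub-counts, and
#'   reaction-level T/S counts with flux-direction-match sub-counts.
#' @export
concordance_statistics <- function(transcript_calls, gene_calls,
                                   reaction_calls, responsiveness) {
  cc <- summarize_concordance(reaction_calls, responsiveness)$summary
  data.frame(
    statistic = c(
      "transcripts_total", "genes_total", "transcripts_per_gene",
      "transcripts_T", "transcripts_S",
      "genes_T", "genes_T_sum_agrees", "genes_S", "genes_S_sum_agrees",
      "reactions_T", "reactions_T_flux_T",
      "reactions_S", "reactions_S_flux_S"),
    value = c(
      nrow(transcript_calls), nrow(gene_calls),
      round(nrow(transcript_calls) / nrow(gene_calls), 1),
      sum(transcript_calls$call == "T"), sum(transcript_calls$call == "S"),
      sum(gene_calls$call == "T"),
      sum(gene_calls$call == "T" & gene_calls$agreement %in% TRUE),
      sum(gene_calls$call == "S"),
      sum(gene_calls$call == "S" & gene_calls$agreement %in% TRUE),
      cc[["expr_T"]], cc[["expr_T_flux_T"]],
      cc[["expr_S"]], cc[["expr_S_flux_S"]]),
    stringsAsFactors = FALSE)
}

#' Run the full concordance pipeline
#'
#' Stages: flux responsiveness classification, differential expression and
#' transcript calls, transcript-to-gene-to-reaction aggregation,
#' flux-change-value and congruence scoring with the concordance summary,
#' optional category tabulation, optional metabolite pooling/testing/crosstab,
#' and the report bundle (TSVs, GML map when a model is supplied, a
#' statistics file, and a JSON run log). Identical config and seed give
#' byte-identical outputs. Any stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return list with all stage results (`responsiveness`, `de`,
#'   `transcript_calls`, `gene_calls`, `reaction_calls`, `fcv`, `congruence`,
#'   `concordance`, `statistics`, optional `categories_table`, `pool_tests`,
#'   `crosstab`) and `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(config$outdir, c(
    responsiveness = "responsiveness.tsv", de = "de_transcripts.tsv",
    genes = "gene_calls.tsv", reactions = "reaction_calls.tsv",
    fcv = "flux_change_values.tsv", congruence = "congruence.tsv",
    matched = "matched_reactions.tsv", stats = "statistics.tsv",
    categories = "category_counts.tsv", pools = "pool_tests.tsv",
    crosstab = "flux_metabolite_crosstab.tsv", map = "reaction_map.gml",
    log = "run_log.json"))
  names(out) <- c("responsiveness", "de", "genes", "reactions", "fcv",
                  "congruence", "matched", "stats", "categories", "pools",
                  "crosstab", "map", "log")

  bounds_a <- .load_input(config$bounds_a, read_flux_bounds)
  bounds_b <- .load_input(config$bounds_b, read_flux_bounds)
  cm <- .load_input(config$counts, read_counts)
  gpr <- if (is.character(config$gpr))
    read_gpr(config$gpr[1], config$gpr[2]) else validate_gpr(config$gpr)
  model <- if (is.character(config$model)) load_model(config$model)
           else config$model

  resp <- stage("responsiveness",
                classify_responsiveness(bounds_a, bounds_b, eps = config$eps))
  de <- stage("differential_expression",
              de_test(cm, high_lipid = config$high_lipid))
  tcalls <- stage("transcript_calls",
                  call_transcripts(de, config$padj_threshold,
                                   config$fold_threshold))
  gcalls <- stage("gene_aggregation", aggregate_to_genes(tcalls, gpr))
  rcalls <- stage("reaction_aggregation", aggregate_to_reactions(gcalls, gpr))
  fcv <- stage("flux_change_value",
               flux_change_value(bounds_a, bounds_b, eps = config$eps))
  cong <- stage("congruence",
                congruence_score(de, fcv, gpr, p_threshold = config$p_threshold))
  conc <- stage("concordance_summary", summarize_concordance(rcalls, resp))
  stats_tab <- stage("statistics",
                     concordance_statistics(tcalls, gcalls, rcalls, resp))

  .write_tsv(resp, out["responsiveness"])
  .write_tsv(tcalls, out["de"])
  .write_tsv(gcalls, out["genes"])
  .write_tsv(rcalls, out["reactions"])
  .write_tsv(fcv, out["fcv"])
  .write_tsv(cong, out["congruence"])
  .write_tsv(conc$matched_reactions, out["matched"])
  .write_tsv(stats_tab, out["stats"])

  res <- list(responsiveness = resp, de = de, transcript_calls = tcalls,
              gene_calls = gcalls, reaction_calls = rcalls, fcv = fcv,
              congruence = cong, concordance = conc, statistics = stats_tab,
              outdir = config$outdir)

  if (!is.null(config$categories)) {
    categories <- .load_input(config$categories, .read_tsv)
    res$categories_table <- stage("category_tabulation",
                                  tabulate_categories(gcalls, categories))
    .write_tsv(res$categories_table, out["categories"])
  }
  if (!is.null(model)) {
    stage("map_export", export_map(model, cong, fcv, out["map"]))
  }
  if (!is.null(config$metabolites)) {
    metab <- .load_input(config$metabolites, read_metabolites)
    pools <- .load_input(config$pools, .read_tsv)
    pooled <- stage("metabolite_pooling", pool_levels(metab, pools))
    a <- config$high_lipid
    b <- setdiff(config$accessions, a)
    res$pool_tests <- stage("metabolite_tests",
                            compare_pools(pooled, a, b,
                                          alpha = config$metab_alpha))
    .write_tsv(res$pool_tests, out["pools"])
    links <- if (!is.null(config$links)) .load_input(config$links, .read_tsv)
             else unique(pools[, c("pool_id", "reaction_id")])
    res$crosstab <- stage("flux_metabolite_crosstab",
                          crosstab_flux_metabolite(res$pool_tests, resp, links))
    .write_tsv(res$crosstab$table, out["crosstab"])
  }
  jsonlite::write_json(
    list(package = "fluxcord",
         version = as.character(utils::packageVersion("fluxcord")),
         seed = config$seed,
         thresholds = config[c("padj_threshold", "fold_threshold", "eps",
                               "p_threshold", "metab_alpha")],
         accessions = config$accessions, high_lipid = config$high_lipid),
    out["log"], auto_unbox = TRUE, pretty = TRUE)
  res
}
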