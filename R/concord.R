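#' Flux-change-value per reaction
#'
#' For each reaction, the slopes of the minimum and maximum flux between the
#' accessions are taken on absolute values (only net-flux changes are of
#' interest): `slope_min = |vmin_A| - |vmin_B|`, `slope_max = |vmax_A| -
#' |vmax_B|`; their mean is the flux-change-value. A positive value indicates
#' higher net flux in the high-lipid accession A. A reaction is flagged
#' responsive when `|flux_change_value| >= eps`.
#'
#' @param bounds_a,bounds_b `flux_bounds` for accessions A (high lipid) and B.
#' @param eps responsiveness threshold in umol/h (default 1e-7).
#' @return data.frame with `reaction_id`, `slope_min`, `slope_max`,
#'   `flux_change_value`, `responsive`.
#' @export
flux_change_value <- function(bounds_a, bounds_b, eps = 1e-7) {
  if (!setequal(bounds_a$reaction_id, bounds_b$reaction_id))
    stop("bound sets cover different reactions", call. = FALSE)
  b <- bounds_b[match(bounds_a$reaction_id, bounds_b$reaction_id), ]
  slope_min <- abs(bounds_a$vmin) - abs(b$vmin)
  slope_max <- abs(bounds_a$vmax) - abs(b$vmax)
  fcv <- (slope_min + slope_max) / 2
  data.frame(reaction_id = bounds_a$reaction_id,
             slope_min = slope_min, slope_max = slope_max,
             flux_change_value = fcv, responsive = abs(fcv) >= eps,
             stringsAsFactors = FALSE)
}

#' Congruence of transcript fold change with flux change
#'
#' Pairs significantly differential transcripts (raw `pvalue` below
#' `p_threshold`) with flux-responsive reactions via the GPR map
#' (transcript -> gene -> reaction) and scores each pair +1 when the signs of
#' the transcript log2 fold change and the reaction's flux-change-value
#' agree (both positive or both negative in A vs B), -1 otherwise. Pairs with
#' `log2fc` exactly 0 score -1 (congruence is defined only for co-signed
#' changes). Non-significant transcripts and non-responsive reactions are
#' not emitted.
#'
#' @param de differential-expression table ([de_test()] output).
#' @param fcv flux-change-value table ([flux_change_value()] output).
#' @param gpr GPR map (transcript and reaction tables).
#' @param p_threshold raw p-value cutoff for transcript selection
#'   (default 0.01).
#' @return data.frame with `reaction_id`, `transcript_id`, `log2fc`,
#'   `flux_change_value`, `congruence` (+1 / -1).
#' @export
congruence_score <- function(de, fcv, gpr, p_threshold = 0.01) {
  sig <- de[!is.na(de$pvalue) & de$pvalue < p_threshold, ]
  resp <- fcv[fcv$responsive, ]
  tm <- gpr$transcript_map
  rm_ <- gpr$reaction_map
  sig$gene_id <- tm$gene_id[match(sig$transcript_id, tm$transcript_id)]
  sig <- sig[!is.na(sig$gene_id), ]
  pairs <- merge(merge(sig[, c("transcript_id", "gene_id", "log2fc")],
                       rm_, by = "gene_id"),
                 resp[, c("reaction_id", "flux_change_value")],
                 by = "reaction_id")
  if (nrow(pairs) == 0)
    return(data.frame(reaction_id = character(0), transcript_id = character(0),
                      log2fc = numeric(0), flux_change_value = numeric(0),
                      congruence = integer(0)))
  congruence <- ifelse(
    sign(pairs$log2fc) == sign(pairs$flux_change_value) & pairs$log2fc != 0,
    1L, -1L)
  out <- data.frame(reaction_id = pairs$reaction_id,
                    transcript_id = pairs$transcript_id,
                    log2fc = pairs$log2fc,
                    flux_change_value = pairs$flux_change_value,
                    congruence = congruence, stringsAsFactors = FALSE)
  out[order(out$reaction_id, out$transcript_id), ]
}

#' Concordance summary of reaction-level expression calls vs flux calls
#'
#' Cross-tabulates reaction-level expression calls (from the stringent
#' aggregation) with flux responsiveness calls, counting reactions whose
#' directions match: expression `T` with flux `T`, and expression `S` with
#' flux `S` (the flux call being the combined one with `N` bounds ignored).
#'
#' @param reaction_calls data.frame with `reaction_id`, `call` (expression
#'   side, `{T, S, N, X}`).
#' @param responsiveness data.frame with `reaction_id`, `combined_call` (flux
#'   side, from [classify_responsiveness()]).
#' @return list with `summary` (named counts: `expr_T`, `expr_T_flux_T`,
#'   `expr_S`, `expr_S_flux_S`, `matched`) and `matched_reactions` (data.frame
#'   of the direction-matched reactions with both calls).
#' @export
summarize_concordance <- function(reaction_calls, responsiveness) {
  m <- merge(reaction_calls, responsiveness[, c("reaction_id", "combined_call")],
             by = "reaction_id")
  expr_t <- m$call == "T"
  expr_s <- m$call == "S"
  match_t <- expr_t & m$combined_call == "T"
  match_s <- expr_s & m$combined_call == "S"
  matched <- m[match_t | match_s, c("reaction_id", "call", "combined_call")]
  names(matched) <- c("reaction_id", "expression_call", "flux_call")
  list(summary = c(expr_T = sum(expr_t), expr_T_flux_T = sum(match_t),
                   expr_S = sum(expr_s), expr_S_flux_S = sum(match_s),
                   matched = sum(match_t | match_s)),
       matched_reactions = matched[order(matched$reaction_id), ])
}

#' Export a pathway/compartment-grouped reaction map as GML
#'
#' Writes one node per model reaction, keyed by the reaction id, with
#' `compartment` and `pathway` grouping attributes (nesting: compartment ->
#' pathway -> reaction), a comma-joined list of the per-transcript +/-1
#' congruence values mapped to the reaction, and a `fluxdir` frame attribute
#' encoding the direction of the flux change in the high-lipid accession
#' (+1 increase, -1 decrease, 0 unchanged). Edges connect reactions sharing a
#' metabolite (substrate-product adjacency) so the file renders as a
#' connected map.
#'
#' @param model a `stoich_model`.
#' @param congruence [congruence_score()] output (may be empty).
#' @param fcv [flux_change_value()] output.
#' @param path output GML path.
#' @return `path`, invisibly.
#' @export
export_map <- function(model, congruence, fcv, path) {
  rids <- reaction_ids(model)
  pathway <- vapply(model$reactions, function(r) r$pathway, character(1))
  compartment <- vapply(model$reactions, function(r) r$compartment, character(1))
  cong <- vapply(rids, function(rid) {
    v <- congruence$congruence[congruence$reaction_id == rid]
    if (length(v) == 0) "" else paste(v, collapse = ",")
  }, character(1))
  fdir <- rep(0, length(rids))
  idx <- match(fcv$reaction_id, rids)
  fdir[idx[!is.na(idx)]] <-
    ifelse(fcv$responsive, sign(fcv$flux_change_value), 0)[!is.na(idx)]
  S <- stoich_matrix(model)
  adj <- crossprod(S != 0) > 0
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  g <- igraph::set_vertex_attr(g, "pathway", value = pathway)
  g <- igraph::set_vertex_attr(g, "compartment", value = compartment)
  g <- igraph::set_vertex_attr(g, "congruence", value = cong)
  g <- igraph::set_vertex_attr(g, "fluxdir", value = fdir)
  igraph::write_graph(g, path, format = "gml")
  invisible(path)
}

#' Read back an exported reaction map
#' @param path GML path written by [export_map()].
#' @return igraph graph with the node attributes intact; the `congruence`
#'   attribute can be split on "," to recover the per-transcript values.
#' @export
read_map <- function(path) igraph::read_graph(path, format = "gml")
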