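# Curated reference tables from the two-accession oilseed rape embryo study
# (accessions 3170, high lipid, vs 3231, high starch), shipped as plain TSV
# under inst/extdata. They serve as in-package worked examples: the printed
# per-reaction call strings and flux-bound responsiveness labels, the
# dataset-level call statistics, and the per-category (MapMan BIN) call
# counts.

#' Load the matched-reaction reference table
#'
#' 27 reactions of the oilseed rape central-metabolism model for which the
#' change in gene expression correlates with the flux difference between the
#' contrasting accessions. Columns: `reaction_index`, `abbreviation`, `name`,
#' `bound_responsiveness` (lower;upper flux-bound labels, e.g. `"N;S"`), and
#' `call_string` (per-gene transcript calls in the parenthesis dialect).
#' The loader derives `lower_call`, `upper_call`, `flux_call` (combined, `N`
#' bounds ignored) and `expression_call` (stringent aggregation of the call
#' string) with the package's own operations.
#'
#' @param path TSV path (defaults to the shipped fixture).
#' @return data.frame with the raw and derived columns.
#' @export
reference_matched_reactions <- function(path = system.file(
    "extdata", "bnapus_matched_reactions.tsv", package = "fluxcord",
    mustWork = TRUE)) {
  tab <- .read_tsv(path, colClasses = "character")
  bounds <- strsplit(tab$bound_responsiveness, ";", fixed = TRUE)
  tab$lower_call <- vapply(bounds, `[`, "", 1)
  tab$upper_call <- vapply(bounds, `[`, "", 2)
  tab$flux_call <- combine_bound_calls(tab$lower_call, tab$upper_call)
  tab$expression_call <- vapply(tab$call_string, call_string_reaction_call, "",
                                USE.NAMES = FALSE)
  tab
}

#' Load the dataset-level call statistics reference table
#'
#' Printed transcript/gene/reaction bookkeeping of the study: annotated
#' transcript and gene-identifier totals, T/S transcript call counts,
#' gene-level aggregated counts with summed-expression agreement, and
#' reaction-level counts with flux-direction matches.
#'
#' @param path TSV path (defaults to the shipped fixture).
#' @return data.frame with `statistic`, `value`.
#' @export
reference_call_summary <- function(path = system.file(
    "extdata", "bnapus_call_summary.tsv", package = "fluxcord",
    mustWork = TRUE)) {
  .read_tsv(path)
}

#' Load the per-category (BIN) call-count reference table
#'
#' Printed per-functional-category counts of gene-level `S` and `T` calls.
#' Columns: `bin_code`, `n_S`, `n_T`, `bin_name`.
#'
#' @param path TSV path (defaults to the shipped fixture).
#' @return data.frame.
#' @export
reference_bin_counts <- function(path = system.file(
    "extdata", "bnapus_bin_counts.tsv", package = "fluxcord",
    mustWork = TRUE)) {
  .read_tsv(path)
}
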