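#' Stringent combination of T/S/N/X calls
#'
#' The study's most-stringent aggregation rule, applied identically at
#' transcript-to-gene and gene-to-reaction level: `N` (not significant) and
#' `X` (no transcripts found) are neutral and ignored; if the remaining calls
#' are all `T` the combination is `T`, all `S` gives `S`, and any mixture of
#' `T` with `S` is a conflict, combined to `N`. An empty (or all-neutral)
#' list combines to `N`.
#'
#' @param calls character vector over `{T, S, N, X}`.
#' @return single character, one of `T`, `S`, `N`.
#' @export
combine_calls <- function(calls) {
  if (length(calls) == 0) stop("empty call list", call. = FALSE)
  bad <- setdiff(calls, c("T", "S", "N", "X"))
  if (length(bad))
    stop("unknown call symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  eff <- unique(setdiff(calls, c("N", "X")))
  if (length(eff) == 0) "N" else if (length(eff) == 1) eff else "N"
}

#' Parse a per-gene call string
#'
#' Dialect used in the study's matched-reaction table: one parenthesis group
#' per associated gene, each group a run of per-transcript calls from
#' `{T, S}`; `()` is a gene with no significant transcripts and `(X)` a gene
#' for which no transcripts were found.
#'
#' @param text a call string like `"()(TT)(X)(S)"`.
#' @return list with one element per gene: a character vector of transcript
#'   calls (possibly empty), or the string `"X"` for a missing gene.
#' @export
parse_call_string <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  chars <- strsplit(text, "")[[1]]
  groups <- list()
  cur <- NULL
  open <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      if (open) stop("nested '(' at position ", i, call. = FALSE)
      open <- TRUE; cur <- character(0)
    } else if (ch == ")") {
      if (!open) stop("unmatched ')' at position ", i, call. = FALSE)
      open <- FALSE
      groups[[length(groups) + 1]] <-
        if (identical(cur, "X")) "X" else cur
    } else if (ch %in% c("T", "S", "X")) {
      if (!open) stop("call symbol outside parentheses at position ", i,
                      call. = FALSE)
      if (ch == "X" && length(cur) > 0)
        stop("'X' must stand alone in its group (position ", i, ")",
             call. = FALSE)
      cur <- c(cur, ch)
    } else {
      stop("invalid character '", ch, "' at position ", i, call. = FALSE)
    }
  }
  if (open) stop("unbalanced '(' at end of string", call. = FALSE)
  groups
}

#' Reaction-level call implied by a call string
#'
#' Combines the per-transcript calls within each gene group, then the gene
#' calls across genes, with the stringent rule at both levels; `(X)` groups
#' stay neutral. A string whose groups are all `(X)` yields `X` (no
#' expression information at all).
#'
#' @param text a call string (see [parse_call_string()]).
#' @return single character over `{T, S, N, X}`.
#' @export
call_string_reaction_call <- function(text) {
  groups <- parse_call_string(text)
  gene_calls <- vapply(groups, function(g) {
    if (identical(g, "X")) "X"
    else if (length(g) == 0) "N"
    else combine_calls(g)
  }, character(1))
  if (length(gene_calls) == 0) "X" else {
    if (all(gene_calls == "X")) "X" else combine_calls(gene_calls)
  }
}

#' Aggregate transcript calls to gene level
#'
#' Gene call = stringent combination of the member transcripts' calls; the
#' gene's normalized counts are summed per accession, and an `agreement` flag
#' records whether the call direction matches which accession's summed
#' expression is strictly larger (ties count as disagreement).
#'
#' @param transcript_calls data.frame with `transcript_id`, `call` and the
#'   normalized per-accession means `mean_A`, `mean_B` (as from
#'   [call_transcripts()]).
#' @param gpr GPR map (list with `transcript_map`); transcripts absent from
#'   the map are excluded with a warning.
#' @return data.frame with `gene_id`, `call`, `sum_A`, `sum_B`, `agreement`
#'   (NA for `N` calls).
#' @export
aggregate_to_genes <- function(transcript_calls, gpr) {
  tm <- gpr$transcript_map
  idx <- match(transcript_calls$transcript_id, tm$transcript_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " transcript(s) without gene mapping excluded")
    transcript_calls <- transcript_calls[!is.na(idx), ]
    idx <- idx[!is.na(idx)]
  }
  gene <- tm$gene_id[idx]
  split_rows <- split(seq_len(nrow(transcript_calls)), gene)
  out <- do.call(rbind, lapply(names(split_rows), function(g) {
    rows <- split_rows[[g]]
    call <- combine_calls(transcript_calls$call[rows])
    sum_a <- sum(transcript_calls$mean_A[rows])
    sum_b <- sum(transcript_calls$mean_B[rows])
    agree <- if (call == "T") sum_a > sum_b else if (call == "S") sum_b > sum_a
             else NA
    data.frame(gene_id = g, call = call, sum_A = sum_a, sum_B = sum_b,
               agreement = agree, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate gene calls to reaction level
#'
#' Reaction call = stringent combination of the associated genes' calls
#' (conflicting gene calls are non-significant at the reaction level).
#' Reactions whose genes were all absent from the expression data, or that
#' have no associated genes, are marked `X`.
#'
#' @param gene_calls data.frame with `gene_id`, `call` (gene-level `X`
#'   allowed for genes with no transcripts found).
#' @param gpr GPR map (list with `reaction_map`).
#' @return data.frame with `reaction_id`, `call` over `{T, S, N, X}`.
#' @export
aggregate_to_reactions <- function(gene_calls, gpr) {
  rm_ <- gpr$reaction_map
  calls <- stats::setNames(gene_calls$call, gene_calls$gene_id)
  out <- do.call(rbind, lapply(split(rm_$gene_id, rm_$reaction_id),
                               function(genes) {
    gc <- calls[genes]
    gc[is.na(gc)] <- "X"   # gene not found in expression data
    found <- gc[gc != "X"]
    data.frame(call = if (length(found) == 0) "X" else combine_calls(gc),
               stringsAsFactors = FALSE)
  }))
  data.frame(reaction_id = rownames(out), call = out$call,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tabulate gene-level calls by functional category
#'
#' Counts `S` and `T` gene calls per category BIN and reports the T/S ratio
#' (rounded to 2 decimals; `Inf` when a BIN has T calls but no S calls).
#' Genes missing from the category map fall into `"not assigned"`; BINs with
#' neither S nor T calls are omitted.
#'
#' @param gene_calls data.frame with `gene_id`, `call`.
#' @param categories data.frame with `gene_id`, `bin_code`, `bin_name`.
#' @return data.frame with `bin_code`, `bin_name`, `n_S`, `n_T`, `ratio`.
#' @export
tabulate_categories <- function(gene_calls, categories) {
  sig <- gene_calls[gene_calls$call %in% c("T", "S"), ]
  idx <- match(sig$gene_id, categories$gene_id)
  bin_code <- ifelse(is.na(idx), "NA", categories$bin_code[idx])
  bin_name <- ifelse(is.na(idx), "not assigned", categories$bin_name[idx])
  key <- paste(bin_code, bin_name, sep = "\r")
  tab <- table(key, factor(sig$call, levels = c("S", "T")))
  parts <- strsplit(rownames(tab), "\r", fixed = TRUE)
  out <- data.frame(
    bin_code = vapply(parts, `[`, "", 1),
    bin_name = vapply(parts, `[`, "", 2),
    n_S = as.integer(tab[, "S"]),
    n_T = as.integer(tab[, "T"]),
    stringsAsFactors = FALSE)
  out <- out[out$n_S + out$n_T > 0, ]
  out$ratio <- bin_ratio(out$n_T, out$n_S)
  out[order(-(out$n_S + out$n_T)), ]
}

#' T/S ratio as reported in category tables
#'
#' `n_T / n_S` rounded to 2 decimals, with `Inf` when `n_S` is 0 (and `n_T`
#' positive), matching the printed convention.
#'
#' @param n_t,n_s counts of T and S calls.
#' @return numeric vector.
#' @export
bin_ratio <- function(n_t, n_s) {
  ifelse(n_s == 0, ifelse(n_t > 0, Inf, NaN), round(n_t / n_s, 2))
}
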