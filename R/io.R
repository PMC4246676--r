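# Plain-text IO: UTF-8, tab-separated, '#' comment lines throughout.

.write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Construct a transcript x sample count matrix
#'
#' @param counts non-negative integer matrix, transcripts in rows (rownames =
#'   transcript ids), samples in columns (colnames = sample ids).
#' @param accession factor (or character) of length `ncol(counts)` with
#'   exactly two levels assigning each sample to an accession.
#' @return object of class `count_matrix`: list with `counts` and `accession`.
#' @export
count_matrix <- function(counts, accession) {
  counts <- as.matrix(counts)
  accession <- factor(accession)
  if (length(accession) != ncol(counts))
    stop("accession factor length must equal the number of samples", call. = FALSE)
  if (nlevels(accession) != 2)
    stop("exactly two accession levels are required, got ", nlevels(accession),
         call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(table(accession) < 2))
    stop("at least 2 samples per accession are required for testing", call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, accession = accession), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d transcripts x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: n=%d", levels(x$accession),
                            table(x$accession)), collapse = ", ")))
  invisible(x)
}

#' Read/write a count matrix as TSV
#'
#' Layout: a `# accession:` comment line mapping sample ids to accession
#' levels, then a header of sample ids with `transcript_id` as first column.
#' Round-trips bit-exactly through `read_counts()`.
#'
#' @param cm a `count_matrix`.
#' @param path file path.
#' @return `write_counts` returns `path` invisibly; `read_counts` a
#'   `count_matrix`.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(transcript_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path, comments = paste0(
    "accession: ",
    paste(colnames(cm$counts), as.character(cm$accession),
          sep = "=", collapse = " ")))
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  lines <- readLines(path, n = 50, encoding = "UTF-8")
  acc_line <- grep("^# accession:", lines, value = TRUE)
  if (length(acc_line) != 1)
    stop("counts TSV lacks the '# accession:' header line", call. = FALSE)
  pairs <- strsplit(strsplit(sub("^# accession: *", "", acc_line), " ")[[1]], "=")
  acc <- stats::setNames(vapply(pairs, `[`, "", 2), vapply(pairs, `[`, "", 1))
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$transcript_id
  count_matrix(m, acc[colnames(m)])
}

#' Read/write transcript-gene and gene-reaction association tables
#'
#' The GPR map is two tables: `transcript_map` (`transcript_id`, `gene_id`)
#' with each transcript mapping to exactly one gene, and `reaction_map`
#' (`gene_id`, `reaction_id`) where genes may serve multiple reactions
#' (any-gene-suffices semantics; no boolean AND/OR structure).
#'
#' @param gpr list with `transcript_map` and `reaction_map` data.frames.
#' @param transcript_path,reaction_path file paths for the two tables.
#' @return `write_gpr` returns invisibly; `read_gpr` returns the list form.
#' @export
write_gpr <- function(gpr, transcript_path, reaction_path) {
  .write_tsv(gpr$transcript_map, transcript_path)
  .write_tsv(gpr$reaction_map, reaction_path)
  invisible(list(transcript_path, reaction_path))
}

#' @rdname write_gpr
#' @export
read_gpr <- function(transcript_path, reaction_path) {
  tm <- .read_tsv(transcript_path, colClasses = "character")
  rm_ <- .read_tsv(reaction_path, colClasses = "character")
  validate_gpr(list(transcript_map = tm, reaction_map = rm_))
}

#' Validate a GPR map
#' @param gpr list with `transcript_map` and `reaction_map`.
#' @return the map, invisibly returned after checks.
#' @export
validate_gpr <- function(gpr) {
  tm <- gpr$transcript_map
  if (!all(c("transcript_id", "gene_id") %in% names(tm)))
    stop("transcript map needs columns transcript_id, gene_id", call. = FALSE)
  if (anyDuplicated(tm$transcript_id))
    stop("a transcript maps to more than one gene: ",
         paste(unique(tm$transcript_id[duplicated(tm$transcript_id)]),
               collapse = ", "), call. = FALSE)
  if (!all(c("gene_id", "reaction_id") %in% names(gpr$reaction_map)))
    stop("reaction map needs columns gene_id, reaction_id", call. = FALSE)
  gpr
}

#' Read/write replicate metabolite measurements
#'
#' Long layout: `compound`, `accession`, `bio_rep`, `tech_rep`, `value`
#' (concentration per g dry weight).
#'
#' @param tab data.frame in the layout above.
#' @param path file path.
#' @return `write_metabolites` returns `path` invisibly; `read_metabolites`
#'   the data.frame.
#' @export
write_metabolites <- function(tab, path) .write_tsv(tab, path)

#' @rdname write_metabolites
#' @export
read_metabolites <- function(path)
  .read_tsv(path, colClasses = c(compound = "character", accession = "character"))
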