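#' Classify flux responsiveness between two accessions
#'
#' Compares the FVA bounds of the high-lipid accession (A) against the
#' high-starch accession (B), bound-wise (lower with lower, upper with upper),
#' on flux magnitude (absolute value). A bound is called `T` (TAG responsive)
#' if its magnitude is larger in A by more than `eps`, `S` (starch responsive)
#' if larger in B, and `N` otherwise. The combined reaction call is `T` if the
#' non-`N` bound calls are all `T`, `S` if all `S`, `N` if both bounds are
#' `N`, and `X` when the two bounds disagree (one `T`, one `S`).
#'
#' Fluxes with magnitude below the LP feasibility tolerance (1e-9) are
#' snapped to zero before comparison.
#'
#' @param bounds_a,bounds_b `flux_bounds` data.frames (`reaction_id`, `vmin`,
#'   `vmax`) for accession A (high lipid) and B (high starch); must cover the
#'   same reactions.
#' @param eps numerical tolerance in umol/h for a difference to count as a
#'   change (default 1e-7).
#' @return data.frame with `reaction_id`, `lower_call`, `upper_call`,
#'   `combined_call` (factors over T/S/N and T/S/N/X).
#' @export
classify_responsiveness <- function(bounds_a, bounds_b, eps = 1e-7) {
  if (!setequal(bounds_a$reaction_id, bounds_b$reaction_id))
    stop("bound sets cover different reactions", call. = FALSE)
  b <- bounds_b[match(bounds_a$reaction_id, bounds_b$reaction_id), ]
  snap <- function(x) ifelse(abs(x) < .FEAS_TOL, 0, x)
  bound_call <- function(xa, xb) {
    xa <- abs(snap(xa)); xb <- abs(snap(xb))
    ifelse(xa > xb + eps, "T", ifelse(xb > xa + eps, "S", "N"))
  }
  lower <- bound_call(bounds_a$vmin, b$vmin)
  upper <- bound_call(bounds_a$vmax, b$vmax)
  data.frame(reaction_id = bounds_a$reaction_id,
             lower_call = lower, upper_call = upper,
             combined_call = combine_bound_calls(lower, upper),
             stringsAsFactors = FALSE)
}

#' Combine per-bound T/S/N calls into one reaction call
#'
#' Vectorized over pairs: `N` bounds are ignored; agreement gives `T` or `S`,
#' disagreement (`T` with `S`) gives `X`, two `N` give `N`.
#'
#' @param lower,upper character vectors over `{T, S, N}`.
#' @return character vector over `{T, S, N, X}`.
#' @export
combine_bound_calls <- function(lower, upper) {
  stopifnot(length(lower) == length(upper))
  out <- character(length(lower))
  for (i in seq_along(lower)) {
    s <- setdiff(c(lower[i], upper[i]), "N")
    out[i] <- if (length(s) == 0) "N" else if (length(unique(s)) == 1) s[1] else "X"
  }
  out
}

#' Read/write flux bounds as TSV
#'
#' Column layout: `reaction_id`, `accession`, `vmin`, `vmax`; tab-separated,
#' UTF-8, `#` comment lines.
#'
#' @param bounds a `flux_bounds` data.frame.
#' @param path file path.
#' @return `write_flux_bounds` returns `path` invisibly; `read_flux_bounds`
#'   returns a `flux_bounds` data.frame.
#' @export
write_flux_bounds <- function(bounds, path) {
  .write_tsv(bounds[, c("reaction_id", "accession", "vmin", "vmax")], path)
}

#' @rdname write_flux_bounds
#' @export
read_flux_bounds <- function(path) {
  out <- .read_tsv(path, colClasses = c(reaction_id = "character",
                                        accession = "character"))
  class(out) <- c("flux_bounds", "data.frame")
  out
}
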