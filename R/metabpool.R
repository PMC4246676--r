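#' Pool metabolite measurements to flux-level groups
#'
#' Where the flux analysis lumps several reactions into one flux value, the
#' member metabolites are pooled correspondingly: technical replicates are
#' averaged first (per compound, accession, biological replicate), and the
#' pool value per biological replicate is the sum of its members' means.
#' Pools with a member missing in either accession are flagged incomplete and
#' excluded from testing.
#'
#' @param metabolites long-format data.frame: `compound`, `accession`,
#'   `bio_rep`, `tech_rep`, `value`.
#' @param pools data.frame with `pool_id`, `compound`, and optionally
#'   `reaction_id` (link to a flux group).
#' @return data.frame with `pool_id`, `accession`, `bio_rep`, `value`,
#'   `complete`.
#' @export
pool_levels <- function(metabolites, pools) {
  stopifnot(all(c("compound", "accession", "bio_rep", "value") %in%
                  names(metabolites)))
  # average technical replicates
  bio <- stats::aggregate(value ~ compound + accession + bio_rep,
                          data = metabolites, FUN = mean)
  accs <- unique(bio$accession)
  out <- list()
  for (pid in unique(pools$pool_id)) {
    members <- pools$compound[pools$pool_id == pid]
    sub <- bio[bio$compound %in% members, ]
    complete <- all(vapply(accs, function(a)
      setequal(unique(sub$compound[sub$accession == a]), members), logical(1)))
    pooled <- stats::aggregate(value ~ accession + bio_rep, data = sub, FUN = sum)
    pooled$pool_id <- pid
    pooled$complete <- complete
    out[[pid]] <- pooled
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("pool_id", "accession", "bio_rep", "value", "complete")]
}

#' Compare pooled metabolite levels between accessions
#'
#' Welch two-sided t-test on biological-replicate pool values, one test per
#' pool, significant at `alpha` (no multiple-testing correction, matching the
#' per-compound asterisk convention). Zero variance on both sides with equal
#' means gives p = 1; incomplete pools are skipped.
#'
#' @param pooled [pool_levels()] output.
#' @param accession_a,accession_b the two accession labels (A = high lipid).
#' @param alpha significance level (default 0.05).
#' @return data.frame with `pool_id`, `mean_A`, `mean_B`, `pvalue`,
#'   `significant`, `direction` (`"A"`/`"B"`/`"none"`: which accession is
#'   higher, when significant).
#' @export
compare_pools <- function(pooled, accession_a, accession_b, alpha = 0.05) {
  out <- lapply(unique(pooled$pool_id), function(pid) {
    sub <- pooled[pooled$pool_id == pid, ]
    if (!all(sub$complete)) return(NULL)
    xa <- sub$value[sub$accession == accession_a]
    xb <- sub$value[sub$accession == accession_b]
    if (length(xa) < 2 || length(xb) < 2)
      stop("pool '", pid, "': need >= 2 biological replicates per accession",
           call. = FALSE)
    p <- if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      if (mean(xa) == mean(xb)) 1 else 0
    } else {
      stats::t.test(xa, xb, var.equal = FALSE)$p.value
    }
    sig <- p < alpha
    data.frame(pool_id = pid, mean_A = mean(xa), mean_B = mean(xb),
               pvalue = p, significant = sig,
               direction = if (!sig) "none" else
                 if (mean(xa) > mean(xb)) "A" else "B",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-tabulate metabolite shifts against flux changes
#'
#' Joins pool-level significance with flux responsiveness via the
#' pool-to-reaction links and reports, per linked pair, whether the flux
#' changed, whether the metabolite pool shifted, and the directions; the
#' headline statistic is the fraction of flux-changed reactions whose linked
#' pool also shifted significantly.
#'
#' @param pool_tests [compare_pools()] output.
#' @param responsiveness [classify_responsiveness()] output (`reaction_id`,
#'   `combined_call`).
#' @param links data.frame with `pool_id`, `reaction_id`.
#' @return list with `table` (per-pair records) and `fraction_shifted`
#'   (NA when no flux-changed reaction is linked).
#' @export
crosstab_flux_metabolite <- function(pool_tests, responsiveness, links) {
  m <- merge(links, pool_tests, by = "pool_id")
  m <- merge(m, responsiveness[, c("reaction_id", "combined_call")],
             by = "reaction_id")
  m$flux_changed <- m$combined_call %in% c("T", "S")
  m$flux_direction <- ifelse(m$combined_call == "T", "A",
                             ifelse(m$combined_call == "S", "B", "none"))
  tab <- m[, c("pool_id", "reaction_id", "flux_changed", "flux_direction",
               "significant", "direction", "pvalue")]
  names(tab)[names(tab) == "significant"] <- "metabolite_shifted"
  names(tab)[names(tab) == "direction"] <- "metabolite_direction"
  n_changed <- sum(tab$flux_changed)
  list(table = tab,
       fraction_shifted = if (n_changed == 0) NA_real_ else
         sum(tab$flux_changed & tab$metabolite_shifted) / n_changed)
}
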