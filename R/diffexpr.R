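#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: for each sample j,
#' \eqn{s_j = \mathrm{median}_i\, k_{ij} / (\prod_j k_{ij})^{1/m}}, the median
#' taken over transcripts with all-positive counts (the classical
#' median-of-ratios estimator for RNA-seq library size).
#'
#' @param counts non-negative integer matrix (transcripts x samples) or a
#'   `count_matrix`.
#' @param pseudo_reference if `TRUE`, fall back to transcripts whose geometric
#'   mean is positive (zeros allowed in some samples) when no all-positive
#'   transcript exists.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  kk <- counts
  log_geo <- rowMeans(log(kk))
  use <- is.finite(log_geo)
  if (!any(use)) {
    if (!pseudo_reference)
      stop("no transcript has all-positive counts; rerun with ",
           "pseudo_reference = TRUE to use a partial reference", call. = FALSE)
    kk[kk == 0] <- NA  # partial reference: geometric mean over positive counts
    log_geo <- rowMeans(log(kk), na.rm = TRUE)
    use <- is.finite(log_geo)
    if (!any(use)) stop("all-zero count matrix", call. = FALSE)
  }
  sf <- apply(kk[use, , drop = FALSE], 2, function(k)
    exp(stats::median(log(k) - log_geo[use], na.rm = TRUE)))
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor for sample(s): ",
         paste(colnames(counts)[!is.finite(sf) | sf <= 0], collapse = ", "),
         call. = FALSE)
  sf
}

#' Method-of-moments NB dispersion estimates with trend shrinkage
#'
#' Per transcript, the normalized counts are pooled within conditions: the
#' within-condition variance (shot noise subtracted) gives the raw
#' method-of-moments estimate \eqn{\alpha_{raw} = (w - z)/q^2} where \eqn{q}
#' is the base mean, \eqn{w} the pooled within-condition variance of
#' normalized counts and \eqn{z = q\,\overline{1/s_j}} the sampling-noise
#' term. A least-squares log-log trend of dispersion on mean is fitted to
#' binned means of the raw estimates (binning keeps the heavily skewed
#' per-transcript estimates from biasing the fit; negative raw values stay in
#' the bin means), and each transcript's dispersion is the 50/50 average of
#' its floored raw estimate and the trend value at its mean. Rows with zero
#' within-condition variance carry no dispersion evidence and sit at the
#' floor.
#'
#' @param cm a `count_matrix`.
#' @param sf size factors (defaults to `size_factors(cm)`).
#' @param min_disp dispersion floor (default 1e-8).
#' @param n_bins number of mean bins for the trend fit.
#' @return list with `alpha` (per-transcript shrunk dispersion), `alpha_raw`,
#'   `base_mean`, and `trend` (function of mean).
#' @export
estimate_dispersions <- function(cm, sf = size_factors(cm$counts),
                                 min_disp = 1e-8, n_bins = 20) {
  k <- cm$counts
  norm <- sweep(k, 2, sf, "/")
  q <- rowMeans(norm)
  cond <- cm$accession
  m <- ncol(k)
  ncond <- nlevels(cond)
  ss <- 0
  for (lv in levels(cond)) {
    sub <- norm[, cond == lv, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  w <- ss / (m - ncond)
  z <- q * mean(1 / sf)
  alpha_raw <- ifelse(q > 0, (w - z) / q^2, 0)
  use <- q > 0
  cf <- NULL
  if (sum(use) >= 50 && length(unique(q[use])) > n_bins) {
    bins <- cut(log(q[use]), breaks = n_bins)
    bin_alpha <- tapply(alpha_raw[use], bins, mean)
    bin_logq <- tapply(log(q[use]), bins, mean)
    okb <- !is.na(bin_alpha) & bin_alpha > 0
    if (sum(okb) >= 2)
      cf <- stats::lm.fit(cbind(1, bin_logq[okb]),
                          log(bin_alpha[okb]))$coefficients
  }
  if (is.null(cf)) {
    level <- mean(pmax(alpha_raw[use], 0))
    cf <- c(log(max(level, min_disp)), 0)
  }
  trend <- function(mu) pmax(exp(cf[1] + cf[2] * log(pmax(mu, 1e-8))), min_disp)
  alpha <- ifelse(w == 0, min_disp,
                  0.5 * pmax(alpha_raw, 0) + 0.5 * trend(q))
  alpha <- pmax(alpha, min_disp)
  list(alpha = alpha, alpha_raw = alpha_raw, base_mean = q, trend = trend)
}

# log NB density that degrades gracefully to Poisson as size -> Inf / alpha -> 0
.dnb_log <- function(x, mu, size) {
  if (!is.finite(size) || size > 1e12) stats::dpois(x, mu, log = TRUE)
  else stats::dnbinom(x, mu = mu, size = size, log = TRUE)
}

#' Conditioned exact negative-binomial test
#'
#' Two-sided exact test on the condition-summed counts: given the total
#' \eqn{s = k_A + k_B}, the p-value is the probability, conditional on the
#' total, of all splits \eqn{(a, s-a)} at most as likely as the observed one:
#' \deqn{p = \frac{\sum_{a: P(a)P(s-a) \le P(k_A)P(k_B)} P(a)P(s-a)}
#'            {\sum_{a=0}^{s} P(a)P(s-a)}}
#' with \eqn{P} the fitted NB densities of the two condition sums. The sum is
#' truncated where the conditional probability falls below \eqn{10^{-16}}
#' times its maximum (renormalized accordingly).
#'
#' @param k_a,k_b observed summed counts in the two conditions (non-negative
#'   integers).
#' @param mu_a,mu_b fitted means of the two condition sums.
#' @param size_a,size_b fitted NB size parameters (\eqn{1/\alpha}-scale);
#'   `Inf` gives the Poisson limit.
#' @return two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(k_a, k_b, mu_a, mu_b, size_a = Inf, size_b = Inf) {
  if (k_a != round(k_a) || k_b != round(k_b) || k_a < 0 || k_b < 0)
    stop("counts must be non-negative integers", call. = FALSE)
  s <- k_a + k_b
  if (s == 0) return(1)
  a <- 0:s
  lp <- .dnb_log(a, mu_a, size_a) + .dnb_log(s - a, mu_b, size_b)
  lp_max <- max(lp)
  keep <- lp > lp_max - 36.9  # ~1e-16 relative truncation
  lp_obs <- lp[k_a + 1]
  pr <- exp(lp[keep] - lp_max)
  num <- sum(pr[lp[keep] <= lp_obs + 1e-10])
  p <- num / sum(pr)
  min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control via `stats::p.adjust(method = "BH")`, with input
#' validation (NaN rejected).
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in \[0, 1\].
#' @export
adjust_bh <- function(pvalues) {
  if (any(is.nan(pvalues)))
    stop("NaN p-value in input", call. = FALSE)
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Differential expression between two accessions
#'
#' Runs the full testing stack on a count matrix: median-of-ratios size
#' factors, method-of-moments dispersions with trend shrinkage, the
#' conditioned exact NB test on condition-summed counts (means and variances
#' of the sums fitted under the null of a common normalized mean), and BH
#' adjustment. The fold-change convention is anchored on the high-lipid
#' accession: `log2fc > 0` means higher expression there.
#'
#' @param cm a `count_matrix`.
#' @param high_lipid the accession level treated as the high-lipid genotype
#'   (direction anchor, "A"); defaults to the first level.
#' @return data.frame with `transcript_id`, `mean_A`, `mean_B`, `log2fc`,
#'   `pvalue`, `padj`.
#' @export
de_test <- function(cm, high_lipid = levels(cm$accession)[1]) {
  stopifnot(high_lipid %in% levels(cm$accession))
  k <- cm$counts
  sf <- size_factors(k, pseudo_reference = TRUE)
  disp <- estimate_dispersions(cm, sf)
  in_a <- cm$accession == high_lipid
  if (sum(in_a) < 2 || sum(!in_a) < 2)
    stop("need >= 2 replicates per accession", call. = FALSE)
  norm <- sweep(k, 2, sf, "/")
  mean_a <- rowMeans(norm[, in_a, drop = FALSE])
  mean_b <- rowMeans(norm[, !in_a, drop = FALSE])
  q <- disp$base_mean
  alpha <- disp$alpha
  sA <- sum(sf[in_a]); sB <- sum(sf[!in_a])
  sA2 <- sum(sf[in_a]^2); sB2 <- sum(sf[!in_a]^2)
  kA <- rowSums(k[, in_a, drop = FALSE])
  kB <- rowSums(k[, !in_a, drop = FALSE])
  n <- nrow(k)
  p <- numeric(n)
  for (i in seq_len(n)) {
    if (kA[i] + kB[i] == 0) { p[i] <- 1; next }
    muA <- q[i] * sA; muB <- q[i] * sB
    varA <- muA + alpha[i] * q[i]^2 * sA2
    varB <- muB + alpha[i] * q[i]^2 * sB2
    szA <- if (varA > muA) muA^2 / (varA - muA) else Inf
    szB <- if (varB > muB) muB^2 / (varB - muB) else Inf
    p[i] <- nb_exact_test(kA[i], kB[i], muA, muB, szA, szB)
  }
  log2fc <- ifelse(mean_a == 0 & mean_b == 0, 0, log2(mean_a / mean_b))
  data.frame(transcript_id = rownames(k), mean_A = mean_a, mean_B = mean_b,
             log2fc = log2fc, pvalue = p, padj = adjust_bh(p),
             stringsAsFactors = FALSE)
}

#' T/S/N calls on transcripts
#'
#' Applies the study's significance definition: `T` if `padj` is below the
#' threshold and the high-lipid accession's normalized mean exceeds the
#' other's by more than the fold threshold, `S` for the symmetric case, `N`
#' otherwise.
#'
#' @param de result of [de_test()].
#' @param padj_threshold adjusted-p cutoff (default 0.01).
#' @param fold_threshold fold-change cutoff, strict (default 2, i.e. "more
#'   than 2-fold").
#' @return `de` with an added `call` column over `{T, S, N}`.
#' @export
call_transcripts <- function(de, padj_threshold = 0.01, fold_threshold = 2) {
  sig <- !is.na(de$padj) & de$padj < padj_threshold
  call <- ifelse(sig & de$mean_A > fold_threshold * de$mean_B, "T",
          ifelse(sig & de$mean_B > fold_threshold * de$mean_A, "S", "N"))
  de$call <- call
  de
}

#' Variance-stabilizing transformation (constant-dispersion closed form)
#'
#' \eqn{g(\mu) = (2/\sqrt{\alpha}) \,\mathrm{asinh}(\sqrt{\alpha \mu})
#'  = (2/\sqrt{\alpha}) \ln(\sqrt{\alpha\mu} + \sqrt{1 + \alpha\mu})}, the
#' transformation with derivative \eqn{1/\sqrt{\mu + \alpha\mu^2}} that
#' renders NB variance approximately constant; strictly increasing with
#' \eqn{g(0) = 0}. Used for reporting only, never for calls.
#'
#' @param mu normalized mean(s), non-negative.
#' @param alpha common dispersion, positive.
#' @return transformed values.
#' @export
vst <- function(mu, alpha) {
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (any(mu < 0)) stop("mu must be non-negative", call. = FALSE)
  (2 / sqrt(alpha)) * log(sqrt(alpha * mu) + sqrt(1 + alpha * mu))
}

#' Relative transcript abundance from qPCR Ct values (2^-ddCt)
#'
#' \eqn{2^{-((Ct_{target,t} - Ct_{ref,t}) - (Ct_{target,c} - Ct_{ref,c}))}}:
#' target-gene abundance in the treated condition relative to control, each
#' normalized to a reference (housekeeping) gene.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   cycle-threshold values (finite).
#' @return relative abundance (1 = no change).
#' @export
ddct <- function(ct_target_treated, ct_ref_treated,
                 ct_target_control, ct_ref_control) {
  vals <- c(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (any(!is.finite(vals))) stop("Ct values must be finite", call. = FALSE)
  ddct_val <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct_val)
}
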