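# Independent oracles, written from first principles (no shared code with the
# package's LP or testing layers).

# All vertices of {v : Aeq v = beq, lb <= v <= ub}, by exhaustive enumeration:
# fix (n - rank(Aeq)) variables at one of their bounds, solve the remaining
# square system, keep solutions that satisfy everything. Only for tiny models.
enumerate_vertices <- function(Aeq, beq, lb, ub, tol = 1e-8) {
  n <- length(lb)
  r <- qr(Aeq)$rank
  k <- n - r
  fix_sets <- if (k == 0) list(integer(0)) else
    utils::combn(n, k, simplify = FALSE)
  verts <- list()
  for (fixed in fix_sets) {
    free <- setdiff(seq_len(n), fixed)
    Af <- Aeq[, free, drop = FALSE]
    if (length(free) > 0 && qr(Af)$rank < length(free)) next
    grid <- if (length(fixed) == 0) matrix(0, nrow = 1, ncol = 0) else
      as.matrix(expand.grid(lapply(fixed, function(j) unique(c(lb[j], ub[j])))))
    for (g in seq_len(nrow(grid))) {
      v <- numeric(n)
      v[fixed] <- as.numeric(grid[g, ])
      rhs <- beq - if (length(fixed)) Aeq[, fixed, drop = FALSE] %*% v[fixed]
                   else 0
      v[free] <- if (length(free)) qr.solve(Af, rhs) else numeric(0)
      if (max(abs(Aeq %*% v - beq)) > tol) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      verts[[length(verts) + 1]] <- pmin(pmax(v, lb), ub)
    }
  }
  if (!length(verts)) return(matrix(numeric(0), ncol = n))
  V <- do.call(rbind, verts)
  V[!duplicated(round(V, 6)), , drop = FALSE]
}

# FVA by vertex enumeration: the optimal face of a bounded LP is spanned by
# polytope vertices, so per-reaction flux extrema over the optimal flux space
# are extrema over the optimal vertices.
fva_oracle <- function(model, ratio_constraints = NULL, tol = 1e-6) {
  S <- stoich_matrix(model)
  rc <- if (is.null(ratio_constraints)) model$flux_ratios else ratio_constraints
  if (!is.null(rc) && nrow(rc) > 0) {
    for (i in seq_len(nrow(rc))) {
      row <- stats::setNames(rep(0, ncol(S)), colnames(S))
      row[rc$numerator[i]] <- 1
      row[rc$denominator[i]] <- -rc$ratio[i]
      S <- rbind(S, row)
    }
  }
  bd <- model_bounds(model)
  V <- enumerate_vertices(S, rep(0, nrow(S)), bd$lower_bound, bd$upper_bound)
  stopifnot(nrow(V) > 0)
  i_obj <- match(model$objective, bd$reaction_id)
  opt <- max(V[, i_obj])
  Vopt <- V[V[, i_obj] >= opt - tol, , drop = FALSE]
  data.frame(reaction_id = bd$reaction_id,
             vmin = apply(Vopt, 2, min), vmax = apply(Vopt, 2, max),
             objective = opt, stringsAsFactors = FALSE)
}

# Conditioned binomial (Poisson-limit) exact test: given the total s, the
# count in condition A is Binomial(s, muA/(muA+muB)); two-sided p sums all
# outcomes no more probable than the observed one.
binom_exact_oracle <- function(k_a, s, mu_a, mu_b) {
  probs <- stats::dbinom(0:s, s, mu_a / (mu_a + mu_b))
  obs <- probs[k_a + 1]
  min(sum(probs[probs <= obs * (1 + 1e-8)]), 1)
}

# Direct full-range NB conditional summation (no truncation), for small sums.
nb_exact_oracle <- function(k_a, k_b, mu_a, mu_b, size_a, size_b) {
  s <- k_a + k_b
  a <- 0:s
  pr <- stats::dnbinom(a, mu = mu_a, size = size_a) *
    stats::dnbinom(s - a, mu = mu_b, size = size_b)
  obs <- pr[k_a + 1]
  sum(pr[pr <= obs * (1 + 1e-8)]) / sum(pr)
}
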