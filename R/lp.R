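# Linear programming layer for FBA/FVA.
#
# The solver is a dense two-phase primal simplex with Bland's anti-cycling
# rule, written for the small problem sizes of this package (tens of
# variables). Variables are shifted by their lower bounds to x = v - lb >= 0;
# upper bounds become explicit slack rows x + s = width. Bland's rule makes
# termination guaranteed, which matters more here than speed.

.BIG_BOUND <- 1e6   # stands in for infinite bounds; optima at this cap => unbounded
.FEAS_TOL <- 1e-9   # LP feasibility tolerance; |v| below it is snapped to 0 downstream

# One simplex run on an explicit tableau: min cost' x over the current basis.
# tab = [B^-1 A | B^-1 b]; basis indexes the columns currently basic.
.simplex_iterate <- function(tab, basis, cost, tol = 1e-9) {
  m <- nrow(tab)
  ncols <- ncol(tab) - 1L
  repeat {
    rc <- cost - as.numeric(crossprod(cost[basis], tab[, seq_len(ncols),
                                                       drop = FALSE]))
    entering <- which(rc < -tol)
    if (!length(entering))
      return(list(tab = tab, basis = basis, status = "optimal"))
    j <- min(entering)                       # Bland: smallest index enters
    col <- tab[, j]
    rows <- which(col > tol)
    if (!length(rows))
      return(list(tab = tab, basis = basis, status = "unbounded"))
    ratios <- tab[rows, ncols + 1L] / col[rows]
    rmin <- min(ratios)
    cand <- rows[ratios <= rmin + tol]
    i <- cand[which.min(basis[cand])]        # Bland: smallest basic index leaves
    tab[i, ] <- tab[i, ] / tab[i, j]
    other <- setdiff(seq_len(m), i)
    tab[other, ] <- tab[other, ] - outer(tab[other, j], tab[i, ])
    basis[i] <- j
  }
}

# min c'x subject to A x = b, x >= 0, with b >= 0 required.
# Returns list(status, x, objective).
.simplex_two_phase <- function(A, b, cvec, tol = 1e-9) {
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(all(b >= 0))
  # phase 1: artificial basis, minimize sum of artificials
  tab <- cbind(A, diag(m), b, deparse.level = 0)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  res <- .simplex_iterate(tab, basis, cost1, tol)
  # phase-1 objective is bounded below by 0, so "unbounded" cannot occur
  z1 <- sum(cost1[res$basis] * res$tab[, n + m + 1L])
  if (z1 > 1e-7) return(list(status = "infeasible"))
  tab <- res$tab
  basis <- res$basis
  # drive remaining (zero-level) artificials out of the basis
  drop_rows <- integer(0)
  for (i in which(basis > n)) {
    piv <- which(abs(tab[i, seq_len(n)]) > tol)
    if (!length(piv)) { drop_rows <- c(drop_rows, i); next }  # redundant row
    j <- piv[1]
    tab[i, ] <- tab[i, ] / tab[i, j]
    other <- setdiff(seq_len(nrow(tab)), i)
    tab[other, ] <- tab[other, ] - outer(tab[other, j], tab[i, ])
    basis[i] <- j
  }
  if (length(drop_rows)) {
    tab <- tab[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  tab <- tab[, c(seq_len(n), n + m + 1L), drop = FALSE]
  # phase 2
  res <- .simplex_iterate(tab, basis, cvec, tol)
  if (res$status == "unbounded") return(list(status = "unbounded"))
  x <- numeric(n)
  x[res$basis] <- res$tab[, n + 1L]
  list(status = "optimal", x = x, objective = sum(cvec * x))
}

# Solve max/min obj'v subject to Aeq v = beq, lb <= v <= ub.
# Returns list(status = "optimal"|"infeasible"|"unbounded", objective, fluxes).
.solve_lp <- function(obj, Aeq, beq, lb, ub, maximize = TRUE) {
  n <- length(obj)
  capped <- !is.finite(lb) | !is.finite(ub)
  lb2 <- pmax(lb, -.BIG_BOUND)
  ub2 <- pmin(ub, .BIG_BOUND)
  if (any(lb2 > ub2)) return(list(status = "infeasible"))
  width <- ub2 - lb2
  # shift x = v - lb2 >= 0; upper bounds as slack rows x_i + s_i = width_i
  b_eq <- as.numeric(beq - Aeq %*% lb2)
  A <- rbind(cbind(Aeq, matrix(0, nrow(Aeq), n)),
             cbind(diag(n), diag(n)))
  b <- c(b_eq, width)
  neg <- b < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg] }
  cvec <- c(if (maximize) -obj else obj, rep(0, n))
  sol <- .simplex_two_phase(A, b, cvec)
  if (sol$status != "optimal") return(list(status = sol$status))
  v <- sol$x[seq_len(n)] + lb2
  objective <- sum(obj * v)
  hit_cap <- any(capped & (abs(v + .BIG_BOUND) < 1e-6 | abs(v - .BIG_BOUND) < 1e-6) &
                   obj != 0)
  if (hit_cap) return(list(status = "unbounded"))
  list(status = "optimal", objective = objective,
       fluxes = stats::setNames(v, colnames(Aeq)))
}

# Equality system for a model: steady state S v = 0 plus one row per
# flux-ratio constraint (v_num - r * v_den = 0).
.equality_system <- function(model, ratio_constraints = NULL) {
  S <- stoich_matrix(model)
  beq <- rep(0, nrow(S))
  rc <- if (is.null(ratio_constraints)) model$flux_ratios else ratio_constraints
  if (!is.null(rc) && nrow(rc) > 0) {
    rids <- colnames(S)
    extra <- matrix(0, nrow(rc), ncol(S), dimnames = list(NULL, rids))
    for (i in seq_len(nrow(rc))) {
      if (!rc$numerator[i] %in% rids || !rc$denominator[i] %in% rids)
        stop("flux-ratio constraint references unknown reaction: ",
             rc$numerator[i], "/", rc$denominator[i], call. = FALSE)
      extra[i, rc$numerator[i]] <- 1
      extra[i, rc$denominator[i]] <- -rc$ratio[i]
    }
    S <- rbind(S, extra)
    beq <- c(beq, rep(0, nrow(rc)))
  }
  list(Aeq = S, beq = beq)
}

#' Flux balance analysis
#'
#' Maximizes the model's objective reaction flux subject to steady-state mass
#' balance (\eqn{S v = 0}), the reaction bounds, and any flux-ratio equality
#' constraints (\eqn{v_{num} - r\,v_{den} = 0}).
#'
#' @param model a `stoich_model`.
#' @param ratio_constraints optional data.frame (`numerator`, `denominator`,
#'   `ratio`) overriding the constraints stored in the model.
#' @return list with `objective_value` and `fluxes` (named flux vector at one
#'   optimum).
#' @export
fba <- function(model, ratio_constraints = NULL) {
  eq <- .equality_system(model, ratio_constraints)
  bd <- model_bounds(model)
  obj <- as.numeric(colnames(eq$Aeq) == model$objective)
  sol <- .solve_lp(obj, eq$Aeq, eq$beq, bd$lower_bound, bd$upper_bound,
                   maximize = TRUE)
  if (sol$status == "infeasible")
    stop("FBA problem is infeasible under the given bounds and ratio constraints",
         call. = FALSE)
  if (sol$status == "unbounded")
    stop("FBA problem is unbounded: the objective has no finite maximum",
         call. = FALSE)
  list(objective_value = sol$objective, fluxes = sol$fluxes)
}

#' Flux variability analysis
#'
#' For every reaction, minimizes and maximizes its flux with the objective
#' constrained to at least `optimality_fraction` times the FBA optimum
#' (default 1, i.e. the optimal flux space), yielding the interval
#' \eqn{[v_{min}, v_{max}]} per reaction.
#'
#' @inheritParams fba
#' @param optimality_fraction fraction of the FBA optimum the objective must
#'   retain while each flux is varied; 1 confines the space to optimality.
#' @param accession optional label recorded on the result (e.g. which genotype
#'   parameterization was solved).
#' @return a `flux_bounds` data.frame: `reaction_id`, `vmin`, `vmax`,
#'   `accession`, with attribute `objective_value`.
#' @export
fva <- function(model, ratio_constraints = NULL, optimality_fraction = 1.0,
                accession = NA_character_) {
  stopifnot(optimality_fraction > 0, optimality_fraction <= 1)
  opt <- fba(model, ratio_constraints)$objective_value
  eq <- .equality_system(model, ratio_constraints)
  bd <- model_bounds(model)
  # pin the objective via its lower bound: v_obj >= f * opt (exact and cheap)
  i_obj <- match(model$objective, bd$reaction_id)
  lb <- bd$lower_bound
  lb[i_obj] <- max(lb[i_obj], optimality_fraction * opt - .FEAS_TOL)
  rids <- bd$reaction_id
  vmin <- vmax <- numeric(length(rids))
  for (i in seq_along(rids)) {
    obj <- as.numeric(seq_along(rids) == i)
    for (dir in c(FALSE, TRUE)) {
      sol <- .solve_lp(obj, eq$Aeq, eq$beq, lb, bd$upper_bound, maximize = dir)
      if (sol$status != "optimal")
        stop(sprintf("FVA %s failed for reaction '%s': %s",
                     if (dir) "maximization" else "minimization",
                     rids[i], sol$status), call. = FALSE)
      if (dir) vmax[i] <- sol$objective else vmin[i] <- sol$objective
    }
  }
  # numerical cleanup: snap near-zero values, enforce ordering within tolerance
  vmin[abs(vmin) < .FEAS_TOL] <- 0
  vmax[abs(vmax) < .FEAS_TOL] <- 0
  if (any(vmin > vmax + 1e-6))
    stop("FVA produced vmin > vmax beyond tolerance for: ",
         paste(rids[vmin > vmax + 1e-6], collapse = ", "), call. = FALSE)
  swap <- vmin > vmax
  if (any(swap)) { m <- vmin[swap]; vmin[swap] <- vmax[swap]; vmax[swap] <- m }
  out <- data.frame(reaction_id = rids, vmin = vmin, vmax = vmax,
                    accession = accession, stringsAsFactors = FALSE)
  class(out) <- c("flux_bounds", "data.frame")
  attr(out, "objective_value") <- opt
  out
}
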