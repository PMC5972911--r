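# Flux balance analysis: LP formulation and solution, flux variability
# analysis, and an independent brute-force optimum for small networks.
#
# The LP is max/min c'v subject to S v = 0 and lb <= v <= ub, solved by
# the bounded-variable simplex in lp.R.  Infinite bounds are capped at
# BIG_BOUND; an optimum whose objective runs into such a cap is reported
# as status "unbounded", never as a number.

BIG_BOUND <- 1e6

# internal: solve max/min obj'v s.t. S v = 0, extra_ge %*% v >= extra_rhs,
# lb <= v <= ub.  Inequalities get one slack column each.
# Returns list(status, value, fluxes).
lp_flux <- function(S, lb, ub, obj, maximize = TRUE,
                    extra_ge = NULL, extra_rhs = NULL, tol = 1e-9) {
  n <- ncol(S)
  rxn_ids <- colnames(S)
  inf_lb <- is.infinite(lb)
  inf_ub <- is.infinite(ub)
  lb[inf_lb] <- -BIG_BOUND
  ub[inf_ub] <- BIG_BOUND

  A <- unname(S)
  b <- rep(0, nrow(S))
  lbx <- unname(lb)
  ubx <- unname(ub)
  objx <- unname(obj)
  if (!is.null(extra_ge)) {
    k <- nrow(extra_ge)
    # G v >= r  ->  G v - s = r, 0 <= s <= 2*BIG
    A <- rbind(cbind(A, matrix(0, nrow(A), k)),
               cbind(unname(extra_ge), -diag(k)))
    b <- c(b, extra_rhs)
    lbx <- c(lbx, rep(0, k))
    ubx <- c(ubx, rep(2 * BIG_BOUND, k))
    objx <- c(objx, rep(0, k))
  }
  res <- lp_bounded(A, b, lbx, ubx, objx, maximize = maximize, tol = tol)
  if (res$status == "infeasible") {
    return(list(status = "infeasible", value = NA_real_,
                fluxes = stats::setNames(rep(NA_real_, n), rxn_ids)))
  }
  v <- res$x[seq_len(n)]
  if (res$status == "unbounded") {
    return(list(status = "unbounded", value = NA_real_,
                fluxes = stats::setNames(v, rxn_ids)))
  }
  # an optimum pinned to a cap that replaced an infinite bound => unbounded
  at_cap <- (inf_ub & (v > BIG_BOUND * (1 - 1e-6))) |
    (inf_lb & (v < -BIG_BOUND * (1 - 1e-6)))
  if (any(at_cap & obj != 0)) {
    return(list(status = "unbounded", value = NA_real_,
                fluxes = stats::setNames(v, rxn_ids)))
  }
  list(status = "optimal", value = sum(obj * v),
       fluxes = stats::setNames(v, rxn_ids))
}

#' Solve the flux balance analysis LP
#'
#' Maximizes (or minimizes) the flux through one reaction subject to
#' steady state (`S v = 0` for every metabolite) and the model's flux
#' bounds, optionally with selected fluxes fixed.
#'
#' @param model A `stoich_model`.
#' @param objective Reaction id whose flux is optimized.
#' @param fixed_fluxes Named numeric vector; each named reaction's flux is
#'   fixed to the given value.  Values must lie within the reaction's
#'   declared bounds.
#' @param maximize Maximize (default) or minimize the objective.
#' @param tol Feasibility tolerance used when checking the returned
#'   solution.
#' @return An object of class `fba_solution`: list with `status`
#'   (`"optimal"`, `"infeasible"` or `"unbounded"`), `objective_value`,
#'   `fluxes` (named vector over all reactions), `objective`, and
#'   `residual` (largest steady-state violation).
#' @examples
#' chain <- generate_linear_chain(2)
#' sol <- solve_fba(chain, "EX_out", fixed_fluxes = c(EX_in = -10))
#' sol$objective_value
#' @export
solve_fba <- function(model, objective, fixed_fluxes = NULL,
                      maximize = TRUE, tol = 1e-9) {
  validate_model(model)
  if (!objective %in% model$reactions$id) {
    stop("unknown objective reaction: ", objective)
  }
  S <- stoich_matrix(model)
  b <- model_bounds(model)
  lb <- b$lb
  ub <- b$ub
  if (!is.null(fixed_fluxes)) {
    if (is.null(names(fixed_fluxes)) || any(!nzchar(names(fixed_fluxes)))) {
      stop("fixed_fluxes must be a named numeric vector of reaction ids")
    }
    unknown <- setdiff(names(fixed_fluxes), model$reactions$id)
    if (length(unknown)) {
      stop("fixed flux for unknown reaction: ", paste(unknown, collapse = ", "))
    }
    out <- fixed_fluxes < lb[names(fixed_fluxes)] - 1e-9 |
      fixed_fluxes > ub[names(fixed_fluxes)] + 1e-9
    if (any(out)) {
      stop("fixed flux outside declared bounds for reaction: ",
           paste(names(fixed_fluxes)[out], collapse = ", "))
    }
    lb[names(fixed_fluxes)] <- fixed_fluxes
    ub[names(fixed_fluxes)] <- fixed_fluxes
  }
  obj <- as.numeric(model$reactions$id == objective)
  res <- lp_flux(S, lb, ub, obj, maximize = maximize, tol = tol)
  residual <- NA_real_
  if (res$status == "optimal") {
    residual <- max(abs(S %*% res$fluxes))
    scale <- max(1, max(abs(res$fluxes)))
    if (residual > 1e-9 * scale * 100) {
      stop(sprintf("solver returned a solution violating steady state (residual %g)",
                   residual))
    }
  }
  structure(list(status = res$status, objective_value = res$value,
                 fluxes = res$fluxes, objective = objective,
                 residual = residual),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat(sprintf("<fba_solution> %s: status %s", x$objective, x$status))
  if (x$status == "optimal") {
    cat(sprintf(", objective %.6g (steady-state residual %.1e)",
                x$objective_value, x$residual))
  }
  cat("\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' For each requested reaction, computes the minimum and maximum flux
#' attainable while the objective flux is held at or above
#' `fraction * optimum`.  At `fraction = 1` the objective reaction's own
#' range collapses to the optimum; reactions whose range has positive
#' width carry alternate optima.
#'
#' @param model A `stoich_model`.
#' @param objective Reaction id of the FBA objective.
#' @param fraction Fraction of the optimum the objective must retain,
#'   in (0, 1].
#' @param reactions Reaction ids to scan (default: all).
#' @param fixed_fluxes Passed to [solve_fba()].
#' @return A data.frame of class `flux_range` with columns `reaction`,
#'   `min`, `max`.
#' @export
flux_variability <- function(model, objective, fraction = 1,
                             reactions = NULL, fixed_fluxes = NULL) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  base <- solve_fba(model, objective, fixed_fluxes = fixed_fluxes)
  if (base$status != "optimal") {
    stop("flux variability requires an optimal base problem; status: ",
         base$status)
  }
  if (is.null(reactions)) reactions <- model$reactions$id
  unknown <- setdiff(reactions, model$reactions$id)
  if (length(unknown)) {
    stop("unknown reaction: ", paste(unknown, collapse = ", "))
  }
  S <- stoich_matrix(model)
  b <- model_bounds(model)
  lb <- b$lb
  ub <- b$ub
  if (!is.null(fixed_fluxes)) {
    lb[names(fixed_fluxes)] <- fixed_fluxes
    ub[names(fixed_fluxes)] <- fixed_fluxes
  }
  c_obj <- matrix(as.numeric(model$reactions$id == objective), nrow = 1)
  rhs <- fraction * base$objective_value
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(reactions)) {
    e <- as.numeric(model$reactions$id == reactions[i])
    for (dir in c(FALSE, TRUE)) {
      r <- lp_flux(S, lb, ub, e, maximize = dir,
                   extra_ge = c_obj, extra_rhs = rhs)
      if (r$status == "unbounded") {
        val <- if (dir) Inf else -Inf
      } else if (r$status != "optimal") {
        stop("flux variability subproblem not optimal for reaction ",
             reactions[i], " (status ", r$status, ")")
      } else {
        val <- r$value
      }
      if (dir) out$max[i] <- val else out$min[i] <- val
    }
  }
  stopifnot(all(out$min <= out$max + 1e-6))
  class(out) <- c("flux_range", "data.frame")
  out
}

#' Brute-force maximum flux for small models
#'
#' Computes the maximum objective flux by exhaustive enumeration of the
#' vertices of the flux polytope `{v : S v = 0, lb <= v <= ub}`: every
#' choice of rank(S) basic reactions with the remaining fluxes pinned to a
#' bound is solved and feasibility-checked.  This is an independent check
#' on the simplex path, intended for fixture-sized networks only.
#'
#' @param model A `stoich_model` with all bounds finite and at most
#'   `max_reactions` reactions.
#' @param objective Reaction id to maximize.
#' @param max_reactions Size guard (default 14).
#' @return The maximum flux value (numeric scalar).
#' @export
oracle_max_flux <- function(model, objective, max_reactions = 14L) {
  validate_model(model)
  if (!objective %in% model$reactions$id) {
    stop("unknown objective reaction: ", objective)
  }
  S <- stoich_matrix(model)
  n <- ncol(S)
  if (n > max_reactions) {
    stop(sprintf("oracle_max_flux is for fixtures: model has %d reactions (limit %d)",
                 n, max_reactions))
  }
  b <- model_bounds(model)
  lb <- b$lb
  ub <- b$ub
  if (any(is.infinite(lb)) || any(is.infinite(ub))) {
    stop("oracle_max_flux requires finite bounds on every reaction")
  }
  r <- qr(S)$rank
  n_comb <- choose(n, r) * 2^(n - r)
  if (n_comb > 3e5) {
    stop("oracle_max_flux enumeration too large for this model")
  }
  obj_idx <- match(objective, colnames(S))
  tol <- 1e-7
  best <- -Inf

  eval_vertex <- function(v) {
    if (max(abs(S %*% v)) > tol) return(invisible(NULL))
    if (any(v < lb - tol) || any(v > ub + tol)) return(invisible(NULL))
    if (v[obj_idx] > best) best <<- v[obj_idx]
    invisible(NULL)
  }

  if (r == 0L) {
    # no coupling: optimum is the objective at its upper bound
    v <- ifelse(seq_len(n) == obj_idx, ub, pmax(lb, pmin(0, ub)))
    eval_vertex(v)
    return(best)
  }
  free_sets <- utils::combn(n, r, simplify = FALSE)
  for (F in free_sets) {
    SF <- S[, F, drop = FALSE]
    qF <- qr(SF)
    if (qF$rank < r) next
    N <- setdiff(seq_len(n), F)
    k <- length(N)
    # enumerate bound assignments for the non-basic variables
    varying <- N[ub[N] - lb[N] > tol]
    n_var <- length(varying)
    for (mask in 0:(2^n_var - 1)) {
      vN <- lb[N]
      if (n_var) {
        pick <- as.logical(bitwAnd(mask, 2^(seq_len(n_var) - 1)))
        vN[match(varying[pick], N)] <- ub[varying[pick]]
      }
      rhs <- if (k) -as.vector(S[, N, drop = FALSE] %*% vN) else
        numeric(nrow(S))
      vF <- qr.coef(qF, rhs)
      if (any(is.na(vF))) next
      v <- numeric(n)
      v[N] <- vN
      v[F] <- vF
      eval_vertex(v)
      if (n_var == 0L) break
    }
  }
  if (!is.finite(best)) stop("oracle found no feasible vertex (infeasible model)")
  unname(best)
}
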