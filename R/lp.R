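# Bounded-variable primal simplex.
#
# Solves   max/min  obj' x   s.t.  A x = b,  lb <= x <= ub
# by the two-phase simplex method for variables with upper and lower
# bounds.  Entering variables are chosen by the most-negative reduced cost
# with a switch to Bland's smallest-index rule after a degeneracy budget,
# which guarantees termination.  Redundant equality rows are harmless:
# their artificial variables simply stay basic at zero.
#
# This solver exists because flux-balance LPs are highly degenerate
# (conserved cofactor moieties make S rank-deficient and optima sit on
# many ties), and it is cross-checked against exhaustive vertex
# enumeration in the test suite.

#' Solve a bounded-variable linear program
#'
#' @param A Constraint matrix (m x n) of the equality system `A x = b`.
#' @param b Right-hand side, length m.
#' @param lb,ub Variable bounds, length n; must be finite with
#'   `lb <= ub`.
#' @param obj Objective coefficients, length n.
#' @param maximize Maximize (default) or minimize.
#' @param tol Reduced-cost and pivot tolerance.
#' @param max_iter Iteration cap per phase.
#' @return List with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `value` and `x`.
#' @keywords internal
lp_bounded <- function(A, b, lb, ub, obj, maximize = TRUE, tol = 1e-9,
                       max_iter = 50000L) {
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(b) == m, length(lb) == n, length(ub) == n,
            length(obj) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("lp_bounded requires finite bounds")
  }
  if (any(lb > ub)) {
    return(list(status = "infeasible", value = NA_real_,
                x = rep(NA_real_, n)))
  }
  cmin <- if (maximize) -obj else obj

  # start structural variables at the bound nearer zero
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  at_ub <- abs(lb) > abs(ub)
  r <- b - as.vector(A %*% x)
  esign <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(esign, nrow = m))
  x <- c(x, abs(r))
  at_ub <- c(at_ub, rep(FALSE, m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))
  basic <- n + seq_len(m)
  is_basic <- c(rep(FALSE, n), rep(TRUE, m))

  run_phase <- function(cost, enterable) {
    iter <- 0L
    degen_budget <- 5L * (n + m)
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) stop("simplex iteration limit reached")
      B <- Afull[, basic, drop = FALSE]
      # refresh basic values from the factorization to kill numeric drift
      x[basic] <<- tryCatch(
        solve(B, b - as.vector(Afull[, !is_basic, drop = FALSE] %*%
                                 x[!is_basic])),
        error = function(e) stop("singular simplex basis"))
      y <- solve(t(B), cost[basic])
      d <- cost - as.vector(crossprod(Afull, y))
      cand <- which(!is_basic & enterable &
                      ((!at_ub & d < -tol) | (at_ub & d > tol)))
      if (!length(cand)) {
        return(list(value = sum(cost * x), x = x))
      }
      j <- if (iter > degen_budget) min(cand) else
        cand[which.max(abs(d[cand]))]
      dir <- if (at_ub[j]) -1 else 1
      w <- solve(B, Afull[, j]) # x_basic changes by -dir*w per unit step
      delta <- -dir * w
      t_self <- ubf[j] - lbf[j]
      steps <- rep(Inf, m)
      dn <- delta < -tol
      up <- delta > tol
      steps[dn] <- (x[basic[dn]] - lbf[basic[dn]]) / (-delta[dn])
      steps[up] <- (ubf[basic[up]] - x[basic[up]]) / delta[up]
      tmax <- min(t_self, steps)
      if (!is.finite(tmax)) {
        return(list(unbounded = TRUE))
      }
      tmax <- max(tmax, 0)
      x[basic] <<- x[basic] + tmax * delta
      x[j] <<- x[j] + dir * tmax
      if (t_self <= min(steps)) {
        at_ub[j] <<- !at_ub[j] # bound flip, basis unchanged
      } else {
        hit <- which(abs(steps - tmax) <= tol * (1 + abs(tmax)))
        if (!length(hit)) hit <- which.min(steps)
        i_out <- hit[which.min(basic[hit])] # Bland tie-break
        leave <- basic[i_out]
        at_ub[leave] <<- delta[i_out] > 0
        x[leave] <<- if (at_ub[leave]) ubf[leave] else lbf[leave]
        is_basic[leave] <<- FALSE
        basic[i_out] <<- j
        is_basic[j] <<- TRUE
      }
    }
  }

  # phase 1: minimize the artificial mass
  c1 <- c(rep(0, n), rep(1, m))
  p1 <- run_phase(c1, enterable = rep(TRUE, n + m))
  if (isTRUE(p1$unbounded)) stop("phase-1 LP unbounded; this cannot happen")
  if (p1$value > 1e-7 * max(1, max(abs(b)))) {
    return(list(status = "infeasible", value = NA_real_,
                x = rep(NA_real_, n)))
  }
  # phase 2: artificials pinned to zero, structural cost
  ubf[n + seq_len(m)] <- 0
  x[n + seq_len(m)][!is_basic[n + seq_len(m)]] <- 0
  c2 <- c(cmin, rep(0, m))
  p2 <- run_phase(c2, enterable = c(rep(TRUE, n), rep(FALSE, m)))
  if (isTRUE(p2$unbounded)) {
    return(list(status = "unbounded", value = NA_real_,
                x = x[seq_len(n)]))
  }
  xs <- p2$x[seq_len(n)]
  value <- sum(obj * xs)
  list(status = "optimal", value = value, x = xs)
}
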