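# Branch-and-bound for mixed-integer LPs whose integer variables are binary
# indicator variables with a unit-cost objective (the flux-change
# minimization problems). Depth-first search, branching the fractional
# indicator to 0 first (the restrictive branch, which reaches integer
# leaves quickly), with integer-rounding of the relaxation bound for
# pruning: the objective is a count, so a node whose relaxation bound
# rounds up to >= the incumbent cannot improve.

#' Solve a binary-indicator MILP by branch and bound
#'
#' @param A,b,obj,lb,ub LP data as in [lp_solve()] (equality rows only;
#'   callers encode inequalities with slack columns).
#' @param int_idx column indices required to be binary (bounds must be
#'   within \[0, 1\]).
#' @param incumbent optional starting feasible solution: list with `x` and
#'   `obj` (its objective value).
#' @param node_limit maximum branch-and-bound nodes before giving up with a
#'   `crossfeedr_timeout` condition that carries the best proven bound.
#' @param int_tol integrality tolerance.
#' @return list with `x`, `obj` (proven optimal), `nodes`, `gap` (always 0
#'   on success).
#' @keywords internal
milp_solve <- function(A, b, obj, lb, ub, int_idx,
                       incumbent = NULL, node_limit = 200000L,
                       int_tol = 1e-6) {
  A <- as.matrix(A)
  n <- ncol(A)
  best_x <- NULL
  best_obj <- Inf
  if (!is.null(incumbent)) {
    best_x <- incumbent$x
    best_obj <- incumbent$obj
  }

  # stack of nodes; each node carries bound overrides for the binaries only
  stack <- list(list(lb = lb[int_idx], ub = ub[int_idx]))
  nodes <- 0L
  best_bound_open <- -Inf # largest lower bound among pruned-by-limit nodes

  while (length(stack) > 0L) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > node_limit) {
      cf_abort("crossfeedr_timeout",
               sprintf(
                 "branch-and-bound node limit (%d) reached; incumbent %s, best bound %s",
                 node_limit,
                 if (is.finite(best_obj)) format(best_obj) else "none",
                 format(min(best_obj, best_bound_open))),
               incumbent = best_obj, bound = best_bound_open)
    }

    lbk <- lb; ubk <- ub
    lbk[int_idx] <- node$lb
    ubk[int_idx] <- node$ub
    rel <- lp_solve(A, b, obj, lbk, ubk, sense = "min",
                    on_infeasible = "status")
    if (rel$status != 0L) next # infeasible subproblem
    bound <- ceiling(rel$obj - 1e-6)
    if (bound >= best_obj) next # cannot improve the incumbent

    fvals <- rel$x[int_idx]
    frac <- pmin(fvals - floor(fvals), ceiling(fvals) - fvals)
    frac[node$lb == node$ub] <- 0 # fixed binaries are integral by fiat
    if (max(frac) <= int_tol) {
      # integer-feasible leaf
      cand_obj <- round(sum(obj[int_idx] * round(fvals)) +
                          sum(obj[-int_idx] * rel$x[-int_idx]))
      if (cand_obj < best_obj) {
        best_obj <- cand_obj
        best_x <- rel$x
        best_x[int_idx] <- round(fvals)
      }
      next
    }
    j <- which.max(frac) # most fractional indicator
    up <- node; up$lb[j] <- 1
    dn <- node; dn$ub[j] <- 0
    # LIFO: push the f = 1 branch first so f = 0 is explored first
    stack[[length(stack) + 1L]] <- up
    stack[[length(stack) + 1L]] <- dn
  }

  if (!is.finite(best_obj)) {
    cf_abort("crossfeedr_infeasible",
             "mixed-integer program infeasible: no binary assignment admits a feasible flux distribution")
  }
  list(x = best_x, obj = best_obj, nodes = nodes, gap = 0)
}
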