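# Linear-programming layer over the compiled bounded-variable simplex.
#
# All flux problems in this package reduce to
#   min c'x   s.t.  A x = b,  lb <= x <= ub
# with finite bounds. Inequality rows are handled by the callers through
# explicit slack columns, so this layer stays a thin, predictable wrapper.

# largest magnitude admitted as a "finite" bound; model infinities are
# clamped here, far above any realistic flux (mmol gDW^-1 h^-1)
CF_BIG <- 1e6

cf_clamp_bounds <- function(lb, ub) {
  lb <- pmax(lb, -CF_BIG)
  ub <- pmin(ub, CF_BIG)
  list(lb = lb, ub = ub)
}

#' Solve a bounded linear program
#'
#' Minimizes (or maximizes) `obj %*% x` subject to `A x = b` and
#' `lb <= x <= ub`, using the package's dense two-phase simplex.
#'
#' @param A constraint matrix (dense or `Matrix`), one row per equality.
#' @param b right-hand side vector.
#' @param obj objective coefficient vector.
#' @param lb,ub variable bounds; infinities are clamped to `1e6`.
#' @param sense `"min"` or `"max"`.
#' @param on_infeasible `"error"` to raise a `crossfeedr_infeasible`
#'   condition, `"status"` to return the status code quietly (used by
#'   feasibility scans).
#' @return list with `x`, `obj`, `status` (0 optimal), and solver metadata.
#' @keywords internal
lp_solve <- function(A, b, obj, lb, ub, sense = c("min", "max"),
                     on_infeasible = c("error", "status"),
                     max_iter = 50000L) {
  sense <- match.arg(sense)
  on_infeasible <- match.arg(on_infeasible)
  A <- as.matrix(A)
  stopifnot(nrow(A) == length(b), ncol(A) == length(obj),
            length(lb) == ncol(A), length(ub) == ncol(A))
  bb <- cf_clamp_bounds(lb, ub)
  if (any(bb$lb > bb$ub + 1e-9)) {
    if (on_infeasible == "status") {
      return(list(status = 1L, x = NULL, obj = NA_real_))
    }
    bad <- which(bb$lb > bb$ub + 1e-9)
    cf_abort("crossfeedr_infeasible",
             sprintf("empty variable box (lb > ub) for %d column(s), first: %d",
                     length(bad), bad[1]),
             columns = bad)
  }
  cvec <- if (sense == "max") -obj else obj
  res <- .lp_simplex(A, b, cvec, bb$lb, bb$ub, as.integer(max_iter))
  res$obj <- if (sense == "max") -res$obj else res$obj
  if (res$status == 0L) {
    # a solution pinned to a clamped (originally infinite) bound is an
    # unbounded ray in the real problem
    hit <- c(which(lb < -CF_BIG & res$x <= -CF_BIG + 1e-3),
             which(ub > CF_BIG & res$x >= CF_BIG - 1e-3))
    if (length(hit) > 0) {
      cf_abort("crossfeedr_unbounded",
               sprintf("linear program unbounded; witness column %d", hit[1]),
               witness = hit[1])
    }
  }
  if (res$status == 1L && on_infeasible == "error") {
    cf_abort("crossfeedr_infeasible",
             sprintf("linear program infeasible (phase-1 residual %.3g)",
                     res$infeasibility),
             infeasibility = res$infeasibility)
  }
  if (res$status == 2L) {
    cf_abort("crossfeedr_unbounded",
             sprintf("linear program unbounded; witness column %d",
                     res$witness),
             witness = res$witness)
  }
  if (res$status >= 3L) {
    cf_abort("crossfeedr_solver_error",
             sprintf("simplex did not converge (status %d after %d iterations)",
                     res$status, res$iterations))
  }
  res
}
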