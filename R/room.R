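# Flux-change minimization: ROOM (regulatory on/off minimization) against a
# fixed reference distribution, and a heterogeneous-ancestor variant that
# finds the ancestral and the evolved distribution in one optimization.
#
# Both are mixed-integer linear programs with one binary indicator f_i per
# counted internal reaction; f_i = 1 iff reaction i changes flux by more
# than beta. Indicator coupling uses the two linear inequalities whose
# big-M terms are implicit in the flux bounds, so any MILP backend could
# solve them; here the package's own branch-and-bound does.

CF_SLACK_UB <- 1e7 # upper bound for inequality slack columns

#' Define a ROOM problem
#'
#' @param reference the ancestral [flux_distribution()] (or bare numeric
#'   vector in model reaction order).
#' @param evolved list with `lb`, `ub`: bounds (including any equalities as
#'   `lb == ub`) that the evolved strain must satisfy.
#' @param beta flux-change significance threshold, mmol gDW^-1 h^-1.
#' @param counted indices (or reaction ids) whose indicators enter the
#'   objective; defaults to all internal reactions.
#' @return list of class `room_problem`.
#' @export
room_problem <- function(reference, evolved, beta = 0.001, counted = NULL) {
  cf_assert(beta > 0, "crossfeedr_contract_error", "beta must be positive")
  structure(list(reference = reference, evolved = evolved, beta = beta,
                 counted = counted),
            class = "room_problem")
}

#' Define a heterogeneous-ancestor problem
#'
#' @param ancestor list with `lb`, `ub`: the ancestral population's
#'   constraint set (e.g. growth at the dilution rate, capped glucose).
#' @param evolved list with `lb`, `ub`: the evolved strain's constraints.
#' @param beta flux-change significance threshold, mmol gDW^-1 h^-1.
#' @param counted as in [room_problem()].
#' @return list of class `het_problem`.
#' @export
het_problem <- function(ancestor, evolved, beta = 0.001, counted = NULL) {
  cf_assert(beta > 0, "crossfeedr_contract_error", "beta must be positive")
  structure(list(ancestor = ancestor, evolved = evolved, beta = beta,
                 counted = counted),
            class = "het_problem")
}

resolve_counted <- function(model, counted) {
  if (is.null(counted)) return(internal_indices(model))
  if (is.character(counted)) counted <- rxn_index(model, counted)
  cf_assert(all(model$reaction_role[counted] == "internal"),
            "crossfeedr_contract_error",
            "counted reactions must be internal reactions")
  as.integer(counted)
}

ref_values <- function(reference, model) {
  v <- if (inherits(reference, "flux_distribution")) reference$values
       else as.numeric(reference)
  cf_assert(length(v) == length(model$reaction_ids),
            "crossfeedr_contract_error",
            "reference flux vector length differs from model")
  v
}

#' Regulatory on/off minimization (ROOM)
#'
#' Finds an evolved flux distribution `e` satisfying the evolved
#' constraints while minimizing the number of counted internal reactions
#' whose flux deviates from the reference `a` by more than `beta`:
#' minimize sum(f_i) subject to `S e = 0`, the evolved bounds, and for each
#' counted reaction the indicator inequalities
#' `e_i - f_i (u_i - (a_i + beta)) <= a_i + beta` and
#' `e_i - f_i (l_i - (a_i - beta)) >= a_i - beta` with binary `f_i`.
#' Solved to proven optimality; indicators are rounded and the indicator
#' constraints re-verified at tolerance 1e-6 after the solve.
#'
#' @param model a [metabolic_model()].
#' @param problem a [room_problem()].
#' @param node_limit branch-and-bound node budget (exceeding it raises a
#'   `crossfeedr_timeout` carrying the best bound, never a silent
#'   suboptimal answer).
#' @return list with `evolved` (a [flux_distribution()]), `distance`
#'   (integer optimal count), `changed` (ids of reactions with f = 1 in
#'   the returned optimum -- one optimum among possibly many), `f`,
#'   `nodes`.
#' @export
room <- function(model, problem, node_limit = 200000L) {
  stopifnot(inherits(problem, "room_problem"))
  counted <- resolve_counted(model, problem$counted)
  a <- ref_values(problem$reference, model)
  beta <- problem$beta
  ev <- cf_clamp_bounds(problem$evolved$lb, problem$evolved$ub)

  r <- length(model$reaction_ids)
  nf <- length(counted)
  Sd <- as.matrix(model$S)
  m <- nrow(Sd)

  # columns: e (r) | f (nf) | s_up (nf) | s_dn (nf)
  K1 <- ev$ub[counted] - (a[counted] + beta)
  K2 <- ev$lb[counted] - (a[counted] - beta)
  Aup <- matrix(0, nf, r); Aup[cbind(seq_len(nf), counted)] <- 1
  Adn <- Aup
  A <- rbind(
    cbind(Sd, matrix(0, m, 3 * nf)),
    cbind(Aup, diag(-K1, nf), diag(nf), matrix(0, nf, nf)),
    cbind(Adn, diag(-K2, nf), matrix(0, nf, nf), -diag(nf)))
  b <- c(numeric(m), a[counted] + beta, a[counted] - beta)
  obj <- c(numeric(r), rep(1, nf), numeric(2 * nf))
  lb <- c(ev$lb, numeric(nf), numeric(2 * nf))
  ub <- c(ev$ub, rep(1, nf), rep(CF_SLACK_UB, 2 * nf))
  int_idx <- r + seq_len(nf)

  inc <- room_incumbent(model, ev, a, beta, counted, K1, K2)
  sol <- milp_solve(A, b, obj, lb, ub, int_idx, incumbent = inc,
                    node_limit = node_limit)

  e <- sol$x[seq_len(r)]
  f <- round(sol$x[int_idx])
  verify_indicators(e[counted], a[counted], f, beta,
                    ev$lb[counted], ev$ub[counted])
  dist <- as.integer(round(sol$obj))
  list(evolved = flux_distribution(e, model, method = "room",
                                   objective = dist, bounds = ev,
                                   extra = list(beta = beta,
                                                nodes = sol$nodes,
                                                gap = sol$gap)),
       distance = dist,
       changed = model$reaction_ids[counted][f > 0.5],
       f = setNames(f, model$reaction_ids[counted]),
       nodes = sol$nodes)
}

# feasible starting incumbent: any evolved-feasible flux vector, with
# f_i = 1 wherever it deviates from the reference by more than beta
room_incumbent <- function(model, ev, a, beta, counted, K1, K2) {
  r <- length(model$reaction_ids)
  sol <- lp_solve(model$S, numeric(nrow(model$S)), numeric(r),
                  ev$lb, ev$ub, sense = "min", on_infeasible = "status")
  if (sol$status != 0) {
    cf_abort("crossfeedr_infeasible",
             "evolved constraints are infeasible: no steady-state flux distribution satisfies them")
  }
  e0 <- sol$x
  f0 <- as.numeric(abs(e0[counted] - a[counted]) > beta)
  s_up <- (a[counted] + beta) - e0[counted] + K1 * f0
  s_dn <- e0[counted] - (a[counted] - beta) + K2 * f0
  list(x = c(e0, f0, pmax(s_up, 0), pmax(s_dn, 0)), obj = sum(f0))
}

verify_indicators <- function(e, a, f, beta, lb, ub, tol = 1e-6) {
  off <- f < 0.5
  cf_assert(all(abs(e[off] - a[off]) <= beta + tol),
            "crossfeedr_contract_error",
            "post-solve verification failed: an unchanged reaction deviates by more than beta")
  cf_assert(all(e >= lb - tol & e <= ub + tol),
            "crossfeedr_contract_error",
            "post-solve verification failed: evolved bounds violated")
  invisible(TRUE)
}

#' Joint ancestral/evolved flux-change minimization
#'
#' Finds two steady-state flux distributions simultaneously -- `a`
#' satisfying the ancestral constraint set and `e` the evolved one --
#' minimizing the number of counted internal reactions with
#' `|e_i - a_i| > beta`. This models a phenotypically heterogeneous
#' ancestral population: the ancestor is any member of its allowed flux
#' space, not a fixed reference. The indicator coupling is linearized as
#' `|e_i - a_i| <= beta + f_i M_i` with `M_i` taken from the box bounds,
#' which coincides with the indicator semantics at every integer `f`.
#'
#' @param model a [metabolic_model()].
#' @param problem a [het_problem()].
#' @param node_limit as in [room()].
#' @return list with `ancestor`, `evolved` ([flux_distribution()]s),
#'   `distance`, `changed`, `f`, `nodes`.
#' @export
room_het <- function(model, problem, node_limit = 200000L) {
  stopifnot(inherits(problem, "het_problem"))
  counted <- resolve_counted(model, problem$counted)
  beta <- problem$beta
  an <- cf_clamp_bounds(problem$ancestor$lb, problem$ancestor$ub)
  ev <- cf_clamp_bounds(problem$evolved$lb, problem$evolved$ub)

  r <- length(model$reaction_ids)
  nf <- length(counted)
  Sd <- as.matrix(model$S)
  m <- nrow(Sd)

  M1 <- pmax(ev$ub[counted] - an$lb[counted] - beta, 0)
  M2 <- pmax(an$ub[counted] - ev$lb[counted] - beta, 0)

  sel <- matrix(0, nf, r); sel[cbind(seq_len(nf), counted)] <- 1
  # columns: a (r) | e (r) | f (nf) | s_up (nf) | s_dn (nf)
  A <- rbind(
    cbind(Sd, matrix(0, m, r + 3 * nf)),
    cbind(matrix(0, m, r), Sd, matrix(0, m, 3 * nf)),
    cbind(-sel, sel, diag(-M1, nf), diag(nf), matrix(0, nf, nf)),
    cbind(-sel, sel, diag(M2, nf), matrix(0, nf, nf), -diag(nf)))
  b <- c(numeric(2 * m), rep(beta, nf), rep(-beta, nf))
  obj <- c(numeric(2 * r), rep(1, nf), numeric(2 * nf))
  lb <- c(an$lb, ev$lb, numeric(nf), numeric(2 * nf))
  ub <- c(an$ub, ev$ub, rep(1, nf), rep(CF_SLACK_UB, 2 * nf))
  int_idx <- 2 * r + seq_len(nf)

  inc <- het_incumbent(model, an, ev, beta, counted, M1, M2)
  sol <- milp_solve(A, b, obj, lb, ub, int_idx, incumbent = inc,
                    node_limit = node_limit)

  av <- sol$x[seq_len(r)]
  evv <- sol$x[r + seq_len(r)]
  f <- round(sol$x[int_idx])
  off <- f < 0.5
  cf_assert(all(abs(evv[counted][off] - av[counted][off]) <= beta + 1e-6),
            "crossfeedr_contract_error",
            "post-solve verification failed: an unchanged reaction pair deviates by more than beta")
  dist <- as.integer(round(sol$obj))
  list(ancestor = flux_distribution(av, model, method = "room_het/ancestor",
                                    objective = dist, bounds = an),
       evolved = flux_distribution(evv, model, method = "room_het/evolved",
                                   objective = dist, bounds = ev,
                                   extra = list(beta = beta,
                                                nodes = sol$nodes)),
       distance = dist,
       changed = model$reaction_ids[counted][f > 0.5],
       f = setNames(f, model$reaction_ids[counted]),
       nodes = sol$nodes)
}

het_incumbent <- function(model, an, ev, beta, counted, M1, M2) {
  r <- length(model$reaction_ids)
  feas <- function(bb, which_set) {
    sol <- lp_solve(model$S, numeric(nrow(model$S)), numeric(r),
                    bb$lb, bb$ub, sense = "min", on_infeasible = "status")
    if (sol$status != 0) {
      cf_abort("crossfeedr_infeasible",
               sprintf("%s constraints are infeasible", which_set))
    }
    sol$x
  }
  a0 <- feas(an, "ancestor")
  e0 <- feas(ev, "evolved")
  f0 <- as.numeric(abs(e0[counted] - a0[counted]) > beta)
  d <- e0[counted] - a0[counted]
  s_up <- beta - d + M1 * f0
  s_dn <- d + beta + M2 * f0
  list(x = c(a0, e0, f0, pmax(s_up, 0), pmax(s_dn, 0)), obj = sum(f0))
}

#' Minimization of metabolic adjustment (MoMA)
#'
#' Returns the evolved flux distribution minimizing the squared Euclidean
#' distance `sum((e_i - a_i)^2)` to the reference, subject to steady state
#' and the evolved bounds. Solved as a strictly convex quadratic program.
#'
#' @param model a [metabolic_model()].
#' @param reference ancestral [flux_distribution()] or numeric vector.
#' @param evolved list with `lb`, `ub` for the evolved strain.
#' @return a [flux_distribution()]; `provenance$objective` is the squared
#'   distance.
#' @export
moma <- function(model, reference, evolved) {
  a <- ref_values(reference, model)
  ev <- cf_clamp_bounds(evolved$lb, evolved$ub)
  r <- length(a)
  Sd <- as.matrix(model$S)
  # equalities: steady state rows (independent subset) + fixed fluxes
  fixed <- which(ev$ub - ev$lb < 1e-12)
  Eq <- Sd
  beq <- numeric(nrow(Sd))
  if (length(fixed) > 0) {
    Fm <- matrix(0, length(fixed), r); Fm[cbind(seq_along(fixed), fixed)] <- 1
    Eq <- rbind(Eq, Fm)
    beq <- c(beq, ev$lb[fixed])
  }
  keep <- independent_rows(Eq)
  Eq <- Eq[keep, , drop = FALSE]; beq <- beq[keep]
  free <- setdiff(seq_len(r), fixed)
  # inequalities: bounds on the non-fixed fluxes
  Ain <- rbind(diag(r)[free, , drop = FALSE], -diag(r)[free, , drop = FALSE])
  bin <- c(ev$lb[free], -ev$ub[free])
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = diag(r), dvec = a,
                       Amat = t(rbind(Eq, Ain)),
                       bvec = c(beq, bin), meq = nrow(Eq)),
    error = function(e) cf_abort(
      "crossfeedr_infeasible",
      sprintf("MoMA quadratic program failed: %s", conditionMessage(e))))
  e <- sol$solution
  e[fixed] <- ev$lb[fixed]
  flux_distribution(e, model, method = "moma",
                    objective = sum((e - a)^2), bounds = ev)
}

independent_rows <- function(M, tol = 1e-9) {
  if (nrow(M) == 0) return(integer(0))
  qd <- qr(t(M), tol = tol)
  sort(qd$pivot[seq_len(qd$rank)])
}

#' Classify flux changes between two distributions
#'
#' Partitions the reactions whose flux differs by more than `beta` into
#' `turned_on` (inactive in the ancestor, active in the evolved strain),
#' `turned_off` (the reverse), and `magnitude_change` (active in both).
#' A reaction is active when `|flux| > activity_threshold`. The rare
#' changed reaction inactive in both (possible only when
#' `beta > activity_threshold` is violated marginally) is counted as a
#' magnitude change so the three classes always partition the changed set.
#'
#' @param a,e [flux_distribution()]s (or named numeric vectors) over the
#'   same reactions.
#' @param beta flux-change threshold, mmol gDW^-1 h^-1.
#' @param activity_threshold activity threshold, mmol gDW^-1 h^-1.
#' @param reactions optional subset of reaction ids to classify (e.g. the
#'   counted internal reactions); default: all shared reactions.
#' @return list of class `change_classification` with the three id sets
#'   and `n_changed`.
#' @export
classify_changes <- function(a, e, beta = 0.001, activity_threshold = 0.001,
                             reactions = NULL) {
  va <- if (inherits(a, "flux_distribution")) a$values else a
  ve <- if (inherits(e, "flux_distribution")) e$values else e
  cf_assert(length(va) == length(ve) &&
              (is.null(names(va)) || identical(names(va), names(ve))),
            "crossfeedr_contract_error",
            "flux vectors are over different reaction sets")
  if (!is.null(reactions)) {
    va <- va[reactions]; ve <- ve[reactions]
  }
  ids <- names(va)
  if (is.null(ids)) ids <- as.character(seq_along(va))
  changed <- abs(ve - va) > beta
  act_a <- abs(va) > activity_threshold
  act_e <- abs(ve) > activity_threshold
  on <- changed & !act_a & act_e
  off <- changed & act_a & !act_e
  mag <- changed & !(on | off)
  structure(list(turned_on = ids[on], turned_off = ids[off],
                 magnitude_change = ids[mag],
                 n_changed = sum(changed),
                 beta = beta, activity_threshold = activity_threshold),
            class = "change_classification")
}

#' @export
print.change_classification <- function(x, ...) {
  cat(sprintf("<change_classification> %d changed: %d on, %d off, %d magnitude\n",
              x$n_changed, length(x$turned_on), length(x$turned_off),
              length(x$magnitude_change)))
  invisible(x)
}
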