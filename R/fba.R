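# Flux balance analysis primitives: FBA, parsimonious FBA, and targeted
# uptake minimization under chemostat constraints.

#' Construct a flux distribution
#'
#' A steady-state flux vector with provenance metadata. Construction
#' asserts the steady-state and bound invariants (tolerance 1e-6).
#'
#' @param values named numeric vector, one flux per reaction (model order).
#' @param model the [metabolic_model()] the fluxes belong to.
#' @param method,objective,extra provenance fields.
#' @param bounds the lb/ub actually imposed (defaults to model bounds).
#' @return object of class `flux_distribution`.
#' @export
flux_distribution <- function(values, model, method = "unknown",
                              objective = NA_real_, bounds = NULL,
                              extra = list()) {
  stopifnot(length(values) == length(model$reaction_ids))
  values <- setNames(as.numeric(values), model$reaction_ids)
  resid <- max(abs(as.numeric(model$S %*% values)))
  cf_assert(resid <= 1e-6, "crossfeedr_contract_error",
            sprintf("steady-state violated: max |S v| = %.3g", resid))
  if (is.null(bounds)) bounds <- list(lb = model$lb, ub = model$ub)
  cf_assert(all(values >= pmax(bounds$lb, -CF_BIG) - 1e-6) &&
              all(values <= pmin(bounds$ub, CF_BIG) + 1e-6),
            "crossfeedr_contract_error", "flux bound violated")
  structure(list(values = values,
                 provenance = c(list(method = method, objective = objective,
                                     solver = "crossfeedr simplex",
                                     tolerance = 1e-6), extra)),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  nz <- sum(abs(x$values) > 1e-6)
  cat(sprintf("<flux_distribution> %s: %d reactions, %d active, objective %s\n",
              x$provenance$method, length(x$values), nz,
              format(x$provenance$objective)))
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux through one reaction subject to
#' steady state (`S v = 0`) and bounds.
#'
#' @param model a [metabolic_model()].
#' @param env a [chemostat_env()] or `NULL`.
#' @param objective reaction id to optimize (default: biomass).
#' @param sense `"max"` or `"min"`.
#' @param bounds optional explicit bound overrides (list `lb`, `ub`);
#'   supersedes `env`.
#' @return a [flux_distribution()] with the objective value in provenance.
#' @export
fba <- function(model, env = NULL, objective = model$biomass_reaction_id,
                sense = c("max", "min"), bounds = NULL) {
  sense <- match.arg(sense)
  if (is.null(bounds)) bounds <- env_bounds(model, env)
  r <- length(model$reaction_ids)
  obj <- numeric(r); obj[rxn_index(model, objective)] <- 1
  sol <- tryCatch(
    lp_solve(model$S, numeric(nrow(model$S)), obj, bounds$lb, bounds$ub,
             sense = sense),
    crossfeedr_infeasible = function(e) {
      cf_abort("crossfeedr_infeasible",
               paste0("FBA infeasible under the given environment; ",
                      "binding constraints include the fixed-flux reactions: ",
                      paste(model$reaction_ids[bounds$lb == bounds$ub],
                            collapse = ", ")))
    })
  flux_distribution(sol$x, model, method = sprintf("fba(%s)", sense),
                    objective = sol$obj, bounds = bounds,
                    extra = list(objective_reaction = objective))
}

#' Parsimonious flux balance analysis
#'
#' Among all flux distributions that grow at exactly `growth_rate`,
#' returns one minimizing the total absolute flux `sum(|v|)`. Absolute
#' values are realized by splitting each reaction into non-negative
#' forward and reverse parts inside the solver.
#'
#' @param model a [metabolic_model()].
#' @param env a [chemostat_env()] or `NULL`.
#' @param growth_rate required growth rate, h^-1 (defaults to the
#'   environment's dilution rate).
#' @param bounds optional explicit bound overrides; supersedes `env`.
#' @return a [flux_distribution()]; `provenance$objective` holds the
#'   minimal total flux.
#' @export
pfba <- function(model, env = NULL,
                 growth_rate = if (!is.null(env)) env$dilution_rate else NULL,
                 bounds = NULL) {
  if (is.null(bounds)) bounds <- env_bounds(model, env)
  if (!is.null(growth_rate)) {
    bounds <- set_flux_equal(bounds, rxn_index(model, model$biomass_reaction_id),
                             growth_rate)
  }
  sol <- pfba_split_solve(model, bounds)
  v <- sol$v
  if (!is.null(growth_rate)) {
    cf_assert(abs(v[rxn_index(model, model$biomass_reaction_id)] -
                    growth_rate) <= 1e-6,
              "crossfeedr_contract_error",
              "pFBA growth differs from the required rate")
  }
  flux_distribution(v, model, method = "pfba", objective = sol$total,
                    bounds = bounds,
                    extra = list(growth_rate = growth_rate,
                                 total_flux = sol$total))
}

# forward/reverse split LP: v = p - n, p,n >= 0, min sum(p + n)
pfba_split_solve <- function(model, bounds) {
  bb <- cf_clamp_bounds(bounds$lb, bounds$ub)
  Sd <- as.matrix(model$S)
  A <- cbind(Sd, -Sd)
  r <- ncol(Sd)
  lbp <- pmax(0, bb$lb); ubp <- pmax(0, bb$ub)
  lbn <- pmax(0, -bb$ub); ubn <- pmax(0, -bb$lb)
  sol <- lp_solve(A, numeric(nrow(A)), rep(1, 2 * r),
                  c(lbp, lbn), c(ubp, ubn), sense = "min")
  v <- sol$x[seq_len(r)] - sol$x[r + seq_len(r)]
  list(v = v, total = sol$obj)
}

#' Minimal uptake through an exchange reaction
#'
#' Finds the smallest uptake magnitude through `exchange_id` compatible
#' with steady state, the environment, and a set of fixed-flux equalities
#' (e.g. growth at the dilution rate, a by-product excretion rate).
#'
#' @param model a [metabolic_model()].
#' @param env a [chemostat_env()] or `NULL`.
#' @param exchange_id exchange reaction whose uptake is minimized.
#' @param fixed named numeric vector of fixed fluxes (reaction id ->
#'   value), imposed as equalities.
#' @param bounds optional explicit starting bounds; supersedes `env`.
#' @return list with `uptake` (non-negative magnitude, mmol gDW^-1 h^-1)
#'   and `flux` (the solving [flux_distribution()]).
#' @export
minimize_uptake <- function(model, env = NULL, exchange_id,
                            fixed = numeric(0), bounds = NULL) {
  if (is.null(bounds)) bounds <- env_bounds(model, env)
  for (id in names(fixed)) {
    bounds <- set_flux_equal(bounds, rxn_index(model, id), fixed[[id]])
  }
  j <- rxn_index(model, exchange_id)
  # uptake is negative flux; restrict to consumption and push toward zero
  bounds$lb[j] <- min(bounds$lb[j], 0)
  bounds$ub[j] <- min(bounds$ub[j], 0)
  obj <- numeric(length(model$reaction_ids)); obj[j] <- 1
  sol <- lp_solve(model$S, numeric(nrow(model$S)), obj,
                  bounds$lb, bounds$ub, sense = "max")
  flux <- flux_distribution(sol$x, model, method = "minimize_uptake",
                            objective = sol$obj, bounds = bounds,
                            extra = list(exchange = exchange_id))
  list(uptake = max(0, -sol$obj), flux = flux)
}
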