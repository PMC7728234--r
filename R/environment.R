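# Chemostat growth environment: a minimal medium with one limiting carbon
# source, applied to a model by rewriting exchange-reaction bounds.

#' Define a glucose-limited chemostat environment
#'
#' At steady state the population grows at the chemostat's dilution rate
#' `D`. The primary carbon source is capped for uptake; inorganic nutrients
#' are open without limit; every other exchange is closed for uptake
#' (secretion stays as the model allows).
#'
#' @param dilution_rate dilution rate `D`, h^-1.
#' @param primary_carbon exchange reaction id of the limiting carbon source.
#' @param uptake_cap maximum uptake of the primary carbon source, stated as
#'   a positive magnitude, mmol gDW^-1 h^-1.
#' @param inorganics character vector of exchange ids supplied in
#'   non-limiting amounts (opened to uptake without bound).
#' @return object of class `chemostat_env`.
#' @export
chemostat_env <- function(dilution_rate = 0.2, primary_carbon,
                          uptake_cap = 10, inorganics = character()) {
  cf_assert(dilution_rate > 0, "crossfeedr_contract_error",
            "dilution rate must be positive")
  cf_assert(uptake_cap >= 0, "crossfeedr_contract_error",
            "uptake cap must be non-negative")
  structure(list(dilution_rate = dilution_rate,
                 primary_carbon = primary_carbon,
                 uptake_cap = uptake_cap,
                 inorganics = inorganics),
            class = "chemostat_env")
}

#' Flux bounds implied by an environment
#'
#' Starts from the model's bounds and closes uptake through every exchange
#' reaction except the primary carbon source (capped) and the non-limiting
#' inorganics (opened wide). Uptake is negative flux.
#'
#' @param model a [metabolic_model()].
#' @param env a [chemostat_env()], or `NULL` to keep model bounds.
#' @return list with numeric vectors `lb` and `ub`.
#' @export
env_bounds <- function(model, env) {
  lb <- model$lb; ub <- model$ub
  if (is.null(env)) return(list(lb = lb, ub = ub))
  cf_assert(env$primary_carbon %in% model$reaction_ids,
            "crossfeedr_contract_error",
            sprintf("primary carbon exchange '%s' not in model",
                    env$primary_carbon))
  exch <- model$reaction_role == "exchange"
  lb[exch] <- pmax(lb[exch], 0)
  io <- rxn_index(model, intersect(env$inorganics, model$reaction_ids))
  lb[io] <- -CF_BIG
  pc <- rxn_index(model, env$primary_carbon)
  lb[pc] <- -env$uptake_cap
  list(lb = lb, ub = ub)
}

# bound-override helpers: constraints are plain lb/ub vectors over reactions
set_flux_equal <- function(bounds, idx, value) {
  bounds$lb[idx] <- value; bounds$ub[idx] <- value; bounds
}
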