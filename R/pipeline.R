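# Orchestration of the cross-feeding experiments: ancestral state, producer
# and consumer constraint construction per candidate metabolite, distance
# computation, ranking, overlap statistics and the glucose sweep.

#' Ancestral flux state
#'
#' The flux distribution of the ancestral strain: parsimonious FBA at a
#' growth rate equal to the chemostat dilution rate under the environment.
#'
#' @param model a [metabolic_model()].
#' @param env a [chemostat_env()].
#' @return a [flux_distribution()].
#' @export
ancestral_state <- function(model, env) {
  pfba(model, env, growth_rate = env$dilution_rate)
}

#' Describe an evolved strain's constraint pattern
#'
#' @param role `"ancestor"`, `"producer"`, `"consumer"`, or
#'   `"consumer_with_glucose"`.
#' @param secondary exchange reaction id of the cross-fed metabolite
#'   (ignored for the ancestor).
#' @param excretion_rate producer excretion of the secondary metabolite,
#'   mmol gDW^-1 h^-1.
#' @param glucose_policy for the ancestor role: `"minimal_required"` or a
#'   numeric uptake cap, mmol gDW^-1 h^-1.
#' @return list of class `strain_spec`.
#' @export
strain_spec <- function(role = c("ancestor", "producer", "consumer",
                                 "consumer_with_glucose"),
                        secondary = NULL, excretion_rate = 1,
                        glucose_policy = "minimal_required") {
  role <- match.arg(role)
  if (role == "producer") {
    cf_assert(excretion_rate > 0, "crossfeedr_contract_error",
              "producer excretion rate must be positive")
  }
  if (role != "ancestor") {
    cf_assert(!is.null(secondary), "crossfeedr_contract_error",
              "producer/consumer specs need a secondary metabolite exchange")
  }
  structure(list(role = role, secondary = secondary,
                 excretion_rate = excretion_rate,
                 glucose_policy = glucose_policy),
            class = "strain_spec")
}

#' Build the bound constraints defining a strain
#'
#' Producer: growth fixed at the dilution rate, secondary excretion fixed
#' at `excretion_rate`, and glucose uptake fixed at the minimal value that
#' keeps both feasible. Consumer: growth fixed, glucose uptake disallowed
#' (or fixed at 1 mmol gDW^-1 h^-1 for the `consumer_with_glucose`
#' variant), and secondary uptake fixed at its minimal feasible value.
#' Ancestor: growth fixed, glucose uptake bounded above by its policy cap
#' (not fixed).
#'
#' @param model a [metabolic_model()].
#' @param env a [chemostat_env()].
#' @param spec a [strain_spec()].
#' @param ancestor the ancestral [flux_distribution()] (currently unused
#'   by the constraint construction itself; accepted for provenance).
#' @return list with `lb`, `ub`, plus `glucose` and `secondary` fixed
#'   values where applicable.
#' @export
build_strain_constraints <- function(model, env, spec, ancestor = NULL) {
  stopifnot(inherits(spec, "strain_spec"))
  bounds <- env_bounds(model, env)
  D <- env$dilution_rate
  bio <- rxn_index(model, model$biomass_reaction_id)
  glc <- rxn_index(model, env$primary_carbon)
  bounds <- set_flux_equal(bounds, bio, D)

  if (spec$role == "ancestor") {
    cap <- if (identical(spec$glucose_policy, "minimal_required")) {
      minimize_uptake(model, env, env$primary_carbon,
                      fixed = setNames(D, model$biomass_reaction_id))$uptake
    } else {
      as.numeric(spec$glucose_policy)
    }
    bounds$lb[glc] <- -cap
    bounds$glucose <- cap
    return(bounds)
  }

  sec <- rxn_index(model, spec$secondary)
  if (spec$role == "producer") {
    bounds <- set_flux_equal(bounds, sec, spec$excretion_rate)
    mu <- minimize_uptake(model, env = NULL, env$primary_carbon,
                          bounds = bounds)
    bounds <- set_flux_equal(bounds, glc, -mu$uptake)
    bounds$glucose <- mu$uptake
    bounds$secondary <- spec$excretion_rate
  } else {
    glc_fix <- if (spec$role == "consumer_with_glucose") 1 else 0
    if (glc_fix > 0) {
      bounds <- set_flux_equal(bounds, glc, -glc_fix)
    } else {
      bounds$lb[glc] <- 0 # uptake disallowed, secretion as the model allows
    }
    bounds$lb[sec] <- -CF_BIG # open the secondary source for uptake
    mu <- minimize_uptake(model, env = NULL, spec$secondary, bounds = bounds)
    bounds <- set_flux_equal(bounds, sec, -mu$uptake)
    bounds$glucose <- glc_fix
    bounds$secondary <- mu$uptake
  }
  bounds
}

#' Metabolic distances for producer and consumer of each metabolite
#'
#' For every candidate cross-fed metabolite, builds the producer and
#' consumer constraint sets and computes the minimal number of internal
#' reactions requiring a flux change, by ROOM against the pFBA ancestor or
#' by the joint heterogeneous-ancestor optimization.
#'
#' @param model a [metabolic_model()].
#' @param env a [chemostat_env()].
#' @param metabolites character vector of secondary-metabolite exchange
#'   reaction ids.
#' @param method `"room"` or `"room_het"`.
#' @param beta flux-change threshold.
#' @param excretion_rate producer excretion, mmol gDW^-1 h^-1.
#' @param ancestor optional precomputed ancestral [flux_distribution()]
#'   (ROOM) -- computed on demand.
#' @param ancestor_cap glucose cap for the heterogeneous ancestor's
#'   constraint set; default the minimal glucose uptake at the dilution
#'   rate (`"minimal_required"`).
#' @return list of distance results; each has `metabolite`, `role`,
#'   `distance`, `classification`, `ancestor_flux`, `evolved_flux`,
#'   `method`. Metabolites infeasible in a role are reported in
#'   `attr(, "failures")` and skipped.
#' @export
compute_distances <- function(model, env, metabolites,
                              method = c("room", "room_het"),
                              beta = 0.001, excretion_rate = 1,
                              ancestor = NULL,
                              ancestor_cap = "minimal_required") {
  method <- match.arg(method)
  counted <- internal_indices(model)
  if (method == "room" && is.null(ancestor)) {
    ancestor <- ancestral_state(model, env)
  }
  anc_bounds <- NULL
  if (method == "room_het") {
    anc_bounds <- build_strain_constraints(
      model, env, strain_spec("ancestor", glucose_policy = ancestor_cap))
  }

  results <- list()
  failures <- list()
  for (met in metabolites) {
    for (role in c("producer", "consumer")) {
      res <- tryCatch({
        sp <- strain_spec(role, secondary = met,
                          excretion_rate = excretion_rate)
        ev <- build_strain_constraints(model, env, sp, ancestor)
        if (method == "room") {
          out <- room(model, room_problem(ancestor, ev, beta = beta,
                                          counted = counted))
          anc_flux <- ancestor
        } else {
          out <- room_het(model, het_problem(anc_bounds, ev, beta = beta,
                                             counted = counted))
          anc_flux <- out$ancestor
        }
        cls <- classify_changes(anc_flux, out$evolved, beta = beta,
                                reactions = model$reaction_ids[counted])
        dr <- list(metabolite = met, role = role, distance = out$distance,
                   classification = cls, ancestor_flux = anc_flux,
                   evolved_flux = out$evolved, changed = out$changed,
                   method = method,
                   glucose = ev$glucose, secondary = ev$secondary)
        class(dr) <- "distance_result"
        dr
      }, crossfeedr_infeasible = function(e) {
        structure(list(metabolite = met, role = role,
                       message = conditionMessage(e)),
                  class = "distance_failure")
      })
      if (inherits(res, "distance_failure")) {
        warning(sprintf("%s %s infeasible: excluded (%s)", met, res$role,
                        res$message), call. = FALSE)
        failures[[length(failures) + 1L]] <- res
      } else {
        results[[length(results) + 1L]] <- res
      }
    }
  }
  attr(results, "failures") <- failures
  results
}

#' Rank metabolites by total metabolic distance
#'
#' Total distance = producer distance + consumer distance; rank 1 is the
#' smallest total (the cross-feeding interaction predicted most likely to
#' evolve). Ties share the minimum rank (competition ranking).
#'
#' @param results output of [compute_distances()].
#' @return data.frame with `metabolite`, `producer`, `consumer`, `total`,
#'   `rank`; attribute `tie_rule` records the tie-breaking convention.
#' @export
rank_metabolites <- function(results) {
  mets <- unique(vapply(results, function(x) x$metabolite, character(1)))
  rows <- list()
  for (met in mets) {
    pick <- function(role) {
      hit <- Filter(function(x) x$metabolite == met && x$role == role,
                    results)
      if (length(hit) == 0) NA_integer_ else hit[[1]]$distance
    }
    p <- pick("producer"); cns <- pick("consumer")
    if (is.na(p) || is.na(cns)) {
      warning(sprintf("metabolite %s lacks a %s distance: omitted from ranking",
                      met, if (is.na(p)) "producer" else "consumer"),
              call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      metabolite = met, producer = p, consumer = cns, total = p + cns,
      stringsAsFactors = FALSE)
  }
  cf_assert(length(rows) > 0, "crossfeedr_contract_error",
            "no metabolite has both producer and consumer distances")
  tab <- do.call(rbind, rows)
  tab$rank <- rank(tab$total, ties.method = "min")
  tab <- tab[order(tab$total, tab$metabolite), ]
  rownames(tab) <- NULL
  attr(tab, "tie_rule") <- "competition (ties share the minimum rank)"
  tab
}

#' Reactions whose flux change is shared across strains
#'
#' @param results output of [compute_distances()].
#' @param role `"producer"` or `"consumer"`.
#' @param fraction a reaction is reported when it changes in at least
#'   `fraction` of the strains (`1` = every strain; values at or below
#'   `1/n` give the union).
#' @return character vector of reaction ids; attribute `caveat` notes that
#'   changed-reaction identities depend on which optimal solution the
#'   solver returned.
#' @export
shared_reactions <- function(results, role = c("producer", "consumer"),
                             fraction = 1) {
  role <- match.arg(role)
  cf_assert(fraction > 0 && fraction <= 1, "crossfeedr_contract_error",
            "fraction must be in (0, 1]")
  sets <- lapply(Filter(function(x) x$role == role, results),
                 function(x) unique(c(x$classification$turned_on,
                                      x$classification$turned_off,
                                      x$classification$magnitude_change)))
  cf_assert(length(sets) > 0, "crossfeedr_contract_error",
            sprintf("no %s results available", role))
  counts <- table(unlist(sets))
  need <- fraction * length(sets)
  out <- names(counts)[counts >= need - 1e-9]
  attr(out, "caveat") <-
    "changed-reaction identities reflect one optimal solution among possibly many"
  out
}

#' Distances as a function of ancestral glucose consumption
#'
#' Repeats the heterogeneous-ancestor distance computation over a grid of
#' glucose uptake caps for the ancestral population (uptake bounded above
#' by the cap, not fixed). Distances can only shrink as the cap grows --
#' the ancestral flux space only gains members -- and this monotonicity is
#' asserted. Also reports the Spearman rank correlation of total distances
#' between consecutive grid points.
#'
#' @param model a [metabolic_model()].
#' @param env a [chemostat_env()].
#' @param metabolites secondary-metabolite exchange ids.
#' @param grid increasing glucose uptake caps, mmol gDW^-1 h^-1; must be
#'   at or above the minimal requirement at the dilution rate.
#' @param beta,excretion_rate as in [compute_distances()].
#' @return list of class `sweep_result`: `grid`, `distances` (data.frame
#'   metabolite x role x cap), `totals` (matrix metabolite x cap),
#'   `rank_correlations` (consecutive-cap Spearman coefficients).
#' @export
glucose_sweep <- function(model, env, metabolites, grid, beta = 0.001,
                          excretion_rate = 1) {
  grid <- sort(grid)
  rows <- list()
  totals <- matrix(NA_real_, length(metabolites), length(grid),
                   dimnames = list(metabolites, format(grid)))
  for (k in seq_along(grid)) {
    res <- compute_distances(model, env, metabolites, method = "room_het",
                             beta = beta, excretion_rate = excretion_rate,
                             ancestor_cap = grid[k])
    for (x in res) {
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = x$metabolite, role = x$role, cap = grid[k],
        distance = x$distance, stringsAsFactors = FALSE)
    }
    for (met in metabolites) {
      dd <- vapply(Filter(function(x) x$metabolite == met, res),
                   function(x) x$distance, numeric(1))
      if (length(dd) == 2) totals[met, k] <- sum(dd)
    }
  }
  distances <- do.call(rbind, rows)

  # per-metabolite, per-role monotone non-increase along the caps
  for (met in metabolites) {
    for (role in c("producer", "consumer")) {
      d <- distances$distance[distances$metabolite == met &
                                distances$role == role]
      cf_assert(all(diff(d) <= 0), "crossfeedr_contract_error",
                sprintf("distance not monotone along the glucose grid for %s %s",
                        met, role))
    }
  }

  rank_cor <- rep(NA_real_, max(0, length(grid) - 1))
  for (k in seq_len(length(grid) - 1)) {
    ok <- stats::complete.cases(totals[, k], totals[, k + 1])
    if (sum(ok) >= 3 && stats::sd(totals[ok, k]) > 0 &&
          stats::sd(totals[ok, k + 1]) > 0) {
      rank_cor[k] <- cor(totals[ok, k], totals[ok, k + 1],
                         method = "spearman")
    }
  }
  structure(list(grid = grid, distances = distances, totals = totals,
                 rank_correlations = rank_cor),
            class = "sweep_result")
}
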