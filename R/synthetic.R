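# Toy metabolic networks and brute-force oracles. Everything here is
# synthetic: generated in code, deterministic under a fixed seed, and small
# enough that flux-change minima can be verified by exhaustive enumeration.

#' Deterministic core toy network
#'
#' A small central-carbon-style network built for testing the whole
#' pipeline: glucose import via a lumped uptake/glycolysis reaction that
#' yields pyruvate and ATP; a lumped oxidative pathway ("TCA") burning
#' pyruvate to CO2 for most of the ATP; an overflow branch excreting an
#' acetate-like by-product at a lower ATP yield; an import/assimilation
#' route for that by-product; a second (glycerol-like) by-product with its
#' own export and catabolic routes; two biomass precursors; an ATP
#' maintenance sink; toy GPR rules. The stoichiometric yields are chosen
#' so that the parsimonious ancestor fully oxidizes glucose (no by-product
#' excretion) while the acetate-like producer is reachable by a known,
#' small rerouting.
#'
#' @param futile_cycle add a three-reaction futile loop around pyruvate
#'   (zero net conversion), useful for parsimony tests.
#' @return a [metabolic_model()].
#' @export
make_core_fixture <- function(futile_cycle = FALSE) {
  mets <- c("glc_e", "pyr_c", "ace_c", "ace_e", "glyc_c", "glyc_e",
            "pre1_c", "pre2_c", "atp_c", "o2_e", "co2_e")
  rxn <- function(id, stoich, lb, ub, gpr = "", subsystem = "unassigned") {
    list(id = id, stoich = stoich, lb = lb, ub = ub, gpr = gpr,
         subsystem = subsystem)
  }
  rxns <- list(
    rxn("EX_glc_e", c(glc_e = -1), -10, 1000, subsystem = "exchange"),
    rxn("GPTS", c(glc_e = -1, pyr_c = 2, atp_c = 2), 0, 1000,
        gpr = "gA1 and gA2", subsystem = "glycolysis"),
    rxn("TCA", c(pyr_c = -1, o2_e = -2.5, co2_e = 3, atp_c = 5), 0, 1000,
        gpr = "gB1 and (gB2 or gB3)", subsystem = "citric acid cycle"),
    rxn("POX", c(pyr_c = -1, ace_c = 1, co2_e = 1, atp_c = 0.6), 0, 1000,
        gpr = "gC1", subsystem = "overflow"),
    rxn("ACEt", c(ace_c = -1, ace_e = 1), -1000, 1000,
        gpr = "gD1 or gD2", subsystem = "transport"),
    rxn("ACS", c(ace_c = -1, co2_e = -1, atp_c = -2, pyr_c = 1), 0, 1000,
        gpr = "gE1", subsystem = "anaplerotic"),
    rxn("PRE1", c(pyr_c = -2, atp_c = -1, pre1_c = 1), 0, 1000,
        gpr = "gF1", subsystem = "biosynthesis"),
    rxn("PRE2", c(pyr_c = -1, atp_c = -1, pre2_c = 1), 0, 1000,
        gpr = "gF2", subsystem = "biosynthesis"),
    rxn("GLPS", c(pyr_c = -1, atp_c = -1, glyc_c = 1), 0, 1000,
        gpr = "gG1", subsystem = "overflow"),
    rxn("GLPt", c(glyc_c = -1, glyc_e = 1), -1000, 1000,
        gpr = "gG2 or gG3", subsystem = "transport"),
    rxn("GLYCk", c(glyc_c = -1, pyr_c = 1), 0, 1000,
        gpr = "gG4", subsystem = "alternate carbon"),
    rxn("ATPM", c(atp_c = -1), 0, 1000, subsystem = "maintenance"),
    rxn("BIOMASS", c(pre1_c = -2, pre2_c = -2, atp_c = -10), 0, 1000,
        subsystem = "biomass"),
    rxn("EX_ace_e", c(ace_e = -1), -1000, 1000, subsystem = "exchange"),
    rxn("EX_glyc_e", c(glyc_e = -1), -1000, 1000, subsystem = "exchange"),
    rxn("EX_o2_e", c(o2_e = -1), -1000, 1000, subsystem = "exchange"),
    rxn("EX_co2_e", c(co2_e = -1), -1000, 1000, subsystem = "exchange"))
  if (futile_cycle) {
    mets <- c(mets, "cyc1_c", "cyc2_c")
    rxns <- c(rxns, list(
      rxn("FC1", c(pyr_c = -1, cyc1_c = 1), 0, 1000, subsystem = "cycle"),
      rxn("FC2", c(cyc1_c = -1, cyc2_c = 1), 0, 1000, subsystem = "cycle"),
      rxn("FC3", c(cyc2_c = -1, pyr_c = 1), 0, 1000, subsystem = "cycle")))
  }
  build_model_from_rxns("core_fixture", mets, rxns,
                        biomass = "BIOMASS", demand = "ATPM")
}

build_model_from_rxns <- function(id, mets, rxns, biomass, demand) {
  r <- length(rxns)
  S <- matrix(0, length(mets), r, dimnames = list(mets, NULL))
  for (j in seq_len(r)) S[names(rxns[[j]]$stoich), j] <- rxns[[j]]$stoich
  metabolic_model(
    id = id, metabolite_ids = mets,
    reaction_ids = vapply(rxns, `[[`, character(1), "id"),
    S = S,
    lb = vapply(rxns, `[[`, numeric(1), "lb"),
    ub = vapply(rxns, `[[`, numeric(1), "ub"),
    biomass_reaction_id = biomass,
    gpr = vapply(rxns, `[[`, character(1), "gpr"),
    subsystem = vapply(rxns, `[[`, character(1), "subsystem"),
    demand_reactions = demand)
}

#' Chemostat environment matching the core fixture
#'
#' Glucose-limited, dilution rate 0.2 h^-1, glucose uptake capped at
#' 10 mmol gDW^-1 h^-1, oxygen and CO2 non-limiting.
#'
#' @return a [chemostat_env()].
#' @export
core_fixture_env <- function() {
  chemostat_env(dilution_rate = 0.2, primary_carbon = "EX_glc_e",
                uptake_cap = 10,
                inorganics = c("EX_o2_e", "EX_co2_e"))
}

#' Toy operon/regulon annotation tables for the core fixture
#'
#' @return an `annotation_tables` object covering the fixture's genes.
#' @export
core_fixture_annotations <- function() {
  op <- c(gA1 = "opA", gA2 = "opA", gB1 = "opB", gB2 = "opB", gB3 = "opB",
          gC1 = "opC", gD1 = "opD", gD2 = "opD", gE1 = "opE",
          gF1 = "opF", gF2 = "opF",
          gG1 = "opG1", gG2 = "opG2", gG3 = "opG2", gG4 = "opG3")
  reg <- list(gA1 = "crpR", gA2 = "crpR", gB1 = c("crpR", "arcR"),
              gB2 = "arcR", gB3 = "arcR", gC1 = "oxR",
              gD1 = "oxR", gD2 = "oxR", gE1 = c("oxR", "crpR"),
              gF1 = "bioR", gF2 = "bioR",
              gG1 = "glpR", gG2 = "glpR", gG3 = "glpR", gG4 = "glpR")
  structure(list(gene_to_operon = op, gene_to_regulon = reg,
                 expression = NULL),
            class = "annotation_tables")
}

#' Generate a random toy network
#'
#' Builds a linear uptake -> backbone -> biomass chain, guaranteeing
#' feasible growth, then decorates it with an excretable/importable
#' by-product branch, optional extra cross-links, an optional futile
#' cycle, reversible reactions and random toy GPR rules. Byte-identical
#' output under a fixed seed.
#'
#' @param n_internal number of internal reactions in the backbone chain
#'   (>= 3), before by-product and decoration reactions.
#' @param by_products labels of excretable by-products (each adds a maker,
#'   a transporter, an exchange and a catabolic reaction).
#' @param reversible_fraction fraction of backbone reactions made
#'   reversible.
#' @param seed RNG seed.
#' @param include_futile_cycle add a three-reaction zero-net loop.
#' @param gpr_density expected genes per reaction (0 disables GPRs).
#' @param n_extra extra random cross-link reactions between backbone
#'   metabolites.
#' @return a [metabolic_model()]; attributes `env` (a matching
#'   [chemostat_env()]) and `by_product_exchanges`.
#' @export
make_toy_network <- function(n_internal = 6, by_products = "bp1",
                             reversible_fraction = 0.2, seed = 1,
                             include_futile_cycle = FALSE,
                             gpr_density = 1.5, n_extra = 2) {
  cf_assert(n_internal >= 3, "crossfeedr_contract_error",
            "n_internal must be at least 3")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  nb <- n_internal
  backbone_mets <- paste0("m", seq_len(nb), "_c")
  mets <- c("s_e", backbone_mets)
  rxns <- list(list(id = "EX_s_e", stoich = c(s_e = -1), lb = -10, ub = 1000,
                    gpr = "", subsystem = "exchange"))
  prev <- "s_e"
  for (k in seq_len(nb)) {
    cur <- backbone_mets[k]
    st <- setNames(c(-1, 1), c(prev, cur))
    rev <- runif(1) < reversible_fraction && k > 1
    rxns[[length(rxns) + 1L]] <- list(
      id = sprintf("R%02d", k), stoich = st,
      lb = if (rev) -1000 else 0, ub = 1000, gpr = "",
      subsystem = "backbone")
    prev <- cur
  }
  # biomass drains the chain end
  rxns[[length(rxns) + 1L]] <- list(
    id = "BIOMASS", stoich = setNames(-1, backbone_mets[nb]),
    lb = 0, ub = 1000, gpr = "", subsystem = "biomass")

  bp_exchanges <- character(0)
  for (bp in by_products) {
    bc <- paste0(bp, "_c"); be <- paste0(bp, "_e")
    mets <- c(mets, bc, be)
    src <- sample(seq_len(max(1, nb - 1)), 1)
    dst <- sample(setdiff(seq_len(nb), src), 1)
    rxns <- c(rxns, list(
      list(id = paste0(toupper(bp), "_syn"),
           stoich = setNames(c(-1, 1), c(backbone_mets[src], bc)),
           lb = 0, ub = 1000, gpr = "", subsystem = "overflow"),
      list(id = paste0(toupper(bp), "_t"),
           stoich = setNames(c(-1, 1), c(bc, be)),
           lb = -1000, ub = 1000, gpr = "", subsystem = "transport"),
      list(id = paste0(toupper(bp), "_cat"),
           stoich = setNames(c(-1, 1), c(bc, backbone_mets[dst])),
           lb = 0, ub = 1000, gpr = "", subsystem = "alternate carbon"),
      list(id = paste0("EX_", be), stoich = setNames(-1, be),
           lb = -1000, ub = 1000, gpr = "", subsystem = "exchange")))
    bp_exchanges <- c(bp_exchanges, paste0("EX_", be))
  }
  for (x in seq_len(n_extra)) {
    ij <- sample(nb, 2)
    rxns[[length(rxns) + 1L]] <- list(
      id = sprintf("X%02d", x),
      stoich = setNames(c(-1, 1), backbone_mets[ij]),
      lb = 0, ub = 1000, gpr = "", subsystem = "cross-link")
  }
  if (include_futile_cycle) {
    mets <- c(mets, "fc1_c", "fc2_c")
    anchor <- backbone_mets[sample(nb, 1)]
    rxns <- c(rxns, list(
      list(id = "FC1", stoich = setNames(c(-1, 1), c(anchor, "fc1_c")),
           lb = 0, ub = 1000, gpr = "", subsystem = "cycle"),
      list(id = "FC2", stoich = c(fc1_c = -1, fc2_c = 1),
           lb = 0, ub = 1000, gpr = "", subsystem = "cycle"),
      list(id = "FC3", stoich = setNames(c(-1, 1), c("fc2_c", anchor)),
           lb = 0, ub = 1000, gpr = "", subsystem = "cycle")))
  }
  if (gpr_density > 0) {
    pool <- paste0("g", sprintf("%03d", 1:30))
    for (j in seq_along(rxns)) {
      if (grepl("^EX_|^BIOMASS", rxns[[j]]$id)) next
      k <- rbinom(1, 4, min(1, gpr_density / 4))
      if (k == 0) next
      gs <- sample(pool, k)
      op <- if (k > 1 && runif(1) < 0.5) " and " else " or "
      rxns[[j]]$gpr <- paste(gs, collapse = op)
    }
  }
  model <- build_model_from_rxns(paste0("toy_seed", seed), mets, rxns,
                                 biomass = "BIOMASS", demand = character(0))
  attr(model, "env") <- chemostat_env(dilution_rate = 0.2,
                                      primary_carbon = "EX_s_e",
                                      uptake_cap = 10)
  attr(model, "by_product_exchanges") <- bp_exchanges
  model
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Brute-force minimal flux-change count
#'
#' Independent oracle for the flux-change minimization optimizers:
#' enumerates candidate change-sets `F` over the counted reactions by
#' increasing size and returns the size of the first feasible one. For a
#' fixed reference (ROOM semantics), feasibility of `F` means the LP with
#' `|e_i - a_i| <= beta` enforced for every counted `i` not in `F` admits
#' a solution. With `ancestor` bounds instead of a fixed reference
#' (heterogeneous semantics), a joint LP in `(a, e)` is tested, coupling
#' `|e_i - a_i| <= beta` outside `F`.
#'
#' @param model a [metabolic_model()].
#' @param evolved list with `lb`, `ub` for the evolved strain.
#' @param reference numeric/[flux_distribution()] reference (ROOM mode),
#'   or `NULL`.
#' @param ancestor list with `lb`, `ub` (heterogeneous mode), or `NULL`.
#'   Exactly one of `reference` / `ancestor` must be given.
#' @param beta flux-change threshold.
#' @param counted counted reaction indices/ids (default internal).
#' @param max_size largest change-set size to try.
#' @return the minimal count (integer), or `NA` with attribute
#'   `exceeded = TRUE` when no set up to `max_size` is feasible.
#' @export
brute_force_min_change <- function(model, evolved, reference = NULL,
                                   ancestor = NULL, beta = 0.001,
                                   counted = NULL, max_size = NULL) {
  cf_assert(xor(is.null(reference), is.null(ancestor)),
            "crossfeedr_contract_error",
            "give exactly one of reference (ROOM) or ancestor bounds (het)")
  counted <- resolve_counted(model, counted)
  if (is.null(max_size)) max_size <- length(counted)
  ev <- cf_clamp_bounds(evolved$lb, evolved$ub)

  if (!is.null(reference)) {
    a <- ref_values(reference, model)
    Sd <- as.matrix(model$S)
    for (k in 0:max_size) {
      sets <- combn(seq_along(counted), k)
      masks <- matrix(0L, length(counted), ncol(sets))
      for (cse in seq_len(ncol(sets))) masks[sets[, cse], cse] <- 1L
      feas <- .lp_feasible_batch(Sd, numeric(nrow(Sd)), ev$lb, ev$ub,
                                 a, as.integer(counted), masks, beta)
      if (any(feas)) return(k)
    }
  } else {
    an <- cf_clamp_bounds(ancestor$lb, ancestor$ub)
    r <- length(model$reaction_ids)
    Sd <- as.matrix(model$S)
    m <- nrow(Sd)
    nf <- length(counted)
    sel <- matrix(0, nf, r); sel[cbind(seq_len(nf), counted)] <- 1
    # columns: a | e | d (difference e_i - a_i on counted reactions)
    A <- rbind(cbind(Sd, matrix(0, m, r + nf)),
               cbind(matrix(0, m, r), Sd, matrix(0, m, nf)),
               cbind(-sel, sel, -diag(nf)))
    b <- numeric(2 * m + nf)
    obj <- numeric(2 * r + nf)
    wide <- 2 * CF_BIG
    for (k in 0:max_size) {
      sets <- combn(seq_along(counted), k)
      for (cse in seq_len(ncol(sets))) {
        dl <- rep(-beta, nf); du <- rep(beta, nf)
        dl[sets[, cse]] <- -wide; du[sets[, cse]] <- wide
        sol <- lp_solve(A, b, obj, c(an$lb, ev$lb, dl), c(an$ub, ev$ub, du),
                        sense = "min", on_infeasible = "status")
        if (sol$status == 0) return(k)
      }
    }
  }
  structure(NA_integer_, exceeded = TRUE, max_size = max_size)
}
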