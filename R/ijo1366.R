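# Genome-scale reproduction runner. The iJO1366 E. coli reconstruction is
# not bundled (it is a ~5 MB third-party file); point this runner at a
# locally downloaded BiGG JSON copy to recompute the glucose-limited
# chemostat quantities at genome scale. With the package's own
# branch-and-bound this is slow at 2583 reactions; the runner is intended
# for overnight integration runs, not routine testing.

#' Standard glucose minimal-medium environment for iJO1366
#'
#' Dilution rate 0.2 h^-1, glucose capped at 10 mmol gDW^-1 h^-1,
#' inorganic nutrients (ammonium, phosphate, sulphate, oxygen, trace
#' metals, water, protons...) non-limiting.
#'
#' @return a [chemostat_env()].
#' @export
ijo1366_env <- function() {
  chemostat_env(
    dilution_rate = 0.2, primary_carbon = "EX_glc__D_e", uptake_cap = 10,
    inorganics = c("EX_nh4_e", "EX_ca2_e", "EX_cl_e", "EX_cobalt2_e",
                   "EX_cu2_e", "EX_fe2_e", "EX_fe3_e", "EX_mg2_e",
                   "EX_mn2_e", "EX_mobd_e", "EX_ni2_e", "EX_o2_e",
                   "EX_pi_e", "EX_k_e", "EX_h_e", "EX_na1_e", "EX_so4_e",
                   "EX_zn2_e", "EX_h2o_e", "EX_sel_e", "EX_slnt_e",
                   "EX_tungs_e", "EX_cbl1_e"))
}

#' Recompute the genome-scale chemostat quantities on iJO1366
#'
#' Loads a local BiGG JSON copy of iJO1366 and recomputes: the model's
#' reaction count, the parsimonious ancestral glucose uptake at dilution
#' rate 0.2 h^-1, the minimal glucose requirement, and producer/consumer
#' metabolic distances for the requested secondary metabolites.
#'
#' @param model_path path to a local `iJO1366.json`.
#' @param metabolites secondary-metabolite exchange ids (default: acetate
#'   and glycerol).
#' @param method `"room"` or `"room_het"`.
#' @param node_limit branch-and-bound budget per strain problem.
#' @return list with `n_reactions`, `ancestral_glucose`,
#'   `minimal_glucose`, and a distance table.
#' @export
ijo1366_reproduction <- function(model_path,
                                 metabolites = c("EX_ac_e", "EX_glyc_e"),
                                 method = "room",
                                 node_limit = 5e6) {
  cf_assert(file.exists(model_path), "crossfeedr_format_error",
            sprintf("iJO1366 model file not found at '%s'", model_path))
  model <- load_model(model_path, dialect = "bigg_json")
  env <- ijo1366_env()
  anc <- ancestral_state(model, env)
  glc <- anc$values[["EX_glc__D_e"]]
  mg <- minimize_uptake(model, env, "EX_glc__D_e",
                        fixed = setNames(env$dilution_rate,
                                         model$biomass_reaction_id))$uptake
  res <- compute_distances(model, env, metabolites, method = method,
                           ancestor = anc)
  tab <- do.call(rbind, lapply(res, function(x) data.frame(
    metabolite = x$metabolite, role = x$role, distance = x$distance)))
  list(n_reactions = length(model$reaction_ids),
       ancestral_glucose = -glc,
       minimal_glucose = mg,
       distances = tab)
}
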