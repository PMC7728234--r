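# Small models built in code for the unit tests.

# Three-reaction linear chain: uptake -> transport -> biomass; maximal
# growth is stoichiometrically forced by the uptake cap.
chain_model <- function(cap = 10) {
  mets <- c("a_e", "a_c")
  rxns <- list(
    list(id = "EX_a_e", stoich = c(a_e = -1), lb = -cap, ub = 1000,
         gpr = "", subsystem = "exchange"),
    list(id = "At", stoich = c(a_e = -1, a_c = 1), lb = 0, ub = 1000,
         gpr = "gT", subsystem = "transport"),
    list(id = "BIOMASS", stoich = c(a_c = -1), lb = 0, ub = 1000,
         gpr = "", subsystem = "biomass"))
  crossfeedr:::build_model_from_rxns("chain", mets, rxns,
                                     biomass = "BIOMASS",
                                     demand = character(0))
}

chain_env <- function(cap = 10) {
  chemostat_env(dilution_rate = 0.2, primary_carbon = "EX_a_e",
                uptake_cap = cap)
}

# Fully reversible miniature model with interior optima, for the MoMA
# projection oracle.
reversible_model <- function() {
  mets <- c("a_c", "b_c")
  rxns <- list(
    list(id = "U", stoich = c(a_c = 1), lb = -5, ub = 5, gpr = "",
         subsystem = "supply"),
    list(id = "R", stoich = c(a_c = -1, b_c = 1), lb = -5, ub = 5,
         gpr = "", subsystem = "conversion"),
    list(id = "BIOMASS", stoich = c(b_c = -1), lb = -5, ub = 5, gpr = "",
         subsystem = "biomass"))
  crossfeedr:::build_model_from_rxns("rev", mets, rxns,
                                     biomass = "BIOMASS",
                                     demand = character(0))
}

# Four-reaction network where exactly one counted reaction must change:
# forcing by-product excretion activates only its synthesis branch.
one_flip_model <- function() {
  mets <- c("s_e", "x_c", "y_e")
  rxns <- list(
    list(id = "EX_s_e", stoich = c(s_e = -1), lb = -10, ub = 1000,
         gpr = "", subsystem = "exchange"),
    list(id = "T", stoich = c(s_e = -1, x_c = 1), lb = 0, ub = 1000,
         gpr = "", subsystem = "transport"),
    list(id = "Ysyn", stoich = c(x_c = -1, y_e = 1), lb = 0, ub = 1000,
         gpr = "", subsystem = "overflow"),
    list(id = "EX_y_e", stoich = c(y_e = -1), lb = 0, ub = 1000,
         gpr = "", subsystem = "exchange"),
    list(id = "BIOMASS", stoich = c(x_c = -1), lb = 0, ub = 1000,
         gpr = "", subsystem = "biomass"))
  crossfeedr:::build_model_from_rxns("oneflip", mets, rxns,
                                     biomass = "BIOMASS",
                                     demand = character(0))
}

fixture_internal <- function(model) {
  model$reaction_ids[model$reaction_role == "internal"]
}
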