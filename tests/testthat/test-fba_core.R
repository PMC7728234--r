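# FBA, parsimonious FBA and targeted uptake minimization.

test_that("maximal growth on the linear chain is stoichiometrically forced", {
  m <- chain_model(cap = 10)
  sol <- fba(m, chain_env(cap = 10))
  expect_equal(sol$provenance$objective, 10, tolerance = 1e-8)
  expect_equal(unname(sol$values[["BIOMASS"]]), 10, tolerance = 1e-8)
})

test_that("FBA optima agree with an independent dense-LP solve", {
  probs <- list(); mine <- numeric(0)
  cases <- list(list(m = make_core_fixture(), env = core_fixture_env()),
                list(m = make_toy_network(seed = 3), env = NULL))
  for (cs in cases) {
    m <- cs$m
    env <- if (is.null(cs$env)) attr(m, "env") else cs$env
    for (cap in c(5, 2)) {
      env$uptake_cap <- cap
      sol <- fba(m, env)
      bb <- env_bounds(m, env)
      obj <- numeric(length(m$reaction_ids))
      obj[match(m$biomass_reaction_id, m$reaction_ids)] <- -1
      probs[[length(probs) + 1L]] <- list(
        A = as.matrix(m$S), b = numeric(nrow(m$S)), c = obj,
        lb = pmax(bb$lb, -1e6), ub = pmin(bb$ub, 1e6))
      mine <- c(mine, sol$provenance$objective)
    }
  }
  oracle <- -scipy_lp_oracle(probs)
  expect_equal(mine, oracle, tolerance = 1e-7)
})

test_that("infeasible and unbounded problems raise typed conditions", {
  m <- chain_model(cap = 10)
  env <- chain_env()
  expect_error(pfba(m, env, growth_rate = 50),
               class = "crossfeedr_infeasible")
  # an uncapped reversible loop in the objective direction is unbounded
  mets <- c("a_c")
  rxns <- list(
    list(id = "F", stoich = c(a_c = 1), lb = -1e7, ub = 1e7, gpr = "",
         subsystem = "x"),
    list(id = "BIOMASS", stoich = c(a_c = -1), lb = -1e7, ub = 1e7,
         gpr = "", subsystem = "biomass"))
  loop <- crossfeedr:::build_model_from_rxns("loop", mets, rxns,
                                             biomass = "BIOMASS",
                                             demand = character(0))
  expect_error(fba(loop, NULL), class = "crossfeedr_unbounded")
})

test_that("pFBA achieves the required growth exactly and minimizes total flux", {
  m <- make_core_fixture()
  env <- core_fixture_env()
  p <- pfba(m, env, growth_rate = 0.2)
  expect_equal(unname(p$values[["BIOMASS"]]), 0.2, tolerance = 1e-8)
  expect_valid_distribution(p, m)

  # total flux no greater than any FBA optimum at the same growth
  bb <- env_bounds(m, env)
  bb <- crossfeedr:::set_flux_equal(bb, match("BIOMASS", m$reaction_ids), 0.2)
  v_fba <- fba(m, bounds = bb)$values
  expect_lte(p$provenance$total_flux, sum(abs(v_fba)) + 1e-8)

  # and equals the independent dense split-LP oracle
  Sd <- as.matrix(m$S)
  A <- cbind(Sd, -Sd)
  lbv <- pmax(bb$lb, -1e6); ubv <- pmin(bb$ub, 1e6)
  prob <- list(list(A = A, b = numeric(nrow(A)), c = rep(1, 2 * ncol(Sd)),
                    lb = c(pmax(0, lbv), pmax(0, -ubv)),
                    ub = c(pmax(0, ubv), pmax(0, -lbv))))
  expect_equal(p$provenance$total_flux, scipy_lp_oracle(prob),
               tolerance = 1e-7)
})

test_that("a futile cycle carries no flux in the parsimonious optimum", {
  m <- make_core_fixture(futile_cycle = TRUE)
  p <- pfba(m, core_fixture_env(), growth_rate = 0.2)
  expect_equal(unname(p$values[c("FC1", "FC2", "FC3")]), rep(0, 3),
               tolerance = 1e-9)
})

test_that("the parsimonious ancestor fully oxidizes: CO2 is the only carbon excretion", {
  m <- make_core_fixture()
  p <- ancestral_state(m, core_fixture_env())
  expect_gt(unname(p$values[["EX_co2_e"]]), 0)
  expect_equal(unname(p$values[["EX_ace_e"]]), 0, tolerance = 1e-9)
  expect_equal(unname(p$values[["EX_glyc_e"]]), 0, tolerance = 1e-9)
  expect_equal(unname(-p$values[["EX_glc_e"]]), 11 / 15, tolerance = 1e-6)
})

test_that("minimal uptake matches a bisection oracle and is monotone in constraints", {
  m <- make_core_fixture()
  env <- core_fixture_env()
  base <- minimize_uptake(m, env, "EX_glc_e", fixed = c(BIOMASS = 0.2))
  expect_equal(base$uptake, 11 / 15, tolerance = 1e-6)
  expect_valid_distribution(base$flux, m)

  # bisection over glucose caps, testing feasibility at each cap
  feasible_at <- function(cap, extra = numeric(0)) {
    bb <- env_bounds(m, env)
    bb <- crossfeedr:::set_flux_equal(bb, match("BIOMASS", m$reaction_ids), 0.2)
    for (id in names(extra)) {
      bb <- crossfeedr:::set_flux_equal(bb, match(id, m$reaction_ids),
                                        extra[[id]])
    }
    bb$lb[match("EX_glc_e", m$reaction_ids)] <- -cap
    out <- crossfeedr:::lp_solve(m$S, numeric(nrow(m$S)),
                                 numeric(length(m$reaction_ids)),
                                 bb$lb, bb$ub, on_infeasible = "status")
    out$status == 0
  }
  bisect <- function(extra = numeric(0)) {
    lo <- 0; hi <- 10
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (feasible_at(mid, extra)) hi <- mid else lo <- mid
    }
    hi
  }
  expect_equal(base$uptake, bisect(), tolerance = 1e-6)

  # producer-style extra equality: oracle again, and never smaller
  withprod <- minimize_uptake(m, env, "EX_glc_e",
                              fixed = c(BIOMASS = 0.2, EX_ace_e = 1))
  expect_equal(withprod$uptake, bisect(c(EX_ace_e = 1)), tolerance = 1e-6)
  expect_gte(withprod$uptake, base$uptake)

  # nothing to sustain: zero growth needs zero uptake
  none <- minimize_uptake(m, env, "EX_glc_e", fixed = c(BIOMASS = 0))
  expect_equal(none$uptake, 0, tolerance = 1e-9)
})
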