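# ROOM, the joint heterogeneous-ancestor variant, MoMA and flux-change
# classification.

test_that("a reference that already satisfies the evolved constraints gives distance 0", {
  m <- make_core_fixture()
  env <- core_fixture_env()
  anc <- ancestral_state(m, env)
  bb <- env_bounds(m, env)
  bb <- crossfeedr:::set_flux_equal(bb, match("BIOMASS", m$reaction_ids), 0.2)
  res <- room(m, room_problem(anc, bb))
  expect_equal(res$distance, 0)
  expect_equal(length(res$changed), 0)
  expect_valid_distribution(res$evolved, m)

  # identical ancestor and evolved constraint sets: joint distance 0
  resh <- room_het(m, het_problem(bb, bb))
  expect_equal(resh$distance, 0)
})

test_that("exactly one reaction must flip in the one-flip network", {
  m <- one_flip_model()
  env <- chemostat_env(dilution_rate = 0.2, primary_carbon = "EX_s_e",
                       uptake_cap = 10)
  anc <- ancestral_state(m, env)
  ev <- env_bounds(m, env)
  ev <- crossfeedr:::set_flux_equal(ev, match("EX_y_e", m$reaction_ids), 0.1)
  res <- room(m, room_problem(anc, ev))
  expect_equal(res$distance, 1)
  expect_equal(res$changed, "Ysyn")
  expect_equal(brute_force_min_change(m, ev, reference = anc), 1)
})

test_that("ROOM and the brute-force subset oracle agree on the core fixture problems", {
  m <- make_core_fixture()
  env <- core_fixture_env()
  anc <- ancestral_state(m, env)
  expected <- c(EX_ace_e.producer = 4, EX_ace_e.consumer = 4,
                EX_glyc_e.producer = 3, EX_glyc_e.consumer = 4)
  for (met in c("EX_ace_e", "EX_glyc_e")) {
    for (role in c("producer", "consumer")) {
      ev <- build_strain_constraints(m, env, strain_spec(role, secondary = met))
      res <- room(m, room_problem(anc, ev))
      bf <- brute_force_min_change(m, ev, reference = anc)
      expect_equal(res$distance, as.integer(bf), info = paste(met, role))
      expect_equal(res$distance,
                   unname(expected[paste(met, role, sep = ".")]),
                   info = paste(met, role))
      expect_valid_distribution(res$evolved, m)
      # unchanged reactions really are within beta of the reference
      counted <- fixture_internal(m)
      unchanged <- setdiff(counted, res$changed)
      expect_lte(max(abs(res$evolved$values[unchanged] -
                           anc$values[unchanged])), 0.001 + 1e-6)
    }
  }
})

test_that("the joint optimization dominates fixed-reference ROOM", {
  m <- make_core_fixture()
  env <- core_fixture_env()
  anc <- ancestral_state(m, env)
  ab <- build_strain_constraints(m, env, strain_spec("ancestor"))
  for (met in c("EX_ace_e", "EX_glyc_e")) {
    for (role in c("producer", "consumer")) {
      ev <- build_strain_constraints(m, env, strain_spec(role, secondary = met))
      d_room <- room(m, room_problem(anc, ev))$distance
      het <- room_het(m, het_problem(ab, ev))
      expect_lte(het$distance, d_room)
      expect_equal(het$distance,
                   as.integer(brute_force_min_change(m, ev, ancestor = ab)))
      # the returned ancestor satisfies the ancestor constraint set
      expect_true(all(het$ancestor$values >= ab$lb - 1e-6 &
                        het$ancestor$values <= ab$ub + 1e-6))
      expect_valid_distribution(het$ancestor, m)
      expect_valid_distribution(het$evolved, m)
    }
  }
})

test_that("distance is non-increasing in beta", {
  m <- make_core_fixture()
  env <- core_fixture_env()
  anc <- ancestral_state(m, env)
  for (role in c("producer", "consumer")) {
    ev <- build_strain_constraints(m, env,
                                   strain_spec(role, secondary = "EX_ace_e"))
    d <- vapply(c(0.0002, 0.001, 0.005), function(beta) {
      room(m, room_problem(anc, ev, beta = beta))$distance
    }, numeric(1))
    expect_true(all(diff(d) <= 0))
    expect_lte(max(d) - min(d), 2) # near-insensitive on this fixture
  }
})

test_that("infeasible evolved constraints and node exhaustion raise typed errors", {
  m <- make_core_fixture()
  env <- core_fixture_env()
  anc <- ancestral_state(m, env)
  ev <- build_strain_constraints(m, env,
                                 strain_spec("producer", secondary = "EX_ace_e"))
  bad <- ev
  bad <- crossfeedr:::set_flux_equal(bad, match("EX_o2_e", m$reaction_ids), 0)
  bad <- crossfeedr:::set_flux_equal(bad, match("ATPM", m$reaction_ids), 50)
  expect_error(room(m, room_problem(anc, bad)),
               class = "crossfeedr_infeasible")
  err <- tryCatch(room(m, room_problem(anc, ev), node_limit = 2L),
                  crossfeedr_timeout = function(e) e)
  expect_s3_class(err, "crossfeedr_timeout")
  expect_match(conditionMessage(err), "best bound")
})

test_that("MoMA reduces to the reference when it is feasible, else to the affine projection", {
  m <- make_core_fixture()
  env <- core_fixture_env()
  anc <- ancestral_state(m, env)
  bb <- env_bounds(m, env)
  bb <- crossfeedr:::set_flux_equal(bb, match("BIOMASS", m$reaction_ids), 0.2)
  e0 <- moma(m, anc, bb)
  expect_equal(unname(e0$values), unname(anc$values), tolerance = 1e-6)
  expect_equal(e0$provenance$objective, 0, tolerance = 1e-9)

  # interior case: closed-form projection onto {S e = 0, e_R = 0.3}
  mr <- reversible_model()
  a <- c(U = 0.2, R = 0.2, BIOMASS = 0.2)
  ev <- list(lb = c(-5, 0.3, -5), ub = c(5, 0.3, 5))
  got <- moma(mr, a, ev)
  C <- rbind(as.matrix(mr$S), c(0, 1, 0))
  d <- c(0, 0, 0.3)
  proj <- a + t(C) %*% solve(C %*% t(C), d - C %*% a)
  expect_equal(unname(got$values), as.numeric(proj), tolerance = 1e-8)
})

test_that("MoMA changes at least as many reactions as ROOM minimally needs", {
  for (seed in 1:10) {
    m <- make_toy_network(n_internal = sample(4:6, 1), seed = seed,
                          reversible_fraction = 0.3)
    env <- attr(m, "env")
    anc <- ancestral_state(m, env)
    ev <- tryCatch(
      build_strain_constraints(m, env,
                               strain_spec("producer", secondary = "EX_bp1_e",
                                           excretion_rate = 0.3)),
      crossfeedr_infeasible = function(e) NULL)
    if (is.null(ev)) next
    d_room <- room(m, room_problem(anc, ev))$distance
    e_moma <- moma(m, anc, ev)
    counted <- fixture_internal(m)
    cl <- classify_changes(anc, e_moma, reactions = counted)
    expect_gte(cl$n_changed, d_room)
  }
})

test_that("flux-change classification matches its literal definition", {
  # constructed example
  a <- c(r1 = 0, r2 = 1, r3 = 2)
  e <- c(r1 = 1, r2 = 0, r3 = 2.5)
  cl <- classify_changes(a, e, beta = 0.001, activity_threshold = 0.001)
  expect_equal(cl$turned_on, "r1")
  expect_equal(cl$turned_off, "r2")
  expect_equal(cl$magnitude_change, "r3")

  # identity
  cl0 <- classify_changes(a, a)
  expect_equal(cl0$n_changed, 0)

  # random vectors vs the one-line oracle
  set.seed(11)
  for (k in 1:50) {
    n <- sample(5:30, 1)
    av <- round(rnorm(n, 0, 1), 3)
    evv <- av + sample(c(0, 0.0005, 0.1, -0.2), n, replace = TRUE)
    names(av) <- names(evv) <- paste0("r", seq_len(n))
    beta <- 0.001; thr <- 0.001
    cl <- classify_changes(av, evv, beta, thr)
    orc <- classify_oracle(av, evv, beta, thr)
    expect_equal(cl$turned_on, names(av)[orc$on])
    expect_equal(cl$turned_off, names(av)[orc$off])
    expect_equal(cl$magnitude_change, names(av)[orc$mag])
    # partition property
    expect_equal(sort(c(cl$turned_on, cl$turned_off, cl$magnitude_change)),
                 sort(names(av)[abs(evv - av) > beta]))
  }
  expect_error(classify_changes(a, e[1:2]),
               class = "crossfeedr_contract_error")
})
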