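# Gene, operon and regulon mapping of changed reactions, and the
# expression-concordance Fisher tests.

test_that("genes behind reaction sets are the union of GPR leaves", {
  m <- make_core_fixture()
  g <- genes_for_reactions(m, c("GPTS", "TCA", "ACEt"))
  expect_setequal(g, c("gA1", "gA2", "gB1", "gB2", "gB3", "gD1", "gD2"))
  expect_length(attr(g, "unmapped"), 0)

  # reactions with empty GPR contribute nothing and are listed unmapped
  g2 <- genes_for_reactions(m, c("GPTS", "ATPM"))
  expect_setequal(as.character(g2), c("gA1", "gA2"))
  expect_equal(attr(g2, "unmapped"), "ATPM")

  expect_error(genes_for_reactions(m, "NOPE"),
               class = "crossfeedr_contract_error")

  # hand enumeration on overlapping GPRs
  for (seed in 1:5) {
    toy <- make_toy_network(seed = seed, gpr_density = 2)
    ids <- sample(fixture_internal(toy), 4)
    by_hand <- unique(unlist(lapply(
      toy$gpr[match(ids, toy$reaction_ids)], gpr_oracle_genes)))
    expect_setequal(as.character(genes_for_reactions(toy, ids)),
                    by_hand)
  }
})

test_that("gene impact aggregates operon and regulon counts", {
  tabs <- core_fixture_annotations()
  gi <- aggregate_gene_impact(c("gA1", "gA2", "gB1"), tabs)
  expect_equal(gi$n_genes, 3)
  expect_equal(gi$n_operons, 2) # opA, opB
  expect_equal(gi$n_regulons, 2) # crpR, arcR
  expect_false(gi$missing_annotation)

  # empty tables: counts 0 with the missing-annotation flag
  gi0 <- aggregate_gene_impact(c("g1", "g2"), empty_annotations())
  expect_equal(gi0$n_genes, 2)
  expect_equal(gi0$n_operons, 0)
  expect_equal(gi0$n_regulons, 0)
  expect_true(gi0$missing_annotation)

  # random toy tables vs brute-force set construction; monotone under union
  set.seed(3)
  genes <- paste0("g", 1:40)
  ops <- setNames(sample(paste0("op", 1:12), 40, replace = TRUE), genes)
  regs <- setNames(lapply(genes, function(g)
    sample(paste0("rg", 1:8), sample(1:3, 1))), genes)
  tabs2 <- structure(list(gene_to_operon = ops, gene_to_regulon = regs,
                          expression = NULL), class = "annotation_tables")
  sub1 <- sample(genes, 10); sub2 <- sample(genes, 15)
  for (gs in list(sub1, sub2, union(sub1, sub2))) {
    gi <- aggregate_gene_impact(gs, tabs2)
    expect_equal(gi$n_operons, length(unique(unname(ops[gs]))))
    expect_equal(gi$n_regulons, length(unique(unlist(regs[gs]))))
  }
  gu <- aggregate_gene_impact(union(sub1, sub2), tabs2)
  for (gs in list(sub1, sub2)) {
    gi <- aggregate_gene_impact(gs, tabs2)
    expect_lte(gi$n_genes, gu$n_genes)
    expect_lte(gi$n_operons, gu$n_operons)
    expect_lte(gi$n_regulons, gu$n_regulons)
  }
})

test_that("per-gene direction calls follow the reaction flux magnitudes", {
  m <- make_core_fixture()
  a <- setNames(numeric(17), m$reaction_ids)
  e <- a
  a["GPTS"] <- 0.7; e["GPTS"] <- 1.1  # |e| > |a| + beta: up
  a["TCA"] <- 0.3; e["TCA"] <- 0      # down
  a["PRE1"] <- 0.4; e["PRE1"] <- 0.4  # unchanged
  obs <- c(gA1 = "up", gA2 = "down", gB1 = "down", gF1 = "unchanged")
  out <- expression_concordance(m, a, e, obs)
  up <- out[out$category == "up", ]
  expect_equal(up$true_positives, 1) # gA1 predicted up, observed up
  expect_equal(up$false_positives, 1) # gA2 predicted up, observed down
  dn <- out[out$category == "down", ]
  expect_equal(dn$true_positives, 1) # gB1
  expect_error(expression_concordance(m, a, e, character(0)),
               class = "crossfeedr_contract_error")
})

test_that("all-unchanged predictions against all-unchanged observations give p = 1", {
  m <- make_core_fixture()
  a <- setNames(numeric(17), m$reaction_ids)
  obs <- setNames(rep("unchanged", 4), c("gA1", "gB1", "gC1", "gF1"))
  out <- expression_concordance(m, a, a, obs)
  expect_true(all(out$p_value == 1))
  expect_equal(out$true_positives[out$category == "unchanged"], 4)
})

test_that("concordance p-values equal the hypergeometric oracle on a planted table", {
  # chain model with one gene per reaction; plant ~30% concordance
  set.seed(42)
  n <- 200
  mets <- c(paste0("m", 1:(n + 1), "_c"))
  rxns <- lapply(seq_len(n), function(i) {
    list(id = sprintf("R%03d", i),
         stoich = setNames(c(-1, 1), mets[c(i, i + 1)]),
         lb = -1000, ub = 1000, gpr = sprintf("g%03d", i),
         subsystem = "chain")
  })
  rxns <- c(list(list(id = "SRC", stoich = setNames(1, mets[1]), lb = -1000,
                      ub = 1000, gpr = "", subsystem = "supply")),
            rxns,
            list(list(id = "BIOMASS", stoich = setNames(-1, mets[n + 1]),
                      lb = 0, ub = 1000, gpr = "", subsystem = "biomass")))
  m <- crossfeedr:::build_model_from_rxns("planted", mets, rxns,
                                          biomass = "BIOMASS",
                                          demand = character(0))
  a <- setNames(rep(1, n + 2), m$reaction_ids)
  e <- a
  pred_dir <- sample(c("up", "down", "unchanged"), n, replace = TRUE)
  e[sprintf("R%03d", which(pred_dir == "up"))] <- 1.5
  e[sprintf("R%03d", which(pred_dir == "down"))] <- 0.4
  obs <- ifelse(runif(n) < 0.3, pred_dir,
                sample(c("up", "down", "unchanged"), n, replace = TRUE))
  names(obs) <- sprintf("g%03d", seq_len(n))
  out <- expression_concordance(m, a, e, obs)
  for (i in seq_len(nrow(out))) {
    aa <- out$true_positives[i]
    bb <- out$false_positives[i]
    cc <- out$n_observed[i] - aa
    dd <- attr(out, "n_genes") - aa - bb - cc
    expect_equal(out$p_value[i], hyper_fisher_p(aa, bb, cc, dd),
                 tolerance = 1e-10)
  }
})
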