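# Model construction, serialization round-trips, role detection, GPR
# parsing and annotation tables.

test_that("a minimal hand-written model loads with the expected shape", {
  f <- tempfile(fileext = ".json")
  write_model_json(chain_model(), f)
  m <- load_model(f, dialect = "bigg_json")
  expect_equal(length(m$metabolite_ids), 2)
  expect_equal(length(m$reaction_ids), 3)
  expect_equal(sum(m$reaction_role == "biomass"), 1)
  expect_equal(m$reaction_role,
               c("exchange", "internal", "biomass"))
})

test_that("JSON round-trip is a fixed point for S, lb and ub", {
  m1 <- make_core_fixture()
  f <- tempfile(fileext = ".json")
  write_model_json(m1, f)
  m2 <- load_model(f, dialect = "bigg_json")
  expect_identical(as.matrix(m1$S), as.matrix(m2$S))
  expect_identical(m1$lb, m2$lb)
  expect_identical(m1$ub, m2$ub)
  expect_identical(m1$reaction_ids, m2$reaction_ids)
  expect_identical(m1$reaction_role, m2$reaction_role)
  expect_identical(m1$gpr, m2$gpr)
  # and a second round trip reproduces the file exactly
  f2 <- tempfile(fileext = ".json")
  write_model_json(m2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("the committed fixture file matches the in-code generator", {
  path <- system.file("extdata", "core_fixture.json", package = "crossfeedr")
  m1 <- load_model(path)
  m2 <- make_core_fixture()
  expect_identical(as.matrix(m1$S), as.matrix(m2$S))
  expect_identical(m1$lb, m2$lb)
  expect_identical(m1$ub, m2$ub)
})

test_that("SBML-FBC models load with bounds, GPRs and compartments", {
  path <- system.file("extdata", "chain_model.xml", package = "crossfeedr")
  m <- load_model(path, dialect = "sbml_fbc")
  expect_equal(length(m$metabolite_ids), 2)
  expect_equal(length(m$reaction_ids), 3)
  expect_equal(m$lb, c(-10, 0, 0))
  expect_equal(m$ub, c(1000, 1000, 1000))
  expect_equal(m$biomass_reaction_id, "BIOMASS")
  expect_equal(m$reaction_role[1], "exchange")
  expect_setequal(gpr_genes(m$gpr[2]), c("gT", "gU"))
})

test_that("format errors name the offending element", {
  f <- tempfile(fileext = ".json")
  writeLines("{not json", f)
  expect_error(load_model(f), class = "crossfeedr_format_error")
  jsonlite::write_json(list(metabolites = list()), f, auto_unbox = TRUE)
  expect_error(load_model(f), class = "crossfeedr_format_error",
               regexp = "reactions")
  expect_error(load_model(tempfile()), class = "crossfeedr_format_error")
})

test_that("a model without a biomass reaction is rejected", {
  expect_error(
    metabolic_model("x", "a_c", "R1", matrix(1, 1, 1), 0, 10,
                    biomass_reaction_id = "nope"),
    class = "crossfeedr_model_error")
})

test_that("exchange detection agrees with a brute-force column scan", {
  for (seed in 1:5) {
    m <- make_toy_network(n_internal = 5, by_products = c("bp1", "bp2"),
                          seed = seed)
    nz <- Matrix::colSums(m$S != 0)
    brute <- vapply(seq_along(m$reaction_ids), function(j) {
      if (m$reaction_ids[j] == m$biomass_reaction_id) return(FALSE)
      if (m$reaction_ids[j] %in% m$demand_reactions) return(FALSE)
      nz[j] == 1 &&
        m$metabolite_compartment[which(m$S[, j] != 0)] == "e"
    }, logical(1))
    expect_identical(m$reaction_role == "exchange", brute)
  }
})

test_that("GPR parsing matches an independent re-parse on gene sets and truth tables", {
  rules <- c("b0001 and b0002",
             "(g1 or g2) and g3",
             "g1 or (g2 and g3) or (g4 and (g5 or g6))",
             "((g1))",
             "g1 and g2 and g3 or g4")
  set.seed(7)
  for (rule in rules) {
    tree <- parse_gpr(rule)
    expect_setequal(gpr_genes(tree), gpr_oracle_genes(rule))
    genes <- gpr_oracle_genes(rule)
    for (k in 1:20) {
      asg <- setNames(as.list(runif(length(genes)) > 0.5), genes)
      expect_identical(gpr_tree_eval(tree, asg),
                       gpr_oracle_eval(rule, asg),
                       info = rule)
    }
  }
})

test_that("GPR corner cases: empty rule, two-gene complex, syntax errors", {
  expect_identical(gpr_genes(parse_gpr("")), character(0))
  tr <- parse_gpr("b0001 and b0002")
  expect_equal(tr$type, "and")
  expect_setequal(gpr_genes(tr), c("b0001", "b0002"))
  expect_error(parse_gpr("(g1 and g2"), class = "crossfeedr_gpr_syntax_error")
  expect_error(parse_gpr("g1 and and g2"),
               class = "crossfeedr_gpr_syntax_error")
  expect_error(parse_gpr("g1 g2)"), class = "crossfeedr_gpr_syntax_error")
})

test_that("annotation tables load, reject duplicates, tolerate empties", {
  op <- system.file("extdata", "toy_operons.tsv", package = "crossfeedr")
  rg <- system.file("extdata", "toy_regulons.tsv", package = "crossfeedr")
  ex <- system.file("extdata", "toy_expression.tsv", package = "crossfeedr")
  tab <- load_annotations(op, rg, ex)
  expect_equal(length(tab$gene_to_operon), 15)
  expect_equal(unname(tab$gene_to_operon["gA1"]), "opA")
  expect_setequal(tab$gene_to_regulon[["gB1"]], c("crpR", "arcR"))
  expect_equal(nrow(tab$expression), 30)

  f <- tempfile(fileext = ".tsv")
  writeLines("gene\toperon", f)
  expect_equal(length(load_annotations(f)$gene_to_operon), 0)

  writeLines(c("gene\toperon", "g1\topA", "g1\topB"), f)
  expect_error(load_annotations(f), class = "crossfeedr_format_error",
               regexp = "duplicate")

  writeLines(c("gene\toperon", "g1\t"), f)
  expect_error(load_annotations(f), class = "crossfeedr_format_error",
               regexp = "row")
})
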