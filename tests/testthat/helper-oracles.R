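# Independent oracles used across the test suite. Each one deliberately
# re-derives its quantity by a different route than the package code.

# Batched dense-LP oracle: scipy's HiGHS solver via the system python.
# Takes a list of problems (A, b, c, lb, ub), returns optimal objectives
# (NA where scipy reports infeasible/unbounded).
scipy_lp_oracle <- function(problems) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(problems, fin, digits = NA, matrix = "rowmajor")
  script <- paste(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    sprintf("probs = json.load(open(%s))", deparse(fin)),
    "out = []",
    "for p in probs:",
    "    A = np.atleast_2d(np.array(p['A'], dtype=float))",
    "    res = linprog(np.array(p['c'], dtype=float), A_eq=A,",
    "                  b_eq=np.array(p['b'], dtype=float),",
    "                  bounds=list(zip(p['lb'], p['ub'])), method='highs')",
    "    out.append(res.fun if res.status == 0 else None)",
    sprintf("json.dump(out, open(%s, 'w'))", deparse(fout)),
    sep = "\n")
  status <- system2("python", c("-c", shQuote(script)))
  if (status != 0) stop("LP oracle run failed (python/scipy)")
  vals <- jsonlite::read_json(fout, simplifyVector = FALSE)
  vapply(vals, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
         numeric(1))
}

# Two-sided Fisher exact p for a 2x2 table by direct hypergeometric
# point-probability summation (sum of all outcomes no more probable than
# the observed one, with the same relative tolerance R's fisher.test uses).
hyper_fisher_p <- function(a, b, c, d) {
  m <- a + b # margin: row 1
  n <- c + d # row 2
  k <- a + c # column 1
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  dens <- dhyper(support, m, n, k)
  p0 <- dhyper(a, m, n, k)
  sum(dens[dens <= p0 * (1 + 1e-7)])
}

# Independent GPR re-parse: rewrite the rule as an R logical expression
# and use R's own parser.
gpr_oracle_genes <- function(rule_text) {
  if (trimws(rule_text) == "") return(character(0))
  expr_text <- gsub("\\bor\\b", "|", gsub("\\band\\b", "&", rule_text,
                                          ignore.case = TRUE),
                    ignore.case = TRUE)
  sort(unique(all.vars(parse(text = expr_text)[[1]])))
}

# Evaluate the rule under a named logical assignment, via R's parser.
gpr_oracle_eval <- function(rule_text, assignment) {
  expr_text <- gsub("\\bor\\b", "||", gsub("\\band\\b", "&&", rule_text,
                                           ignore.case = TRUE),
                    ignore.case = TRUE)
  eval(parse(text = expr_text)[[1]], envir = as.list(assignment))
}

# Evaluate the package's parsed GPR tree under the same assignment.
gpr_tree_eval <- function(tree, assignment) {
  switch(tree$type,
         empty = TRUE,
         gene = assignment[[tree$gene]],
         and = all(vapply(tree$children, gpr_tree_eval, logical(1),
                          assignment = assignment)),
         or = any(vapply(tree$children, gpr_tree_eval, logical(1),
                         assignment = assignment)))
}

# Literal re-statement of the flux-change classification definitions.
classify_oracle <- function(a, e, beta, thr) {
  changed <- abs(e - a) > beta
  on <- changed & abs(a) <= thr & abs(e) > thr
  off <- changed & abs(a) > thr & abs(e) <= thr
  mag <- changed & !on & !off
  list(on = which(on), off = which(off), mag = which(mag))
}

# Steady-state and bound check used by several invariant tests.
expect_valid_distribution <- function(fd, model, tol = 1e-6) {
  expect_lte(max(abs(as.numeric(model$S %*% fd$values))), tol)
}
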