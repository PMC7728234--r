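# Reading, validating and serializing metabolic models.
#
# Two dialects are supported: BiGG-style JSON and SBML Level 3 with the
# `fbc` package. Reaction and metabolite order always follows file order.
# Sign convention: for an exchange reaction, negative flux is uptake and
# positive flux is secretion.

#' Construct a metabolic model
#'
#' Builds the numerical structure used by every optimizer in the package:
#' the sparse stoichiometric matrix `S` (metabolites x reactions), flux
#' bounds, per-reaction roles and gene-protein-reaction (GPR) rules.
#'
#' @param id model identifier.
#' @param metabolite_ids character vector of metabolite identifiers. A
#'   metabolite is taken as extracellular when its compartment (explicit via
#'   `metabolite_compartment`, or the `_e` id suffix) is `"e"`.
#' @param reaction_ids character vector of reaction identifiers.
#' @param S stoichiometric matrix, `length(metabolite_ids)` rows by
#'   `length(reaction_ids)` columns (dense or sparse).
#' @param lb,ub lower/upper flux bounds, mmol gDW^-1 h^-1 (the biomass
#'   reaction is in h^-1).
#' @param biomass_reaction_id id of the single biomass reaction.
#' @param gpr character vector of boolean gene rules (`""` for none).
#' @param subsystem optional character vector of pathway labels.
#' @param metabolite_compartment optional compartment codes; inferred from
#'   id suffixes (`_e` / `_c`, or trailing `[e]`-style tags) when `NULL`.
#' @param demand_reactions reaction ids explicitly flagged as demand/sink
#'   reactions (single-metabolite columns on internal metabolites, e.g.
#'   ATP maintenance); these keep role `internal`.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolite_ids, reaction_ids, S, lb, ub,
                            biomass_reaction_id, gpr = NULL, subsystem = NULL,
                            metabolite_compartment = NULL,
                            demand_reactions = character()) {
  m <- length(metabolite_ids)
  r <- length(reaction_ids)
  S <- Matrix::Matrix(S, sparse = TRUE)
  dimnames(S) <- NULL # ids live in metabolite_ids/reaction_ids
  cf_assert(nrow(S) == m && ncol(S) == r, "crossfeedr_model_error",
            sprintf("S must be %d x %d, got %d x %d", m, r, nrow(S), ncol(S)))
  cf_assert(length(lb) == r && length(ub) == r, "crossfeedr_model_error",
            "lb and ub must have one entry per reaction")
  cf_assert(all(lb <= ub), "crossfeedr_model_error",
            sprintf("lb > ub for reaction(s): %s",
                    paste(reaction_ids[lb > ub], collapse = ", ")))
  cf_assert(!anyDuplicated(reaction_ids) && !anyDuplicated(metabolite_ids),
            "crossfeedr_model_error", "duplicate reaction or metabolite ids")
  cf_assert(biomass_reaction_id %in% reaction_ids, "crossfeedr_model_error",
            sprintf("biomass reaction '%s' not in model", biomass_reaction_id))
  if (is.null(gpr)) gpr <- rep("", r)
  if (is.null(subsystem)) subsystem <- rep("unassigned", r)
  subsystem[is.na(subsystem) | subsystem == ""] <- "unassigned"
  if (is.null(metabolite_compartment)) {
    metabolite_compartment <- infer_compartment(metabolite_ids)
  }

  role <- classify_reaction_roles(S, reaction_ids, metabolite_compartment,
                                  biomass_reaction_id, demand_reactions)

  # structural invariants
  nz <- Matrix::colSums(S != 0)
  zero_ok <- reaction_ids %in% demand_reactions
  cf_assert(all(nz > 0 | zero_ok), "crossfeedr_model_error",
            sprintf("all-zero stoichiometry column(s): %s",
                    paste(reaction_ids[nz == 0 & !zero_ok], collapse = ", ")))
  exch <- which(role == "exchange")
  cf_assert(all(nz[exch] == 1), "crossfeedr_model_error",
            "every exchange reaction must touch exactly one metabolite")

  structure(
    list(id = id,
         metabolite_ids = metabolite_ids,
         metabolite_compartment = metabolite_compartment,
         reaction_ids = reaction_ids,
         S = S, lb = as.numeric(lb), ub = as.numeric(ub),
         reaction_role = role,
         gpr = gpr,
         subsystem = subsystem,
         biomass_reaction_id = biomass_reaction_id,
         demand_reactions = demand_reactions),
    class = "metabolic_model")
}

infer_compartment <- function(met_ids) {
  comp <- rep("c", length(met_ids))
  comp[grepl("_e$|\\[e\\]$", met_ids)] <- "e"
  comp
}

# A reaction is an exchange iff its column touches exactly one metabolite
# and that metabolite is extracellular; explicitly flagged demand/sink
# reactions and the biomass reaction are never exchanges.
classify_reaction_roles <- function(S, reaction_ids, compartment,
                                    biomass_reaction_id, demand_reactions) {
  nz <- Matrix::colSums(S != 0)
  only_met <- function(j) which(S[, j] != 0)[1]
  role <- rep("internal", length(reaction_ids))
  for (j in seq_along(reaction_ids)) {
    if (reaction_ids[j] == biomass_reaction_id) { role[j] <- "biomass"; next }
    if (reaction_ids[j] %in% demand_reactions) next
    if (nz[j] == 1 && compartment[only_met(j)] == "e") role[j] <- "exchange"
  }
  role
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites x %d reactions\n",
              x$id, length(x$metabolite_ids), length(x$reaction_ids)))
  cat(sprintf("  roles: %d internal, %d exchange, biomass = %s\n",
              sum(x$reaction_role == "internal"),
              sum(x$reaction_role == "exchange"), x$biomass_reaction_id))
  invisible(x)
}

rxn_index <- function(model, id) {
  i <- match(id, model$reaction_ids)
  cf_assert(!anyNA(i), "crossfeedr_contract_error",
            sprintf("unknown reaction id(s): %s",
                    paste(id[is.na(i)], collapse = ", ")))
  i
}

internal_indices <- function(model) which(model$reaction_role == "internal")

#' Load a genome-scale metabolic model
#'
#' @param path path to the model file.
#' @param dialect `"bigg_json"` for BiGG-style JSON, `"sbml_fbc"` for SBML
#'   Level 3 with the fbc package.
#' @return a [metabolic_model()].
#' @export
load_model <- function(path, dialect = c("bigg_json", "sbml_fbc")) {
  dialect <- match.arg(dialect)
  cf_assert(file.exists(path), "crossfeedr_format_error",
            sprintf("model file not found: %s", path))
  switch(dialect,
         bigg_json = load_model_bigg_json(path),
         sbml_fbc = load_model_sbml(path))
}

load_model_bigg_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) cf_abort(
                    "crossfeedr_format_error",
                    sprintf("cannot parse JSON model '%s': %s",
                            path, conditionMessage(e))))
  for (field in c("metabolites", "reactions")) {
    cf_assert(!is.null(doc[[field]]), "crossfeedr_format_error",
              sprintf("JSON model lacks required element '%s'", field))
  }
  met_ids <- vapply(doc$metabolites, function(m) m$id, character(1))
  comp <- vapply(doc$metabolites, function(m) {
    if (!is.null(m$compartment)) as.character(m$compartment) else NA_character_
  }, character(1))
  if (anyNA(comp)) comp <- infer_compartment(met_ids)

  rxns <- doc$reactions
  rxn_ids <- vapply(rxns, function(x) x$id, character(1))
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (j in seq_along(rxns)) {
    mets <- rxns[[j]]$metabolites
    if (length(mets) == 0) next
    idx <- match(names(mets), met_ids)
    cf_assert(!anyNA(idx), "crossfeedr_format_error",
              sprintf("reaction '%s' references unknown metabolite '%s'",
                      rxn_ids[j], names(mets)[is.na(idx)][1]))
    ii <- c(ii, idx); jj <- c(jj, rep(j, length(idx)))
    vv <- c(vv, vapply(mets, as.numeric, numeric(1)))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(length(met_ids), length(rxn_ids)))
  lb <- vapply(rxns, function(x) as.numeric(x$lower_bound), numeric(1))
  ub <- vapply(rxns, function(x) as.numeric(x$upper_bound), numeric(1))
  gpr <- vapply(rxns, function(x) {
    if (is.null(x$gene_reaction_rule)) "" else as.character(x$gene_reaction_rule)
  }, character(1))
  subsystem <- vapply(rxns, function(x) {
    if (is.null(x$subsystem)) "" else as.character(x$subsystem)
  }, character(1))

  biomass <- find_biomass_reaction(doc, rxn_ids)
  demand <- vapply(rxns, function(x) isTRUE(x$demand) ||
                     isTRUE(x$annotation$demand), logical(1))
  # conventional maintenance pseudo-reaction ids count as flagged demands
  demand <- demand | grepl("^(ATPM|DM_)", rxn_ids)

  metabolic_model(
    id = if (!is.null(doc$id)) doc$id else basename(path),
    metabolite_ids = met_ids, reaction_ids = rxn_ids, S = S,
    lb = lb, ub = ub, biomass_reaction_id = biomass, gpr = gpr,
    subsystem = subsystem, metabolite_compartment = comp,
    demand_reactions = rxn_ids[demand])
}

find_biomass_reaction <- function(doc, rxn_ids) {
  # BiGG convention: objective_coefficient 1, or an id containing BIOMASS
  obj <- vapply(doc$reactions, function(x) {
    oc <- x$objective_coefficient
    !is.null(oc) && as.numeric(oc) != 0
  }, logical(1))
  if (any(obj)) return(rxn_ids[which(obj)[1]])
  hit <- grepl("biomass", rxn_ids, ignore.case = TRUE)
  cf_assert(any(hit), "crossfeedr_model_error",
            "model declares no biomass reaction (no objective coefficient, no BIOMASS id)")
  rxn_ids[which(hit)[1]]
}

load_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) cf_abort(
                    "crossfeedr_format_error",
                    sprintf("cannot parse SBML '%s': %s", path,
                            conditionMessage(e))))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  cf_assert(length(species) > 0, "crossfeedr_format_error",
            "SBML model has no species (is it Level 3 core?)")
  met_ids <- xml2::xml_attr(species, "id")
  comp <- xml2::xml_attr(species, "compartment")
  comp[is.na(comp)] <- "c"

  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                   xml2::xml_attr(params, "id"))

  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxn_ids <- xml2::xml_attr(rx, "id")
  lb <- ub <- numeric(length(rx))
  gpr <- character(length(rx))
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  bound_of <- function(node, attr, default) {
    ref <- xml2::xml_attr(node, attr) # xml2 matches sans namespace prefix
    if (is.na(ref)) return(default)
    if (!is.na(suppressWarnings(as.numeric(ref)))) return(as.numeric(ref))
    cf_assert(ref %in% names(pval), "crossfeedr_format_error",
              sprintf("fbc bound parameter '%s' undefined", ref))
    pval[[ref]]
  }
  for (j in seq_along(rx)) {
    node <- rx[[j]]
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb[j] <- bound_of(node, "lowerFluxBound", if (rev) -1000 else 0)
    ub[j] <- bound_of(node, "upperFluxBound", 1000)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(node, sprintf("./s:%s/s:speciesReference", side), ns)
      if (length(refs) == 0) next
      sp <- xml2::xml_attr(refs, "species")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      idx <- match(sp, met_ids)
      cf_assert(!anyNA(idx), "crossfeedr_format_error",
                sprintf("reaction '%s' references unknown species '%s'",
                        rxn_ids[j], sp[is.na(idx)][1]))
      ii <- c(ii, idx); jj <- c(jj, rep(j, length(idx))); vv <- c(vv, sgn * st)
    }
    ga <- xml2::xml_find_first(node, ".//fbc:geneProductAssociation", ns)
    gpr[j] <- if (inherits(ga, "xml_missing")) "" else sbml_gpr_text(ga, ns)
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(length(met_ids), length(rxn_ids)))

  # biomass: fbc active objective
  obj_ref <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  biomass <- if (!inherits(obj_ref, "xml_missing")) {
    xml2::xml_attr(obj_ref, "reaction")
  } else {
    hit <- grepl("biomass", rxn_ids, ignore.case = TRUE)
    cf_assert(any(hit), "crossfeedr_model_error", "no biomass reaction found")
    rxn_ids[which(hit)[1]]
  }
  metabolic_model(
    id = xml2::xml_attr(xml2::xml_find_first(doc, ".//s:model", ns), "id"),
    metabolite_ids = met_ids, reaction_ids = rxn_ids, S = S,
    lb = lb, ub = ub, biomass_reaction_id = biomass, gpr = gpr,
    metabolite_compartment = sub("^C_", "", comp))
}

sbml_gpr_text <- function(node, ns) {
  nm <- xml2::xml_name(node)
  kids <- xml2::xml_children(node)
  if (nm == "geneProductRef") {
    g <- xml2::xml_attr(node, "geneProduct")
    return(sub("^G_", "", g))
  }
  parts <- vapply(kids, sbml_gpr_text, character(1), ns = ns)
  parts <- parts[parts != ""]
  if (nm == "and") return(paste0("(", paste(parts, collapse = " and "), ")"))
  if (nm == "or") return(paste0("(", paste(parts, collapse = " or "), ")"))
  if (length(parts) == 1) return(parts)
  ""
}

#' Serialize a model to BiGG-style JSON
#'
#' Round-trip stable: `load_model(write_model_json(m, f))` reproduces `S`,
#' `lb` and `ub` bit-exactly.
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  mets <- lapply(seq_along(model$metabolite_ids), function(i) {
    list(id = model$metabolite_ids[i],
         compartment = model$metabolite_compartment[i])
  })
  Sd <- as.matrix(model$S)
  rxns <- lapply(seq_along(model$reaction_ids), function(j) {
    nz <- which(Sd[, j] != 0)
    out <- list(
      id = model$reaction_ids[j],
      metabolites = as.list(setNames(Sd[nz, j], model$metabolite_ids[nz])),
      lower_bound = model$lb[j],
      upper_bound = model$ub[j],
      gene_reaction_rule = model$gpr[j],
      subsystem = model$subsystem[j])
    if (model$reaction_ids[j] == model$biomass_reaction_id) {
      out$objective_coefficient <- 1
    }
    if (model$reaction_ids[j] %in% model$demand_reactions) out$demand <- TRUE
    out
  })
  jsonlite::write_json(list(id = model$id, metabolites = mets,
                            reactions = rxns),
                       path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

# GPR rules -----------------------------------------------------------------

#' Parse a gene-protein-reaction rule
#'
#' Parses a boolean rule such as `"(b0001 and b0002) or b0003"` into a tree
#' of `and` / `or` nodes over gene leaves. Empty text gives an empty rule.
#'
#' @param rule_text the rule string (case-insensitive `and` / `or`,
#'   parentheses, gene tokens).
#' @return list with `type` (`"gene"`, `"and"`, `"or"`, `"empty"`),
#'   `children` or `gene`, of class `gpr_rule`.
#' @export
parse_gpr <- function(rule_text) {
  stopifnot(is.character(rule_text), length(rule_text) == 1)
  txt <- trimws(rule_text)
  if (txt == "") {
    return(structure(list(type = "empty"), class = "gpr_rule"))
  }
  toks <- gpr_tokenize(txt)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  tree <- gpr_parse_or(st)
  cf_assert(st$pos > length(st$toks), "crossfeedr_gpr_syntax_error",
            sprintf("trailing tokens in GPR rule near '%s'",
                    st$toks[st$pos]))
  structure(tree, class = "gpr_rule")
}

gpr_tokenize <- function(txt) {
  txt <- gsub("([()])", " \\1 ", txt)
  toks <- strsplit(txt, "\\s+")[[1]]
  toks[toks != ""]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
gpr_take <- function(st) { t <- gpr_peek(st); st$pos <- st$pos + 1L; t }

gpr_parse_or <- function(st) {
  kids <- list(gpr_parse_and(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    gpr_take(st)
    kids <- c(kids, list(gpr_parse_and(st)))
  }
  if (length(kids) == 1) kids[[1]] else list(type = "or", children = kids)
}

gpr_parse_and <- function(st) {
  kids <- list(gpr_parse_atom(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    gpr_take(st)
    kids <- c(kids, list(gpr_parse_atom(st)))
  }
  if (length(kids) == 1) kids[[1]] else list(type = "and", children = kids)
}

gpr_parse_atom <- function(st) {
  t <- gpr_take(st)
  cf_assert(!is.na(t), "crossfeedr_gpr_syntax_error",
            "unexpected end of GPR rule")
  if (t == "(") {
    inner <- gpr_parse_or(st)
    cf_assert(identical(gpr_take(st), ")"), "crossfeedr_gpr_syntax_error",
              "unbalanced parentheses in GPR rule")
    return(inner)
  }
  cf_assert(t != ")" && !(tolower(t) %in% c("and", "or")),
            "crossfeedr_gpr_syntax_error",
            sprintf("unexpected token '%s' in GPR rule", t))
  list(type = "gene", gene = t)
}

#' Genes named by a GPR rule
#'
#' @param rule a `gpr_rule` from [parse_gpr()], or a rule string.
#' @return character vector of gene ids (empty for the empty rule).
#' @export
gpr_genes <- function(rule) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  collect <- function(nd) {
    switch(nd$type,
           empty = character(0),
           gene = nd$gene,
           unlist(lapply(nd$children, collect)))
  }
  unique(collect(rule))
}

# Annotation tables ----------------------------------------------------------

#' Load gene annotation tables
#'
#' Reads tab-separated tables with header rows mapping genes to operons, to
#' regulons, and (optionally) to observed expression changes per strain.
#'
#' @param operon_path TSV with columns `gene`, `operon` (one row per gene).
#' @param regulon_path TSV with columns `gene`, `regulon` (a gene may
#'   appear in several rows, one per regulon).
#' @param expression_path optional TSV with columns `gene`, `strain`,
#'   `change` (`up` / `down` / `unchanged`).
#' @return list with `gene_to_operon` (named character),
#'   `gene_to_regulon` (named list of character vectors), `expression`
#'   (data.frame or `NULL`); class `annotation_tables`.
#' @export
load_annotations <- function(operon_path = NULL, regulon_path = NULL,
                             expression_path = NULL) {
  read_tsv_checked <- function(path, required) {
    df <- tryCatch(read.delim(path, sep = "\t", stringsAsFactors = FALSE),
                   error = function(e) cf_abort(
                     "crossfeedr_format_error",
                     sprintf("cannot read TSV '%s': %s", path,
                             conditionMessage(e))))
    missing <- setdiff(required, names(df))
    cf_assert(length(missing) == 0, "crossfeedr_format_error",
              sprintf("'%s' lacks column(s): %s", path,
                      paste(missing, collapse = ", ")))
    bad <- which(apply(df[required], 1, function(r) any(is.na(r) | r == "")))
    cf_assert(length(bad) == 0, "crossfeedr_format_error",
              sprintf("malformed row %d in '%s'",
                      if (length(bad)) bad[1] + 1L else 0L, path))
    df
  }

  gene_to_operon <- character(0)
  if (!is.null(operon_path)) {
    op <- read_tsv_checked(operon_path, c("gene", "operon"))
    dup <- op$gene[duplicated(op$gene)]
    cf_assert(length(dup) == 0, "crossfeedr_format_error",
              sprintf("duplicate gene key(s) in operon table: %s",
                      paste(unique(dup), collapse = ", ")))
    gene_to_operon <- setNames(as.character(op$operon), op$gene)
  }
  gene_to_regulon <- list()
  if (!is.null(regulon_path)) {
    rg <- read_tsv_checked(regulon_path, c("gene", "regulon"))
    gene_to_regulon <- lapply(split(as.character(rg$regulon), rg$gene), unique)
  }
  expression <- NULL
  if (!is.null(expression_path)) {
    expression <- read_tsv_checked(expression_path,
                                   c("gene", "strain", "change"))
    bad <- setdiff(unique(expression$change), c("up", "down", "unchanged"))
    cf_assert(length(bad) == 0, "crossfeedr_format_error",
              sprintf("invalid expression change value(s): %s",
                      paste(bad, collapse = ", ")))
  }
  structure(list(gene_to_operon = gene_to_operon,
                 gene_to_regulon = gene_to_regulon,
                 expression = expression),
            class = "annotation_tables")
}

#' Empty annotation tables
#' @return an `annotation_tables` object with no entries.
#' @export
empty_annotations <- function() {
  structure(list(gene_to_operon = character(0),
                 gene_to_regulon = list(), expression = NULL),
            class = "annotation_tables")
}
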