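# From changed reactions to genes, operons and regulons, and comparison of
# predicted regulation direction with observed expression changes.

#' Genes behind a set of reactions
#'
#' Union of the genes named by the GPR rules of the given reactions.
#'
#' @param model a [metabolic_model()].
#' @param reactions character vector of reaction ids.
#' @return character vector of gene ids; attribute `unmapped` lists
#'   reactions without a GPR rule.
#' @export
genes_for_reactions <- function(model, reactions) {
  idx <- rxn_index(model, reactions)
  rules <- model$gpr[idx]
  unmapped <- reactions[trimws(rules) == ""]
  genes <- unique(unlist(lapply(rules, gpr_genes)))
  if (is.null(genes)) genes <- character(0)
  structure(genes, unmapped = unmapped)
}

#' Aggregate gene impact over annotation tables
#'
#' @param genes character vector of gene ids.
#' @param tables an `annotation_tables` object (may be empty).
#' @return list of class `gene_impact`: `genes`, `n_genes`, `n_operons`,
#'   `n_regulons`, `missing_annotation` flag.
#' @export
aggregate_gene_impact <- function(genes, tables = empty_annotations()) {
  genes <- unique(as.character(genes))
  ops <- unique(unname(tables$gene_to_operon[genes]))
  ops <- ops[!is.na(ops)]
  regs <- unique(unlist(tables$gene_to_regulon[
    intersect(genes, names(tables$gene_to_regulon))]))
  structure(list(genes = genes,
                 n_genes = length(genes),
                 n_operons = length(ops),
                 n_regulons = length(regs),
                 missing_annotation = length(tables$gene_to_operon) == 0 &&
                   length(tables$gene_to_regulon) == 0),
            class = "gene_impact")
}

#' Concordance of predicted flux changes with expression changes
#'
#' Predicts, for each gene, whether its expression should be up, down or
#' unchanged from the flux-magnitude changes of the reactions it is
#' associated with (per-reaction: `|e| - |a| > beta` up, `< -beta` down,
#' else unchanged; a gene's direction is the majority over its reactions,
#' ties giving unchanged). Each category is then compared with the
#' observed calls by a two-sided Fisher's exact test on the 2x2 table of
#' predicted-in-category by observed-in-category.
#'
#' @param model a [metabolic_model()].
#' @param a,e ancestral and evolved [flux_distribution()]s.
#' @param expression named character vector gene -> observed change
#'   (`"up"`, `"down"`, `"unchanged"`); genes absent from the model's GPRs
#'   are ignored.
#' @param beta flux-change threshold.
#' @return data.frame with one row per category: true/false positives,
#'   Fisher's exact p (degenerate tables give p = 1), and significance
#'   marks at 0.05 (`*`) and 0.01 (`**`).
#' @export
expression_concordance <- function(model, a, e, expression, beta = 0.001) {
  cf_assert(length(expression) > 0, "crossfeedr_contract_error",
            "expression table is empty")
  va <- if (inherits(a, "flux_distribution")) a$values else a
  ve <- if (inherits(e, "flux_distribution")) e$values else e

  # reaction-level direction of |flux| change
  dmag <- abs(ve) - abs(va)
  rdir <- ifelse(dmag > beta, "up", ifelse(dmag < -beta, "down", "unchanged"))

  gene_rxns <- list()
  for (j in seq_along(model$reaction_ids)) {
    for (g in gpr_genes(model$gpr[j])) {
      gene_rxns[[g]] <- c(gene_rxns[[g]], j)
    }
  }
  genes <- intersect(names(expression), names(gene_rxns))
  pred <- vapply(genes, function(g) {
    votes <- table(rdir[gene_rxns[[g]]])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) top else "unchanged"
  }, character(1))
  obs <- expression[genes]

  cats <- c("up", "down", "unchanged")
  rows <- lapply(cats, function(cat) {
    p_in <- pred == cat
    o_in <- obs == cat
    tab <- matrix(c(sum(p_in & o_in), sum(p_in & !o_in),
                    sum(!p_in & o_in), sum(!p_in & !o_in)), 2, 2)
    pval <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      1 # degenerate margin: no information against chance
    } else {
      fisher.test(tab, alternative = "two.sided")$p.value
    }
    data.frame(category = cat,
               true_positives = sum(p_in & o_in),
               false_positives = sum(p_in & !o_in),
               n_predicted = sum(p_in), n_observed = sum(o_in),
               p_value = pval,
               significance = if (pval < 0.01) "**"
                              else if (pval < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_genes") <- length(genes)
  out
}
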