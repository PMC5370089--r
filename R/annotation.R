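# Annotation of screen hits: protein-target category breakdown of a drug
# ranking (pie-chart payload) and hypergeometric over-representation of
# target genes against category gene sets.

#' Category breakdown of a drug ranking's protein targets
#'
#' Each ranked drug contributes once, to the category of its
#' highest-priority protein target (priority = row order of the
#' `drug_targets` table); drugs without any target fall into
#' `"uncharacterized"`.  Percentages are computed over all categorized
#' drugs and rows are ordered by count descending with alphabetical
#' tie-break (the clockwise pie order).
#'
#' @param ranking data frame with a `drug` column (e.g. the `positive`
#'   table of [rank_drugs()]), or a `drug_ranking` (positive table used).
#' @param drug_targets data frame `drug`, `protein`; row order defines
#'   target priority.
#' @param protein_category data frame `protein`, `category`.
#' @return a `category_breakdown` data frame: `category`, `count`,
#'   `percentage` (sums to 100 up to rounding).
#' @export
classify_drug_targets <- function(ranking, drug_targets, protein_category) {
  if (inherits(ranking, "drug_ranking")) ranking <- ranking$positive
  drugs <- ranking$drug
  cat_of_protein <- setNames(protein_category$category, protein_category$protein)
  category <- vapply(drugs, function(d) {
    prots <- drug_targets$protein[drug_targets$drug == d]
    if (!length(prots)) return("uncharacterized")
    known <- prots[prots %in% names(cat_of_protein)]
    if (!length(known)) return("uncharacterized")
    unname(cat_of_protein[known[1]])
  }, character(1))
  tab <- table(category)
  out <- data.frame(category = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$percentage <- 100 * out$count / sum(out$count)
  out <- out[order(-out$count, out$category), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("category_breakdown", "data.frame")
  out
}

#' Hypergeometric over-representation of a gene list in category gene sets
#'
#' One-sided hypergeometric tail per category (probability of at least the
#' observed overlap), Benjamini-Hochberg adjustment across categories, rows
#' sorted by p ascending (ties by category name).
#'
#' @param genes character vector of query genes (non-empty, unique).
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]); sets are intersected with the universe.
#' @param universe character vector containing every queryable gene; must
#'   contain all of `genes`.
#' @return an `enrichment_table` data frame: `category`, `overlap`,
#'   `set_size`, `query_size`, `universe_size`, `p`, `q`.
#' @export
enrich_categories <- function(genes, gene_sets, universe) {
  genes <- unique(genes)
  if (!length(genes)) stopf("enrich_categories: empty query")
  if (!all(genes %in% universe)) {
    stopf("enrich_categories: %d query gene(s) missing from the universe",
          sum(!genes %in% universe))
  }
  N <- length(unique(universe))
  q_size <- length(genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    k <- length(intersect(genes, set))
    K <- length(set)
    p <- phyper(k - 1, K, N - K, q_size, lower.tail = FALSE)
    data.frame(category = nm, overlap = k, set_size = K,
               query_size = q_size, universe_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$category), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Directional enrichment of a target-gene set
#'
#' Runs [enrich_categories()] separately on the up- and down-regulated
#' target genes (direction taken from the query signature), the layout the
#' per-drug enrichment listings use.
#'
#' @param target_set a [target_gene_set][derive_target_genes].
#' @param gene_sets named list of category gene sets.
#' @param universe gene universe.
#' @param fdr_threshold rows with q below this are flagged `significant`.
#' @return list of `enrichment_table`s, `up` and `down` (NULL when that
#'   side is empty).
#' @export
enrich_target_genes <- function(target_set, gene_sets, universe,
                                fdr_threshold = 0.02) {
  one_side <- function(g) {
    if (!length(g)) return(NULL)
    tab <- enrich_categories(g, gene_sets, universe)
    tab$significant <- tab$q < fdr_threshold
    tab
  }
  list(up = one_side(target_set$gene[target_set$direction > 0]),
       down = one_side(target_set$gene[target_set$direction < 0]))
}
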