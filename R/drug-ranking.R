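# Target-gene derivation and drug ranking: per-drug perturbed-gene calls
# (replicates pooled, one-sample Student t), intersection with the query
# signature ("target genes"), and the count-ranked drug tables.

#' Per-gene perturbation table for one drug
#'
#' Pools the drug's instance profiles: per gene, the pooled log2 fold
#' change (mean across instances) and a one-sample Student t-test of the
#' instance fold changes against 0; genes with p <= `p_threshold` are kept.
#' When the database stores probe-level rows (it carries a `probe_to_gene`
#' map), significant probes are collapsed to genes by the biggest absolute
#' fold change (ties: smaller p, then lexicographic row id).  A drug with a
#' single instance cannot support a t-test; supply `fc_fallback` to keep
#' genes with pooled |log2 FC| >= that value instead (the result is flagged
#' `fallback`).
#'
#' @param db a [drug_profile_db].
#' @param drug drug name.
#' @param p_threshold t-test p-value cutoff (default 0.05).
#' @param fc_fallback |log2 FC| cutoff used when only one instance exists.
#' @return data frame `gene`, `fc` (pooled log2 FC), `t`, `p`, sorted by
#'   |fc| descending.
#' @export
derive_perturbed_genes <- function(db, drug, p_threshold = 0.05,
                                   fc_fallback = NULL) {
  stopifnot(inherits(db, "drug_profile_db"))
  ids <- db$instances$instance_id[db$instances$drug == drug]
  if (!length(ids)) stopf("derive_perturbed_genes: unknown drug '%s'", drug)
  fc <- db$fc[, ids, drop = FALSE]
  k <- ncol(fc)
  fallback <- FALSE
  if (k >= 2) {
    m <- rowMeans(fc)
    s <- sqrt(rowSums((fc - m)^2) / (k - 1))
    t <- ifelse(s > 0, m / (s / sqrt(k)), ifelse(m == 0, 0, Inf * sign(m)))
    p <- 2 * pt(-abs(t), k - 1)
    keep <- p <= p_threshold
  } else {
    if (is.null(fc_fallback)) {
      stopf("derive_perturbed_genes: drug '%s' has a single instance; supply fc_fallback",
            drug)
    }
    m <- fc[, 1]
    t <- rep(NA_real_, length(m)); p <- rep(NA_real_, length(m))
    keep <- abs(m) >= fc_fallback
    fallback <- TRUE
  }
  out <- data.frame(gene = rownames(fc), fc = unname(m), t = unname(t),
                    p = unname(p), stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (!is.null(db$probe_to_gene)) {
    out$probe <- out$gene
    out$gene <- unname(db$probe_to_gene[out$probe])
    out <- out[!is.na(out$gene) & out$gene != "", , drop = FALSE]
    ord <- order(out$gene, -abs(out$fc), out$p, out$probe)
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(out$gene), , drop = FALSE]
  }
  out <- out[order(-abs(out$fc), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drug") <- drug
  attr(out, "fallback") <- fallback
  out
}

#' Target genes: signature genes perturbed by a drug
#'
#' The intersection of the query signature with the drug's perturbed-gene
#' set, with the drug-side fold change and signature direction carried
#' along; its size is the drug-ranking statistic.
#'
#' @param perturbed table from [derive_perturbed_genes()].
#' @param sig a non-empty `cmap_signature`.
#' @return a `target_gene_set` data frame (`gene`, `drug_fc`, `direction`)
#'   with attributes `drug` and `count`.
#' @export
derive_target_genes <- function(perturbed, sig) {
  stopifnot(inherits(sig, "cmap_signature"))
  if (!nrow(sig)) stopf("derive_target_genes: empty signature")
  hit <- perturbed$gene %in% sig$gene
  out <- data.frame(
    gene = perturbed$gene[hit],
    drug_fc = perturbed$fc[hit],
    direction = sig$direction[match(perturbed$gene[hit], sig$gene)],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, drug = attr(perturbed, "drug"), count = nrow(out),
            class = c("target_gene_set", "data.frame"))
}

#' Rank drugs by target-gene count, split by connectivity call
#'
#' Produces the positive-range and negative-range ranking tables: within
#' each call sign, drugs are sorted by target-gene count descending, ties
#' broken by drug name ascending, ranks consecutive from 1.  Null-called
#' drugs appear in neither table.
#'
#' @param counts named numeric vector drug -> target-gene count, or a list
#'   of `target_gene_set` objects.
#' @param calls a [connectivity_result][aggregate_instances] (needs columns
#'   `drug`, `call`).
#' @param screen screen label attached to the tables.
#' @return a `drug_ranking` list with data frames `positive` and `negative`
#'   (`rank`, `drug`, `count`, `call`).
#' @export
rank_drugs <- function(counts, calls, screen = "custom") {
  if (is.list(counts) && !is.data.frame(counts)) {
    counts <- vapply(counts, function(ts) attr(ts, "count"), numeric(1),
                     USE.NAMES = FALSE) |>
      setNames(vapply(counts, function(ts) attr(ts, "drug"), character(1)))
  }
  missing <- setdiff(calls$drug[calls$call != "null"], names(counts))
  if (length(missing)) {
    stopf("rank_drugs: no target-gene count for drug(s): %s",
          paste(missing, collapse = ", "))
  }
  one_table <- function(call_value) {
    d <- calls$drug[calls$call == call_value]
    if (!length(d)) {
      return(data.frame(rank = integer(), drug = character(),
                        count = numeric(), call = character()))
    }
    cnt <- counts[d]
    ord <- order(-cnt, d)
    data.frame(rank = seq_along(d), drug = d[ord], count = unname(cnt[ord]),
               call = call_value, stringsAsFactors = FALSE)
  }
  structure(list(positive = one_table("positive correlation"),
                 negative = one_table("negative correlation")),
            screen = screen, class = "drug_ranking")
}

#' @export
print.drug_ranking <- function(x, n = 10, ...) {
  cat(sprintf("drug ranking ('%s' screen)\n", attr(x, "screen")))
  cat("positive range (top):\n"); print.data.frame(head(x$positive, n))
  cat("negative range (top):\n"); print.data.frame(head(x$negative, n))
  invisible(x)
}

#' Overlap fraction between the top-k drugs of two rankings
#'
#' @param a,b data frames with a `drug` column ordered by rank (e.g. the
#'   `positive` table of a [rank_drugs()] result), or `drug_ranking`
#'   objects (their positive tables are used).
#' @param top_k depth of the comparison; must not exceed either ranking.
#' @return fraction in \[0, 1\]: |top-k intersection| / top_k.
#' @export
ranking_overlap <- function(a, b, top_k) {
  if (inherits(a, "drug_ranking")) a <- a$positive
  if (inherits(b, "drug_ranking")) b <- b$positive
  if (top_k > min(nrow(a), nrow(b))) {
    stopf("ranking_overlap: top_k = %d exceeds a ranking length", top_k)
  }
  length(intersect(a$drug[seq_len(top_k)], b$drug[seq_len(top_k)])) / top_k
}

#' Target-gene counts for every drug in a database
#'
#' Convenience wrapper running [derive_perturbed_genes()] +
#' [derive_target_genes()] over all drugs.
#'
#' @inheritParams derive_perturbed_genes
#' @param sig the query signature.
#' @return named numeric vector drug -> target-gene count, with the
#'   `target_gene_set`s in attribute `"target_sets"`.
#' @export
target_gene_counts <- function(db, sig, p_threshold = 0.05,
                               fc_fallback = NULL) {
  drugs <- unique(db$instances$drug)
  sets <- lapply(drugs, function(d) {
    derive_target_genes(
      derive_perturbed_genes(db, d, p_threshold = p_threshold,
                             fc_fallback = fc_fallback), sig)
  })
  names(sets) <- drugs
  counts <- vapply(sets, function(ts) as.numeric(attr(ts, "count")), numeric(1))
  structure(counts, target_sets = sets)
}
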