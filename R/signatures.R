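# Signature construction: per-probe differential expression between
# condition groups, probe -> gene collapsing by largest absolute fold
# change, and assembly of directional positive/negative-range signatures.

#' Expression compendium container
#'
#' A log2-scale probe x sample matrix (assumed already RMA-normalized)
#' together with a probe -> gene-symbol map and a sample -> condition map.
#'
#' @param values numeric probe x sample matrix, log2 scale, no missing
#'   values, unique row names (probe ids) and column names (sample ids).
#' @param probe_to_gene named character vector mapping probe id -> gene
#'   symbol; probes with no annotation may be `NA`.
#' @param sample_to_condition named character vector mapping sample id ->
#'   condition label.
#' @return an `expression_compendium`.
#' @export
expression_compendium <- function(values, probe_to_gene, sample_to_condition) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyNA(values)) stopf("expression_compendium: missing values are not allowed")
  if (anyDuplicated(rownames(values))) {
    stopf("expression_compendium: probe ids must be unique")
  }
  if (!all(colnames(values) %in% names(sample_to_condition))) {
    stopf("expression_compendium: every sample needs a condition")
  }
  probe_to_gene <- probe_to_gene[rownames(values)]
  names(probe_to_gene) <- rownames(values)
  structure(list(values = values, probe_to_gene = probe_to_gene,
                 sample_to_condition = sample_to_condition[colnames(values)]),
            class = "expression_compendium")
}

#' @export
print.expression_compendium <- function(x, ...) {
  cat(sprintf("expression compendium: %d probes x %d samples (%d conditions)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_to_condition))))
  tab <- table(x$sample_to_condition)
  cat("  conditions:", paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Contrast specification
#'
#' Defines a two-group comparison: a positive range (the conditions the
#' signature should be enriched in) against a negative range, a linear
#' fold-change threshold, and an FDR threshold.  The default thresholds
#' (1.8-fold, FDR < 5%) are those used for screening signatures; the
#' morphogen-profiling setting uses 1.65-fold at the same FDR.
#'
#' @param positive,negative disjoint, non-empty sets of condition labels.
#' @param fc_threshold linear fold change (> 1); a probe passes when its
#'   linear |FC| = 2^|log2 FC| is at least this.
#' @param fdr_threshold FDR level in (0, 1); a probe passes when its BH-
#'   adjusted q is strictly below this.
#' @param label free-text label for the contrast.
#' @return a `contrast_spec`.
#' @export
contrast_spec <- function(positive, negative, fc_threshold = 1.8,
                          fdr_threshold = 0.05, label = NULL) {
  if (!length(positive) || !length(negative)) {
    stopf("contrast_spec: both condition sets must be non-empty")
  }
  if (length(intersect(positive, negative))) {
    stopf("contrast_spec: condition sets must be disjoint")
  }
  if (fc_threshold <= 1) stopf("contrast_spec: fc_threshold must be > 1")
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stopf("contrast_spec: fdr_threshold must lie in (0, 1)")
  }
  structure(list(positive = positive, negative = negative,
                 fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
                 label = label %||% paste(paste(positive, collapse = "+"), "vs",
                                          paste(negative, collapse = "+"))),
            class = "contrast_spec")
}

#' Per-probe differential expression for a contrast
#'
#' Two-sample Student t-test (pooled variance, two-sided) per probe between
#' all samples of the positive versus negative condition sets, with
#' Benjamini-Hochberg adjustment over all tested probes.  A probe passes the
#' screen filter when linear |FC| >= `fc_threshold` and q < `fdr_threshold`.
#' A probe with zero variance in both groups and equal means gets t = 0,
#' p = 1; unequal means with zero pooled variance give p = 0.
#'
#' @param compendium an [expression_compendium].
#' @param contrast a [contrast_spec()].
#' @return a `probe_stats` data frame: `probe`, `gene`, `log2_fc`
#'   (mean(positive) - mean(negative)), `t`, `p`, `q`, `passes`.
#' @export
differential_expression <- function(compendium, contrast) {
  stopifnot(inherits(compendium, "expression_compendium"),
            inherits(contrast, "contrast_spec"))
  cond <- compendium$sample_to_condition
  for (cc in c(contrast$positive, contrast$negative)) {
    n <- sum(cond == cc)
    if (n == 0) stopf("differential_expression: condition '%s' absent from compendium", cc)
    if (n < 2) stopf("differential_expression: condition '%s' has < 2 replicates", cc)
  }
  pos <- names(cond)[cond %in% contrast$positive]
  neg <- names(cond)[cond %in% contrast$negative]
  x <- compendium$values[, pos, drop = FALSE]
  y <- compendium$values[, neg, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  ss1 <- rowSums((x - m1)^2); ss2 <- rowSums((y - m2)^2)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  delta <- m1 - m2
  t <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, Inf * sign(delta)))
  p <- 2 * pt(-abs(t), df)
  q <- p.adjust(p, method = "BH")
  passes <- abs(delta) >= log2(contrast$fc_threshold) & q < contrast$fdr_threshold
  out <- data.frame(
    probe = rownames(compendium$values),
    gene = unname(compendium$probe_to_gene[rownames(compendium$values)]),
    log2_fc = unname(delta), t = unname(t), p = unname(p), q = unname(q),
    passes = unname(passes), stringsAsFactors = FALSE
  )
  attr(out, "contrast") <- contrast
  class(out) <- c("probe_stats", "data.frame")
  out
}

#' Collapse probe-level statistics to one row per gene
#'
#' Keeps, per gene, the probe with the biggest absolute log2 fold change;
#' ties are broken by smaller p, then lexicographic probe id.  Probes
#' without a gene symbol are dropped.
#'
#' @param stats a `probe_stats` data frame (from
#'   [differential_expression()]), or any data frame with `probe`,
#'   `log2_fc`, `p` columns.
#' @param probe_to_gene optional probe -> gene map; defaults to the `gene`
#'   column already present in `stats`.
#' @return a `gene_stats` data frame: `gene`, `probe`, `log2_fc`, `p`, `q`,
#'   `passes` (carried over if present).
#' @export
collapse_probes <- function(stats, probe_to_gene = NULL) {
  df <- as.data.frame(stats)
  if (!is.null(probe_to_gene)) df$gene <- unname(probe_to_gene[df$probe])
  df <- df[!is.na(df$gene) & df$gene != "", , drop = FALSE]
  if (!nrow(df)) {
    out <- df[, intersect(c("gene", "probe", "log2_fc", "p", "q", "passes"),
                          names(df)), drop = FALSE]
    class(out) <- c("gene_stats", "data.frame")
    return(out)
  }
  ord <- order(df$gene, -abs(df$log2_fc), df$p, df$probe)
  df <- df[ord, , drop = FALSE]
  out <- df[!duplicated(df$gene), , drop = FALSE]
  keep <- intersect(c("gene", "probe", "log2_fc", "t", "p", "q", "passes"),
                    names(out))
  out <- out[order(out$gene), keep, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "contrast") <- attr(stats, "contrast", exact = TRUE)
  class(out) <- c("gene_stats", "data.frame")
  out
}

#' Construct a directional signature
#'
#' @param gene character vector of gene symbols (no duplicates).
#' @param direction +1/-1 per gene.
#' @param log2_fc optional fold changes (for ordering/reporting).
#' @param label signature label.
#' @param provenance optional list of the contrast specs used.
#' @return a `cmap_signature` data frame (`gene`, `direction`, `log2_fc`).
#' @export
new_signature <- function(gene, direction, log2_fc = NULL, label = "signature",
                          provenance = NULL) {
  if (anyDuplicated(gene)) stopf("signature: a gene may appear at most once")
  if (!all(direction %in% c(-1, 1))) stopf("signature: directions must be +1/-1")
  out <- data.frame(gene = as.character(gene),
                    direction = as.integer(direction),
                    log2_fc = if (is.null(log2_fc)) NA_real_ else log2_fc,
                    stringsAsFactors = FALSE)
  structure(out, label = label, provenance = provenance,
            class = c("cmap_signature", "data.frame"))
}

#' @export
print.cmap_signature <- function(x, ...) {
  cat(sprintf("signature '%s': %d genes (%d up, %d down)\n",
              attr(x, "label") %||% "?", nrow(x),
              sum(x$direction > 0), sum(x$direction < 0)))
  invisible(x)
}

#' Build a signature from gene-level statistics with negative-range refinement
#'
#' Genes passing the contrast's thresholds in `primary` enter the signature
#' with direction = sign(log2 FC).  A gene is then removed when any
#' refinement table (gene-level statistics for a negative-range contrast)
#' shows it passing the same fold-change/FDR thresholds — by default with
#' the same direction (i.e. the gene is not specific to the positive range);
#' `exclude = "any"` removes it regardless of direction.  Output rows are
#' ordered by |log2 FC| descending (ties by gene) so the listing is
#' deterministic.
#'
#' @param primary a `gene_stats` data frame computed at the contrast's
#'   thresholds.
#' @param contrast the [contrast_spec()] used for `primary` (supplies the
#'   thresholds re-applied to the refinement tables).
#' @param refinements list of `gene_stats` data frames from other contrasts.
#' @param label signature label.
#' @param exclude `"same"` (default) or `"any"` direction matching rule.
#' @return a `cmap_signature`; errors if no gene survives.
#' @export
build_signature <- function(primary, contrast, refinements = list(),
                            label = NULL, exclude = c("same", "any")) {
  exclude <- match.arg(exclude)
  stopifnot(inherits(contrast, "contrast_spec"))
  lfc_thr <- log2(contrast$fc_threshold)
  pass <- primary$passes %||%
    (abs(primary$log2_fc) >= lfc_thr & primary$q < contrast$fdr_threshold)
  sel <- primary[pass, , drop = FALSE]
  drop <- rep(FALSE, nrow(sel))
  for (ref in refinements) {
    idx <- match(sel$gene, ref$gene)
    hit <- !is.na(idx)
    j <- idx[hit]
    ref_pass <- abs(ref$log2_fc[j]) >= lfc_thr & ref$q[j] < contrast$fdr_threshold
    if (exclude == "same") {
      ref_pass <- ref_pass & sign(ref$log2_fc[j]) == sign(sel$log2_fc[hit])
    }
    drop[hit] <- drop[hit] | ref_pass
  }
  sel <- sel[!drop, , drop = FALSE]
  if (!nrow(sel)) stopf("empty signature")
  sel <- sel[order(-abs(sel$log2_fc), sel$gene), , drop = FALSE]
  new_signature(sel$gene, sign(sel$log2_fc), log2_fc = sel$log2_fc,
                label = label %||% contrast$label,
                provenance = list(contrast = contrast,
                                  n_refinements = length(refinements)))
}

#' Count probes below an FDR level
#'
#' Reporting statistic: the number of probes whose BH-adjusted q falls
#' within a given FDR range (default 10%) for a contrast, irrespective of
#' fold change.
#'
#' @param stats a `probe_stats` data frame.
#' @param fdr FDR level.
#' @return integer count.
#' @export
count_probes_at_fdr <- function(stats, fdr = 0.10) {
  sum(stats$q < fdr)
}
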