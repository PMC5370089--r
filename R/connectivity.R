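# Connectivity scoring: match a directional signature against every
# instance of a drug-perturbation reference database, with the classic
# two-sided Kolmogorov-Smirnov running-sum statistic (connectivity-map
# lineage) or a rank/direction correlation scorer, then aggregate instance
# scores to per-drug connectivity calls with an empirical permutation p.

#' Drug-perturbation profile database
#'
#' @param ranks integer gene x instance matrix; within each column the ranks
#'   are a permutation of 1..n over the gene universe, 1 = most
#'   up-regulated.
#' @param fc numeric gene x instance matrix of log2 fold changes, same
#'   dimnames as `ranks`.
#' @param instances data frame with one row per instance: `instance_id`,
#'   `drug`, plus free metadata columns (cell line, dose, ...).
#' @param probe_to_gene optional named map when the profile rows are probes
#'   rather than genes; consumed by [derive_perturbed_genes()].
#' @return a `drug_profile_db`.
#' @export
drug_profile_db <- function(ranks, fc, instances, probe_to_gene = NULL) {
  stopifnot(is.matrix(ranks), is.matrix(fc),
            identical(dim(ranks), dim(fc)),
            identical(rownames(ranks), rownames(fc)),
            all(colnames(ranks) %in% instances$instance_id))
  if (anyDuplicated(instances$instance_id)) {
    stopf("drug_profile_db: instance ids must be unique")
  }
  n <- nrow(ranks)
  ok <- apply(ranks, 2, function(r) identical(sort(as.integer(r)), seq_len(n)))
  if (!all(ok)) {
    stopf("drug_profile_db: column '%s' is not a permutation of 1..%d",
          colnames(ranks)[which(!ok)[1]], n)
  }
  structure(list(ranks = ranks, fc = fc,
                 instances = instances[match(colnames(ranks),
                                             instances$instance_id), ,
                                       drop = FALSE],
                 gene_universe = rownames(ranks),
                 probe_to_gene = probe_to_gene),
            class = "drug_profile_db")
}

#' @export
print.drug_profile_db <- function(x, ...) {
  cat(sprintf("drug profile database: %d drugs, %d instances, %d genes\n",
              length(unique(x$instances$drug)), ncol(x$ranks), nrow(x$ranks)))
  invisible(x)
}

# Signed KS running-sum statistic for one tag set.
# positions: sorted 1-based ranks of the tag genes; n: universe size.
# a = max_j( j/t - V(j)/n ), b = max_j( V(j)/n - (j-1)/t );
# the statistic is a if a > b, else -b.
ks_stat <- function(positions, n) {
  t <- length(positions)
  if (t == 0) return(0)
  j <- seq_len(t)
  a <- max(j / t - positions / n)
  b <- max(positions / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Two-sided KS connectivity score of a signature against one instance
#'
#' Computes the signed KS running-sum statistic separately for the up-set
#' and the down-set of the signature against the instance's gene ranking,
#' and combines them as `ks_up - ks_down` when the two have opposite signs
#' and 0 otherwise (the classic same-sign rule).  A signature whose up- or
#' down-set is empty (or entirely absent from the universe) is scored
#' one-sided: the missing side contributes 0 and the combined score is the
#' populated side's statistic (negated for the down side), flagged
#' `one_sided`.
#'
#' @param sig a `cmap_signature`.
#' @param ranks named integer vector: gene -> rank (1 = most up-regulated),
#'   a permutation of 1..n.
#' @return an `instance_score` list: `ks_up`, `ks_down`, `combined`
#'   (in \[-2, 2\]), `one_sided`, `n_dropped` (signature genes absent from
#'   the instance's universe).
#' @export
ks_connectivity_score <- function(sig, ranks) {
  stopifnot(inherits(sig, "cmap_signature"))
  n <- length(ranks)
  present <- sig$gene %in% names(ranks)
  n_dropped <- sum(!present)
  if (!any(present)) {
    stopf("ks_connectivity_score: no signature gene is present in the instance universe")
  }
  s <- sig[present, , drop = FALSE]
  up <- sort(unname(ranks[s$gene[s$direction > 0]]))
  dn <- sort(unname(ranks[s$gene[s$direction < 0]]))
  ks_up <- ks_stat(up, n)
  ks_dn <- ks_stat(dn, n)
  one_sided <- length(up) == 0 || length(dn) == 0
  combined <- if (length(up) == 0) {
    -ks_dn
  } else if (length(dn) == 0) {
    ks_up
  } else if (sign(ks_up) == sign(ks_dn)) {
    0
  } else {
    ks_up - ks_dn
  }
  structure(list(ks_up = ks_up, ks_down = ks_dn, combined = combined,
                 one_sided = one_sided, n_dropped = n_dropped),
            class = "instance_score")
}

#' Correlation connectivity score of a signature against one instance
#'
#' Pearson correlation between the signature's direction vector (+1/-1) and
#' the instance's log2 fold changes over the gene intersection, with a
#' two-sided p from the t transform of r.  A zero-variance fold-change
#' vector yields an undefined score (`NA`, reported as a null call
#' downstream).
#'
#' @param sig a `cmap_signature`.
#' @param fc named numeric vector: gene -> log2 fold change.
#' @return an `instance_score` list: `r`, `p`, `combined` (= r), `n_overlap`.
#' @export
correlation_connectivity_score <- function(sig, fc) {
  stopifnot(inherits(sig, "cmap_signature"))
  common <- intersect(sig$gene, names(fc))
  if (length(common) < 3) {
    stopf("correlation_connectivity_score: fewer than 3 overlapping genes")
  }
  d <- sig$direction[match(common, sig$gene)]
  v <- unname(fc[common])
  if (sd(v) == 0 || sd(d) == 0) {
    return(structure(list(r = NA_real_, p = NA_real_, combined = NA_real_,
                          n_overlap = length(common)),
                     class = "instance_score"))
  }
  r <- cor(d, v)
  k <- length(common)
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(r) * sqrt((k - 2) / (1 - r^2)), k - 2)
  structure(list(r = r, p = p, combined = r, n_overlap = length(common)),
            class = "instance_score")
}

#' Score a signature against every instance of a database
#'
#' @param sig a `cmap_signature`.
#' @param db a [drug_profile_db].
#' @param scorer `"ks"` (default, two-sided KS) or `"corr"` (direction/
#'   fold-change Pearson correlation).
#' @return data frame with one row per instance: `instance_id`, `drug`,
#'   `score` (the combined statistic), plus scorer-specific columns.
#' @export
score_instances <- function(sig, db, scorer = c("ks", "corr")) {
  scorer <- match.arg(scorer)
  stopifnot(inherits(db, "drug_profile_db"))
  ids <- colnames(db$ranks)
  if (scorer == "ks") {
    # integer-index fast path over the shared universe
    idx_up <- match(sig$gene[sig$direction > 0], db$gene_universe)
    idx_dn <- match(sig$gene[sig$direction < 0], db$gene_universe)
    n_dropped <- sum(is.na(idx_up)) + sum(is.na(idx_dn))
    idx_up <- idx_up[!is.na(idx_up)]; idx_dn <- idx_dn[!is.na(idx_dn)]
    if (!length(idx_up) && !length(idx_dn)) {
      stopf("score_instances: no signature gene is present in the database universe")
    }
    if (n_dropped > 0) {
      message(sprintf("score_instances: dropped %d signature gene(s) absent from the universe",
                      n_dropped))
    }
    n <- nrow(db$ranks)
    rows <- lapply(ids, function(iid) {
      r <- db$ranks[, iid]
      ks_up <- ks_stat(sort(r[idx_up]), n)
      ks_dn <- ks_stat(sort(r[idx_dn]), n)
      one_sided <- length(idx_up) == 0 || length(idx_dn) == 0
      combined <- if (!length(idx_up)) -ks_dn
                  else if (!length(idx_dn)) ks_up
                  else if (sign(ks_up) == sign(ks_dn)) 0
                  else ks_up - ks_dn
      data.frame(instance_id = iid, score = combined, ks_up = ks_up,
                 ks_down = ks_dn, one_sided = one_sided,
                 stringsAsFactors = FALSE)
    })
  } else {
    rows <- lapply(ids, function(iid) {
      s <- correlation_connectivity_score(sig, db$fc[, iid])
      data.frame(instance_id = iid, score = s$combined, r = s$r, p = s$p,
                 n_overlap = s$n_overlap, stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  out$drug <- db$instances$drug[match(out$instance_id, db$instances$instance_id)]
  out[, c("instance_id", "drug", setdiff(names(out), c("instance_id", "drug")))]
}

#' Aggregate instance scores to per-drug connectivity calls
#'
#' Per drug, instance scores are averaged (or median-summarized), then all
#' drug aggregates are normalized by the maximum absolute aggregate so
#' scores lie in \[-1, 1\].  The call is `positive`/`negative` by score sign
#' when |score| exceeds `call_floor`, else `null`; undefined (NA) aggregates
#' are null.
#'
#' @param instance_scores data frame from [score_instances()].
#' @param method `"mean"` (default) or `"median"`.
#' @param call_floor minimum normalized |score| for a non-null call.
#' @return a `connectivity_result` data frame: `drug`, `score` (normalized),
#'   `raw_score`, `n_instances`, `call`; the normalization constant is kept
#'   in attribute `"norm"`.
#' @export
aggregate_instances <- function(instance_scores, method = c("mean", "median"),
                                call_floor = 0) {
  method <- match.arg(method)
  agg_fun <- if (method == "mean") function(v) mean(v, na.rm = TRUE)
             else function(v) stats::median(v, na.rm = TRUE)
  sp <- split(instance_scores$score, instance_scores$drug)
  raw <- vapply(sp, function(v) {
    if (all(is.na(v))) NA_real_ else agg_fun(v)
  }, numeric(1))
  norm <- max(abs(raw), na.rm = TRUE)
  score <- if (is.finite(norm) && norm > 0) raw / norm else raw
  call <- ifelse(is.na(score), "null",
                 ifelse(score > call_floor, "positive correlation",
                        ifelse(score < -call_floor, "negative correlation",
                               "null")))
  out <- data.frame(drug = names(raw), score = unname(score),
                    raw_score = unname(raw),
                    n_instances = unname(lengths(sp)),
                    call = unname(call), stringsAsFactors = FALSE)
  out <- out[order(-abs(out$score), out$drug), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "norm") <- norm
  attr(out, "method") <- method
  class(out) <- c("connectivity_result", "data.frame")
  out
}

#' @export
print.connectivity_result <- function(x, n = 10, ...) {
  cat(sprintf("connectivity result: %d drugs (%d positive, %d negative, %d null)\n",
              nrow(x), sum(x$call == "positive correlation"),
              sum(x$call == "negative correlation"), sum(x$call == "null")))
  print.data.frame(head(as.data.frame(x), n))
  invisible(x)
}

#' Per-drug permutation p-values for connectivity scores
#'
#' For every drug, the null distribution is built by rescoring `n_perm`
#' random signatures with the same up/down sizes, drawn uniformly from the
#' database's gene universe, against the drug's instances (same aggregation
#' as the observed score) and `p = (1 + #\{|null| >= |observed|\}) /
#' (n_perm + 1)`.  Each drug consumes its own RNG stream derived from
#' `seed` and a hash of the drug name, so p-values do not depend on drug
#' order.
#'
#' @param sig a `cmap_signature`.
#' @param db a [drug_profile_db].
#' @param n_perm number of permutations (>= 100).
#' @param seed master seed.
#' @param scorer `"ks"` or `"corr"`.
#' @param method aggregation across instances, `"mean"` or `"median"`.
#' @return data frame: `drug`, `raw_score` (observed aggregate), `p`.
#' @export
permutation_pvalue <- function(sig, db, n_perm = 200, seed = 1,
                               scorer = c("ks", "corr"),
                               method = c("mean", "median")) {
  scorer <- match.arg(scorer); method <- match.arg(method)
  if (n_perm < 100) stopf("permutation_pvalue: n_perm must be >= 100")
  agg_fun <- if (method == "mean") mean else stats::median
  n <- nrow(db$ranks)
  n_up <- sum(sig$direction > 0 & sig$gene %in% db$gene_universe)
  n_dn <- sum(sig$direction < 0 & sig$gene %in% db$gene_universe)
  obs_inst <- score_instances(sig, db, scorer = scorer)
  obs <- vapply(split(obs_inst$score, obs_inst$drug),
                function(v) agg_fun(v[!is.na(v)]), numeric(1))
  drugs <- names(obs)
  inst_of <- split(db$instances$instance_id, db$instances$drug)
  p <- vapply(drugs, function(d) {
    ids <- inst_of[[d]]
    rank_mat <- db$ranks[, ids, drop = FALSE]
    fc_mat <- if (scorer == "corr") db$fc[, ids, drop = FALSE] else NULL
    with_seed(seed + string_hash(d), {
      null_stats <- vapply(seq_len(n_perm), function(b) {
        idx <- sample.int(n, n_up + n_dn)
        iu <- idx[seq_len(n_up)]
        idn <- idx[n_up + seq_len(n_dn)]
        inst <- vapply(seq_along(ids), function(j) {
          if (scorer == "ks") {
            r <- rank_mat[, j]
            ks_up <- ks_stat(sort(r[iu]), n)
            ks_dn <- ks_stat(sort(r[idn]), n)
            if (!n_up) -ks_dn
            else if (!n_dn) ks_up
            else if (sign(ks_up) == sign(ks_dn)) 0
            else ks_up - ks_dn
          } else {
            v <- fc_mat[c(iu, idn), j]
            dvec <- rep(c(1, -1), c(n_up, n_dn))
            if (sd(v) == 0) 0 else cor(dvec, v)
          }
        }, numeric(1))
        agg_fun(inst)
      }, numeric(1))
      (1 + sum(abs(null_stats) >= abs(obs[[d]]))) / (n_perm + 1)
    })
  }, numeric(1))
  data.frame(drug = drugs, raw_score = unname(obs), p = unname(p),
             stringsAsFactors = FALSE)
}
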