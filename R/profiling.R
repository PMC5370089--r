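# Expression profiling of target genes: per-gene standardization and
# agglomerative hierarchical clustering (1 - Pearson distance, average
# linkage by default) with a fully specified tie-break so dendrograms are
# deterministic: at every step the closest pair with the smallest cluster
# labels merges first, and leaf order puts the tighter (lower-height)
# subtree first.

#' Row-standardize an expression matrix
#'
#' Scales each row (gene) to mean 0 and s.d. 1.  Zero-variance rows are set
#' to all zeros and listed in attribute `"constant_rows"`.
#'
#' @param mat numeric matrix with at least 2 columns.
#' @return standardized matrix of the same shape.
#' @export
standardize_rows <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  m <- rowMeans(mat)
  s <- sqrt(rowSums((mat - m)^2) / (ncol(mat) - 1))
  constant <- s == 0
  s[constant] <- 1
  z <- (mat - m) / s
  z[constant, ] <- 0
  attr(z, "constant_rows") <- rownames(mat)[constant]
  z
}

# distance matrix between rows: 1 - Pearson correlation, or Euclidean
row_distances <- function(mat, distance) {
  if (distance == "pearson") {
    1 - stats::cor(t(mat))
  } else {
    as.matrix(stats::dist(mat, method = "euclidean"))
  }
}

#' Agglomerative hierarchical clustering with deterministic tie-breaks
#'
#' Clusters the rows of `mat` with distance `1 - Pearson` (default) or
#' Euclidean, and average (UPGMA, default) or complete linkage.  Ties in
#' the minimum inter-cluster distance are resolved toward the pair with the
#' smallest cluster labels (singletons labelled by input order, merged
#' clusters by creation order), so the merge sequence is a pure function of
#' the input.  Leaf order follows the tighter-cluster-first recursion: at
#' each internal node the child with the smaller merge height is visited
#' first (singletons have height 0; ties by smallest leaf label).
#'
#' @param mat numeric matrix, >= 2 rows.
#' @param distance `"pearson"` (1 - correlation) or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @return a `cluster_result`: `merge` (hclust-style signed matrix),
#'   `height`, `order` (leaf permutation), `labels`, `distance`, `linkage`.
#' @export
hierarchical_cluster <- function(mat, distance = c("pearson", "euclidean"),
                                 linkage = c("average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(mat))
  n <- nrow(mat)
  if (n < 2) stopf("hierarchical_cluster: need at least 2 rows")
  labels <- rownames(mat) %||% as.character(seq_len(n))
  d <- row_distances(mat, distance)
  diag(d) <- Inf
  # active[i]: signed hclust id of cluster currently stored at slot i
  active <- -(seq_len(n))
  size <- rep(1, n)
  alive <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(alive)
    # find min distance; first pair in slot order wins ties (slots are
    # ordered by cluster creation, so this is the smallest-label pair)
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      if (ii == length(idx)) break
      js <- idx[(ii + 1):length(idx)]
      dj <- d[i, js]
      jmin <- which.min(dj)
      if (dj[jmin] < best_d) {
        best_d <- dj[jmin]; best <- c(i, js[jmin])
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(active[i], active[j]),
                          decreasing = FALSE) |> (\(v) {
      # hclust convention: singletons (negative) before merges, both ascending
      if (all(v < 0)) sort(v, decreasing = TRUE) else v
    })()
    height[step] <- best_d
    # Lance-Williams update into slot i
    others <- idx[idx != i & idx != j]
    if (length(others)) {
      if (linkage == "average") {
        d[i, others] <- (size[i] * d[i, others] + size[j] * d[j, others]) /
          (size[i] + size[j])
      } else {
        d[i, others] <- pmax(d[i, others], d[j, others])
      }
      d[others, i] <- d[i, others]
    }
    size[i] <- size[i] + size[j]
    alive[j] <- FALSE
    active[i] <- step
  }
  res <- structure(list(merge = merge, height = height, labels = labels,
                        distance = distance, linkage = linkage),
                   class = "cluster_result")
  res$order <- leaf_order(res)
  res
}

# tighter-cluster-first leaf ordering
leaf_order <- function(res) {
  h_of <- function(id) if (id < 0) 0 else res$height[id]
  min_leaf <- function(id) {
    if (id < 0) return(-id)
    min(min_leaf(res$merge[id, 1]), min_leaf(res$merge[id, 2]))
  }
  walk <- function(id) {
    if (id < 0) return(-id)
    a <- res$merge[id, 1]; b <- res$merge[id, 2]
    ha <- h_of(a); hb <- h_of(b)
    first_a <- ha < hb || (ha == hb && min_leaf(a) <= min_leaf(b))
    if (first_a) c(walk(a), walk(b)) else c(walk(b), walk(a))
  }
  walk(nrow(res$merge))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("hierarchical clustering of %d items (%s distance, %s linkage)\n",
              length(x$labels), x$distance, x$linkage))
  cat("  merge heights:", paste(signif(x$height, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Convert a cluster_result to a base hclust object
#'
#' @param x a `cluster_result`.
#' @return an object of class `hclust` (plottable, cuttable with
#'   [stats::cutree()]).
#' @export
as_hclust <- function(x) {
  stopifnot(inherits(x, "cluster_result"))
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels,
                 method = x$linkage, dist.method = x$distance,
                 call = match.call()),
            class = "hclust")
}

#' Cut a cluster_result into k groups
#'
#' @param x a `cluster_result`.
#' @param k number of groups.
#' @return named integer vector of group memberships.
#' @export
cut_clusters <- function(x, k) {
  stats::cutree(as_hclust(x), k = k)
}

#' Cluster target-gene expression across the compendium
#'
#' Restricts the compendium to the given target genes (one probe per gene
#' by largest expression range), row-standardizes, and clusters both genes
#' (rows) and samples (columns) — the heatmap payload for profiling screen
#' hits across cell types and lineages.
#'
#' @param compendium an [expression_compendium].
#' @param genes character vector of target genes (>= 2 with data).
#' @param distance,linkage passed to [hierarchical_cluster()].
#' @return a `profile_clustering` list: `z` (standardized gene x sample
#'   matrix), `row_clust`, `col_clust` (both `cluster_result`).
#' @export
cluster_target_genes <- function(compendium, genes,
                                 distance = "pearson", linkage = "average") {
  stopifnot(inherits(compendium, "expression_compendium"))
  p2g <- compendium$probe_to_gene
  probes <- names(p2g)[p2g %in% genes]
  if (length(probes) < 2) {
    stopf("cluster_target_genes: fewer than 2 target genes have probes")
  }
  vals <- compendium$values[probes, , drop = FALSE]
  rng <- apply(vals, 1, function(v) diff(range(v)))
  ord <- order(p2g[probes], -rng, probes)
  keep <- probes[ord][!duplicated(p2g[probes][ord])]
  m <- vals[keep, , drop = FALSE]
  rownames(m) <- unname(p2g[keep])
  if (nrow(m) < 2) stopf("cluster_target_genes: fewer than 2 target genes have probes")
  z <- standardize_rows(m)
  structure(list(
    z = z,
    row_clust = hierarchical_cluster(z, distance, linkage),
    col_clust = hierarchical_cluster(t(z), distance, linkage)
  ), class = "profile_clustering")
}

#' Write a profile clustering as renderable text payloads
#'
#' Emits the standardized matrix as TSV and both dendrograms as Newick-like
#' nested strings plus leaf-order TSVs.
#'
#' @param pc a `profile_clustering`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return `dir`, invisibly.
#' @export
write_profile_clustering <- function(pc, dir, prefix = "profile") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(data.frame(gene = rownames(pc$z), pc$z, check.names = FALSE),
            file.path(dir, paste0(prefix, "_zmatrix.tsv")))
  for (side in c("row_clust", "col_clust")) {
    cl <- pc[[side]]
    writeLines(cluster_newick(cl),
               file.path(dir, paste0(prefix, "_", side, ".nwk")))
    write_tsv(data.frame(position = seq_along(cl$order),
                         label = cl$labels[cl$order]),
              file.path(dir, paste0(prefix, "_", side, "_leaves.tsv")))
  }
  invisible(dir)
}

#' Newick string for a cluster_result
#' @param x a `cluster_result`.
#' @return single Newick string (heights as branch lengths).
#' @export
cluster_newick <- function(x) {
  h_of <- function(id) if (id < 0) 0 else x$height[id]
  walk <- function(id, parent_h) {
    if (id < 0) {
      sprintf("%s:%g", x$labels[-id], parent_h)
    } else {
      h <- x$height[id]
      sprintf("(%s,%s):%g",
              walk(x$merge[id, 1], h), walk(x$merge[id, 2], h),
              parent_h - h)
    }
  }
  root <- nrow(x$merge)
  h <- x$height[root]
  sprintf("(%s,%s);", walk(x$merge[root, 1], h), walk(x$merge[root, 2], h))
}
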