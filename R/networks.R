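# Shortest-path subnetwork extraction over a typed interaction graph:
# single-source Dijkstra distances with all tied predecessors retained, and
# the node-capped union of shortest seed-pair paths (added by whole
# path-length strata) that connects a screen's target genes.

#' Typed interaction graph
#'
#' @param nodes data frame `id`, `role` (role labels such as ligand,
#'   receptor, kinase, transcription-factor, target-gene).
#' @param edges data frame `from`, `to`, `type`, optional `weight`
#'   (>= 0, default 1).  Self-loops are rejected; endpoints must exist in
#'   `nodes`.
#' @return an `interaction_graph`.
#' @export
interaction_graph <- function(nodes, edges) {
  stopifnot(all(c("id", "role") %in% names(nodes)),
            all(c("from", "to", "type") %in% names(edges)))
  if (is.null(edges$weight)) edges$weight <- 1
  if (any(edges$weight < 0)) stopf("interaction_graph: negative edge weights")
  if (any(edges$from == edges$to)) stopf("interaction_graph: self-loops are not allowed")
  bad <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(bad)) {
    stopf("interaction_graph: edge endpoint(s) missing from node table: %s",
          paste(head(bad, 3), collapse = ", "))
  }
  if (anyDuplicated(nodes$id)) stopf("interaction_graph: duplicate node ids")
  edges <- edges[, c("from", "to", "type", "weight",
                     setdiff(names(edges), c("from", "to", "type", "weight"))),
                 drop = FALSE]
  structure(list(nodes = nodes, edges = edges), class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("interaction graph: %d nodes, %d directed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  cat("  roles:", paste(names(table(x$nodes$role)), collapse = ", "), "\n")
  invisible(x)
}

#' Convert an interaction graph to igraph
#' @param graph an [interaction_graph].
#' @return an igraph object (directed, weighted).
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = graph$nodes)
}

#' Single-source shortest paths (Dijkstra) with all tied predecessors
#'
#' Exact shortest distances from `source` to every node (following edge
#' direction), plus, for each reachable node, the set of predecessors lying
#' on *some* shortest path — so all tied shortest paths are enumerable.
#' Unreachable nodes get distance `Inf`.
#'
#' @param graph an [interaction_graph] with non-negative weights.
#' @param source source node id.
#' @return list with `dist` (named numeric) and `predecessors` (named list
#'   of character vectors).
#' @export
shortest_paths_from <- function(graph, source) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (!source %in% graph$nodes$id) stopf("shortest_paths_from: unknown source '%s'", source)
  g <- as_igraph(graph)
  d <- igraph::distances(g, v = source, mode = "out",
                         weights = igraph::E(g)$weight)[1, ]
  e <- graph$edges
  de <- d[e$from] + e$weight
  on_sp <- is.finite(de) & abs(de - d[e$to]) < 1e-9
  preds <- split(e$from[on_sp], e$to[on_sp])
  predecessors <- setNames(vector("list", length(d)), names(d))
  predecessors[names(preds)] <- lapply(preds, unique)
  list(dist = d, predecessors = predecessors)
}

# all shortest paths between two nodes as a list of id vectors
all_shortest_node_paths <- function(g, from, to) {
  res <- suppressWarnings(
    igraph::all_shortest_paths(g, from = from, to = to, mode = "out",
                               weights = igraph::E(g)$weight)
  )
  lapply(res$vpaths %||% res$res, function(p) names(p))
}

#' Extract the node-capped shortest-path subnetwork connecting seed genes
#'
#' Computes all shortest paths between every ordered pair of seed nodes and
#' assembles their union by whole path-length strata: pair distances are
#' visited in ascending order and a stratum's nodes are added only if the
#' running node count stays within `cap_max` (a stratum is never truncated,
#' so the result is order-independent and monotone in the cap).  If the
#' full union stays below `cap_min` it is returned as-is and flagged.  With
#' `signaling_to_tf = TRUE` only paths from a signaling-role seed (ligand,
#' receptor, kinase) to a transcriptional-role seed (transcription-factor,
#' target-gene) are considered.
#'
#' @param graph an [interaction_graph].
#' @param seeds character vector of seed node ids; at least 2 must be
#'   present in the graph.
#' @param cap_min,cap_max node-count window (defaults 70-80).
#' @param signaling_to_tf restrict to signaling-to-transcription paths.
#' @return a `subnetwork`: `nodes` (data frame `id`, `role`, `is_seed`),
#'   `edges` (edges along included paths), `paths` (per-pair lists of node
#'   vectors), `missing_seeds`, `unreached_pairs`, `below_cap_min`,
#'   `included_strata` (the distances whose strata were added).
#' @export
extract_subnetwork <- function(graph, seeds, cap_min = 70, cap_max = 80,
                               signaling_to_tf = FALSE) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (cap_min > cap_max) stopf("extract_subnetwork: cap_min > cap_max")
  seeds <- unique(seeds)
  missing_seeds <- setdiff(seeds, graph$nodes$id)
  seeds_in <- setdiff(seeds, missing_seeds)
  if (length(seeds_in) < 2) {
    stopf("extract_subnetwork: fewer than 2 seeds are present in the graph")
  }
  if (cap_max < length(seeds_in)) stopf("cap below seed count")
  role_of <- setNames(graph$nodes$role, graph$nodes$id)
  signaling <- c("ligand", "receptor", "kinase")
  transcriptional <- c("transcription-factor", "target-gene")
  g <- as_igraph(graph)
  dmat <- igraph::distances(g, v = seeds_in, to = seeds_in, mode = "out",
                            weights = igraph::E(g)$weight)
  pairs <- expand.grid(from = seeds_in, to = seeds_in,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  if (signaling_to_tf) {
    pairs <- pairs[role_of[pairs$from] %in% signaling &
                   role_of[pairs$to] %in% transcriptional, , drop = FALSE]
  }
  pairs$dist <- dmat[cbind(pairs$from, pairs$to)]
  unreached <- pairs[!is.finite(pairs$dist), c("from", "to"), drop = FALSE]
  pairs <- pairs[is.finite(pairs$dist), , drop = FALSE]

  node_set <- seeds_in
  included <- numeric(0)
  kept_paths <- list()
  for (dv in sort(unique(pairs$dist))) {
    stratum <- pairs[pairs$dist == dv, , drop = FALSE]
    stratum_paths <- list()
    for (r in seq_len(nrow(stratum))) {
      ps <- all_shortest_node_paths(g, stratum$from[r], stratum$to[r])
      stratum_paths[[paste(stratum$from[r], stratum$to[r], sep = "->")]] <- ps
    }
    stratum_nodes <- unique(unlist(stratum_paths, use.names = FALSE))
    candidate <- union(node_set, stratum_nodes)
    if (length(candidate) > cap_max) break
    node_set <- candidate
    included <- c(included, dv)
    kept_paths <- c(kept_paths, stratum_paths)
  }
  below_cap_min <- length(node_set) < cap_min
  # edges along the kept paths
  edge_keys <- character(0)
  for (ps in kept_paths) for (p in ps) {
    if (length(p) >= 2) {
      edge_keys <- c(edge_keys, paste(p[-length(p)], p[-1], sep = "\r"))
    }
  }
  edge_keys <- unique(edge_keys)
  gk <- paste(graph$edges$from, graph$edges$to, sep = "\r")
  edges <- graph$edges[gk %in% edge_keys, , drop = FALSE]
  nodes <- data.frame(id = node_set, role = unname(role_of[node_set]),
                      is_seed = node_set %in% seeds_in,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, paths = kept_paths,
                 missing_seeds = missing_seeds,
                 unreached_pairs = unreached,
                 below_cap_min = below_cap_min,
                 included_strata = included,
                 cap_min = cap_min, cap_max = cap_max),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("subnetwork: %d nodes (%d seeds), %d edges; cap window %d-%d%s\n",
              nrow(x$nodes), sum(x$nodes$is_seed), nrow(x$edges),
              x$cap_min, x$cap_max,
              if (x$below_cap_min) " [below cap_min]" else ""))
  if (nrow(x$unreached_pairs)) {
    cat(sprintf("  %d seed pair(s) unreachable\n", nrow(x$unreached_pairs)))
  }
  invisible(x)
}

#' Write a subnetwork as SIF + node table + per-pair path JSON
#'
#' @param sn a `subnetwork`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return `dir`, invisibly.
#' @export
write_subnetwork <- function(sn, dir, prefix = "subnetwork") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  e <- sn$edges
  writeLines(paste(e$from, e$type, e$to, sep = "\t"),
             file.path(dir, paste0(prefix, ".sif")))
  write_tsv(sn$nodes, file.path(dir, paste0(prefix, "_nodes.tsv")))
  jsonlite::write_json(sn$paths, file.path(dir, paste0(prefix, "_paths.json")),
                       auto_unbox = FALSE)
  invisible(dir)
}
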