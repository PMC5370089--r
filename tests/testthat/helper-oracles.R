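# Independent brute-force oracles used to verify the package's statistics.
# They are deliberately naive (loops, enumeration) and share no code with
# the implementation.

# pooled-variance two-sample t-test from the textbook formula
oracle_t_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  delta <- mean(x) - mean(y)
  t <- if (se > 0) delta / se else if (delta == 0) 0 else Inf * sign(delta)
  list(t = t, p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

# one-sample t against 0
oracle_t_one <- function(x) {
  k <- length(x)
  s <- stats::sd(x)
  t <- if (s > 0) mean(x) / (s / sqrt(k)) else if (mean(x) == 0) 0 else Inf * sign(mean(x))
  list(t = t, p = 2 * stats::pt(-abs(t), k - 1))
}

# Benjamini-Hochberg step-up: sort p, take running minimum of p*m/rank from
# the bottom, map back to input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# signed KS running-sum statistic by explicit enumeration of the universe
# positions 1..n; tags = the tag set's positions
oracle_ks <- function(tags, n) {
  t <- length(tags)
  if (t == 0) return(0)
  a <- -Inf; b <- -Inf
  seen <- 0
  for (i in seq_len(n)) {
    if (i %in% tags) {
      # just before counting this tag: b candidate; after: a candidate
      b <- max(b, i / n - seen / t)
      seen <- seen + 1
      a <- max(a, seen / t - i / n)
    }
  }
  if (a > b) a else -b
}

oracle_combined <- function(up, dn, n) {
  ku <- oracle_ks(up, n); kd <- oracle_ks(dn, n)
  if (length(up) == 0) return(-kd)
  if (length(dn) == 0) return(ku)
  if (sign(ku) == sign(kd)) 0 else ku - kd
}

# probe -> gene collapse by scanning every gene's probes for max |FC|
oracle_collapse <- function(df) {
  df <- df[!is.na(df$gene), , drop = FALSE]
  genes <- sort(unique(df$gene))
  rows <- lapply(genes, function(g) {
    sub <- df[df$gene == g, , drop = FALSE]
    best <- sub[1, ]
    for (r in seq_len(nrow(sub))[-1]) {
      cand <- sub[r, ]
      if (abs(cand$log2_fc) > abs(best$log2_fc) ||
          (abs(cand$log2_fc) == abs(best$log2_fc) && cand$p < best$p) ||
          (abs(cand$log2_fc) == abs(best$log2_fc) && cand$p == best$p &&
           cand$probe < best$probe)) {
        best <- cand
      }
    }
    best
  })
  do.call(rbind, rows)
}

# hypergeometric upper tail P(X >= k) by enumerating every q-subset of the
# universe (exact, for small universes)
oracle_hyper_enum <- function(N, K, q, k) {
  subsets <- utils::combn(N, q)
  hits <- sum(apply(subsets, 2, function(s) sum(s <= K) >= k))
  hits / ncol(subsets)
}

# average-linkage agglomeration recomputing every cluster-pair distance from
# the original matrix at each step; ties -> smallest (first, second) indices
oracle_avg_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  ids <- -(seq_len(n))
  merges <- list(); heights <- numeric(0)
  for (step in seq_len(n - 1)) {
    best <- NULL; best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    merges[[step]] <- sort(c(ids[best[1]], ids[best[2]]))
    heights[step] <- best_d
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    ids[best[1]] <- step
    clusters[[best[2]]] <- NULL
    ids <- ids[-best[2]]
  }
  list(merges = merges, heights = heights)
}

# all-pairs shortest distances by exhaustive simple-path enumeration
# (graphs with <= 8 nodes); edges: data frame from,to,weight
oracle_all_distances <- function(nodes, edges) {
  adj <- lapply(setNames(nodes, nodes), function(v) {
    idx <- which(edges$from == v)
    list(to = edges$to[idx], w = edges$weight[idx])
  })
  dist_one <- function(s, t) {
    best <- Inf
    walk <- function(v, len, visited) {
      if (len >= best) return()
      if (v == t) { best <<- min(best, len); return() }
      a <- adj[[v]]
      for (i in seq_along(a$to)) {
        if (!(a$to[i] %in% visited)) {
          walk(a$to[i], len + a$w[i], c(visited, a$to[i]))
        }
      }
    }
    walk(s, 0, s)
    best
  }
  m <- matrix(Inf, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  diag(m) <- 0
  for (s in nodes) for (t in nodes) if (s != t) m[s, t] <- dist_one(s, t)
  m
}

# every shortest simple path between two nodes (branch-and-bound DFS)
oracle_shortest_paths <- function(nodes, edges, s, t) {
  adj <- lapply(setNames(nodes, nodes), function(v) {
    idx <- which(edges$from == v)
    list(to = edges$to[idx], w = edges$weight[idx])
  })
  best <- Inf; paths <- list()
  walk <- function(v, len, path) {
    if (len > best) return()
    if (v == t) {
      if (len < best - 1e-9) { best <<- len; paths <<- list(path) }
      else if (abs(len - best) < 1e-9) paths[[length(paths) + 1]] <<- path
      return()
    }
    a <- adj[[v]]
    for (i in seq_along(a$to)) {
      if (!(a$to[i] %in% path)) {
        walk(a$to[i], len + a$w[i], c(path, a$to[i]))
      }
    }
  }
  walk(s, 0, s)
  list(dist = best, paths = paths)
}

# stratum-rule subnetwork oracle over brute-force shortest paths
oracle_subnetwork_nodes <- function(nodes, edges, seeds, cap_max) {
  pairs <- expand.grid(from = seeds, to = seeds, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  sp <- lapply(seq_len(nrow(pairs)), function(r) {
    oracle_shortest_paths(nodes, edges, pairs$from[r], pairs$to[r])
  })
  pairs$dist <- vapply(sp, `[[`, numeric(1), "dist")
  keep <- is.finite(pairs$dist)
  pairs <- pairs[keep, ]; sp <- sp[keep]
  node_set <- seeds
  for (dv in sort(unique(pairs$dist))) {
    idx <- which(abs(pairs$dist - dv) < 1e-9)
    stratum_nodes <- unique(unlist(lapply(sp[idx], `[[`, "paths")))
    cand <- union(node_set, stratum_nodes)
    if (length(cand) > cap_max) break
    node_set <- cand
  }
  sort(node_set)
}
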