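# Readers/writers for the plain-text interchange formats the pipeline uses:
# GCT 1.2 (expression matrices), GMT (gene sets), SIF (interaction graphs),
# and tab-separated tables.  GMT reading is delegated to fgsea.

#' Write an expression matrix as GCT 1.2
#'
#' @param values numeric matrix (rows = probes/genes, columns = samples).
#' @param path output file path.
#' @param descriptions optional character vector of row descriptions
#'   (defaults to the row names).
#' @return `path`, invisibly.
#' @export
write_gct <- function(values, path, descriptions = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  descriptions <- descriptions %||% rownames(values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(values), ncol(values), sep = "\t")), con)
  df <- data.frame(NAME = rownames(values), Description = descriptions,
                   values, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GCT 1.2 expression matrix
#'
#' @param path path to a GCT file.
#' @return a list with `values` (numeric matrix) and `descriptions`.
#' @export
read_gct <- function(path) {
  header <- readLines(path, n = 2)
  if (!startsWith(header[[1]], "#1.2")) stopf("not a GCT 1.2 file: %s", path)
  dims <- as.integer(strsplit(header[[2]], "\t")[[1]][1:2])
  df <- read.delim(path, skip = 2, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) != dims[1] || ncol(df) - 2L != dims[2]) {
    stopf("GCT dimension line (%d x %d) does not match table", dims[1], dims[2])
  }
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(values) <- df[[1]]
  list(values = values, descriptions = df[[2]])
}

#' Write gene sets as GMT
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param descriptions optional descriptions, recycled to `length(sets)`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from GMT
#'
#' @param path path to a GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write an interaction graph as SIF plus a node-role table
#'
#' The SIF file has one edge per line: `source<TAB>edge_type<TAB>target`.
#'
#' @param graph an [interaction_graph] object.
#' @param sif_path path for the SIF edge list.
#' @param roles_path optional path for a `node<TAB>role` TSV.
#' @return `sif_path`, invisibly.
#' @export
write_sif <- function(graph, sif_path, roles_path = NULL) {
  stopifnot(inherits(graph, "interaction_graph"))
  e <- graph$edges
  writeLines(paste(e$from, e$type, e$to, sep = "\t"), sif_path)
  if (!is.null(roles_path)) {
    write_tsv(graph$nodes, roles_path)
  }
  invisible(sif_path)
}

#' Read an interaction graph from SIF (+ optional node-role TSV)
#'
#' @param sif_path path to a SIF edge list.
#' @param roles_path optional path to a `id<TAB>role` TSV; nodes absent from
#'   it get role `"unknown"`.
#' @param weight edge weight assigned to every edge (SIF carries none).
#' @return an [interaction_graph].
#' @export
read_sif <- function(sif_path, roles_path = NULL, weight = 1) {
  parts <- strsplit(readLines(sif_path), "\t", fixed = TRUE)
  parts <- parts[lengths(parts) >= 3]
  edges <- data.frame(
    from = vapply(parts, `[[`, character(1), 1),
    type = vapply(parts, `[[`, character(1), 2),
    to   = vapply(parts, `[[`, character(1), 3),
    weight = weight, stringsAsFactors = FALSE
  )
  ids <- unique(c(edges$from, edges$to))
  roles <- setNames(rep("unknown", length(ids)), ids)
  if (!is.null(roles_path)) {
    rt <- read_tsv(roles_path)
    roles[rt[[1]]] <- rt[[2]]
    ids <- union(ids, rt[[1]])
    roles <- roles[ids]
    roles[is.na(roles)] <- "unknown"
  }
  interaction_graph(data.frame(id = ids, role = unname(roles[ids]),
                               stringsAsFactors = FALSE), edges)
}

#' Write a data frame as TSV
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV into a data frame
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a directional signature as two-column TSV and/or 2-set GMT
#'
#' @param sig a [signature][build_signature] object.
#' @param tsv_path optional path for a `gene<TAB>direction` TSV.
#' @param gmt_path optional path for a GMT with `<label>_UP` / `<label>_DN` sets.
#' @return the signature, invisibly.
#' @export
write_signature <- function(sig, tsv_path = NULL, gmt_path = NULL) {
  stopifnot(inherits(sig, "cmap_signature"))
  if (!is.null(tsv_path)) {
    write_tsv(data.frame(gene = sig$gene, direction = sig$direction), tsv_path)
  }
  if (!is.null(gmt_path)) {
    label <- attr(sig, "label") %||% "signature"
    sets <- list(sig$gene[sig$direction > 0], sig$gene[sig$direction < 0])
    names(sets) <- paste0(label, c("_UP", "_DN"))
    write_gmt(sets, gmt_path)
  }
  invisible(sig)
}

#' Read a directional signature from a two-column TSV
#'
#' @param path TSV with columns `gene` and `direction` (+1/-1).
#' @param label signature label.
#' @return a `cmap_signature`.
#' @export
read_signature <- function(path, label = basename(path)) {
  df <- read_tsv(path)
  new_signature(df$gene, as.integer(df$direction), label = label)
}
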