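# Shared fixture builders: tiny deterministic containers assembled in code.

# compendium with explicit values: `mat` probe x sample, conditions derived
# from column names "<cond>_r<i>"
make_compendium <- function(mat, probe_to_gene = NULL) {
  if (is.null(probe_to_gene)) {
    probe_to_gene <- setNames(rownames(mat), rownames(mat))
  }
  cond <- sub("_r[0-9]+$", "", colnames(mat))
  expression_compendium(mat, probe_to_gene, setNames(cond, colnames(mat)))
}

# drug DB from a list of per-instance rank permutations (named integer
# vectors over the same gene universe); drug of instance i taken from
# `drugs`
make_db <- function(rank_list, drugs) {
  genes <- names(rank_list[[1]])
  ranks <- vapply(rank_list, function(r) unname(r[genes]),
                  integer(length(genes)))
  rownames(ranks) <- genes
  colnames(ranks) <- sprintf("inst_%02d", seq_along(rank_list))
  n <- length(genes)
  fc <- stats::qnorm(1 - (ranks - 0.5) / n)
  drug_profile_db(ranks, fc,
                  data.frame(instance_id = colnames(ranks), drug = drugs,
                             stringsAsFactors = FALSE))
}

# random permutation over `genes`
rand_ranks <- function(genes) {
  setNames(sample(length(genes)), genes)
}

# small sim config scaled for unit tests
tiny_sim <- function(seed = 1, ...) {
  args <- list(
    n_genes = 200, n_drugs = 30,
    planted_de = lapply(default_planted_de(), function(b) { b$n_genes <- 25; b }),
    planted_mimics = list(dorsalization = list(n_drugs = 3, strength = 0.9,
                                               sign = 1L)),
    graph_spec = list(n_nodes = 60, n_edges = 150),
    seed = seed
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# the packaged 12-probe, 3 vs 3 differential-expression fixture
load_de_fixture <- function() {
  path <- system.file("extdata", "fixture_de_12probe.tsv",
                      package = "nichescreen")
  df <- read.delim(path, check.names = FALSE)
  mat <- as.matrix(df[, -(1:2)])
  rownames(mat) <- df$probe
  make_compendium(mat, setNames(df$gene, df$probe))
}
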