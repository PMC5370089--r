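# Synthetic-data generators: determinism, construction invariants, and the
# planted statistical structure the downstream stages rely on.

test_that("generators are pure functions of (config, seed)", {
  cfg <- tiny_sim(seed = 11)
  a <- generate_compendium(cfg); b <- generate_compendium(cfg)
  expect_identical(a$compendium$values, b$compendium$values)
  expect_identical(a$truth, b$truth)

  sigs <- planted_signatures(a$truth)
  d1 <- generate_drug_db(cfg, sigs); d2 <- generate_drug_db(cfg, sigs)
  expect_identical(d1$db$ranks, d2$db$ranks)
  expect_identical(d1$truth, d2$truth)

  expect_identical(generate_annotations(cfg), generate_annotations(cfg))
  g1 <- generate_graph(cfg); g2 <- generate_graph(cfg)
  expect_identical(g1$edges, g2$edges)

  # a different seed changes the output
  cfg2 <- tiny_sim(seed = 12)
  expect_false(identical(generate_compendium(cfg2)$compendium$values,
                         a$compendium$values))
})

test_that("compendium construction matches the configured shape", {
  cfg <- tiny_sim(seed = 2, n_genes = 100, probes_per_gene = c(3, 3),
                  planted_de = list())
  out <- generate_compendium(cfg)
  expect_equal(nrow(out$compendium$values), 300)  # 100 genes x 3 probes
  expect_equal(ncol(out$compendium$values),
               length(cfg$conditions) * cfg$replicates_per_condition)
  expect_equal(nrow(out$truth), 0)  # nothing planted -> empty truth table
  # zero planted effect likewise yields an empty truth table
  cfg0 <- tiny_sim(seed = 2, planted_de = lapply(default_planted_de(),
                                                 function(b) { b$n_genes <- 0; b }))
  expect_equal(nrow(generate_compendium(cfg0)$truth), 0)
})

test_that("compendium rejects configs that make t-tests impossible", {
  expect_error(generate_compendium(tiny_sim(replicates_per_condition = 1)),
               "replicates")
  expect_error(tiny_sim(noise_sd = 0), "noise_sd")
  expect_error(tiny_sim(n_genes = 100,
                        planted_de = list(list(label = "x",
                                               conditions = "dNSC",
                                               n_genes = 80, log2_effect = 1,
                                               prop_up = 0.5),
                                          list(label = "y",
                                               conditions = "lNSC",
                                               n_genes = 80, log2_effect = 1,
                                               prop_up = 0.5))),
               "disjoint")
})

test_that("planted DE blocks are disjoint and probes share gene direction", {
  cfg <- tiny_sim(seed = 5)
  out <- generate_compendium(cfg)
  sp <- split(out$truth$gene, out$truth$contrast)
  for (i in seq_along(sp)) for (j in seq_along(sp)) {
    if (i < j) expect_length(intersect(sp[[i]], sp[[j]]), 0)
  }
  # measured probe-level fold changes of a planted gene all share its sign
  comp <- out$compendium
  blk <- out$truth[out$truth$contrast == "dorsalization", ]
  cond <- comp$sample_to_condition
  pos <- names(cond)[cond %in% c("dNSC", "dTAP")]
  neg <- names(cond)[!cond %in% c("dNSC", "dTAP")]
  for (g in blk$gene[1:5]) {
    probes <- names(comp$probe_to_gene)[comp$probe_to_gene == g]
    deltas <- rowMeans(comp$values[probes, pos, drop = FALSE]) -
      rowMeans(comp$values[probes, neg, drop = FALSE])
    expect_true(all(sign(deltas) == blk$direction[blk$gene == g]))
  }
})

test_that("planted mimics displace signature genes as configured", {
  cfg <- tiny_sim(seed = 3,
                  planted_mimics = list(dorsalization = list(n_drugs = 2,
                                                             strength = 1,
                                                             sign = 1L)))
  truth <- generate_compendium(cfg)$truth
  sigs <- planted_signatures(truth)
  out <- generate_drug_db(cfg, sigs)
  sig <- sigs$dorsalization
  up <- sig$gene[sig$direction > 0]; dn <- sig$gene[sig$direction < 0]
  for (d in out$truth$drug) {
    ids <- out$db$instances$instance_id[out$db$instances$drug == d]
    for (iid in ids) {
      r <- out$db$ranks[, iid]
      # strength 1, sign +: every up-gene ranks above every down-gene
      expect_lt(max(r[up]), min(r[dn]))
    }
  }
  # sign -1 swaps the two sets
  cfg2 <- tiny_sim(seed = 3,
                   planted_mimics = list(dorsalization = list(n_drugs = 1,
                                                              strength = 1,
                                                              sign = -1L)))
  out2 <- generate_drug_db(cfg2, sigs)
  iid <- out2$db$instances$instance_id[out2$db$instances$drug ==
                                         out2$truth$drug[1]][1]
  r2 <- out2$db$ranks[, iid]
  expect_lt(max(r2[dn]), min(r2[up]))
  # mimic count exceeding the drug count is rejected
  cfg3 <- tiny_sim(n_drugs = 2,
                   planted_mimics = list(dorsalization = list(n_drugs = 5,
                                                              strength = 1,
                                                              sign = 1L)))
  expect_error(generate_drug_db(cfg3, sigs), "exceed")
})

test_that("strength-0 drugs are exchangeable: mean KS score centred at 0", {
  cfg <- tiny_sim(seed = 9, n_genes = 300, n_drugs = 500,
                  instances_per_drug = 1, planted_mimics = list())
  truth <- generate_compendium(cfg)$truth
  sigs <- planted_signatures(truth)
  db <- generate_drug_db(cfg, sigs)$db
  inst <- score_instances(sigs$dorsalization, db, scorer = "ks")
  sem <- sd(inst$score) / sqrt(nrow(inst))
  expect_lt(abs(mean(inst$score)), 2 * sem)
})

test_that("signature recovery from the planted compendium is >= 95% with <= 5% FDR", {
  cfg <- tiny_sim(seed = 21, n_genes = 500,
                  planted_de = list(list(label = "dorsalization",
                                         conditions = c("dNSC", "dTAP"),
                                         n_genes = 100, log2_effect = 2,
                                         prop_up = 0.5)))
  out <- generate_compendium(cfg)  # effect 2.0 = 4x noise_sd 0.5
  contrast <- contrast_spec(c("dNSC", "dTAP"), c("lNSC", "lTAP"))
  sig <- build_signature(collapse_probes(differential_expression(out$compendium,
                                                                 contrast)),
                         contrast, label = "dorsalization")
  truth <- out$truth$gene
  recall <- length(intersect(sig$gene, truth)) / length(truth)
  fdr <- length(setdiff(sig$gene, truth)) / nrow(sig)
  expect_gte(recall, 0.95)
  expect_lte(fdr, 0.05)
})

test_that("annotations partition proteins and cover every drug", {
  cfg <- tiny_sim(seed = 4)
  ann <- generate_annotations(cfg)
  # categories partition the protein universe: each protein exactly once
  expect_equal(sort(ann$protein_category$protein),
               sprintf("PROT_%03d", seq_len(cfg$n_proteins)))
  expect_false(anyDuplicated(ann$protein_category$protein) > 0)
  # every drug has at least one target
  expect_setequal(unique(ann$drug_targets$drug),
                  sprintf("drug_%03d", seq_len(cfg$n_drugs)))
  # gene sets partition the gene universe
  all_genes <- unlist(ann$gmt, use.names = FALSE)
  expect_equal(sort(all_genes), sprintf("G%04d", seq_len(cfg$n_genes)))
  expect_equal(length(ann$gmt), cfg$n_categories)
  # single category -> downstream pie is one slice at 100%
  ann1 <- generate_annotations(tiny_sim(seed = 4, n_categories = 1))
  rk <- data.frame(drug = unique(ann1$drug_targets$drug)[1:5])
  pie <- classify_drug_targets(rk, ann1$drug_targets, ann1$protein_category)
  expect_equal(nrow(pie), 1)
  expect_equal(pie$percentage, 100)
})

test_that("graph generator honours node count, bans self-loops, stays connected", {
  cfg <- tiny_sim(seed = 6, graph_spec = list(n_nodes = 50, n_edges = 120))
  g <- generate_graph(cfg)
  expect_equal(nrow(g$nodes), 50)
  expect_true(all(g$edges$from != g$edges$to))
  expect_true(all(g$nodes$role %in% c("ligand", "receptor", "kinase",
                                      "transcription-factor", "target-gene")))
  expect_true(all(g$edges$type %in% c("activation", "inhibition", "binding",
                                      "transcriptional-regulation")))
  comp <- igraph::components(as_igraph(g), mode = "weak")
  expect_gte(max(comp$csize) / nrow(g$nodes), 0.8)
})

test_that("simulate_inputs writes a round-trippable file bundle", {
  dir <- withr::local_tempdir()
  cfg <- tiny_sim(seed = 8, n_genes = 100, n_drugs = 10,
                  planted_de = list(list(label = "dorsalization",
                                         conditions = c("dNSC", "dTAP"),
                                         n_genes = 15, log2_effect = 2,
                                         prop_up = 0.5)),
                  planted_mimics = list(),
                  graph_spec = list(n_nodes = 40, n_edges = 90))
  objs <- simulate_inputs(cfg, dir)
  gct <- read_gct(file.path(dir, "expression.gct"))
  expect_equal(gct$values, objs$compendium$values, tolerance = 1e-12)
  rk <- read_tsv(file.path(dir, "drug_ranks.tsv"))
  expect_equal(as.integer(as.matrix(rk[, -1])),
               as.integer(objs$db$ranks))
  gmt <- read_gmt(file.path(dir, "categories.gmt"))
  expect_equal(lapply(gmt, sort), lapply(objs$annotations$gmt, sort),
               ignore_attr = TRUE)
  g <- read_sif(file.path(dir, "graph.sif"), file.path(dir, "node_roles.tsv"))
  expect_setequal(paste(g$edges$from, g$edges$to, g$edges$type),
                  paste(objs$graph$edges$from, objs$graph$edges$to,
                        objs$graph$edges$type))
})
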