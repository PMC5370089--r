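# Connectivity scoring: KS running-sum statistic against a brute-force
# enumeration oracle, correlation scorer, aggregation, and permutation p.

test_that("KS combined score matches the enumeration oracle on a 10-gene example", {
  genes <- paste0("g", 1:10)
  ranks <- setNames(1:10, genes)
  sig <- new_signature(c("g1", "g2", "g9", "g10"), c(1, 1, -1, -1))
  s <- ks_connectivity_score(sig, ranks)
  expect_true(sign(s$ks_up) != sign(s$ks_down))
  expect_gt(s$combined, 0)
  expect_equal(s$ks_up, oracle_ks(c(1, 2), 10), tolerance = 1e-12)
  expect_equal(s$ks_down, oracle_ks(c(9, 10), 10), tolerance = 1e-12)
  expect_equal(s$combined, oracle_combined(c(1, 2), c(9, 10), 10),
               tolerance = 1e-12)
})

test_that("KS oracle equivalence holds over many random signature/instance pairs", {
  set.seed(101)
  for (rep in 1:300) {
    n <- sample(7:20, 1)
    genes <- paste0("g", seq_len(n))
    ranks <- rand_ranks(genes)
    n_up <- sample(1:3, 1); n_dn <- sample(1:3, 1)
    picked <- sample(genes, n_up + n_dn)
    sig <- new_signature(picked, rep(c(1, -1), c(n_up, n_dn)))
    s <- ks_connectivity_score(sig, ranks)
    up_pos <- sort(unname(ranks[picked[seq_len(n_up)]]))
    dn_pos <- sort(unname(ranks[picked[n_up + seq_len(n_dn)]]))
    expect_identical(s$combined, oracle_combined(up_pos, dn_pos, n))
  }
})

test_that("same-sign KS statistics give exactly zero", {
  genes <- paste0("g", 1:10)
  ranks <- setNames(1:10, genes)
  # both sets at the top: both running sums deviate upward
  sig <- new_signature(c("g1", "g2", "g3", "g4"), c(1, 1, -1, -1))
  s <- ks_connectivity_score(sig, ranks)
  expect_identical(sign(s$ks_up), sign(s$ks_down))
  expect_identical(s$combined, 0)
})

test_that("swapping up- and down-sets exactly negates the combined score", {
  set.seed(55)
  for (rep in 1:50) {
    genes <- paste0("g", 1:15)
    ranks <- rand_ranks(genes)
    picked <- sample(genes, 6)
    sig <- new_signature(picked, rep(c(1, -1), each = 3))
    swapped <- new_signature(picked, rep(c(-1, 1), each = 3))
    a <- ks_connectivity_score(sig, ranks)$combined
    b <- ks_connectivity_score(swapped, ranks)$combined
    expect_identical(a, -b)
  }
})

test_that("one-sided signatures are flagged and scored by the populated side", {
  genes <- paste0("g", 1:10)
  ranks <- setNames(1:10, genes)
  up_only <- new_signature(c("g1", "g2"), c(1, 1))
  s <- ks_connectivity_score(up_only, ranks)
  expect_true(s$one_sided)
  expect_equal(s$combined, s$ks_up)
  dn_only <- new_signature(c("g1", "g2"), c(-1, -1))
  s2 <- ks_connectivity_score(dn_only, ranks)
  expect_true(s2$one_sided)
  expect_equal(s2$combined, -s2$ks_down)
  # no overlap at all -> error
  stranger <- new_signature(c("x1", "x2"), c(1, -1))
  expect_error(ks_connectivity_score(stranger, ranks), "no signature gene")
  # absent genes are dropped and counted
  mixed <- new_signature(c("g1", "x1", "g9"), c(1, 1, -1))
  expect_equal(ks_connectivity_score(mixed, ranks)$n_dropped, 1)
})

test_that("correlation scorer: identity, antisymmetry, and a frozen 8-gene value", {
  genes <- paste0("g", 1:8)
  dirs <- c(1, 1, 1, 1, -1, -1, -1, -1)
  sig <- new_signature(genes, dirs)
  fc <- setNames(as.numeric(dirs), genes)
  expect_equal(correlation_connectivity_score(sig, fc)$r, 1)
  expect_equal(correlation_connectivity_score(sig, -fc)$r, -1)
  # fixed fold-change vector; expected r from the covariance formula
  fc2 <- setNames(c(1.2, 0.8, 0.1, 0.5, -0.9, -1.4, 0.2, -0.3), genes)
  d <- dirs; v <- unname(fc2)
  r_oracle <- sum((d - mean(d)) * (v - mean(v))) /
    sqrt(sum((d - mean(d))^2) * sum((v - mean(v))^2))
  got <- correlation_connectivity_score(sig, fc2)
  expect_equal(got$r, r_oracle, tolerance = 1e-12)
  expect_equal(got$r, 0.7726213, tolerance = 1e-6)
  # p matches the t transform
  tt <- r_oracle * sqrt((8 - 2) / (1 - r_oracle^2))
  expect_equal(got$p, 2 * pt(-abs(tt), 6), tolerance = 1e-12)
  # degenerate inputs
  expect_error(correlation_connectivity_score(sig, fc2[1:2]), "3 overlapping")
  flat <- setNames(rep(1, 8), genes)
  expect_true(is.na(correlation_connectivity_score(sig, flat)$combined))
})

test_that("aggregation normalizes to [-1, 1] with exactly one drug at the max", {
  set.seed(7)
  genes <- paste0("g", 1:50)
  insts <- lapply(1:40, function(i) rand_ranks(genes))
  db <- make_db(insts, rep(sprintf("d%02d", 1:20), each = 2))
  sig <- new_signature(sample(genes, 10), rep(c(1, -1), 5))
  res <- aggregate_instances(score_instances(sig, db, "ks"))
  expect_true(all(abs(res$score) <= 1 + 1e-12))
  expect_equal(sum(abs(abs(res$score) - 1) < 1e-12), 1)
  # single-instance drug keeps its own (normalized) score
  genes12 <- paste0("g", 1:12)
  db1 <- make_db(list(setNames(1:12, genes12), setNames(12:1, genes12),
                      setNames(c(6:1, 12:7), genes12)),
                 c("a", "b", "c"))
  sigd <- new_signature(c("g1", "g2", "g11", "g12"), c(1, 1, -1, -1))
  inst1 <- score_instances(sigd, db1, "ks")
  res1 <- aggregate_instances(inst1)
  norm <- attr(res1, "norm")
  expect_equal(res1$score[res1$drug == "a"],
               inst1$score[inst1$drug == "a"] / norm)
  # opposite instance scores cancel to a null call
  fake <- data.frame(instance_id = c("i1", "i2"), drug = "d",
                     score = c(0.5, -0.5))
  res2 <- aggregate_instances(fake)
  expect_equal(res2$raw_score, 0)
  expect_equal(res2$call, "null")
})

test_that("drug-level scores rise monotonically with planted mimic strength", {
  strengths <- c(0, 0.25, 0.5, 0.75, 1)
  for (scorer in c("ks", "corr")) {
    means <- vapply(strengths, function(s) {
      cfg <- tiny_sim(seed = 31, n_drugs = 12,
                      planted_mimics = if (s == 0) list() else
                        list(dorsalization = list(n_drugs = 4, strength = s,
                                                  sign = 1L)))
      truth <- generate_compendium(cfg)$truth
      sigs <- planted_signatures(truth)
      db <- generate_drug_db(cfg, sigs)
      if (s == 0) return(0)
      inst <- score_instances(sigs$dorsalization, db$db, scorer)
      agg <- aggregate_instances(inst)
      mean(agg$raw_score[agg$drug %in% db$truth$drug])
    }, numeric(1))
    expect_true(all(diff(means) >= -1e-9),
                info = paste("scorer:", scorer))
  }
})

test_that("relabeling genes consistently leaves every score unchanged", {
  set.seed(19)
  genes <- paste0("g", 1:30)
  ranks <- rand_ranks(genes)
  sig <- new_signature(sample(genes, 8), rep(c(1, -1), 4))
  s1 <- ks_connectivity_score(sig, ranks)$combined
  relabel <- setNames(paste0("X", seq_along(genes)), genes)
  ranks2 <- setNames(unname(ranks), unname(relabel[names(ranks)]))
  sig2 <- new_signature(unname(relabel[sig$gene]), sig$direction)
  expect_identical(ks_connectivity_score(sig2, ranks2)$combined, s1)
})

test_that("permutation p-values obey the add-one convention and its bounds", {
  set.seed(23)
  genes <- paste0("g", 1:40)
  insts <- lapply(1:6, function(i) rand_ranks(genes))
  db <- make_db(insts, rep(c("a", "b", "c"), each = 2))
  sig <- new_signature(sample(genes, 8), rep(c(1, -1), 4))
  pv <- permutation_pvalue(sig, db, n_perm = 100, seed = 5)
  expect_true(all(pv$p >= 1 / 101))
  expect_true(all(pv$p <= 1))
  # reproducible, and independent of drug order in the database
  pv2 <- permutation_pvalue(sig, db, n_perm = 100, seed = 5)
  expect_identical(pv$p, pv2$p)
  db_rev <- make_db(rev(insts), rep(c("c", "b", "a"), each = 2))
  pv3 <- permutation_pvalue(sig, db_rev, n_perm = 100, seed = 5)
  expect_equal(pv3$p[match(pv$drug, pv3$drug)], pv$p)
  expect_error(permutation_pvalue(sig, db, n_perm = 50), ">= 100")
})

test_that("an observed aggregate of zero gets p = 1 under the add-one rule", {
  # two instances with exactly mirrored rankings cancel to raw score 0
  genes <- paste0("g", 1:12)
  r1 <- setNames(1:12, genes)
  r2 <- setNames(12:1, genes)
  db <- make_db(list(r1, r2), c("d", "d"))
  sig <- new_signature(c("g1", "g2", "g11", "g12"), c(1, 1, -1, -1))
  pv <- permutation_pvalue(sig, db, n_perm = 100, seed = 9)
  expect_equal(pv$raw_score, 0)
  expect_equal(pv$p, 1)
})
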