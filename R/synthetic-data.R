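# Synthetic-data generators.  They emulate the statistical structure of a
# germinal-zone expression compendium (replicated cell-population conditions,
# several probes per gene, planted condition-specific differential
# expression) and of a rank-based drug-perturbation database (null drugs with
# exchangeable gene ranks, planted mimics that displace a signature's genes
# toward the rank extremes), plus the annotation tables and typed interaction
# graph the downstream stages consume.  Every generator is a pure function of
# (config, seed): each draws from its own RNG stream derived from the master
# seed by a fixed offset.

SEED_OFFSETS <- c(compendium = 101L, drug_db = 202L, annotations = 303L,
                  graph = 404L)

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators.  The defaults emulate
#' a postnatal subventricular-zone compendium: dorsal and lateral stem cells
#' (dNSC/lNSC) and transient amplifying progenitors (dTAP/lTAP),
#' oligodendrocyte-lineage stages (OPC, mOL), and adult NSCs (aNSC), with a
#' block of differential genes planted per screen contrast.
#'
#' @param n_genes number of genes in the universe.
#' @param probes_per_gene integer vector `c(min, max)`; each gene gets a
#'   uniform number of probes in this range.
#' @param conditions condition labels.
#' @param replicates_per_condition replicates per condition (>= 3 by default;
#'   at least 2 are required for t-tests).
#' @param planted_de list of planted differential-expression blocks, each a
#'   list with `label`, `conditions` (where the effect applies), `n_genes`,
#'   `log2_effect` (> 0) and `prop_up` (fraction of up-regulated genes).
#'   Blocks get disjoint gene sets unless `allow_overlap = TRUE`.
#' @param allow_overlap allow planted blocks to share genes.
#' @param noise_sd Gaussian noise s.d. on the log2 scale.
#' @param baseline_mean,baseline_sd distribution of per-probe baseline log2
#'   intensity (RMA-like intensities around 7).
#' @param effect_jitter relative jitter applied per probe to the planted
#'   effect so probe collapsing is non-trivial (0.2 = +/-20%).
#' @param n_drugs number of perturbagens in the reference database.
#' @param instances_per_drug profiles per drug.
#' @param planted_mimics named list: signature label -> list(`n_drugs`,
#'   `strength` in \[0,1\], `sign` +1/-1).
#' @param n_categories number of general annotation categories.
#' @param n_proteins size of the protein-target universe.
#' @param graph_spec list with `n_nodes`, `n_edges`, optional `roles` and
#'   `edge_types` probability weights.
#' @param seed master seed; each generator derives its own stream from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000,
                       probes_per_gene = c(1, 3),
                       conditions = c("dNSC", "dTAP", "lNSC", "lTAP",
                                      "OPC", "mOL", "aNSC"),
                       replicates_per_condition = 3,
                       planted_de = default_planted_de(),
                       allow_overlap = FALSE,
                       noise_sd = 0.5,
                       baseline_mean = 7,
                       baseline_sd = 1.2,
                       effect_jitter = 0.2,
                       n_drugs = 200,
                       instances_per_drug = 3,
                       planted_mimics = default_planted_mimics(),
                       n_categories = 6,
                       n_proteins = 100,
                       graph_spec = list(n_nodes = 150, n_edges = 400),
                       seed = 1) {
  cfg <- list(n_genes = n_genes, probes_per_gene = probes_per_gene,
              conditions = conditions,
              replicates_per_condition = replicates_per_condition,
              planted_de = planted_de, allow_overlap = allow_overlap,
              noise_sd = noise_sd, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, effect_jitter = effect_jitter,
              n_drugs = n_drugs, instances_per_drug = instances_per_drug,
              planted_mimics = planted_mimics, n_categories = n_categories,
              n_proteins = n_proteins, graph_spec = graph_spec,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_planted_de <- function() {
  list(
    list(label = "dorsalization", conditions = c("dNSC", "dTAP"),
         n_genes = 150, log2_effect = 2, prop_up = 0.5),
    list(label = "ventralization", conditions = c("lNSC", "lTAP"),
         n_genes = 150, log2_effect = 2, prop_up = 0.5),
    list(label = "oligodendrogenesis", conditions = c("OPC", "mOL"),
         n_genes = 150, log2_effect = 2, prop_up = 0.5),
    list(label = "rejuvenation", conditions = "aNSC",
         n_genes = 150, log2_effect = 2, prop_up = 0.5)
  )
}

#' @rdname sim_config
#' @export
default_planted_mimics <- function() {
  list(
    dorsalization = list(n_drugs = 5, strength = 0.9, sign = 1L),
    ventralization = list(n_drugs = 5, strength = 0.9, sign = 1L),
    oligodendrogenesis = list(n_drugs = 5, strength = 0.9, sign = 1L),
    rejuvenation = list(n_drugs = 5, strength = 0.9, sign = 1L)
  )
}

validate_sim_config <- function(cfg) {
  for (f in c("n_genes", "replicates_per_condition", "n_drugs",
              "instances_per_drug", "n_categories", "n_proteins")) {
    if (!is_count(cfg[[f]])) stopf("sim_config: '%s' must be a positive count", f)
  }
  if (cfg$noise_sd <= 0) stopf("sim_config: noise_sd must be > 0")
  if (length(cfg$probes_per_gene) != 2 ||
      any(cfg$probes_per_gene < 1) ||
      cfg$probes_per_gene[1] > cfg$probes_per_gene[2]) {
    stopf("sim_config: probes_per_gene must be c(min, max) with 1 <= min <= max")
  }
  for (blk in cfg$planted_de) {
    if (!all(blk$conditions %in% cfg$conditions)) {
      stopf("sim_config: planted block '%s' names unknown conditions", blk$label)
    }
    if (blk$n_genes < 0 || blk$prop_up < 0 || blk$prop_up > 1) {
      stopf("sim_config: planted block '%s' has invalid n_genes/prop_up", blk$label)
    }
  }
  if (!cfg$allow_overlap) {
    total <- sum(vapply(cfg$planted_de, function(b) b$n_genes, numeric(1)))
    if (total > cfg$n_genes) {
      stopf("sim_config: planted DE blocks need %d disjoint genes but only %d exist",
            total, cfg$n_genes)
    }
  }
  for (lbl in names(cfg$planted_mimics)) {
    m <- cfg$planted_mimics[[lbl]]
    if (m$strength < 0 || m$strength > 1) {
      stopf("sim_config: mimic strength for '%s' must lie in [0,1]", lbl)
    }
    if (!m$sign %in% c(-1L, 1L, -1, 1)) {
      stopf("sim_config: mimic sign for '%s' must be +1 or -1", lbl)
    }
  }
  invisible(cfg)
}

gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Generate a synthetic expression compendium with planted DE structure
#'
#' Builds a probe x sample log2-intensity matrix: per-probe baselines drawn
#' once, a planted additive log2 effect for each configured differential
#' block (all probes of a gene share the effect's direction; per-probe
#' magnitudes jittered so max-fold-change probe collapsing has work to do),
#' and i.i.d. Gaussian noise.
#'
#' @param config a [sim_config()].
#' @return a list with `compendium` (an [expression_compendium]) and `truth`,
#'   a data frame of every planted (gene, contrast, signed log2 effect).
#' @export
generate_compendium <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$replicates_per_condition < 2) {
    stopf("generate_compendium: at least 2 replicates per condition are required")
  }
  with_seed(config$seed + SEED_OFFSETS[["compendium"]], {
    genes <- gene_ids(config$n_genes)
    probe_range <- seq(config$probes_per_gene[1], config$probes_per_gene[2])
    n_probes_per_gene <- probe_range[sample.int(length(probe_range),
                                                config$n_genes,
                                                replace = TRUE)]
    probe_gene <- rep(genes, n_probes_per_gene)
    probes <- paste0(probe_gene, "_p",
                     unlist(lapply(n_probes_per_gene, seq_len), use.names = FALSE))
    n_probe <- length(probes)

    samples <- as.vector(t(outer(config$conditions,
                                 seq_len(config$replicates_per_condition),
                                 function(c, r) paste0(c, "_r", r))))
    condition_of <- rep(config$conditions, each = config$replicates_per_condition)
    names(condition_of) <- samples

    baseline <- rnorm(n_probe, config$baseline_mean, config$baseline_sd)
    mu <- matrix(baseline, n_probe, length(samples),
                 dimnames = list(probes, samples))

    # assign disjoint (by default) gene blocks to planted contrasts
    truth <- list()
    pool <- genes
    for (blk in config$planted_de) {
      if (blk$n_genes == 0) next
      picked <- sort(sample(pool, blk$n_genes))
      if (!config$allow_overlap) pool <- setdiff(pool, picked)
      n_up <- round(blk$n_genes * blk$prop_up)
      dirs <- rep(c(1, -1), c(n_up, blk$n_genes - n_up))
      effect <- dirs * blk$log2_effect
      truth[[blk$label]] <- data.frame(
        gene = picked, contrast = blk$label, log2_effect = effect,
        direction = dirs, stringsAsFactors = FALSE
      )
      in_block <- probe_gene %in% picked
      probe_effect <- effect[match(probe_gene[in_block], picked)] *
        runif(sum(in_block), 1 - config$effect_jitter, 1 + config$effect_jitter)
      cols <- condition_of[samples] %in% blk$conditions
      mu[in_block, cols] <- mu[in_block, cols] + probe_effect
    }
    values <- mu + matrix(rnorm(n_probe * length(samples), 0, config$noise_sd),
                          n_probe, length(samples))
    truth <- if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE))
             else data.frame(gene = character(), contrast = character(),
                             log2_effect = numeric(), direction = numeric())
    list(
      compendium = expression_compendium(values,
                                         setNames(probe_gene, probes),
                                         condition_of),
      truth = truth
    )
  })
}

#' Generate a synthetic drug-perturbation database with planted mimics
#'
#' Null drugs get exchangeable random gene ranks per instance.  A planted
#' mimic of strength `s` and sign `+1` displaces the signature's up-genes
#' toward rank 1 and its down-genes toward rank n by a displacement
#' proportional to `s` (sign `-1` swaps the two); at `s = 1` every up-gene
#' ranks above every null gene, which ranks above every down-gene.  Each
#' instance's log2 fold changes are a monotone (normal-quantile) function of
#' its ranks, so ranks and fold changes are always consistent.
#'
#' @param config a [sim_config()].
#' @param signatures named list of signatures (one per label appearing in
#'   `config$planted_mimics`).
#' @return list with `db` (a [drug_profile_db]) and `truth`, a data frame of
#'   planted (drug, signature, strength, sign).
#' @export
generate_drug_db <- function(config, signatures = list()) {
  stopifnot(inherits(config, "sim_config"))
  mimic_labels <- names(config$planted_mimics)
  mimic_labels <- mimic_labels[mimic_labels %in% names(signatures)]
  n_mimics <- sum(vapply(config$planted_mimics[mimic_labels],
                         function(m) m$n_drugs, numeric(1)))
  if (n_mimics > config$n_drugs) {
    stopf("generate_drug_db: %d planted mimics exceed n_drugs = %d",
          n_mimics, config$n_drugs)
  }
  genes <- gene_ids(config$n_genes)
  for (lbl in mimic_labels) {
    sig <- signatures[[lbl]]
    if (!all(sig$gene %in% genes)) {
      stopf("generate_drug_db: signature '%s' contains genes outside the universe", lbl)
    }
  }
  with_seed(config$seed + SEED_OFFSETS[["drug_db"]], {
    n <- config$n_genes
    drugs <- sprintf("drug_%03d", seq_len(config$n_drugs))
    # planted mimics occupy a random subset of drugs
    mimic_drugs <- if (n_mimics > 0) sample(drugs, n_mimics) else character()
    assignment <- list(); k <- 0
    for (lbl in mimic_labels) {
      m <- config$planted_mimics[[lbl]]
      for (i in seq_len(m$n_drugs)) {
        k <- k + 1
        assignment[[mimic_drugs[k]]] <- list(label = lbl,
                                             strength = m$strength,
                                             sign = as.integer(m$sign))
      }
    }
    cell_lines <- c("MCF7", "PC3", "HL60")
    inst_rows <- list(); rank_cols <- list(); fc_cols <- list()
    for (d in drugs) {
      for (i in seq_len(config$instances_per_drug)) {
        iid <- paste0(d, "_i", i)
        u <- runif(n)
        key <- u
        if (!is.null(assignment[[d]])) {
          a <- assignment[[d]]
          sig <- signatures[[a$label]]
          up <- sig$gene[sig$direction > 0]
          dn <- sig$gene[sig$direction < 0]
          if (a$sign < 0) { tmp <- up; up <- dn; dn <- tmp }
          iu <- match(up, genes); idn <- match(dn, genes)
          key[iu] <- (1 - a$strength) * u[iu] + a$strength * 1
          key[idn] <- (1 - a$strength) * u[idn] + a$strength * 0
        }
        ranks <- integer(n)
        ranks[order(-key, -u)] <- seq_len(n)
        inst_rows[[iid]] <- data.frame(
          instance_id = iid, drug = d,
          cell_line = sample(cell_lines, 1),
          dose = sample(c("100 nM", "1 uM", "10 uM"), 1),
          stringsAsFactors = FALSE
        )
        rank_cols[[iid]] <- ranks
        fc_cols[[iid]] <- qnorm(1 - (ranks - 0.5) / n)
      }
    }
    ranks <- do.call(cbind, rank_cols); rownames(ranks) <- genes
    fc <- do.call(cbind, fc_cols); rownames(fc) <- genes
    truth <- if (length(assignment)) {
      data.frame(
        drug = names(assignment),
        signature = vapply(assignment, `[[`, character(1), "label"),
        strength = vapply(assignment, `[[`, numeric(1), "strength"),
        sign = vapply(assignment, `[[`, integer(1), "sign"),
        row.names = NULL, stringsAsFactors = FALSE
      )
    } else {
      data.frame(drug = character(), signature = character(),
                 strength = numeric(), sign = integer())
    }
    list(
      db = drug_profile_db(ranks, fc,
                           do.call(rbind, c(inst_rows, make.row.names = FALSE))),
      truth = truth
    )
  })
}

#' Generate synthetic annotation tables
#'
#' Produces the three tables downstream annotation needs: a GMT of category
#' gene sets that partition the gene universe, a drug -> protein-target map
#' (every drug gets at least one target; row order defines target priority),
#' and a protein -> category map in which categories partition the protein
#' universe.  The default category names follow the broad functional classes
#' used for perturbagen pies (receptor antagonists, signaling, metabolism,
#' gene regulation, epigenetics, cell cycle).
#'
#' @param config a [sim_config()].
#' @return list with `gmt` (named list of gene sets), `drug_targets`
#'   (data frame `drug`, `protein`), `protein_category` (data frame
#'   `protein`, `category`).
#' @export
generate_annotations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + SEED_OFFSETS[["annotations"]], {
    base_names <- c("Receptor antagonist", "Signaling", "Metabolism",
                    "Gene regulation", "Epigenetic", "Cell cycle")
    k <- config$n_categories
    cats <- if (k <= length(base_names)) base_names[seq_len(k)]
            else c(base_names, sprintf("Category %02d", seq_len(k - length(base_names))))
    genes <- gene_ids(config$n_genes)
    # categories partition the gene universe (for enrichment GMT)
    gene_cat <- sample(rep_len(cats, length(genes)))
    gmt <- split(genes, factor(gene_cat, levels = cats))
    # categories partition the protein universe
    proteins <- sprintf("PROT_%03d", seq_len(config$n_proteins))
    prot_cat <- sample(rep_len(cats, length(proteins)))
    protein_category <- data.frame(protein = proteins, category = prot_cat,
                                   stringsAsFactors = FALSE)
    drugs <- sprintf("drug_%03d", seq_len(config$n_drugs))
    drug_targets <- do.call(rbind, lapply(drugs, function(d) {
      data.frame(drug = d,
                 protein = sample(proteins, sample(1:3, 1)),
                 stringsAsFactors = FALSE)
    }))
    list(gmt = gmt, drug_targets = drug_targets,
         protein_category = protein_category)
  })
}

#' Generate a synthetic typed interaction graph
#'
#' Directed graph over a sample of the gene universe.  Nodes carry roles
#' (ligand, receptor, kinase, transcription-factor, target-gene) and edges
#' carry interaction types (activation, inhibition, binding,
#' transcriptional-regulation).  A random attachment backbone guarantees a
#' weakly connected giant component covering at least 80% of nodes; no
#' self-loops are emitted.
#'
#' @param config a [sim_config()].
#' @return an [interaction_graph].
#' @export
generate_graph <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gs <- config$graph_spec
  n_nodes <- gs$n_nodes %||% 150
  n_edges <- gs$n_edges %||% (3 * n_nodes)
  roles <- gs$roles %||% c(ligand = 0.15, receptor = 0.15, kinase = 0.2,
                           `transcription-factor` = 0.2, `target-gene` = 0.3)
  edge_types <- gs$edge_types %||% c(activation = 0.4, inhibition = 0.25,
                                     binding = 0.2,
                                     `transcriptional-regulation` = 0.15)
  if (n_nodes > config$n_genes) {
    stopf("generate_graph: n_nodes (%d) exceeds the gene universe (%d)",
          n_nodes, config$n_genes)
  }
  with_seed(config$seed + SEED_OFFSETS[["graph"]], {
    ids <- sort(sample(gene_ids(config$n_genes), n_nodes))
    node_role <- sample(names(roles), n_nodes, replace = TRUE, prob = roles)
    # backbone over 90% of nodes: each attaches to a random earlier node,
    # random orientation -> weak giant component >= 80% guaranteed
    core <- ceiling(0.9 * n_nodes)
    from <- to <- character(0)
    if (core >= 2) {
      for (i in 2:core) {
        j <- sample(i - 1, 1)
        if (runif(1) < 0.5) { from <- c(from, ids[j]); to <- c(to, ids[i]) }
        else { from <- c(from, ids[i]); to <- c(to, ids[j]) }
      }
    }
    n_extra <- max(0, n_edges - length(from))
    seen <- paste(from, to)
    tries <- 0
    while (n_extra > 0 && tries < 50 * n_edges) {
      tries <- tries + 1
      pair <- sample(n_nodes, 2)
      key <- paste(ids[pair[1]], ids[pair[2]])
      if (key %in% seen) next
      seen <- c(seen, key)
      from <- c(from, ids[pair[1]]); to <- c(to, ids[pair[2]])
      n_extra <- n_extra - 1
    }
    edges <- data.frame(
      from = from, to = to,
      type = sample(names(edge_types), length(from), replace = TRUE,
                    prob = edge_types),
      weight = 1, stringsAsFactors = FALSE
    )
    interaction_graph(data.frame(id = ids, role = node_role,
                                 stringsAsFactors = FALSE), edges)
  })
}

#' Generate and write every synthetic input to a directory
#'
#' Runs all four generators (signatures for planted mimics are taken from
#' the compendium's planted truth) and writes the standard interchange
#' files: GCT + TSV expression matrix, probe annotation and sample metadata
#' TSVs, drug rank/fold-change matrices + instance metadata TSVs, category
#' GMT, drug-target and protein-category TSVs, SIF graph + node roles, and
#' the ground-truth tables.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all generated objects.
#' @export
simulate_inputs <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  comp <- generate_compendium(config)
  sigs <- planted_signatures(comp$truth)
  db <- generate_drug_db(config, sigs)
  ann <- generate_annotations(config)
  graph <- generate_graph(config)

  p <- function(f) file.path(out_dir, f)
  write_gct(comp$compendium$values, p("expression.gct"),
            descriptions = unname(comp$compendium$probe_to_gene))
  write_tsv(data.frame(probe_id = rownames(comp$compendium$values),
                       comp$compendium$values, check.names = FALSE),
            p("expression.tsv"))
  write_tsv(data.frame(probe_id = names(comp$compendium$probe_to_gene),
                       gene_symbol = unname(comp$compendium$probe_to_gene)),
            p("probe_annotation.tsv"))
  s2c <- comp$compendium$sample_to_condition
  write_tsv(data.frame(sample_id = names(s2c), condition = unname(s2c),
                       replicate = sub(".*_r", "", names(s2c))),
            p("sample_metadata.tsv"))
  write_tsv(data.frame(gene = rownames(db$db$ranks), db$db$ranks,
                       check.names = FALSE), p("drug_ranks.tsv"))
  write_tsv(data.frame(gene = rownames(db$db$fc), db$db$fc,
                       check.names = FALSE), p("drug_fold_changes.tsv"))
  write_tsv(db$db$instances, p("drug_instances.tsv"))
  write_gmt(ann$gmt, p("categories.gmt"))
  write_tsv(ann$drug_targets, p("drug_targets.tsv"))
  write_tsv(ann$protein_category, p("protein_categories.tsv"))
  write_sif(graph, p("graph.sif"), p("node_roles.tsv"))
  write_tsv(comp$truth, p("truth_de.tsv"))
  write_tsv(db$truth, p("truth_mimics.tsv"))
  invisible(list(compendium = comp$compendium, truth_de = comp$truth,
                 db = db$db, truth_mimics = db$truth, annotations = ann,
                 graph = graph, signatures = sigs))
}

#' Planted-truth signatures from a ground-truth DE table
#'
#' @param truth the `truth` data frame from [generate_compendium()].
#' @return named list of `cmap_signature` objects, one per planted contrast.
#' @export
planted_signatures <- function(truth) {
  out <- lapply(split(truth, truth$contrast), function(tt) {
    new_signature(tt$gene, tt$direction, log2_fc = tt$log2_effect,
                  label = tt$contrast[1])
  })
  out[unique(truth$contrast)]
}
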