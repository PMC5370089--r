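# Pipeline orchestration: simulate/load inputs, build the screen signature,
# score the drug database, rank drugs by target-gene count, annotate,
# cluster, and extract the subnetwork — one directory of TSV/GMT/SIF/JSON
# outputs per screen plus a checksum manifest.

#' Pipeline configuration
#'
#' Assembles every knob of a screening run.  Inputs are either generated by
#' the synthetic module (`simulate` = a [sim_config()] or a list of its
#' arguments) or loaded from files (`inputs` = named paths).  Each screen
#' defines a positive and negative condition range; thresholds default to
#' the screening settings (1.8-fold change at FDR < 5% for signatures,
#' t-test p <= 0.05 for perturbed genes, enrichment FDR < 2%, subnetwork
#' node cap 70-80).
#'
#' @param config a named list, or a path to a YAML file holding one.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    seed = 1,
    simulate = list(),
    inputs = NULL,
    screens = default_screens(),
    fc_threshold = 1.8,
    fdr_threshold = 0.05,
    target_p = 0.05,
    enrichment_fdr = 0.02,
    cap_min = 70,
    cap_max = 80,
    scorer = "ks",
    aggregate = "mean",
    call_floor = 0,
    n_perm = 0
  )
  cfg <- defaults
  cfg[names(config)] <- config
  if (!cfg$scorer %in% c("ks", "corr")) stopf("pipeline_config: scorer must be ks|corr")
  if (cfg$fc_threshold <= 1) stopf("pipeline_config: fc_threshold must be > 1")
  for (f in c("fdr_threshold", "target_p", "enrichment_fdr")) {
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) stopf("pipeline_config: %s out of (0,1)", f)
  }
  if (!is.null(cfg$inputs)) {
    missing <- Filter(function(p) !file.exists(p), unlist(cfg$inputs))
    if (length(missing)) {
      stopf("pipeline_config: missing input file(s): %s",
            paste(missing, collapse = ", "))
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Default screen definitions over the synthetic compendium conditions
#'
#' Dorsalization contrasts dorsal stem cells/progenitors against lateral
#' ones; ventralization is the reverse; oligodendrogenesis contrasts the
#' oligodendrocyte lineage against its dorsal source populations; and
#' rejuvenation contrasts adult against postnatal stem cells.
#'
#' @return named list of screen specs (`positive`, `negative`).
#' @export
default_screens <- function() {
  list(
    dorsalization = list(positive = c("dNSC", "dTAP"),
                         negative = c("lNSC", "lTAP")),
    ventralization = list(positive = c("lNSC", "lTAP"),
                          negative = c("dNSC", "dTAP")),
    oligodendrogenesis = list(positive = c("OPC", "mOL"),
                              negative = c("dNSC", "dTAP")),
    rejuvenation = list(positive = "aNSC",
                        negative = c("dNSC", "lNSC"))
  )
}

# generate (synthetic) or load the full input bundle
pipeline_inputs <- function(cfg) {
  if (is.null(cfg$inputs)) {
    sim <- cfg$simulate
    if (!inherits(sim, "sim_config")) {
      sim <- do.call(sim_config, utils::modifyList(list(seed = cfg$seed), sim))
    }
    comp <- generate_compendium(sim)
    sigs <- planted_signatures(comp$truth)
    db <- generate_drug_db(sim, sigs)
    ann <- generate_annotations(sim)
    graph <- generate_graph(sim)
    list(compendium = comp$compendium, truth_de = comp$truth,
         db = db$db, truth_mimics = db$truth,
         gmt = ann$gmt, drug_targets = ann$drug_targets,
         protein_category = ann$protein_category, graph = graph)
  } else {
    p <- cfg$inputs
    gct <- read_gct(p$expression)
    annot <- read_tsv(p$probe_annotation)
    meta <- read_tsv(p$sample_metadata)
    ranks_df <- read_tsv(p$drug_ranks)
    fc_df <- read_tsv(p$drug_fold_changes)
    ranks <- as.matrix(ranks_df[, -1]); rownames(ranks) <- ranks_df[[1]]
    fc <- as.matrix(fc_df[, -1]); rownames(fc) <- fc_df[[1]]
    list(
      compendium = expression_compendium(
        gct$values,
        setNames(annot[[2]], annot[[1]]),
        setNames(meta$condition, meta$sample_id)
      ),
      truth_de = NULL,
      db = drug_profile_db(ranks, fc, read_tsv(p$drug_instances)),
      truth_mimics = NULL,
      gmt = read_gmt(p$categories),
      drug_targets = read_tsv(p$drug_targets),
      protein_category = read_tsv(p$protein_categories),
      graph = read_sif(p$graph, p$node_roles)
    )
  }
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run one screen of the pipeline
#'
#' Executes the stage chain for a single screen: differential expression at
#' the configured thresholds, probe collapsing, signature construction,
#' connectivity scoring and aggregation, target-gene derivation and drug
#' ranking, target-category breakdown, directional enrichment of the
#' top-ranked drug's target genes, target-gene expression clustering, and
#' shortest-path subnetwork extraction.  Every intermediate is written to
#' `out_dir` and a manifest records seeds, package version, and md5
#' checksums of all outputs.
#'
#' @param config a [pipeline_config()] (or list/path coerced to one).
#' @param screen screen label (must exist in `config$screens`).
#' @param out_dir output directory.
#' @param inputs optional precomputed input bundle (as returned internally
#'   when the pipeline simulates or loads inputs); reused across screens by
#'   [run_pipeline()].
#' @return invisibly, a list of in-memory results (`signature`, `scores`,
#'   `ranking`, `breakdown`, `enrichment`, `clustering`, `subnetwork`,
#'   `manifest`).
#' @export
run_screen <- function(config, screen, out_dir, inputs = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (!screen %in% names(config$screens)) {
    stopf("run_screen: unknown screen '%s'", screen)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(inputs)) inputs <- stage("inputs", pipeline_inputs(config))
  sc <- config$screens[[screen]]
  p <- function(f) file.path(out_dir, f)

  contrast <- contrast_spec(sc$positive, sc$negative,
                            fc_threshold = sc$fc_threshold %||% config$fc_threshold,
                            fdr_threshold = sc$fdr_threshold %||% config$fdr_threshold,
                            label = screen)
  stats <- stage("differential_expression",
                 differential_expression(inputs$compendium, contrast))
  gstats <- stage("collapse_probes", collapse_probes(stats))
  refinements <- lapply(sc$refine %||% list(), function(lbl) {
    rsc <- config$screens[[lbl]]
    collapse_probes(differential_expression(
      inputs$compendium,
      contrast_spec(rsc$positive, rsc$negative,
                    fc_threshold = config$fc_threshold,
                    fdr_threshold = config$fdr_threshold, label = lbl)))
  })
  sig <- stage("build_signature",
               build_signature(gstats, contrast, refinements, label = screen))
  write_tsv(as.data.frame(stats), p("probe_stats.tsv"))
  write_tsv(as.data.frame(gstats), p("gene_stats.tsv"))
  write_signature(sig, p("signature.tsv"), p("signature.gmt"))

  inst <- stage("connectivity", score_instances(sig, inputs$db,
                                                scorer = config$scorer))
  scores <- stage("aggregate", aggregate_instances(inst,
                                                   method = config$aggregate,
                                                   call_floor = config$call_floor))
  write_tsv(inst, p("instance_scores.tsv"))
  if (config$n_perm >= 100) {
    pv <- stage("permutation", permutation_pvalue(sig, inputs$db,
                                                  n_perm = config$n_perm,
                                                  seed = config$seed,
                                                  scorer = config$scorer,
                                                  method = config$aggregate))
    scores$p <- pv$p[match(scores$drug, pv$drug)]
  }
  write_tsv(as.data.frame(scores), p("drug_scores.tsv"))

  counts <- stage("target_genes",
                  target_gene_counts(inputs$db, sig,
                                     p_threshold = config$target_p))
  ranking <- stage("rank_drugs", rank_drugs(counts, scores, screen = screen))
  write_tsv(ranking$positive, p("ranking_positive.tsv"))
  write_tsv(ranking$negative, p("ranking_negative.tsv"))
  write_tsv(ranking$positive[, c("drug", "count")], p("table1.tsv"))

  breakdown <- stage("classify_targets",
                     classify_drug_targets(ranking, inputs$drug_targets,
                                           inputs$protein_category))
  write_tsv(as.data.frame(breakdown), p("target_category_pie.tsv"))

  target_sets <- attr(counts, "target_sets")
  top_drug <- if (nrow(ranking$positive)) ranking$positive$drug[1] else NULL
  enrichment <- NULL
  clustering <- NULL
  subnet <- NULL
  if (!is.null(top_drug)) {
    ts <- target_sets[[top_drug]]
    enrichment <- stage("enrichment",
                        enrich_target_genes(ts, inputs$gmt,
                                            rownames(inputs$db$ranks),
                                            fdr_threshold = config$enrichment_fdr))
    if (!is.null(enrichment$up)) write_tsv(enrichment$up, p("enrichment_up.tsv"))
    if (!is.null(enrichment$down)) write_tsv(enrichment$down, p("enrichment_down.tsv"))
    if (nrow(ts) >= 2) {
      clustering <- stage("profiling",
                          cluster_target_genes(inputs$compendium, ts$gene))
      write_profile_clustering(clustering, out_dir)
    }
    seeds <- intersect(union(ts$gene, sig$gene), inputs$graph$nodes$id)
    if (length(seeds) >= 2) {
      subnet <- stage("subnetwork",
                      extract_subnetwork(inputs$graph, seeds,
                                         cap_min = config$cap_min,
                                         cap_max = config$cap_max))
      write_subnetwork(subnet, out_dir)
    }
  }

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    screen = screen,
    seed = config$seed,
    scorer = config$scorer,
    package_version = as.character(utils::packageVersion("nichescreen")),
    signature_size = nrow(sig),
    checksums = as.list(tools::md5sum(file.path(out_dir, files))) |>
      setNames(files)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(signature = sig, instance_scores = inst, scores = scores,
                 counts = counts, ranking = ranking, breakdown = breakdown,
                 enrichment = enrichment, clustering = clustering,
                 subnetwork = subnet, manifest = manifest,
                 inputs = inputs))
}

#' Run every configured screen
#'
#' Generates (or loads) the inputs once, runs [run_screen()] for each
#' screen into `out_dir/<screen>/`, and writes a global manifest with every
#' per-screen checksum.
#'
#' @param config a [pipeline_config()] (or list/path coerced to one).
#' @param out_dir output directory.
#' @return invisibly, a named list of per-screen results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- stage("inputs", pipeline_inputs(config))
  results <- list()
  for (screen in names(config$screens)) {
    results[[screen]] <- run_screen(config, screen,
                                    file.path(out_dir, screen),
                                    inputs = inputs)
  }
  global <- list(
    seed = config$seed,
    screens = lapply(results, function(r) r$manifest$checksums)
  )
  jsonlite::write_json(global, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
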