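# Config-driven orchestration of the full analysis:
# simulate -> normalize -> annotate -> select -> cluster -> associate ->
# differential -> integrate (eight stages).

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. All
#' randomness derives from `seed`; stage parameters default to the analysis
#' conventions used throughout the package (top 1% most variable probes,
#' Euclidean/Ward clustering, |delta-beta| > 0.2 with BH-adjusted p < 0.05).
#'
#' @param seed Master seed (integer).
#' @param outdir Output directory for stage artifacts.
#' @param simulate Named list of [simulation_config()] overrides.
#' @param select List: `mode` ("fraction"/"count"), `amount` (default 0.01).
#' @param cluster List: `distance`, `linkage`, `perplexity`.
#' @param dm List: `delta_threshold`, `alpha`.
#' @param de List: `alpha`, `lfc_threshold`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed, outdir = tempfile("methylgemm_run_"),
                            simulate = list(), select = list(),
                            cluster = list(), dm = list(), de = list()) {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    simulate = simulate,
    select = utils::modifyList(list(mode = "fraction", amount = 0.01), select),
    cluster = utils::modifyList(
      list(distance = "euclidean", linkage = "ward.D2", perplexity = 5), cluster),
    dm = utils::modifyList(list(delta_threshold = 0.2, alpha = 0.05), dm),
    de = utils::modifyList(list(alpha = 0.05, lfc_threshold = 0), de)
  )
  if (cfg$select$amount <= 0) stop("select$amount must be > 0", call. = FALSE)
  if (cfg$dm$delta_threshold < 0 || cfg$dm$delta_threshold >= 1) {
    stop("dm$delta_threshold must be in [0, 1)", call. = FALSE)
  }
  if (cfg$dm$alpha <= 0 || cfg$dm$alpha > 1 || cfg$de$alpha <= 0 || cfg$de$alpha > 1) {
    stop("alpha must be in (0, 1]", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [pipeline_config()] arguments: top-level `seed`,
#' `outdir`, and optional `simulate`, `select`, `cluster`, `dm`, `de` blocks.
#'
#' @param path YAML file.
#' @param outdir Optional override of the configured output directory.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must set a seed", call. = FALSE)
  pipeline_config(
    seed = y$seed,
    outdir = outdir %||% y$outdir %||% tempfile("methylgemm_run_"),
    simulate = y$simulate %||% list(),
    select = y$select %||% list(),
    cluster = y$cluster %||% list(),
    dm = y$dm %||% list(),
    de = y$de %||% list()
  )
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(cfg)), f)
  unname(tools::md5sum(f))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the eight stages in dependency order on a seeded synthetic cohort:
#' (1) simulate the mouse and human cohorts with planted truth; (2) simulate
#' raw two-design intensities and SWAN-normalize them; (3) annotate probes to
#' promoter/body gene regions; (4) select the most variable probes; (5)
#' hierarchically cluster with a nested cut of the fusion-negative-like
#' cluster, plus a t-SNE embedding; (6) associate cluster labels with sample
#' metadata (exact tests); (7) call DM probes and DE genes for the main and
#' subset contrasts in mouse and the FP-vs-FN contrast in human; (8)
#' integrate DM/DE, match conserved genes across species, and test enrichment
#' against the planted gene sets. Stage outputs are written under
#' `config$outdir` and check-summed into the run manifest; a failure in any
#' stage halts with a stage-attributed error.
#'
#' Cluster-label orientation is fixed by fusion-expression metadata (the
#' high-fusion-enriched main cluster is ML, the other MR; the smaller MR
#' subset is MR1), so association tables are stable across runs.
#'
#' @param config A `pipeline_config`.
#' @return Object of class `methylgemm_run`: all stage results plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "methylGEMM",
                   version = as.character(utils::packageVersion("methylGEMM")),
                   seed = config$seed,
                   config_hash = config_hash(config),
                   stages = list())
  res <- new.env(parent = emptyenv())

  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    files <- attr(out, "stage_files") %||% character()
    manifest$stages[[name]] <<- list(
      name = name,
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = as.list(tools::md5sum(files))
    )
    out
  }

  # 1. simulate ------------------------------------------------------------
  sim <- stage("simulate", function() {
    simcfg <- do.call(simulation_config,
                      utils::modifyList(list(seed = config$seed),
                                        config$simulate))
    mouse <- generate_mouse_cohort(simcfg)
    human <- generate_human_cohort(simcfg, mouse$truth)
    f1 <- write_cohort(mouse, file.path(config$outdir, "mouse"))
    f2 <- write_cohort(human, file.path(config$outdir, "human"))
    structure(list(simcfg = simcfg, mouse = mouse, human = human),
              stage_files = c(f1, f2))
  })

  # 2. normalize -----------------------------------------------------------
  norm <- stage("normalize", function() {
    intens <- generate_intensities(sim$simcfg)
    sw <- swan_normalize(intens, seed = substream_seed(config$seed, 5L))
    beta <- intensities_to_beta(sw)
    f <- write_matrix_tsv(beta, file.path(config$outdir, "beta_normalized.tsv"),
                          "probe_id")
    structure(list(raw = intens, normalized = sw, beta = beta),
              stage_files = f)
  })

  # 3. annotate ------------------------------------------------------------
  ann <- stage("annotate", function() {
    mouse_assign <- annotate_probes(sim$mouse$manifest, sim$mouse$transcripts)
    tx_h <- as.data.frame(sim$mouse$transcripts)
    tx_h$gene_symbol <- toupper(tx_h$gene_symbol)
    human_manifest <- sim$human$manifest
    human_assign <- annotate_probes(human_manifest, tx_h)
    universe <- build_reference_universe(mouse_assign, human_assign,
                                         sim$human$homolog_map)
    f <- c(write_table_tsv(mouse_assign,
                           file.path(config$outdir, "assignments_mouse.tsv")),
           write_table_tsv(human_assign,
                           file.path(config$outdir, "assignments_human.tsv")))
    structure(list(mouse = mouse_assign, human = human_assign,
                   universe = universe), stage_files = f)
  })

  # 4. select --------------------------------------------------------------
  sel <- stage("select", function() {
    s <- select_top_variable(impute_probe_means(sim$mouse$beta),
                             mode = config$select$mode,
                             amount = config$select$amount)
    structure(list(beta = s),
              stage_files = write_matrix_tsv(
                s, file.path(config$outdir, "beta_selected.tsv"), "probe_id"))
  })

  # 5. cluster -------------------------------------------------------------
  clu <- stage("cluster", function() {
    generic <- hierarchical_cluster(sel$beta, k_main = 2L,
                                    distance = config$cluster$distance,
                                    linkage = config$cluster$linkage)
    oriented <- orient_cluster_labels(generic, sel$beta,
                                      sim$mouse$sample_sheet, config)
    emb <- tsne_embed(sel$beta, perplexity = config$cluster$perplexity,
                      seed = substream_seed(config$seed, 6L))
    f <- file.path(config$outdir, "cluster_labels.csv")
    utils::write.csv(oriented$assignment, f, row.names = FALSE, quote = FALSE)
    fn <- file.path(config$outdir, "dendrogram.nwk")
    write_dendrogram_newick(oriented, fn)
    fe <- write_table_tsv(as.data.frame(emb),
                          file.path(config$outdir, "tsne.tsv"))
    structure(list(clusters = oriented, embedding = emb),
              stage_files = c(f, fn, fe))
  })

  # 6. associate -----------------------------------------------------------
  assoc <- stage("associate", function() {
    sheet <- sim$mouse$sample_sheet
    sheet$fusion_high <- sheet$fusion_expression == "high"
    sheet$fusion_weak <- sheet$fusion_expression == "low"
    for (lin in c("Pax3", "Myf5", "Myf6", "Pax7")) {
      sheet[[paste0(tolower(lin), "_lineage")]] <- sheet$lineage == lin
    }
    factors <- c("fusion_high", "fusion_weak", "pax3_lineage", "myf5_lineage",
                 "myf6_lineage", "pax7_lineage", "ptch1_mut", "rb1_mut",
                 "trp53_mut")
    tab <- withCallingHandlers(
      associate_clusters_with_metadata(clu$clusters, sheet, factors),
      warning = function(w) {
        if (grepl("constant", conditionMessage(w))) invokeRestart("muffleWarning")
      })
    structure(list(table = tab),
              stage_files = write_table_tsv(
                tab, file.path(config$outdir, "associations.tsv")))
  })

  # 7. differential --------------------------------------------------------
  diff <- stage("differential", function() {
    a <- clu$clusters$assignment
    ml <- a$sample_id[a$main == "ML"]
    mr <- a$sample_id[a$main == "MR"]
    mr1 <- a$sample_id[!is.na(a$subset) & a$subset == "MR1"]
    mr2 <- a$sample_id[!is.na(a$subset) & a$subset == "MR2"]
    dm_main <- dm_probes(sim$mouse$beta, ml, mr,
                         delta_threshold = config$dm$delta_threshold,
                         alpha = config$dm$alpha)
    de_main <- de_genes(sim$mouse$expression, ml, mr,
                        alpha = config$de$alpha,
                        lfc_threshold = config$de$lfc_threshold)
    dm_sub <- dm_probes(sim$mouse$beta, mr1, mr2,
                        delta_threshold = config$dm$delta_threshold,
                        alpha = config$dm$alpha)
    de_sub <- de_genes(sim$mouse$expression, mr1, mr2,
                       alpha = config$de$alpha,
                       lfc_threshold = config$de$lfc_threshold)
    hs <- sim$human$sample_sheet
    dm_h <- dm_probes(sim$human$beta,
                      hs$sample_id[hs$group == "FP"],
                      hs$sample_id[hs$group == "FN"],
                      delta_threshold = config$dm$delta_threshold,
                      alpha = config$dm$alpha)
    de_h <- de_genes(sim$human$expression,
                     hs$sample_id[hs$group == "FP"],
                     hs$sample_id[hs$group == "FN"],
                     alpha = config$de$alpha,
                     lfc_threshold = config$de$lfc_threshold)
    f <- c(write_table_tsv(dm_main, file.path(config$outdir, "dm_ml_vs_mr.tsv")),
           write_table_tsv(de_main, file.path(config$outdir, "de_ml_vs_mr.tsv")),
           write_table_tsv(dm_sub, file.path(config$outdir, "dm_mr1_vs_mr2.tsv")),
           write_table_tsv(de_sub, file.path(config$outdir, "de_mr1_vs_mr2.tsv")),
           write_table_tsv(dm_h, file.path(config$outdir, "dm_human_fp_vs_fn.tsv")),
           write_table_tsv(de_h, file.path(config$outdir, "de_human_fp_vs_fn.tsv")))
    structure(list(dm_main = dm_main, de_main = de_main, dm_sub = dm_sub,
                   de_sub = de_sub, dm_human = dm_h, de_human = de_h),
              stage_files = f)
  })

  # 8. integrate -----------------------------------------------------------
  integ <- stage("integrate", function() {
    calls_m <- collapse_to_gene_region(diff$dm_main, ann$mouse)
    calls_h <- collapse_to_gene_region(diff$dm_human, ann$human)
    int_m <- integrate_dm_de(calls_m, diff$de_main, species = "mouse")
    int_h <- integrate_dm_de(calls_h, diff$de_human, species = "human")
    common <- cross_species_common(int_m, int_h, sim$human$homolog_map)
    truth_sets <- list(conserved_core = sim$mouse$truth$conserved_gene_list)
    enr <- enrich_against_collection(common$gene_symbol, truth_sets,
                                     ann$universe)
    f <- c(write_table_tsv(int_m, file.path(config$outdir, "dmde_mouse.tsv")),
           write_table_tsv(int_h, file.path(config$outdir, "dmde_human.tsv")),
           write_table_tsv(common, file.path(config$outdir, "dmde_common.tsv")),
           write_table_tsv(enr, file.path(config$outdir, "enrichment.tsv")))
    structure(list(mouse = int_m, human = int_h, common = common,
                   enrichment = enr), stage_files = f)
  })

  mpath <- file.path(config$outdir, "run_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)

  structure(list(config = config, manifest = manifest,
                 simulation = sim, normalization = norm, annotation = ann,
                 selection = sel, clustering = clu, associations = assoc$table,
                 differential = diff, integration = integ),
            class = "methylgemm_run")
}

# Orient generic C1/C2 (and nested) labels to ML/MR/MR1/MR2: the main cluster
# with the larger share of high fusion expression is ML (by size, smaller = ML,
# when no metadata); the fusion-negative-like MR cluster is then re-cut, with
# the smaller subset labelled MR1.
orient_cluster_labels <- function(clust, beta, sheet, config) {
  a <- clust$assignment
  if (!is.null(sheet$fusion_expression)) {
    high <- sheet$fusion_expression[match(a$sample_id, sheet$sample_id)] == "high"
    share <- tapply(high, a$main, mean)
    ml <- names(share)[which.max(share)]
  } else {
    sizes <- table(a$main)
    ml <- names(sizes)[which.min(sizes)]
  }
  new_main <- ifelse(a$main == ml, "ML", "MR")
  names(new_main) <- a$sample_id
  # re-cut the MR cluster into MR1/MR2
  members <- a$sample_id[new_main == "MR"]
  sub <- hierarchical_cluster(beta[, members, drop = FALSE], k_main = 2L,
                              distance = config$cluster$distance,
                              linkage = config$cluster$linkage)
  sub_raw <- sub$assignment$main
  sizes <- table(sub_raw)
  mr1 <- names(sizes)[order(as.vector(sizes))][1]
  subset_lab <- ifelse(sub_raw == mr1, "MR1", "MR2")
  assignment <- data.frame(
    sample_id = a$sample_id,
    main = unname(new_main),
    subset = NA_character_,
    stringsAsFactors = FALSE
  )
  assignment$subset[match(members, assignment$sample_id)] <- subset_lab
  structure(list(assignment = assignment, tree = clust$tree,
                 subset_tree = sub$tree),
            class = "cluster_assignment")
}

#' @export
print.methylgemm_run <- function(x, ...) {
  cat("methylGEMM pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("  stages: ", paste(names(x$manifest$stages), collapse = " -> "), "\n",
      sep = "")
  a <- x$clustering$clusters$assignment
  cat("  clusters: ", sum(a$main == "ML"), " ML / ", sum(a$main == "MR"),
      " MR (", sum(a$subset == "MR1", na.rm = TRUE), " MR1 / ",
      sum(a$subset == "MR2", na.rm = TRUE), " MR2)\n", sep = "")
  cat("  DM probes (ML vs MR): ", sum(x$differential$dm_main$significant),
      "; DE genes: ", sum(x$differential$de_main$significant), "\n", sep = "")
  cat("  cross-species common DM/DE genes: ", nrow(x$integration$common),
      "\n", sep = "")
  invisible(x)
}
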