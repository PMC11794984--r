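#' Simulation configuration for synthetic methylation/expression cohorts
#'
#' Builds a validated configuration for the seeded synthetic-data generator.
#' The defaults emulate the design of the mouse rhabdomyosarcoma (RMS) GEMM
#' cohort: 31 tumours in three latent groups — a fusion-positive-like (FP)
#' group with high \emph{Pax3::Foxo1} expression, a fusion-negative Myf5
#' lineage-like group, and a fusion-negative Pax7 lineage-like group, with
#' group sizes 11/8/12.
#'
#' @param seed Integer seed; mandatory, all randomness flows from it through
#'   per-product substreams.
#' @param n_mouse_samples Number of mouse samples (default 31).
#' @param group_sizes Named or unnamed integer vector of latent group sizes
#'   (FP-like, FN-Myf5-like, FN-Pax7-like); must sum to `n_mouse_samples`.
#' @param n_probes Number of methylation probes (default 20000).
#' @param n_genes Number of genes (default 2000).
#' @param frac_dm_fp_fn Fraction of probes planted as differentially
#'   methylated between the FP and FN groups (default 0.02, i.e. the top-1%
#'   scale of real arrays is comfortably exceeded so selection and testing
#'   have signal to find).
#' @param frac_dm_fn1_fn2 Fraction planted DM between the two FN groups
#'   (default 0.01).
#' @param delta_beta_range Interval from which planted |delta-beta| values are
#'   drawn (default c(0.25, 0.40)), chosen to clear the |delta-beta| > 0.2
#'   calling threshold.
#' @param noise_sd Within-group beta noise scale (default 0.05).
#' @param n_human_samples Number of human-like samples (default 86).
#' @param human_group_sizes FP/FN split of the human cohort (default 38/48).
#' @param frac_conserved Fraction of planted mouse DM+DE genes whose effects
#'   are replicated (same directions) in the human cohort (default 0.25).
#' @param expr_coupling_prob Probability that a planted DM gene receives a
#'   direction-linked expression shift (default 0.8).
#' @param expr_effect_log2 Magnitude of the planted log2 expression shift
#'   (default 1.5).
#' @param expr_noise_sd Per-sample log2 expression noise (default 0.5).
#' @param body_coupling_sign +1 (default) couples gene-body hypermethylation
#'   to over-expression (and hypo to under); -1 flips the gene-body rule.
#'   Promoter coupling is always hyper -> under, hypo -> over.
#' @param species_offset Global beta offset added to all human probes, which
#'   reproduces the species-dominant clustering seen when mouse and human
#'   cohorts are combined (default 0.15).
#' @param typeII_compression Dynamic-range compression factor in [0, 1) for
#'   type II probe intensities relative to type I (default 0.3); 0 disables
#'   the bias that SWAN-style normalization corrects.
#'
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(seed,
                              n_mouse_samples = 31L,
                              group_sizes = c(fp = 11L, fn_myf5 = 8L, fn_pax7 = 12L),
                              n_probes = 20000L,
                              n_genes = 2000L,
                              frac_dm_fp_fn = 0.02,
                              frac_dm_fn1_fn2 = 0.01,
                              delta_beta_range = c(0.25, 0.40),
                              noise_sd = 0.05,
                              n_human_samples = 86L,
                              human_group_sizes = c(fp = 38L, fn = 48L),
                              frac_conserved = 0.25,
                              expr_coupling_prob = 0.8,
                              expr_effect_log2 = 1.5,
                              expr_noise_sd = 0.5,
                              body_coupling_sign = 1,
                              species_offset = 0.15,
                              typeII_compression = 0.3) {
  if (missing(seed)) stop("seed is mandatory: no implicit entropy", call. = FALSE)
  cfg <- list(
    seed = as.integer(seed),
    n_mouse_samples = as.integer(n_mouse_samples),
    group_sizes = as.integer(group_sizes),
    n_probes = as.integer(n_probes),
    n_genes = as.integer(n_genes),
    frac_dm_fp_fn = frac_dm_fp_fn,
    frac_dm_fn1_fn2 = frac_dm_fn1_fn2,
    delta_beta_range = as.numeric(delta_beta_range),
    noise_sd = noise_sd,
    n_human_samples = as.integer(n_human_samples),
    human_group_sizes = as.integer(human_group_sizes),
    frac_conserved = frac_conserved,
    expr_coupling_prob = expr_coupling_prob,
    expr_effect_log2 = expr_effect_log2,
    expr_noise_sd = expr_noise_sd,
    body_coupling_sign = sign(body_coupling_sign),
    species_offset = species_offset,
    typeII_compression = typeII_compression
  )
  names(cfg$group_sizes) <- c("fp", "fn_myf5", "fn_pax7")
  names(cfg$human_group_sizes) <- c("fp", "fn")
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$group_sizes) != 3L || sum(cfg$group_sizes) != cfg$n_mouse_samples) {
    stop("group_sizes must contain three counts summing to n_mouse_samples",
         call. = FALSE)
  }
  fr <- c(cfg$frac_dm_fp_fn, cfg$frac_dm_fn1_fn2, cfg$frac_conserved,
          cfg$expr_coupling_prob)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  dbr <- cfg$delta_beta_range
  if (length(dbr) != 2L || dbr[1] > dbr[2] || dbr[1] <= 0 || dbr[2] >= 1) {
    stop("delta_beta_range must be an increasing interval within (0, 1)",
         call. = FALSE)
  }
  if (cfg$typeII_compression < 0 || cfg$typeII_compression >= 1) {
    stop("typeII_compression must lie in [0, 1)", call. = FALSE)
  }
  if (sum(cfg$human_group_sizes) != cfg$n_human_samples) {
    stop("human_group_sizes must sum to n_human_samples", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration (seed ", x$seed, ")\n", sep = "")
  cat("  mouse: ", x$n_mouse_samples, " samples in groups ",
      paste(x$group_sizes, collapse = "/"), "; ",
      x$n_probes, " probes, ", x$n_genes, " genes\n", sep = "")
  cat("  planted DM fractions: FP-vs-FN ", x$frac_dm_fp_fn,
      ", FN1-vs-FN2 ", x$frac_dm_fn1_fn2,
      "; |delta-beta| in [", x$delta_beta_range[1], ", ",
      x$delta_beta_range[2], "]\n", sep = "")
  cat("  human: ", x$n_human_samples, " samples (",
      paste(x$human_group_sizes, collapse = "/"),
      "), conserved fraction ", x$frac_conserved, "\n", sep = "")
  invisible(x)
}

# Largest-remainder allocation of n items into proportions w (exact total).
allocate_counts <- function(n, w) {
  q <- n * w / sum(w)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

# Internal per-gene geometry used by both transcript emission and probe
# placement. All coordinates are 0-based half-open. `anchor` is the TSS-side
# boundary: txStart on + strand, txEnd on - strand.
GENE_SLOT <- 60000L
GENE_CHROMS <- paste0("chr", 1:19)

gene_layout <- function(n_genes) {
  idx <- seq_len(n_genes) - 1L
  data.frame(
    gene_id = seq_len(n_genes),
    chrom = GENE_CHROMS[(idx %% length(GENE_CHROMS)) + 1L],
    slot_start = (idx %/% length(GENE_CHROMS)) * GENE_SLOT,
    stringsAsFactors = FALSE
  )
}

mouse_symbol <- function(i) sprintf("Sim%04d", i)
human_symbol <- function(i) sprintf("SIM%04d", i)

#' Generate synthetic transcript models
#'
#' Emits genePred-style transcript models (0-based half-open coordinates) for
#' the configured gene universe. Each gene carries 1-3 transcripts on a common
#' strand; transcripts of a gene share the transcription start site and first
#' exon, and have 2-8 exons that are sorted and non-overlapping within a
#' transcript. Both strands are represented.
#'
#' @param config A [simulation_config()] object.
#' @return A data.frame with columns `transcript_id`, `gene_symbol`, `chrom`,
#'   `strand`, `txStart`, `txEnd`, `exonStarts`, `exonEnds` (comma-separated,
#'   0-based half-open). The internal transcription-space geometry is attached
#'   as attribute `"geometry"` for use by the probe placer.
#' @export
generate_transcript_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  with_seed(substream_seed(config$seed, 1L), {
    lay <- gene_layout(config$n_genes)
    n <- config$n_genes
    strand <- sample(c("+", "-"), n, replace = TRUE)
    # ensure both strands occur even at tiny n
    if (n >= 2L) { strand[1] <- "+"; strand[2] <- "-" }
    e1len <- sample(100:400, n, replace = TRUE)
    rows <- vector("list", n)
    geom <- vector("list", n)
    for (g in seq_len(n)) {
      anchor <- if (strand[g] == "+") {
        lay$slot_start[g] + 5000L + sample(0:1000, 1L)
      } else {
        lay$slot_start[g] + 33000L + sample(0:1000, 1L)
      }
      n_tx <- sample(1:3, 1L)
      tx_geo <- vector("list", n_tx)
      tx_rows <- vector("list", n_tx)
      for (k in seq_len(n_tx)) {
        L <- sample(5000:25000, 1L)
        n_ex <- sample(2:8, 1L)
        # transcription-space exon blocks: first exon fixed per gene, then
        # alternate intron/exon cut points on a coarse grid (>= 50 bp pieces)
        grid <- seq(e1len[g] + 50L, L - 50L, by = 50L)
        n_cuts <- 2L * (n_ex - 1L) - 1L
        cuts <- sort(sample(grid, n_cuts))
        starts <- c(0L, cuts[seq(1L, n_cuts, by = 2L)])
        inner_ends <- if (n_cuts >= 2L) cuts[seq(2L, n_cuts, by = 2L)] else integer(0)
        ends <- c(e1len[g], inner_ends, L)
        # map transcription space [s, e) to genomic coordinates
        if (strand[g] == "+") {
          gs <- anchor + starts; ge <- anchor + ends
          txs <- anchor; txe <- anchor + L
        } else {
          gs <- anchor - ends; ge <- anchor - starts
          o <- order(gs); gs <- gs[o]; ge <- ge[o]
          txs <- anchor - L; txe <- anchor
        }
        tid <- sprintf("%s.t%d", mouse_symbol(g), k)
        tx_rows[[k]] <- data.frame(
          transcript_id = tid, gene_symbol = mouse_symbol(g),
          chrom = lay$chrom[g], strand = strand[g],
          txStart = txs, txEnd = txe,
          exonStarts = paste(gs, collapse = ","),
          exonEnds = paste(ge, collapse = ","),
          stringsAsFactors = FALSE
        )
        tx_geo[[k]] <- list(L = L, starts = starts, ends = ends)
      }
      rows[[g]] <- do.call(rbind, tx_rows)
      geom[[g]] <- list(anchor = anchor, strand = strand[g],
                        e1len = e1len[g], chrom = lay$chrom[g],
                        slot_start = lay$slot_start[g], tx = tx_geo)
    }
    tx <- do.call(rbind, rows)
    rownames(tx) <- NULL
    attr(tx, "geometry") <- geom
    tx
  })
}

# Map a transcription-space offset t (0-based, measured from the TSS) of gene
# geometry `gg` to a genomic position.
txpos_to_genomic <- function(gg, t) {
  if (gg$strand == "+") gg$anchor + t else gg$anchor - 1L - t
}

# Place one probe of a given category on gene geometry `gg`.
place_probe <- function(gg, category) {
  switch(category,
    promoter = if (gg$strand == "+") gg$anchor - pick_one(1:1500)
               else gg$anchor - 1L + pick_one(1:1500),
    first_exon = txpos_to_genomic(gg, pick_one(0:(gg$e1len - 1L))),
    internal_exon = {
      txg <- gg$tx[[pick_one(seq_along(gg$tx))]]
      ex <- pick_one(2:length(txg$starts))
      txpos_to_genomic(gg, pick_one(txg$starts[ex]:(txg$ends[ex] - 1L)))
    },
    intron = {
      txg <- gg$tx[[pick_one(seq_along(gg$tx))]]
      # first intron in transcription space always exists (>= 2 exons)
      txpos_to_genomic(gg, pick_one(txg$ends[1]:(txg$starts[2] - 1L)))
    },
    intergenic = gg$slot_start + pick_one(40000:58000),
    stop("unknown placement category: ", category)
  )
}

#' Generate the synthetic mouse cohort
#'
#' Produces a complete mouse methylation/expression cohort with planted ground
#' truth: a beta-value matrix whose baseline per-probe means are drawn from a
#' bimodal (low/high methylation) mixture, with planted signed delta-beta
#' effects between the configured latent groups; a log-normal expression
#' matrix with direction-coupled log2 shifts; a Table-1-patterned sample
#' sheet (lineage, fusion knock-in, fusion-expression level in
#' \{high, low, none\}, genotype flags); a probe manifest placed on the
#' generated transcript models so that promoter, first-exon, internal-exon,
#' intron and intergenic cases all occur; and the ground-truth tables needed
#' for parameter-recovery testing.
#'
#' Rerunning with the same configuration is bit-identical.
#'
#' @param config A [simulation_config()] object.
#' @return A list of class `mouse_cohort` with elements `beta`, `expression`,
#'   `sample_sheet`, `manifest`, `transcripts`, and `truth` (class
#'   `ground_truth`).
#' @export
generate_mouse_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  transcripts <- generate_transcript_models(config)
  geom <- attr(transcripts, "geometry")
  with_seed(substream_seed(config$seed, 2L), {
    n_probes <- config$n_probes
    n_genes <- config$n_genes
    gsz <- config$group_sizes
    n <- config$n_mouse_samples
    sample_ids <- sprintf("M%02d", seq_len(n))
    group <- rep(c("FP", "FN_Myf5", "FN_Pax7"), times = gsz)
    names(group) <- sample_ids

    # -- planted probe/gene design ------------------------------------------
    n_dm_fp <- round(config$frac_dm_fp_fn * n_probes)
    n_dm_fn <- round(config$frac_dm_fn1_fn2 * n_probes)
    # human-only DM genes keep the cross-species intersection honest
    n_human_extra <- round(0.5 * n_dm_fp)
    need <- n_dm_fp + n_dm_fn + n_human_extra
    if (need > n_genes) {
      stop("not enough genes for the planted design; increase n_genes",
           call. = FALSE)
    }
    if (need > n_probes) stop("n_probes too small for planted design", call. = FALSE)
    picked <- sample.int(n_genes, need)
    genes_fp <- picked[seq_len(n_dm_fp)]
    genes_fn <- picked[seq_len(n_dm_fn) + n_dm_fp]
    genes_hx <- picked[seq_len(n_human_extra) + n_dm_fp + n_dm_fn]

    plant <- function(gene_ids, contrast) {
      k <- length(gene_ids)
      if (k == 0L) {
        return(data.frame(gene_id = integer(), contrast = character(),
                          region = character(), direction = character(),
                          true_delta_beta = numeric(),
                          stringsAsFactors = FALSE))
      }
      data.frame(
        gene_id = gene_ids,
        contrast = contrast,
        region = sample(c("promoter", "body"), k, replace = TRUE),
        direction = sample(c("hypo", "hyper"), k, replace = TRUE),
        true_delta_beta = stats::runif(k, config$delta_beta_range[1],
                                       config$delta_beta_range[2]),
        stringsAsFactors = FALSE
      )
    }
    planted <- rbind(plant(genes_fp, "FP_vs_FN"),
                     plant(genes_fn, "FN1_vs_FN2"),
                     plant(genes_hx, "human_only"))
    planted$true_delta_beta <- ifelse(planted$direction == "hypo",
                                      -planted$true_delta_beta,
                                      planted$true_delta_beta)

    # -- probe manifest ------------------------------------------------------
    n_planted <- nrow(planted)
    n_bg <- n_probes - n_planted
    cat_bg <- sample(c("promoter", "first_exon", "internal_exon", "intron",
                       "intergenic"),
                     n_bg, replace = TRUE,
                     prob = c(0.15, 0.10, 0.20, 0.30, 0.25))
    # guarantee all five placement categories at any n
    if (n_bg >= 5L) cat_bg[1:5] <- c("promoter", "first_exon", "internal_exon",
                                     "intron", "intergenic")
    gene_bg <- sample.int(n_genes, n_bg, replace = TRUE)
    cat_planted <- ifelse(planted$region == "promoter", "promoter",
                          ifelse(stats::runif(n_planted) < 0.5,
                                 "internal_exon", "intron"))
    gene_all <- c(planted$gene_id, gene_bg)
    cat_all <- c(cat_planted, cat_bg)
    pos <- integer(n_probes)
    for (i in seq_len(n_probes)) {
      pos[i] <- place_probe(geom[[gene_all[i]]], cat_all[i])
    }
    probe_ids <- sprintf("mm%06d", seq_len(n_probes))
    manifest <- data.frame(
      probe_id = probe_ids,
      chrom = vapply(gene_all, function(g) geom[[g]]$chrom, character(1)),
      pos = pos,
      strand = ".",
      design_type = sample(c("I", "II"), n_probes, replace = TRUE),
      cpg_count = sample(1:3, n_probes, replace = TRUE,
                         prob = c(0.3, 0.4, 0.3)),
      stringsAsFactors = FALSE
    )

    # -- beta matrix ---------------------------------------------------------
    mu <- numeric(n_probes)
    hi <- stats::runif(n_probes) < 0.5
    mu[hi] <- stats::rbeta(sum(hi), 8, 2)
    mu[!hi] <- stats::rbeta(sum(!hi), 2, 8)
    # planted probes: baselines leaving head-room for the signed shift
    is_planted <- seq_len(n_probes) <= n_planted
    hypo_p <- is_planted & c(planted$direction == "hypo", rep(FALSE, n_bg))
    hyper_p <- is_planted & !hypo_p
    mu[hyper_p] <- stats::runif(sum(hyper_p), 0.30, 0.55)
    mu[hypo_p] <- stats::runif(sum(hypo_p), 0.45, 0.70)

    group_mean <- matrix(mu, n_probes, 3,
                         dimnames = list(probe_ids, c("FP", "FN_Myf5", "FN_Pax7")))
    idx_fp <- which(planted$contrast == "FP_vs_FN")
    group_mean[idx_fp, "FP"] <- mu[idx_fp] + planted$true_delta_beta[idx_fp]
    idx_fn <- which(planted$contrast == "FN1_vs_FN2")
    group_mean[idx_fn, "FN_Myf5"] <- mu[idx_fn] + planted$true_delta_beta[idx_fn]
    group_mean <- clip01(group_mean)

    beta <- draw_beta(group_mean[, match(group, colnames(group_mean)), drop = FALSE],
                      config$noise_sd)
    dimnames(beta) <- list(probe_ids, sample_ids)

    # -- expression matrix ---------------------------------------------------
    gene_symbols <- mouse_symbol(seq_len(n_genes))
    base_log2 <- stats::rnorm(n_genes, 7, 1.2)
    coupled <- stats::runif(n_planted) < config$expr_coupling_prob
    expr_dir <- expr_direction(planted$region, planted$direction,
                               config$body_coupling_sign)
    shift <- ifelse(expr_dir == "over", 1, -1) * config$expr_effect_log2
    log2e <- matrix(base_log2, n_genes, n, dimnames = list(gene_symbols, sample_ids))
    de_rows <- which(coupled & planted$contrast == "FP_vs_FN")
    for (i in de_rows) {
      log2e[planted$gene_id[i], group == "FP"] <-
        log2e[planted$gene_id[i], group == "FP"] + shift[i]
    }
    de_rows_fn <- which(coupled & planted$contrast == "FN1_vs_FN2")
    for (i in de_rows_fn) {
      log2e[planted$gene_id[i], group == "FN_Myf5"] <-
        log2e[planted$gene_id[i], group == "FN_Myf5"] + shift[i]
    }
    log2e <- log2e + matrix(stats::rnorm(n_genes * n, 0, config$expr_noise_sd),
                            n_genes, n)
    expression <- 2^log2e

    # -- sample sheet (Table-1 patterned) ------------------------------------
    sheet <- synth_sample_sheet(sample_ids, group, gsz)

    # -- ground truth --------------------------------------------------------
    mouse_contrasts <- planted$contrast != "human_only"
    dm_probe_table <- data.frame(
      probe_id = probe_ids[seq_len(n_planted)][mouse_contrasts],
      gene_symbol = gene_symbols[planted$gene_id[mouse_contrasts]],
      contrast = planted$contrast[mouse_contrasts],
      region = planted$region[mouse_contrasts],
      direction = planted$direction[mouse_contrasts],
      true_delta_beta = planted$true_delta_beta[mouse_contrasts],
      stringsAsFactors = FALSE
    )
    de_keep <- coupled & mouse_contrasts
    de_gene_table <- data.frame(
      gene_symbol = gene_symbols[planted$gene_id[de_keep]],
      contrast = planted$contrast[de_keep],
      direction = expr_dir[de_keep],
      log2_shift = shift[de_keep],
      stringsAsFactors = FALSE
    )
    fp_dmde <- which(coupled & planted$contrast == "FP_vs_FN")
    n_cons <- round(config$frac_conserved * length(fp_dmde))
    cons_rows <- if (n_cons > 0) sort(sample(fp_dmde, n_cons)) else integer()
    conserved_gene_list <- human_symbol(planted$gene_id[cons_rows])

    truth <- structure(list(
      dm_probe_table = dm_probe_table,
      de_gene_table = de_gene_table,
      conserved_gene_list = conserved_gene_list,
      sample_labels = data.frame(sample_id = sample_ids, group = group,
                                 stringsAsFactors = FALSE),
      generator_state = list(
        planted = planted, coupled = coupled, expr_dir = expr_dir,
        shift = shift, cons_rows = cons_rows, mu = mu,
        base_log2 = base_log2, gene_all = gene_all,
        manifest = manifest, n_planted = n_planted, config = config
      )
    ), class = "ground_truth")

    structure(list(beta = beta, expression = expression,
                   sample_sheet = sheet, manifest = manifest,
                   transcripts = transcripts, truth = truth),
              class = "mouse_cohort")
  })
}

# Beta draws around a probe x sample mean matrix using a (mean, precision)
# parameterization: var = mu(1-mu)/(1+phi) == noise_sd^2, so the noise scale
# is respected mid-range and shrinks towards the [0,1] boundaries.
draw_beta <- function(mean_mat, noise_sd) {
  mu <- clip01(mean_mat)
  phi <- pmax(mu * (1 - mu) / noise_sd^2 - 1, 2)
  b <- stats::rbeta(length(mu), shape1 = as.vector(mu * phi),
                    shape2 = as.vector((1 - mu) * phi))
  matrix(clip01(b, 0.001, 0.999), nrow(mu), ncol(mu))
}

# Direction-coupled expression rule. Promoter methylation is repressive:
# hyper -> under, hypo -> over. Gene-body coupling defaults to the positive
# correlation commonly seen on arrays (hyper -> over); sign configurable.
expr_direction <- function(region, methyl_direction, body_sign = 1) {
  prom <- region == "promoter"
  over <- ifelse(prom,
                 methyl_direction == "hypo",
                 if (body_sign >= 0) methyl_direction == "hyper"
                 else methyl_direction == "hypo")
  ifelse(over, "over", "under")
}

# Lineage / genotype template mirroring the published GEMM cohort: the FP-like
# group holds Pax3/Myf5/Myf6-lineage fusion knock-ins (3/1/7 at default size),
# the FN-Myf5-like group non-fusion Myf5/Myf6/Pax3 tumours (4/3/1), and the
# FN-Pax7-like group Pax7 knock-ins with weak fusion expression plus non-fusion
# Pax7/Myf6/Pax3 tumours (7/2/1/2).
synth_sample_sheet <- function(sample_ids, group, gsz) {
  fp_lin <- rep(c("Pax3", "Myf5", "Myf6"), allocate_counts(gsz[1], c(3, 1, 7)))
  fn1_lin <- rep(c("Myf5", "Myf6", "Pax3"), allocate_counts(gsz[2], c(4, 3, 1)))
  fn2_alloc <- allocate_counts(gsz[3], c(7, 2, 1, 2))
  fn2_lin <- rep(c("Pax7", "Pax7", "Myf6", "Pax3"), fn2_alloc)
  fn2_ki <- rep(c(TRUE, FALSE, FALSE, FALSE), fn2_alloc)
  lineage <- c(fp_lin, fn1_lin, fn2_lin)
  knockin <- c(rep(TRUE, gsz[1]), rep(FALSE, gsz[2]), fn2_ki)
  fusion_expression <- ifelse(!knockin, "none",
                              ifelse(lineage == "Pax7", "low", "high"))
  ptch1 <- !knockin & lineage %in% c("Pax3", "Myf5")
  # one non-fusion Pax7 tumour carries the Ptch1 allele, as in the cohort
  pax7_wt <- which(!knockin & lineage == "Pax7")
  if (length(pax7_wt) > 0) ptch1[pax7_wt[length(pax7_wt)]] <- TRUE
  rb1 <- rep(FALSE, length(sample_ids))
  ki_idx <- which(knockin)
  if (length(ki_idx) >= 4L) rb1[ki_idx[seq(4L, length(ki_idx), by = 4L)]] <- TRUE
  data.frame(
    sample_id = sample_ids,
    group = group,
    lineage = lineage,
    fusion_knockin = knockin,
    fusion_expression = fusion_expression,
    ptch1_mut = ptch1,
    rb1_mut = rb1,
    trp53_mut = TRUE,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Generate the human-like synthetic cohort
#'
#' Mirrors the mouse probe layout onto human-style probe identifiers and
#' uppercase gene symbols, adds a global species beta offset to all probes
#' (reproducing species-dominant clustering when the cohorts are combined),
#' and plants FP-vs-FN effects — with the same directions as in mouse — on the
#' probes and expression of the conserved gene core recorded in the ground
#' truth, plus a disjoint set of human-only DM/DE genes.
#'
#' @param config The [simulation_config()] used for the mouse cohort.
#' @param truth The `ground_truth` returned by [generate_mouse_cohort()].
#' @return A list of class `human_cohort` with elements `beta`, `expression`,
#'   `sample_sheet`, `manifest`, `synteny_map` (mouse_probe_id,
#'   human_probe_id) and `homolog_map` (mouse_symbol, human_symbol).
#' @export
generate_human_cohort <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  st <- truth$generator_state
  with_seed(substream_seed(config$seed, 3L), {
    n_probes <- config$n_probes
    n_genes <- config$n_genes
    nh <- config$n_human_samples
    hg <- config$human_group_sizes
    sample_ids <- sprintf("H%03d", seq_len(nh))
    group <- rep(c("FP", "FN"), times = hg)
    planted <- st$planted

    mu_h <- clip01(st$mu + config$species_offset)
    group_mean <- matrix(mu_h, n_probes, 2,
                         dimnames = list(NULL, c("FP", "FN")))
    # conserved core + human-only genes carry FP-vs-FN effects, mouse sign kept
    active <- sort(c(st$cons_rows, which(planted$contrast == "human_only")))
    dmag <- stats::runif(length(active), config$delta_beta_range[1],
                         config$delta_beta_range[2])
    delta_h <- sign(planted$true_delta_beta[active]) * dmag
    # re-anchor baselines of active probes so the shift stays in range
    hypo <- delta_h < 0
    group_mean[active[!hypo], ] <- stats::runif(sum(!hypo), 0.30, 0.55)
    group_mean[active[hypo], ] <- stats::runif(sum(hypo), 0.45, 0.70)
    group_mean[active, "FP"] <- group_mean[active, "FP"] + delta_h
    group_mean <- clip01(group_mean)

    probe_ids <- sprintf("cg%08d", seq_len(n_probes))
    beta <- draw_beta(group_mean[, match(group, colnames(group_mean)),
                                 drop = FALSE], config$noise_sd)
    dimnames(beta) <- list(probe_ids, sample_ids)

    gene_symbols <- human_symbol(seq_len(n_genes))
    log2e <- matrix(st$base_log2, n_genes, nh,
                    dimnames = list(gene_symbols, sample_ids))
    de_active <- active[st$coupled[active]]
    for (i in de_active) {
      log2e[planted$gene_id[i], group == "FP"] <-
        log2e[planted$gene_id[i], group == "FP"] + st$shift[i]
    }
    log2e <- log2e + matrix(stats::rnorm(n_genes * nh, 0, config$expr_noise_sd),
                            n_genes, nh)

    # the human manifest mirrors the mouse layout gene-for-gene (a pretend
    # synteny), so syntenic pairs interrogate the same relative locus
    manifest <- data.frame(
      probe_id = probe_ids,
      chrom = st$manifest$chrom,
      pos = st$manifest$pos,
      strand = ".",
      design_type = sample(c("I", "II"), n_probes, replace = TRUE),
      cpg_count = sample(1:3, n_probes, replace = TRUE, prob = c(0.3, 0.4, 0.3)),
      stringsAsFactors = FALSE
    )

    sheet <- data.frame(
      sample_id = sample_ids,
      group = group,
      fusion_status = ifelse(group == "FP", "FP", "FN"),
      stringsAsFactors = FALSE
    )
    synteny_map <- data.frame(
      mouse_probe_id = sprintf("mm%06d", seq_len(n_probes)),
      human_probe_id = probe_ids,
      stringsAsFactors = FALSE
    )
    homolog_map <- data.frame(
      mouse_symbol = mouse_symbol(seq_len(n_genes)),
      human_symbol = gene_symbols,
      stringsAsFactors = FALSE
    )
    structure(list(beta = beta, expression = 2^log2e, sample_sheet = sheet,
                   manifest = manifest, synteny_map = synteny_map,
                   homolog_map = homolog_map),
              class = "human_cohort")
  })
}

#' Generate raw two-design-type intensities
#'
#' Simulates per-probe methylated/unmethylated channel intensities for testing
#' SWAN-style normalization: design types are assigned roughly 50/50, each
#' probe carries a CpG count category, and type II intensities are drawn with
#' a systematically compressed dynamic range relative to type I (the bias the
#' normalization corrects). A compression factor of zero makes the two designs
#' statistically indistinguishable.
#'
#' @param config A [simulation_config()] object (`n_probes >= 100`).
#' @return An `intensity_set`: list with `meth` and `unmeth` matrices (probes
#'   x samples), `design_type`, `cpg_count`, `probe_ids`, `sample_ids`.
#' @export
generate_intensities <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_probes < 100L) stop("n_probes must be >= 100", call. = FALSE)
  with_seed(substream_seed(config$seed, 4L), {
    np <- config$n_probes
    ns <- config$n_mouse_samples
    probe_ids <- sprintf("mm%06d", seq_len(np))
    sample_ids <- sprintf("M%02d", seq_len(ns))
    design <- sample(c("I", "II"), np, replace = TRUE)
    cpg <- sample(1:3, np, replace = TRUE, prob = c(0.3, 0.4, 0.3))
    # genomic CpGs are predominantly methylated: high mode dominates
    mu <- numeric(np)
    hi <- stats::runif(np) < 0.65
    mu[hi] <- stats::rbeta(sum(hi), 8, 2)
    mu[!hi] <- stats::rbeta(sum(!hi), 2, 8)
    total <- matrix(stats::rlnorm(np * ns, log(3000), 0.4), np, ns)
    frac <- matrix(clip01(stats::rnorm(np * ns, mu, 0.05), 0.01, 0.99), np, ns)
    meth <- total * frac
    unmeth <- total * (1 - frac)
    cmp <- config$typeII_compression
    if (cmp > 0) {
      ii <- design == "II"
      for (ch in c("meth", "unmeth")) {
        x <- get(ch)
        med <- stats::median(x[ii, ])
        x[ii, ] <- med * (x[ii, ] / med)^(1 - cmp)
        assign(ch, x)
      }
    }
    dimnames(meth) <- dimnames(unmeth) <- list(probe_ids, sample_ids)
    structure(list(meth = meth, unmeth = unmeth, design_type = design,
                   cpg_count = cpg, probe_ids = probe_ids,
                   sample_ids = sample_ids),
              class = "intensity_set")
  })
}
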