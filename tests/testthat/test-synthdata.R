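# Synthetic-cohort generator: configuration contract, determinism, planted
# ground truth, and structural invariants of the emitted objects.

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(), "seed is mandatory")
  expect_error(simulation_config(seed = 1, group_sizes = c(10, 8, 12)),
               "sum")
  expect_error(simulation_config(seed = 1, frac_dm_fp_fn = 1.2), "fractions")
  expect_error(simulation_config(seed = 1, delta_beta_range = c(0.4, 0.2)),
               "increasing")
  expect_error(simulation_config(seed = 1, delta_beta_range = c(0, 0.4)),
               "within")
  expect_error(simulation_config(seed = 1, typeII_compression = 1), "compression")
})

test_that("default cohort shape matches the study design", {
  cohort <- small_cohort()
  expect_identical(ncol(cohort$beta), 31L)
  expect_identical(as.vector(table(cohort$truth$sample_labels$group)[
    c("FP", "FN_Myf5", "FN_Pax7")]), c(11L, 8L, 12L))
  # sample sheet marginals match config exactly
  sheet <- cohort$sample_sheet
  expect_identical(as.vector(table(sheet$group)[c("FP", "FN_Myf5", "FN_Pax7")]),
                   c(11L, 8L, 12L))
  expect_identical(sum(sheet$fusion_expression == "high"), 11L)
  expect_true(all(sheet$fusion_expression[sheet$group == "FN_Pax7" &
                                          sheet$fusion_knockin] == "low"))
  expect_true(all(sheet$trp53_mut))
})

test_that("beta values live in (0, 1) with a bimodal baseline", {
  cohort <- small_cohort()
  expect_true(all(cohort$beta > 0 & cohort$beta < 1))
  means <- rowMeans(cohort$beta)
  # low and high methylation modes both well represented
  expect_gt(mean(means < 0.35), 0.2)
  expect_gt(mean(means > 0.65), 0.2)
})

GOLDEN_BETA_MD5 <- "21b481a64ec7fad333ec3ef91ba498e2"

test_that("regeneration under a fixed config is bit-identical", {
  cfg <- small_config(seed = 7)
  a <- generate_mouse_cohort(cfg)
  b <- generate_mouse_cohort(cfg)
  expect_identical(a$beta, b$beta)
  expect_identical(a$expression, b$expression)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$truth$dm_probe_table, b$truth$dm_probe_table)
  # different seed changes the noise realization
  c <- generate_mouse_cohort(small_config(seed = 8))
  expect_false(identical(a$beta, c$beta))
  # golden checksum of the serialized matrix, frozen for this configuration
  f <- tempfile()
  write_matrix_tsv(round(a$beta[1:50, ], 6), f, "probe_id")
  expect_identical(unname(tools::md5sum(f)), GOLDEN_BETA_MD5)
  unlink(f)
})

test_that("planted effects are recoverable from group means", {
  cohort <- small_cohort()
  truth <- cohort$truth$dm_probe_table
  grp <- cohort$truth$sample_labels$group
  cfg <- small_config()
  dev <- vapply(seq_len(nrow(truth)), function(i) {
    b <- cohort$beta[truth$probe_id[i], ]
    if (truth$contrast[i] == "FP_vs_FN") {
      obs <- mean(b[grp == "FP"]) - mean(b[grp != "FP"])
    } else {
      obs <- mean(b[grp == "FN_Myf5"]) - mean(b[grp == "FN_Pax7"])
    }
    abs(obs - truth$true_delta_beta[i])
  }, numeric(1))
  bound <- 3 * cfg$noise_sd / sqrt(min(cfg$group_sizes))
  # the bound is ~2 sigma on the mean difference, so individual probes exceed
  # it a few percent of the time by construction; require it at the 95% level
  expect_gte(mean(dev <= bound), 0.95)
  expect_lt(stats::median(dev), bound / 2)
})

test_that("a zero DM fraction plants nothing for that contrast", {
  cfg <- simulation_config(seed = 3, n_probes = 1000L, n_genes = 300L,
                           frac_dm_fp_fn = 0)
  cohort <- generate_mouse_cohort(cfg)
  expect_identical(
    sum(cohort$truth$dm_probe_table$contrast == "FP_vs_FN"), 0L)
})

test_that("transcript models satisfy their structural invariants", {
  tx <- generate_transcript_models(small_config())
  expect_true(all(tx$txStart < tx$txEnd))
  for (i in seq_len(nrow(tx))) {
    s <- as.integer(strsplit(tx$exonStarts[i], ",")[[1]])
    e <- as.integer(strsplit(tx$exonEnds[i], ",")[[1]])
    expect_true(all(s < e))
    expect_true(all(s >= tx$txStart[i]) && all(e <= tx$txEnd[i]))
    expect_true(!is.unsorted(s, strictly = TRUE))
    # exons disjoint: each exon ends before the next starts
    if (length(s) > 1) expect_true(all(e[-length(e)] < s[-1]))
  }
  expect_setequal(unique(tx$strand), c("+", "-"))
})

test_that("probe placement covers all five genomic categories", {
  cohort <- small_cohort()
  asg <- annotate_probes(cohort$manifest, cohort$transcripts)
  expect_setequal(unique(asg$region), c("promoter", "body"))
  # intergenic probes exist: some manifest probes get no assignment at all
  expect_gt(sum(!cohort$manifest$probe_id %in% asg$probe_id), 0)
  # minus-strand coverage: at least one probe upstream (genomically above)
  # the TSS-side end of a minus-strand transcript is assigned promoter
  minus <- cohort$transcripts[cohort$transcripts$strand == "-", ]
  prom <- asg[asg$region == "promoter" &
              asg$gene_symbol %in% minus$gene_symbol, ]
  found <- FALSE
  for (i in seq_len(nrow(prom))) {
    p <- cohort$manifest[cohort$manifest$probe_id == prom$probe_id[i], ]
    tx <- minus[minus$gene_symbol == prom$gene_symbol[i], ]
    if (any(p$pos >= tx$txEnd)) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("human cohort carries the species offset and the conserved core", {
  cfg <- small_config(seed = 9)
  mouse <- generate_mouse_cohort(cfg)
  human <- generate_human_cohort(cfg, mouse$truth)
  expect_identical(ncol(human$beta), cfg$n_human_samples)
  expect_true(all(grepl("^cg", rownames(human$beta))))
  expect_true(all(grepl("^SIM", rownames(human$expression))))
  # global offset shifts the bulk of probes upward
  expect_gt(mean(rowMeans(human$beta) - rowMeans(mouse$beta)), 0.05)
  # same seed reproduces
  expect_identical(human$beta, generate_human_cohort(cfg, mouse$truth)$beta)
  # no conserved fraction -> nothing planted across species
  cfg0 <- simulation_config(seed = 9, n_probes = 1000L, n_genes = 300L,
                            frac_conserved = 0)
  m0 <- generate_mouse_cohort(cfg0)
  expect_length(m0$truth$conserved_gene_list, 0)
})

test_that("raw intensities show the type II compression SWAN must correct", {
  cfg <- simulation_config(seed = 4, n_probes = 3000L)
  it <- generate_intensities(cfg)
  expect_true(all(it$meth >= 0) && all(it$unmeth >= 0))
  expect_setequal(unique(it$design_type), c("I", "II"))
  beta <- intensities_to_beta(it)
  # the compression narrows the type II beta distribution markedly
  pm <- rowMeans(beta)
  expect_gt(stats::sd(pm[it$design_type == "I"]),
            stats::sd(pm[it$design_type == "II"]) + 0.02)
  ks <- suppressWarnings(stats::ks.test(beta[it$design_type == "I", 1],
                                        beta[it$design_type == "II", 1]))
  expect_gt(ks$statistic, 0.05)
  # zero compression: the two design distributions are indistinguishable
  it0 <- generate_intensities(simulation_config(seed = 4, n_probes = 3000L,
                                                typeII_compression = 0))
  b0 <- intensities_to_beta(it0)
  ks <- stats::ks.test(b0[it0$design_type == "I", 1],
                       b0[it0$design_type == "II", 1])
  expect_gt(ks$p.value, 0.05)
})

test_that("cohorts round-trip through the TSV writers", {
  cohort <- small_cohort()
  dir <- tempfile("cohort_")
  write_cohort(cohort, dir)
  beta2 <- read_matrix_tsv(file.path(dir, "beta.tsv"))
  expect_equal(beta2, cohort$beta, tolerance = 1e-12)
  sheet2 <- utils::read.csv(file.path(dir, "sample_sheet.csv"))
  expect_identical(nrow(sheet2), nrow(cohort$sample_sheet))
  sets <- read_gmt(file.path(dir, "truth_sets.gmt"))
  expect_setequal(sets$conserved_core,
                  toupper(cohort$truth$conserved_gene_list))
  unlink(dir, recursive = TRUE)
})
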