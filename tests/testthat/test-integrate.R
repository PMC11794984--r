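# DM/DE integration, cross-species matching, gene-set enrichment.

mk_calls <- function(genes, region = "promoter", direction = "hyper") {
  data.frame(gene_symbol = genes, region = region, direction = direction,
             n_supporting_probes = 1L, ambiguous = FALSE,
             stringsAsFactors = FALSE)
}

mk_de <- function(genes, direction = "under", significant = TRUE) {
  data.frame(gene_symbol = genes, log2_fold_change = ifelse(direction == "over", 1, -1),
             p_value = 1e-4, p_adjusted = 1e-3, direction = direction,
             significant = significant, stringsAsFactors = FALSE)
}

test_that("integration keeps only DM genes that are also DE", {
  calls <- mk_calls(c("Col1a2", "OnlyDm"))
  de <- rbind(mk_de("Col1a2", "under"), mk_de("OnlyDe", "over"),
              mk_de("OnlyDm", "over", significant = FALSE))
  out <- integrate_dm_de(calls, de, species = "mouse")
  expect_identical(out$gene_symbol, "Col1a2")
  expect_identical(out$region, "promoter")
  expect_identical(out$methyl_direction, "hyper")
  expect_identical(out$expr_direction, "under")
  sc <- attr(out, "stratum_counts")
  expect_identical(sum(sc), nrow(out))
  expect_identical(as.integer(sc["promoter", "hyper", "under"]), 1L)
})

test_that("stratum counts always sum to the records emitted", {
  cohort <- small_cohort()
  g1 <- group_samples(cohort, "FP")
  g2 <- group_samples(cohort, c("FN_Myf5", "FN_Pax7"))
  dm <- dm_probes(cohort$beta, g1, g2)
  asg <- annotate_probes(cohort$manifest, cohort$transcripts)
  calls <- collapse_to_gene_region(dm, asg)
  de <- de_genes(cohort$expression, g1, g2)
  out <- integrate_dm_de(calls, de)
  expect_identical(sum(attr(out, "stratum_counts")), nrow(out))
  expect_gt(nrow(out), 0L)
})

test_that("full coupling places every planted gene in its planted stratum", {
  cfg <- simulation_config(seed = 21, n_probes = 4000L, n_genes = 600L,
                           expr_coupling_prob = 1)
  cohort <- generate_mouse_cohort(cfg)
  g1 <- group_samples(cohort, "FP")
  g2 <- group_samples(cohort, c("FN_Myf5", "FN_Pax7"))
  dm <- dm_probes(cohort$beta, g1, g2)
  asg <- annotate_probes(cohort$manifest, cohort$transcripts)
  out <- integrate_dm_de(collapse_to_gene_region(dm, asg),
                         de_genes(cohort$expression, g1, g2))
  truth <- cohort$truth$dm_probe_table
  truth <- truth[truth$contrast == "FP_vs_FN", ]
  de_truth <- cohort$truth$de_gene_table
  key_out <- paste(out$gene_symbol, out$region, out$methyl_direction,
                   out$expr_direction)
  want <- paste(truth$gene_symbol, truth$region, truth$direction,
                de_truth$direction[match(truth$gene_symbol,
                                         de_truth$gene_symbol)])
  expect_gte(mean(want %in% key_out), 0.9)
})

test_that("cross-species matching is symbol-level and symmetric", {
  mouse <- data.frame(gene_symbol = c("Col1a2", "Fgf8"),
                      region = c("promoter", "body"),
                      methyl_direction = c("hyper", "hypo"),
                      expr_direction = c("under", "over"),
                      species = "mouse", stringsAsFactors = FALSE)
  human <- data.frame(gene_symbol = c("COL1A2", "ZIC1"),
                      region = c("promoter", "promoter"),
                      methyl_direction = c("hyper", "hyper"),
                      expr_direction = c("under", "under"),
                      species = "human", stringsAsFactors = FALSE)
  out <- cross_species_common(mouse, human)
  expect_identical(out$gene_symbol, "COL1A2")
  expect_identical(out$species, "both")
  expect_identical(out$mouse_strata, "promoter/hyper/under")
  # symbol-level: discordant region/direction still matches
  human2 <- human
  human2$region[1] <- "body"; human2$methyl_direction[1] <- "hypo"
  expect_identical(cross_species_common(mouse, human2)$gene_symbol, "COL1A2")
  # disjoint symbol sets: empty
  expect_identical(nrow(cross_species_common(mouse, human[2, ])), 0L)
  # explicit homolog map overrides case matching
  hm <- data.frame(mouse_symbol = "Fgf8", human_symbol = "ZIC1")
  expect_setequal(cross_species_common(mouse, human, hm)$gene_symbol,
                  c("COL1A2", "ZIC1"))
})

test_that("hypergeometric enrichment matches hand enumeration", {
  universe <- paste0("g", 1:10)
  query <- paste0("g", 1:4)
  target <- paste0("g", c(1:4, 10))
  r <- overlap_enrichment(query, target, universe)
  expect_identical(r$overlap_count, 4L)
  expect_equal(r$p_value, 5 / 210)     # C(5,4) C(5,0) / C(10,4)
  expect_equal(overlap_enrichment(character(), target, universe)$p_value, 1)
  expect_equal(overlap_enrichment(universe, universe, universe)$p_value, 1)
  expect_error(overlap_enrichment(query, target, character()), "empty universe")
  expect_warning(overlap_enrichment(c(query, "outside"), target, universe),
                 "dropped")
})

test_that("enrichment equals the enumerated tail for universes up to 25", {
  # oracle from binomial coefficients, independent of phyper
  tail_oracle <- function(k, Tn, U, q) {
    j <- k:min(Tn, q)
    sum(exp(lchoose(Tn, j) + lchoose(U - Tn, q - j) - lchoose(U, q)))
  }
  for (U in c(5L, 10L, 17L, 25L)) {
    universe <- paste0("u", seq_len(U))
    for (Tn in c(1L, U %/% 2L, U)) {
      for (q in c(1L, U %/% 3L + 1L, U)) {
        target <- universe[seq_len(Tn)]
        query <- universe[seq_len(q)]
        k <- length(intersect(query, target))
        r <- overlap_enrichment(query, target, universe)
        expect_equal(r$p_value, min(1, tail_oracle(k, Tn, U, q)),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("collection enrichment flags exactly the constructed signal", {
  set.seed(2)
  universe <- sprintf("G%03d", 1:200)
  query <- universe[1:20]
  sets <- c(list(planted = universe[c(1:15, 100:104)]),
            lapply(stats::setNames(1:7, paste0("noise", 1:7)),
                   function(i) sample(universe, 20)))
  enr <- enrich_against_collection(query, sets, universe)
  expect_identical(enr$set_name[enr$p_adjusted < 0.05], "planted")
  # a query disjoint from every set: all p = 1
  enr0 <- enrich_against_collection(universe[150:160],
                                    list(s1 = universe[1:10],
                                         s2 = universe[11:20]),
                                    universe)
  expect_true(all(enr0$p_value == 1))
})

test_that("GMT files round-trip", {
  sets <- list(A = c("X1", "X2"), B = c("Y1", "Y2", "Y3"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sets, f, descriptions = c("setA", "setB"))
  back <- read_gmt(f)
  expect_identical(back$A, c("X1", "X2"))
  expect_identical(attr(back, "descriptions"), c("setA", "setB"))
  unlink(f)
})

test_that("published fixture: conserved genes, P3F targets, signature sets", {
  tbl <- load_dmde_fixture("fp_fn")
  expect_identical(length(unique(tbl$gene_symbol)), 40L)
  targets <- p3f_target_genes()
  expect_identical(length(targets), 11L)
  expect_true(all(c("FGF8", "ZIC1", "SCARA5") %in% targets))
  sets <- dmde_gene_sets(tbl)
  expect_true("COL1A2" %in% sets$Wei_Mesenchymal)
  expect_true(all(c("COL1A2", "ERRFI1") %in% sets$Danielli_MuSC))
  # Fnco members per the table
  expect_setequal(sets$Wei_FN.CORE,
                  c("EMILIN1", "HOXC6", "HOXD4", "LTBP4"))
  tbl3 <- load_dmde_fixture("mr1_mr2")
  sets3 <- dmde_gene_sets(tbl3)
  # the myocyte signature is the dominant overlap in the subset comparison
  expect_gte(length(sets3$Patel_Myocyte), 16L)
})
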