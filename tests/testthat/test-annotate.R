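# Promoter/body classification, homolog matching, synteny filtering.

plus_tx <- data.frame(
  transcript_id = "txA.1", gene_symbol = "GeneA", chrom = "chr1", strand = "+",
  txStart = 10000L, txEnd = 18000L,
  exonStarts = "10000,11000,13000,15000", exonEnds = "10200,11400,13500,15800",
  stringsAsFactors = FALSE
)
minus_tx <- data.frame(
  transcript_id = "txB.1", gene_symbol = "GeneB", chrom = "chr1", strand = "-",
  txStart = 1000L, txEnd = 5000L,
  exonStarts = "1000,2500,4600", exonEnds = "1800,3000,5000",
  stringsAsFactors = FALSE
)

probe_at <- function(pos, chrom = "chr1", id = "p1") {
  data.frame(probe_id = id, chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

test_that("promoter and body rules follow the strand-aware definitions", {
  # 1,200 bp upstream of a plus-strand TSS: promoter
  r <- classify_probe_region(probe_at(8800L), plus_tx)
  expect_identical(r$region, "promoter")
  # inside the first exon: promoter
  expect_identical(classify_probe_region(probe_at(10100L), plus_tx)$region,
                   "promoter")
  # inside exon 3: body
  expect_identical(classify_probe_region(probe_at(13200L), plus_tx)$region,
                   "body")
  # inside intron 1: body
  expect_identical(classify_probe_region(probe_at(10600L), plus_tx)$region,
                   "body")
  # 2,000 bp upstream, outside every transcript: no assignment
  expect_identical(nrow(classify_probe_region(probe_at(8000L), plus_tx)), 0L)
  # minus strand: 400 bp beyond txEnd is within 1,500 bp upstream of the TSS
  expect_identical(classify_probe_region(probe_at(5400L), minus_tx)$region,
                   "promoter")
  # minus strand first exon (genomically last)
  expect_identical(classify_probe_region(probe_at(4700L), minus_tx)$region,
                   "promoter")
  # minus strand genomically-first exon is the last in transcription order
  expect_identical(classify_probe_region(probe_at(1500L), minus_tx)$region,
                   "body")
  # zero-exon transcript is an input error
  bad <- plus_tx; bad$exonStarts <- ""; bad$exonEnds <- ""
  expect_error(annotate_probes(probe_at(10100L), bad), "zero exons")
})

# Independent oracle: literal re-statement of the rule, evaluated position by
# position with plain interval arithmetic on expanded exon lists.
oracle_classify <- function(pos, tx) {
  region <- NA_character_
  for (i in seq_len(nrow(tx))) {
    s <- as.integer(strsplit(tx$exonStarts[i], ",")[[1]])
    e <- as.integer(strsplit(tx$exonEnds[i], ",")[[1]])
    if (tx$strand[i] == "+") {
      prom <- (pos >= tx$txStart[i] - 1500 && pos < tx$txStart[i]) ||
        (pos >= s[1] && pos < e[1])
    } else {
      k <- length(s)
      prom <- (pos >= tx$txEnd[i] && pos < tx$txEnd[i] + 1500) ||
        (pos >= s[k] && pos < e[k])
    }
    if (prom) return("promoter")
    inside <- pos >= tx$txStart[i] && pos < tx$txEnd[i]
    if (inside) region <- "body"
  }
  region
}

test_that("classifier matches an exhaustive position scan over 2kb flanks", {
  for (tx in list(plus_tx, minus_tx, rbind(plus_tx, minus_tx))) {
    lo <- min(tx$txStart) - 2000L
    hi <- max(tx$txEnd) + 2000L
    positions <- seq(lo, hi, by = 7L)   # dense scan, ~1.7k positions
    man <- data.frame(probe_id = sprintf("p%05d", seq_along(positions)),
                      chrom = "chr1", pos = positions,
                      stringsAsFactors = FALSE)
    got <- annotate_probes(man, tx)
    for (g in unique(tx$gene_symbol)) {
      txg <- tx[tx$gene_symbol == g, , drop = FALSE]
      want <- vapply(positions, oracle_classify, character(1), tx = txg)
      gg <- got[got$gene_symbol == g, ]
      have <- gg$region[match(man$probe_id, gg$probe_id)]
      expect_identical(have, want)
    }
  }
})

test_that("promoter precedence holds and strand reflection is symmetric", {
  cohort <- small_cohort()
  asg <- annotate_probes(cohort$manifest, cohort$transcripts)
  expect_identical(anyDuplicated(paste(asg$probe_id, asg$gene_symbol)), 0L)

  # reflect all coordinates around a constant and flip strands: regions fixed
  C <- 10000000L
  tx <- as.data.frame(cohort$transcripts)[1:40, ]
  man <- cohort$manifest[cohort$manifest$chrom %in% tx$chrom, ][1:200, ]
  reflect_list <- function(starts, ends) {
    s <- as.integer(strsplit(starts, ",")[[1]])
    e <- as.integer(strsplit(ends, ",")[[1]])
    list(starts = paste(rev(C - e), collapse = ","),
         ends = paste(rev(C - s), collapse = ","))
  }
  tx_r <- tx
  for (i in seq_len(nrow(tx))) {
    r <- reflect_list(tx$exonStarts[i], tx$exonEnds[i])
    tx_r$exonStarts[i] <- r$starts
    tx_r$exonEnds[i] <- r$ends
  }
  tx_r$txStart <- C - tx$txEnd
  tx_r$txEnd <- C - tx$txStart
  tx_r$strand <- ifelse(tx$strand == "+", "-", "+")
  man_r <- man
  man_r$pos <- C - 1L - man$pos
  a1 <- annotate_probes(man, tx)
  a2 <- annotate_probes(man_r, tx_r)
  key <- function(a) a[order(a$probe_id, a$gene_symbol),
                       c("probe_id", "gene_symbol", "region")]
  expect_identical(key(a1), key(a2))
})

test_that("reference universe matching follows symbol-case and homolog rules", {
  m <- data.frame(probe_id = c("m1", "m2", "m3"),
                  gene_symbol = c("Pax7", "Myf5", "Acta1"),
                  region = "promoter", stringsAsFactors = FALSE)
  h <- data.frame(probe_id = c("h1", "h2"),
                  gene_symbol = c("PAX7", "MYOD1"),
                  region = "promoter", stringsAsFactors = FALSE)
  expect_identical(build_reference_universe(m, h), "PAX7")
  hm <- data.frame(mouse_symbol = "Myf5", human_symbol = "MYOD1",
                   stringsAsFactors = FALSE)
  expect_setequal(build_reference_universe(m, h, hm), c("PAX7", "MYOD1"))
  expect_warning(
    u <- build_reference_universe(m, data.frame(probe_id = "h9",
                                                gene_symbol = "TP53",
                                                region = "body")),
    "empty")
  expect_length(u, 0)
})

test_that("synthetic universe contains the planted conserved core", {
  cfg <- small_config(seed = 9)
  mouse <- generate_mouse_cohort(cfg)
  human <- generate_human_cohort(cfg, mouse$truth)
  m_asg <- annotate_probes(mouse$manifest, mouse$transcripts)
  tx_h <- as.data.frame(mouse$transcripts)
  tx_h$gene_symbol <- toupper(tx_h$gene_symbol)
  h_asg <- annotate_probes(human$manifest, tx_h)
  u <- build_reference_universe(m_asg, h_asg, human$homolog_map)
  expect_true(all(mouse$truth$conserved_gene_list %in% u))
})

test_that("synteny filter aligns rows and reports dropped pairs", {
  beta <- matrix(runif(40), 10, 4,
                 dimnames = list(paste0("mm", 1:10), paste0("S", 1:4)))
  map <- data.frame(mouse_probe_id = paste0("mm", c(3, 1, 7)),
                    human_probe_id = paste0("cg", c(3, 1, 7)),
                    stringsAsFactors = FALSE)
  out <- apply_synteny_filter(beta, map, side = "mouse")
  expect_identical(rownames(out), paste0("mm", c(3, 1, 7)))
  expect_identical(nrow(attr(out, "dropped_pairs")), 0L)
  map2 <- rbind(map, data.frame(mouse_probe_id = c("mm99", "mm98"),
                                human_probe_id = c("cg99", "cg98")))
  expect_message(out2 <- apply_synteny_filter(beta, map2, side = "mouse"),
                 "2 synteny pairs dropped")
  expect_identical(nrow(out2), 3L)
  expect_identical(nrow(attr(out2, "dropped_pairs")), 2L)
  expect_error(apply_synteny_filter(beta, map[0, ], "mouse"),
               "empty synteny map")
})
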