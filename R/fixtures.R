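# Packaged fixtures: the published 31-tumour GEMM RMS cohort characteristics,
# methylation cluster labels (partially inferred — see the fixture docs), the
# published cross-species and subset DM/DE gene tables, and the association
# contingency counts reported alongside them.

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "methylGEMM", mustWork = FALSE)
  if (!nzchar(p)) stop("fixture not found: ", name, call. = FALSE)
  p
}

#' Load the 31-tumour GEMM cohort sample sheet
#'
#' Parses the published cohort characteristics table (sample, model, genotype
#' string) into an analysis-ready sample sheet: myogenic `lineage` (Pax3,
#' Myf5, Myf6 or Pax7), `fusion_knockin` (Pax3::Foxo1 knock-in present),
#' `fusion_expression` level (high for Pax3/Myf5/Myf6-lineage knock-ins, low
#' for Pax7-lineage knock-ins whose fusion RNA expression is weak, none
#' otherwise), and `ptch1_mut` / `rb1_mut` / `trp53_mut` flags parsed from the
#' genotype strings. The file content is checksum-verified.
#'
#' @return data.frame with 31 rows.
#' @export
load_table1_fixture <- function() {
  path <- fixture_path("gemm31_samples.tsv")
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, GEMM31_MD5)) {
    stop("fixture checksum mismatch for gemm31_samples.tsv", call. = FALSE)
  }
  df <- utils::read.delim(path, colClasses = "character")
  lineage <- sub("-P3F$", "", df$model)
  knockin <- grepl("-P3F$", df$model)
  data.frame(
    sample_id = df$sample,
    model = df$model,
    lineage = lineage,
    fusion_knockin = knockin,
    fusion_expression = ifelse(!knockin, "none",
                               ifelse(lineage == "Pax7", "low", "high")),
    ptch1_mut = grepl("Ptch1(F1-2m", df$genotype, fixed = TRUE),
    rb1_mut = grepl("Rb1(Flox/Flox)", df$genotype, fixed = TRUE),
    trp53_mut = grepl("Trp53(", df$genotype, fixed = TRUE),
    genotype = df$genotype,
    stringsAsFactors = FALSE
  )
}

# md5 of the packaged cohort table, fixed at packaging time
GEMM31_MD5 <- "ec9a6a6a26162f3e3969f543e4137e19"

#' Load the methylation cluster labels for the GEMM cohort
#'
#' Main clusters ML/MR and MR subsets MR1/MR2. ML membership (the 11
#' high-fusion tumours), the Myf5-lineage tumours in MR1, the Pax7-lineage
#' tumours in MR2, and the MR2 placement of the two Rb1-mutant MR tumours are
#' fixed by the published cluster composition; the remaining split of the
#' non-fusion Pax3/Myf6 tumours between MR1 and MR2 is inferred (not
#' published), hence the fixture's `_inferred` name.
#'
#' @return data.frame: `sample_id`, `main` (ML/MR), `subset` (MR1/MR2 or NA).
#' @export
load_cluster_labels_fixture <- function() {
  df <- utils::read.delim(fixture_path("gemm31_cluster_labels_inferred.tsv"),
                          colClasses = "character")
  df$subset[!nzchar(df$subset)] <- NA_character_
  names(df)[names(df) == "sample"] <- "sample_id"
  df
}

#' Load a published DM/DE gene table
#'
#' Two fixtures are packaged: the 40 cross-species conserved DM/DE genes of
#' the mouse ML-vs-MR / human FP-vs-FN comparison (`"fp_fn"`), and the
#' representative DM/DE genes of the mouse MR1-vs-MR2 comparison
#' (`"mr1_mr2"`). A gene can appear on several rows (one per gene region);
#' single-cell signature memberships (Patel/Wei/Danielli) and — for the
#' cross-species table — PAX3::FOXO1-target status are carried as columns.
#'
#' @param contrast `"fp_fn"` or `"mr1_mr2"`.
#' @return data.frame with one row per (gene, region, direction) record.
#' @export
load_dmde_fixture <- function(contrast = c("fp_fn", "mr1_mr2")) {
  contrast <- match.arg(contrast)
  file <- if (contrast == "fp_fn") "dmde_fp_fn_genes.tsv" else "dmde_mr1_mr2_genes.tsv"
  df <- utils::read.delim(fixture_path(file), stringsAsFactors = FALSE)
  if ("p3f_target" %in% names(df)) df$p3f_target <- as.logical(df$p3f_target)
  df
}

# token -> canonical single-cell signature set name
SIGNATURE_TOKENS <- c(
  Myoc = "Patel_Myocyte", Meso = "Patel_Mesoderm", Myob = "Patel_Myoblast",
  Mese = "Wei_Mesenchymal", Fnco = "Wei_FN.CORE", Mus = "Wei_Muscle",
  MuSC = "Danielli_MuSC", Cycl = "Danielli_Cycling",
  Diff = "Danielli_Differentiated"
)

#' Gene-set collection from a DM/DE fixture table
#'
#' Converts the Patel/Wei/Danielli membership columns of a
#' [load_dmde_fixture()] table into a named gene-set collection. These are the
#' memberships restricted to the published DM/DE genes — not the full
#' single-cell signatures, which are external resources.
#'
#' @param tbl A table from [load_dmde_fixture()].
#' @return Named list of uppercase gene-symbol vectors.
#' @export
dmde_gene_sets <- function(tbl) {
  sets <- stats::setNames(vector("list", length(SIGNATURE_TOKENS)),
                          unname(SIGNATURE_TOKENS))
  cols <- intersect(c("patel", "wei", "danielli"), names(tbl))
  for (col in cols) {
    toks <- strsplit(tbl[[col]], ",", fixed = TRUE)
    for (i in seq_along(toks)) {
      for (tk in toks[[i]]) {
        tk <- trimws(tk)
        if (!nzchar(tk)) next
        nm <- SIGNATURE_TOKENS[[tk]]
        sets[[nm]] <- c(sets[[nm]], tbl$gene_symbol[i])
      }
    }
  }
  lapply(sets, function(s) sort(unique(toupper(s %||% character()))))
}

#' PAX3::FOXO1 target genes among the conserved DM/DE genes
#'
#' @return Character vector of the conserved DM/DE genes flagged as published
#'   PAX3::FOXO1-binding targets.
#' @export
p3f_target_genes <- function() {
  tbl <- load_dmde_fixture("fp_fn")
  sort(unique(tbl$gene_symbol[tbl$p3f_target]))
}

#' Load the reported association contingency counts
#'
#' The 2x2 cell counts of the cluster-vs-metadata association battery as
#' reported for the GEMM cohort (rows = contrast group 1 factor-yes/no,
#' group 2 factor-yes/no), plus the Myf6-lineage x high-fusion agreement
#' table. These printed counts are inputs: the package recomputes every
#' statistic from them.
#'
#' @return data.frame: `factor`, `contrast`, `statistic` (fisher/kappa),
#'   `a`, `b`, `c`, `d`.
#' @export
load_reported_associations <- function() {
  utils::read.delim(fixture_path("reported_associations.tsv"),
                    stringsAsFactors = FALSE)
}

#' Recompute the association battery from reported counts
#'
#' Runs [fisher_exact_2x2()] (or [cohens_kappa()]) on every row of
#' [load_reported_associations()]; nothing is looked up — each statistic is
#' computed from the stored cell counts at call time.
#'
#' @return The counts table with `value` (p-value, or kappa), `ci_low`,
#'   `ci_high` (kappa rows only) and `value_rounded` columns added.
#' @export
reported_association_stats <- function() {
  tab <- load_reported_associations()
  val <- numeric(nrow(tab))
  lo <- hi <- rep(NA_real_, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    cells <- as.integer(tab[i, c("a", "b", "c", "d")])
    if (tab$statistic[i] == "fisher") {
      val[i] <- fisher_exact_2x2(cells)
    } else {
      k <- cohens_kappa(cells)
      val[i] <- k$kappa
      lo[i] <- k$ci95[1]
      hi[i] <- k$ci95[2]
    }
  }
  tab$value <- val
  tab$ci_low <- lo
  tab$ci_high <- hi
  tab$value_rounded <- round(val, 3)
  tab
}

#' Association battery on the packaged GEMM cohort
#'
#' Builds the contingency battery directly from the parsed cohort sample
#' sheet and the packaged cluster labels: every binary factor (lineages,
#' fusion expression levels, mutation flags) against the ML-vs-MR and
#' MR1-vs-MR2 contrasts. Counts are computed from the fixtures, never copied
#' from reported tables, so discrepancies between genotype-derived counts and
#' reported ones remain visible.
#'
#' @return Association table as from [associate_clusters_with_metadata()].
#' @export
gemm_association_battery <- function() {
  sheet <- load_table1_fixture()
  labels <- load_cluster_labels_fixture()
  sheet <- merge(sheet, labels, by = "sample_id", sort = FALSE)
  sheet$fusion_high <- sheet$fusion_expression == "high"
  sheet$fusion_weak <- sheet$fusion_expression == "low"
  for (lin in c("Pax3", "Myf5", "Myf6", "Pax7")) {
    sheet[[paste0(tolower(lin), "_lineage")]] <- sheet$lineage == lin
  }
  assign <- data.frame(sample_id = sheet$sample_id, main = sheet$main,
                       subset = sheet$subset, stringsAsFactors = FALSE)
  factors <- c("fusion_high", "fusion_weak", "pax3_lineage", "myf5_lineage",
               "myf6_lineage", "pax7_lineage", "ptch1_mut", "rb1_mut",
               "trp53_mut")
  withCallingHandlers(
    associate_clusters_with_metadata(assign, sheet, factors),
    warning = function(w) {
      # trp53 is constant (mutated in every model) and is skipped by design
      if (grepl("constant", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  )
}
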