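# Plain-text readers/writers for the pipeline's exchange formats.
# Matrices travel as TSV with an `id` first column; sample sheets as CSV.

#' Write a probes/genes x samples matrix as TSV
#' @param m Numeric matrix with rownames and colnames.
#' @param file Output path.
#' @param id_col Name for the identifier column (default "id").
#' @export
write_matrix_tsv <- function(m, file, id_col = "id") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param file Input path.
#' @return Numeric matrix with rownames from the first column.
#' @export
read_matrix_tsv <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write/read a data.frame as TSV
#' @param df data.frame.
#' @param file Path.
#' @export
write_table_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' Write an entire synthetic cohort to a directory
#'
#' Emits the standard file set: `beta.tsv`, `expression.tsv`,
#' `sample_sheet.csv`, `manifest.tsv`, `transcripts.tsv`, ground-truth tables
#' (`truth_dm_probes.tsv`, `truth_de_genes.tsv`, `truth_samples.tsv`), the
#' planted gene sets as `truth_sets.gmt`, and — for a human cohort —
#' `synteny_map.tsv` and `homolog_map.tsv`.
#'
#' @param cohort A `mouse_cohort` or `human_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    write_matrix_tsv(cohort$beta, file.path(dir, "beta.tsv"), "probe_id"),
    write_matrix_tsv(cohort$expression, file.path(dir, "expression.tsv"),
                     "gene_symbol")
  )
  utils::write.csv(cohort$sample_sheet, file.path(dir, "sample_sheet.csv"),
                   row.names = FALSE, quote = FALSE)
  files <- c(files, file.path(dir, "sample_sheet.csv"),
             write_table_tsv(cohort$manifest, file.path(dir, "manifest.tsv")))
  if (!is.null(cohort$transcripts)) {
    files <- c(files, write_table_tsv(as.data.frame(cohort$transcripts),
                                      file.path(dir, "transcripts.tsv")))
  }
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    files <- c(
      files,
      write_table_tsv(tr$dm_probe_table, file.path(dir, "truth_dm_probes.tsv")),
      write_table_tsv(tr$de_gene_table, file.path(dir, "truth_de_genes.tsv")),
      write_table_tsv(tr$sample_labels, file.path(dir, "truth_samples.tsv"))
    )
    sets <- list(
      planted_dm_fp = unique(tr$dm_probe_table$gene_symbol[
        tr$dm_probe_table$contrast == "FP_vs_FN"]),
      planted_de_fp = unique(tr$de_gene_table$gene_symbol[
        tr$de_gene_table$contrast == "FP_vs_FN"]),
      conserved_core = tr$conserved_gene_list
    )
    files <- c(files, write_gmt(sets, file.path(dir, "truth_sets.gmt")))
  }
  if (!is.null(cohort$synteny_map)) {
    files <- c(files,
               write_table_tsv(cohort$synteny_map, file.path(dir, "synteny_map.tsv")),
               write_table_tsv(cohort$homolog_map, file.path(dir, "homolog_map.tsv")))
  }
  invisible(files)
}
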