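# DM/DE integration, cross-species matching, and gene-set enrichment.

#' Intersect DM gene-region calls with DE calls
#'
#' Keeps the differentially methylated (gene, region, methylation-direction)
#' calls whose gene is also significantly differentially expressed, annotating
#' each with the expression direction. Genes DM but not DE are excluded.
#' Counts per stratum (2 regions x 2 methylation directions x 2 expression
#' directions = 8 strata) are attached as attribute `"stratum_counts"`.
#'
#' @param calls Gene-region calls from [collapse_to_gene_region()].
#' @param de DE results from [de_genes()] for the same species/contrast.
#' @param species Species tag recorded on the output (default "mouse").
#' @return data.frame: `gene_symbol`, `region`, `methyl_direction`,
#'   `expr_direction`, `species`.
#' @export
integrate_dm_de <- function(calls, de, species = "mouse") {
  sig_de <- de[de$significant, c("gene_symbol", "direction"), drop = FALSE]
  names(sig_de)[2] <- "expr_direction"
  out <- merge(calls, sig_de, by = "gene_symbol")
  out <- data.frame(
    gene_symbol = out$gene_symbol,
    region = out$region,
    methyl_direction = out$direction,
    expr_direction = out$expr_direction,
    species = species,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_symbol, out$region, out$methyl_direction), ]
  rownames(out) <- NULL
  strata <- table(
    region = factor(out$region, c("promoter", "body")),
    methyl = factor(out$methyl_direction, c("hypo", "hyper")),
    expr = factor(out$expr_direction, c("over", "under"))
  )
  attr(out, "stratum_counts") <- strata
  out
}

#' Cross-species common DM/DE genes
#'
#' Matches integrated mouse and human DM/DE calls by gene symbol only —
#' region/direction concordance is not required, since conserved genes are
#' reported at the symbol level with their per-species strata retained.
#' Mouse symbols are canonicalized to the human-style uppercase form, via an
#' explicit homolog map when given, else by uppercasing.
#'
#' @param mouse,human Integrated call tables from [integrate_dm_de()].
#' @param homolog_map Optional data.frame (`mouse_symbol`, `human_symbol`).
#' @return data.frame with one row per common gene: `gene_symbol` (canonical),
#'   `species` ("both"), `mouse_strata`, `human_strata` (collapsed
#'   region/methyl/expr descriptors).
#' @export
cross_species_common <- function(mouse, human, homolog_map = NULL) {
  canon <- toupper(mouse$gene_symbol)
  if (!is.null(homolog_map)) {
    hit <- match(mouse$gene_symbol, homolog_map$mouse_symbol)
    canon[!is.na(hit)] <- homolog_map$human_symbol[hit[!is.na(hit)]]
  }
  strata_str <- function(df) {
    paste(df$region, df$methyl_direction, df$expr_direction, sep = "/")
  }
  m_str <- tapply(strata_str(mouse), canon, function(s) paste(sort(unique(s)), collapse = ";"))
  h_str <- tapply(strata_str(human), human$gene_symbol,
                  function(s) paste(sort(unique(s)), collapse = ";"))
  common <- sort(intersect(names(m_str), names(h_str)))
  data.frame(
    gene_symbol = common,
    species = rep("both", length(common)),
    mouse_strata = unname(m_str[common]),
    human_strata = unname(h_str[common]),
    stringsAsFactors = FALSE
  )
}

#' Hypergeometric over-representation of one gene set
#'
#' Upper-tail hypergeometric probability of observing at least the realized
#' overlap between `query` and `target` inside `universe` (equivalent to a
#' one-sided Fisher exact test for over-representation). Query/target members
#' outside the universe are dropped with a warning.
#'
#' @param query,target,universe Character vectors of gene symbols.
#' @return A one-row data.frame: `overlap_count`, `set_size`, `query_size`,
#'   `universe_size`, `p_value`.
#' @export
overlap_enrichment <- function(query, target, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- unique(query)
  target <- unique(target)
  out_q <- setdiff(query, universe)
  out_t <- setdiff(target, universe)
  if (length(out_q) > 0L || length(out_t) > 0L) {
    warning(length(out_q), " query and ", length(out_t),
            " target genes outside the universe were dropped", call. = FALSE)
  }
  query <- intersect(query, universe)
  target <- intersect(target, universe)
  k <- length(intersect(query, target))
  # P(overlap >= k) drawing |query| genes from a universe containing |target|
  p <- stats::phyper(k - 1, length(target), length(universe) - length(target),
                     length(query), lower.tail = FALSE)
  data.frame(overlap_count = k, set_size = length(target),
             query_size = length(query), universe_size = length(universe),
             p_value = min(1, p))
}

#' Enrichment of a query against a named gene-set collection
#'
#' Runs [overlap_enrichment()] for every named set and adds a
#' Benjamini-Hochberg adjusted p across the collection.
#'
#' @param query Character vector of gene symbols.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Reference gene universe.
#' @return data.frame: `set_name`, `overlap_count`, `set_size`, `query_size`,
#'   `universe_size`, `p_value`, `p_adjusted`.
#' @export
enrich_against_collection <- function(query, sets, universe) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must be uniquely named", call. = FALSE)
  }
  rows <- lapply(names(sets), function(nm) {
    cbind(set_name = nm, overlap_enrichment(query, sets[[nm]], universe))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Symbols are uppercase-canonicalized.
#'
#' @param file Path to a .gmt file.
#' @return Named list of character vectors; descriptions kept as attribute.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) toupper(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT", call. = FALSE)
  attr(sets, "descriptions") <- vapply(parts, `[[`, character(1), 2L)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors.
#' @param file Output path.
#' @param descriptions Optional character vector (recycled "na" otherwise).
#' @export
write_gmt <- function(sets, file, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- rep("na", length(sets))
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}
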