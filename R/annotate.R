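# Probe-to-gene region annotation.
#
# The classification rule: a probe is in the "promoter" of a gene if it lies
# within the 1,500 bp immediately upstream of the transcription start site
# (strand-aware, half-open window [TSS-1500, TSS)) and/or inside the first
# exon (first in transcription order) of any transcript of that gene. It is in
# the "body" if it lies inside any intron or any exon other than the first
# exon. Promoter takes precedence within a gene; assignments to different
# genes are independent, so one probe can be promoter of gene A and body of
# gene B. All coordinates are 0-based half-open; the manifest `pos` is the
# single interrogated CpG base.

# Parse comma-separated genePred exon lists into integer vectors.
parse_exon_list <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])

# Internal: classify one position against one transcript row (already parsed
# exon starts/ends). Returns "promoter", "body" or NA.
classify_position_tx <- function(pos, strand, txStart, txEnd, ex_s, ex_e) {
  if (length(ex_s) == 0L) stop("transcript with zero exons", call. = FALSE)
  if (strand == "+") {
    tss <- txStart
    in_prom_window <- pos >= tss - 1500L && pos < tss
    first <- 1L                      # transcription order = genomic order
  } else {
    tss <- txEnd                     # TSS-side boundary (half-open end)
    in_prom_window <- pos >= tss && pos < tss + 1500L
    first <- length(ex_s)            # transcription order reversed
  }
  in_first_exon <- pos >= ex_s[first] && pos < ex_e[first]
  if (in_prom_window || in_first_exon) return("promoter")
  # inside the span but outside the first exon: a non-first exon or an
  # intron, both of which are "body"
  if (pos >= txStart && pos < txEnd) return("body")
  NA_character_
}

#' Classify a probe into promoter/body regions per gene
#'
#' Applies the strand-aware promoter/body rule (see Details) to one probe
#' against a set of transcript models and returns at most one record per gene:
#' promoter if the probe falls in the 1,500-bp upstream window `[TSS-1500,
#' TSS)` of, or in the first exon (in transcription order) of, any transcript
#' of the gene; otherwise body if it falls in any intron or any non-first
#' exon; otherwise no record. Promoter takes precedence over body within a
#' gene; a probe may map to several genes.
#'
#' @param probe A one-row data.frame (or list) with `probe_id`, `chrom`, `pos`.
#' @param transcripts Transcript models: data.frame with `transcript_id`,
#'   `gene_symbol`, `chrom`, `strand`, `txStart`, `txEnd`, `exonStarts`,
#'   `exonEnds` (comma-separated, 0-based half-open).
#' @return data.frame with columns `probe_id`, `gene_symbol`, `region`.
#' @export
classify_probe_region <- function(probe, transcripts) {
  tx <- transcripts[transcripts$chrom == probe$chrom, , drop = FALSE]
  if (nrow(tx) == 0L) {
    return(data.frame(probe_id = character(), gene_symbol = character(),
                      region = character(), stringsAsFactors = FALSE))
  }
  pos <- as.integer(probe$pos)
  region_by_gene <- character(0)
  for (i in seq_len(nrow(tx))) {
    r <- classify_position_tx(pos, tx$strand[i], tx$txStart[i], tx$txEnd[i],
                              parse_exon_list(tx$exonStarts[i]),
                              parse_exon_list(tx$exonEnds[i]))
    if (is.na(r)) next
    g <- tx$gene_symbol[i]
    if (!g %in% names(region_by_gene)) {
      region_by_gene[g] <- r
    } else if (region_by_gene[[g]] == "body" && r == "promoter") {
      region_by_gene[g] <- "promoter"   # promoter precedence within a gene
    }
  }
  if (length(region_by_gene) == 0L) {
    return(data.frame(probe_id = character(), gene_symbol = character(),
                      region = character(), stringsAsFactors = FALSE))
  }
  data.frame(probe_id = probe$probe_id,
             gene_symbol = names(region_by_gene),
             region = unname(region_by_gene),
             stringsAsFactors = FALSE)
}

#' Annotate a full probe manifest against transcript models
#'
#' Vectorized driver over [classify_probe_region()]: classifies every manifest
#' probe and returns the concatenated (probe_id, gene_symbol, region)
#' assignment table with promoter precedence per gene.
#'
#' @param manifest Probe manifest data.frame (`probe_id`, `chrom`, `pos`).
#' @param transcripts Transcript models (see [classify_probe_region()]).
#' @return data.frame with columns `probe_id`, `gene_symbol`, `region`.
#' @export
annotate_probes <- function(manifest, transcripts) {
  # Pre-parse transcripts once; interval tests are vectorized per transcript
  # over all probes on its chromosome, which is what makes a 20k-probe
  # manifest tractable without an interval-tree dependency.
  ex_s <- lapply(transcripts$exonStarts, parse_exon_list)
  ex_e <- lapply(transcripts$exonEnds, parse_exon_list)
  if (any(lengths(ex_s) == 0L)) stop("transcript with zero exons", call. = FALSE)
  out <- vector("list", nrow(transcripts))
  for (i in seq_len(nrow(transcripts))) {
    on_chr <- which(manifest$chrom == transcripts$chrom[i])
    if (length(on_chr) == 0L) next
    pos <- manifest$pos[on_chr]
    s <- ex_s[[i]]; e <- ex_e[[i]]
    if (transcripts$strand[i] == "+") {
      tss <- transcripts$txStart[i]
      prom_win <- pos >= tss - 1500L & pos < tss
      first <- 1L
    } else {
      tss <- transcripts$txEnd[i]
      prom_win <- pos >= tss & pos < tss + 1500L
      first <- length(s)
    }
    first_ex <- pos >= s[first] & pos < e[first]
    promoter <- prom_win | first_ex
    body <- !promoter & pos >= transcripts$txStart[i] & pos < transcripts$txEnd[i]
    hit <- promoter | body
    if (!any(hit)) next
    out[[i]] <- data.frame(
      probe_id = manifest$probe_id[on_chr][hit],
      gene_symbol = transcripts$gene_symbol[i],
      region = ifelse(promoter[hit], "promoter", "body"),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(probe_id = character(), gene_symbol = character(),
                      region = character(), stringsAsFactors = FALSE))
  }
  # promoter precedence per (probe, gene) across transcripts
  key <- paste(res$probe_id, res$gene_symbol, sep = "\r")
  rank <- ifelse(res$region == "promoter", 0L, 1L)
  best <- res[order(key, rank), ]
  best <- best[!duplicated(paste(best$probe_id, best$gene_symbol, sep = "\r")), ]
  rownames(best) <- NULL
  best
}

#' Build the cross-platform reference gene universe
#'
#' Returns the set of gene symbols represented by at least one probe
#' assignment on both the mouse and the human platform. Matching defaults to
#' uppercase symbol equality (mouse `Pax7` matches human `PAX7`); an explicit
#' two-column homolog map (`mouse_symbol`, `human_symbol`) overrides or
#' augments the case rule. The canonical form is the human-style uppercase
#' symbol.
#'
#' @param mouse_assignments,human_assignments Assignment tables from
#'   [annotate_probes()].
#' @param homolog_map Optional data.frame (`mouse_symbol`, `human_symbol`).
#' @return Character vector of canonical (uppercase) symbols.
#' @export
build_reference_universe <- function(mouse_assignments, human_assignments,
                                     homolog_map = NULL) {
  mouse_genes <- unique(mouse_assignments$gene_symbol)
  human_genes <- unique(human_assignments$gene_symbol)
  canon <- toupper(mouse_genes)
  if (!is.null(homolog_map)) {
    hit <- match(mouse_genes, homolog_map$mouse_symbol)
    canon[!is.na(hit)] <- homolog_map$human_symbol[hit[!is.na(hit)]]
  }
  universe <- sort(unique(intersect(canon, human_genes)))
  if (length(universe) == 0L) {
    warning("no genes shared between the two platforms; empty reference set")
  }
  universe
}

#' Restrict a beta matrix to syntenic probes
#'
#' Subsets a mouse or human beta matrix to the probes present in a synteny map
#' and orders the rows by the map, so that the mouse and human matrices
#' produced from the same map are row-aligned. Pairs whose probe is missing
#' from the matrix are excluded and reported.
#'
#' @param beta Beta matrix (probes x samples, rownames = probe ids).
#' @param map data.frame with columns `mouse_probe_id`, `human_probe_id`.
#' @param side Which column of the map indexes `beta`: "mouse" or "human".
#' @return The row-subset beta matrix, with the excluded pairs attached as
#'   attribute `"dropped_pairs"`.
#' @export
apply_synteny_filter <- function(beta, map, side = c("mouse", "human")) {
  side <- match.arg(side)
  if (is.null(map) || nrow(map) == 0L) stop("empty synteny map", call. = FALSE)
  ids <- if (side == "mouse") map$mouse_probe_id else map$human_probe_id
  present <- ids %in% rownames(beta)
  dropped <- map[!present, , drop = FALSE]
  if (nrow(dropped) > 0L) {
    message(nrow(dropped), " synteny pairs dropped (probe absent from matrix)")
  }
  out <- beta[ids[present], , drop = FALSE]
  attr(out, "dropped_pairs") <- dropped
  out
}
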