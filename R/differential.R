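# Differential methylation and expression calling.

check_groups <- function(ids, group1, group2) {
  if (length(intersect(group1, group2)) > 0L) {
    stop("groups overlap", call. = FALSE)
  }
  if (length(group1) < 2L || length(group2) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  missing <- setdiff(c(group1, group2), ids)
  if (length(missing) > 0L) {
    stop("samples not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

#' Call differentially methylated probes between two groups
#'
#' Per probe: a Welch two-sample t-test on M-values (variance-stabilized
#' logit-2 scale) with the effect size reported as delta-beta =
#' mean(group1) - mean(group2) on the beta scale, Benjamini-Hochberg
#' adjustment across all tested probes, and the conjunction significance rule
#' |delta-beta| > `delta_threshold` AND adjusted p < `alpha`. Probes with any
#' missing value in either group are dropped (and counted in attribute
#' `"n_dropped"`). Direction is relative to group 1: `hyper` when group 1 is
#' more methylated.
#'
#' @param beta Beta matrix (probes x samples).
#' @param group1,group2 Disjoint character vectors of sample ids, each of
#'   size >= 2.
#' @param delta_threshold Minimum |delta-beta| (default 0.2).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return data.frame: `probe_id`, `delta_beta`, `p_value`, `p_adjusted`,
#'   `significant`, `direction`.
#' @export
dm_probes <- function(beta, group1, group2, delta_threshold = 0.2,
                      alpha = 0.05) {
  check_groups(colnames(beta), group1, group2)
  complete <- rowSums(is.na(beta[, c(group1, group2), drop = FALSE])) == 0L
  n_dropped <- sum(!complete)
  b <- beta[complete, , drop = FALSE]
  m <- beta_to_m(b)
  w <- row_welch(m, match(group1, colnames(m)), match(group2, colnames(m)))
  delta_beta <- rowMeans(b[, group1, drop = FALSE]) -
    rowMeans(b[, group2, drop = FALSE])
  p_adj <- stats::p.adjust(w$p_value, method = "BH")
  out <- data.frame(
    probe_id = rownames(b),
    delta_beta = delta_beta,
    p_value = w$p_value,
    p_adjusted = p_adj,
    significant = abs(delta_beta) > delta_threshold & p_adj < alpha,
    direction = ifelse(delta_beta > 0, "hyper", "hypo"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Collapse significant probes to directional gene-region calls
#'
#' Joins significant differentially methylated probes with their
#' promoter/body gene assignments and emits one call per (gene, region,
#' direction) with at least one significant supporting probe. When both
#' directions are significant within the same gene region, both calls are
#' emitted and flagged `ambiguous` — a pattern seen in real data where, e.g.,
#' a gene can be promoter-hypermethylated and body-hypomethylated at once.
#'
#' @param dm Result of [dm_probes()].
#' @param assignments Probe-region assignments from [annotate_probes()].
#' @return data.frame: `gene_symbol`, `region`, `direction`,
#'   `n_supporting_probes`, `ambiguous`.
#' @export
collapse_to_gene_region <- function(dm, assignments) {
  sig <- dm[dm$significant, , drop = FALSE]
  hit <- merge(sig[, c("probe_id", "direction")], assignments, by = "probe_id")
  if (nrow(hit) == 0L) {
    return(data.frame(gene_symbol = character(), region = character(),
                      direction = character(), n_supporting_probes = integer(),
                      ambiguous = logical(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(
    list(n_supporting_probes = hit$probe_id),
    by = list(gene_symbol = hit$gene_symbol, region = hit$region,
              direction = hit$direction),
    FUN = length
  )
  gr <- paste(agg$gene_symbol, agg$region, sep = "\r")
  agg$ambiguous <- gr %in% gr[duplicated(gr)]
  agg <- agg[order(agg$gene_symbol, agg$region, agg$direction),
             c("gene_symbol", "region", "direction", "n_supporting_probes",
               "ambiguous")]
  rownames(agg) <- NULL
  agg
}

#' Call differentially expressed genes between two groups
#'
#' Per gene: a Welch two-sample t-test on log2 expression with
#' Benjamini-Hochberg adjustment; significance requires adjusted p < `alpha`
#' and |log2 fold change| >= `lfc_threshold`. Direction is relative to
#' group 1 (`over` = higher in group 1).
#'
#' @param expr Expression matrix (genes x samples) on the linear scale, or on
#'   the log2 scale with `log2_input = TRUE`.
#' @param group1,group2 Disjoint sample-id vectors, each of size >= 2.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param lfc_threshold Minimum |log2 fold change| (default 0).
#' @param log2_input Set TRUE if `expr` is already log2-transformed.
#' @return data.frame: `gene_symbol`, `log2_fold_change`, `p_value`,
#'   `p_adjusted`, `direction`, `significant`.
#' @export
de_genes <- function(expr, group1, group2, alpha = 0.05, lfc_threshold = 0,
                     log2_input = FALSE) {
  check_groups(colnames(expr), group1, group2)
  x <- if (log2_input) expr else log2(expr)
  complete <- rowSums(is.na(x[, c(group1, group2), drop = FALSE])) == 0L
  x <- x[complete, , drop = FALSE]
  w <- row_welch(x, match(group1, colnames(x)), match(group2, colnames(x)))
  p_adj <- stats::p.adjust(w$p_value, method = "BH")
  data.frame(
    gene_symbol = rownames(x),
    log2_fold_change = w$delta,
    p_value = w$p_value,
    p_adjusted = p_adj,
    direction = ifelse(w$delta > 0, "over", "under"),
    significant = p_adj < alpha & abs(w$delta) >= lfc_threshold,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
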