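# Intensity normalization and beta-value preprocessing.

#' Subset-quantile within-array normalization of two-design intensities
#'
#' Harmonizes the intensity distributions of type I and type II probes within
#' each array, separately per channel (methylated / unmethylated). For each
#' array and channel a random subset with equal numbers of type I and type II
#' probes per CpG-count category (1, 2, 3+) is drawn, the subset size per
#' category being the smallest category count across the two types. The target
#' distribution is the mean of the two types' sorted subset intensities;
#' subset probes map to the target by rank and all remaining probes are
#' linearly interpolated between flanking subset quantiles, with the extremes
#' clamped to the subset minimum/maximum. The map is monotone, so ranks within
#' each design type are preserved.
#'
#' @param intens An `intensity_set` (see [generate_intensities()]): list with
#'   `meth`/`unmeth` matrices, `design_type`, `cpg_count`.
#' @param seed Integer seed for the subset draw; the same seed reproduces the
#'   output bit-for-bit.
#' @return A normalized `intensity_set` of the same shape.
#' @export
swan_normalize <- function(intens, seed) {
  stopifnot(inherits(intens, "intensity_set"))
  design <- intens$design_type
  if (!all(c("I", "II") %in% design)) {
    stop("SWAN requires both probe types", call. = FALSE)
  }
  cpg_cat <- pmin(intens$cpg_count, 3L)
  idx_I <- which(design == "I")
  idx_II <- which(design == "II")
  cats <- intersect(unique(cpg_cat[idx_I]), unique(cpg_cat[idx_II]))
  if (length(cats) == 0L) {
    stop("SWAN requires at least one CpG-count category present in both types",
         call. = FALSE)
  }
  out <- intens
  with_seed(seed, {
    for (s in seq_along(intens$sample_ids)) {
      for (ch in c("meth", "unmeth")) {
        x <- intens[[ch]][, s]
        sub_I <- integer(0)
        sub_II <- integer(0)
        for (k in cats) {
          ck_I <- idx_I[cpg_cat[idx_I] == k]
          ck_II <- idx_II[cpg_cat[idx_II] == k]
          nk <- min(length(ck_I), length(ck_II))
          if (nk == 0L) next
          sub_I <- c(sub_I, sample_exact(ck_I, nk))
          sub_II <- c(sub_II, sample_exact(ck_II, nk))
        }
        q_I <- sort(x[sub_I])
        q_II <- sort(x[sub_II])
        target <- (q_I + q_II) / 2
        out[[ch]][idx_I, s] <- swan_map(x[idx_I], q_I, target)
        out[[ch]][idx_II, s] <- swan_map(x[idx_II], q_II, target)
      }
    }
  })
  out
}

# Monotone map taking the subset quantiles `q` (sorted raw values of one
# design type) onto `target`; other values interpolate linearly between the
# flanking subset quantiles and the extremes clamp to the target range.
swan_map <- function(x, q, target) {
  keep <- !duplicated(q)            # approx() needs strictly increasing knots
  stats::approx(q[keep], target[keep], xout = x, rule = 2, ties = "ordered")$y
}

#' Convert channel intensities to beta values
#'
#' `beta = M / (M + U + offset)`, the standard array convention; the offset
#' regularizes low-intensity probes.
#'
#' @param intens An `intensity_set`.
#' @param offset Non-negative regularization constant (default 100).
#' @return Beta matrix (probes x samples) in `[0, 1)`.
#' @export
intensities_to_beta <- function(intens, offset = 100) {
  stopifnot(inherits(intens, "intensity_set"))
  if (offset < 0) stop("offset must be >= 0", call. = FALSE)
  if (any(intens$meth < 0) || any(intens$unmeth < 0)) {
    stop("negative intensity", call. = FALSE)
  }
  beta <- intens$meth / (intens$meth + intens$unmeth + offset)
  beta[intens$meth + intens$unmeth + offset == 0] <- 0
  dimnames(beta) <- list(intens$probe_ids, intens$sample_ids)
  beta
}

#' Convert beta values to M-values
#'
#' `M = log2(beta / (1 - beta))` after clipping beta into
#' `[clip_eps, 1 - clip_eps]`; the logit-2 scale is variance-stabilized and is
#' what the differential tests operate on. Monotone in beta.
#'
#' @param beta Beta matrix.
#' @param clip_eps Clipping bound in (0, 0.5), default 1e-3.
#' @return M-value matrix of the same shape; always finite.
#' @export
beta_to_m <- function(beta, clip_eps = 1e-3) {
  if (clip_eps <= 0 || clip_eps >= 0.5) {
    stop("clip_eps must be in (0, 0.5)", call. = FALSE)
  }
  b <- pmin(pmax(beta, clip_eps), 1 - clip_eps)
  m <- log2(b / (1 - b))
  dimnames(m) <- dimnames(beta)
  m
}

#' Select the most variable probes
#'
#' Ranks probes by across-sample variance (unbiased, n-1 denominator) in
#' descending order and returns the top fraction or count. Probes with more
#' than 20% missing values are excluded before ranking; remaining missing
#' entries are ignored in the variance (complete-observation variance). Ties
#' break deterministically by ascending probe id.
#'
#' @param matrix Beta (or M-value) matrix with probe rownames.
#' @param mode "fraction" (of rows, `round(fraction * n)` selected) or "count".
#' @param amount The fraction (in (0, 1]) or the count.
#' @param max_missing Maximum tolerated per-probe missingness (default 0.2).
#' @return The selected submatrix, rows in decreasing-variance order.
#' @export
select_top_variable <- function(matrix, mode = c("fraction", "count"), amount,
                                max_missing = 0.2) {
  mode <- match.arg(mode)
  if (amount <= 0) stop("amount must be > 0", call. = FALSE)
  miss <- rowMeans(is.na(matrix))
  m <- matrix[miss <= max_missing, , drop = FALSE]
  n <- nrow(m)
  k <- if (mode == "fraction") {
    if (amount > 1) stop("fraction must be <= 1", call. = FALSE)
    round(amount * n)
  } else {
    as.integer(amount)
  }
  if (k > n) stop("requested more probes than available (", k, " > ", n, ")",
                  call. = FALSE)
  v <- row_vars(m, na.rm = TRUE)
  ord <- order(-v, rownames(m))
  m[ord[seq_len(k)], , drop = FALSE]
}

#' Mean-impute missing beta values per probe
#'
#' For clustering/embedding only (differential testing never sees imputed
#' values): replaces each probe's missing entries by the probe's observed
#' mean. Probes missing everywhere are dropped.
#'
#' @param beta Beta matrix possibly containing NA.
#' @return Completed matrix.
#' @export
impute_probe_means <- function(beta) {
  all_na <- rowSums(!is.na(beta)) == 0L
  m <- beta[!all_na, , drop = FALSE]
  na_idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(na_idx) > 0L) {
    rm <- rowMeans(m, na.rm = TRUE)
    m[na_idx] <- rm[na_idx[, 1L]]
  }
  m
}
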