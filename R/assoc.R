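# Exact association statistics between cluster labels and sample metadata.

as_2x2 <- function(t) {
  if (is.matrix(t) || inherits(t, "table")) {
    if (!all(dim(t) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
    t <- c(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
  }
  if (length(t) != 4L) stop("need four cell counts a, b, c, d", call. = FALSE)
  if (any(t < 0)) stop("negative cell count", call. = FALSE)
  if (any(t != round(t))) stop("cell counts must be integers", call. = FALSE)
  if (sum(t) == 0) stop("empty table", call. = FALSE)
  as.integer(t)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional exact test with both margins fixed: the two-sided p-value is
#' the sum of hypergeometric point probabilities, over all tables with the
#' observed margins, that do not exceed the observed table's probability
#' (up to a relative tolerance of 1e-7 guarding against floating-point ties).
#' Cells are laid out as rows = factor present/absent in group 1 vs group 2:
#' `a, b` = yes/no in group 1, `c, d` = yes/no in group 2.
#'
#' @param t Cell counts: a length-4 vector `c(a, b, c, d)` or a 2x2 matrix
#'   (row-major `a, b / c, d`).
#' @return The two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(t) {
  t <- as_2x2(t)
  a <- t[1]; b <- t[2]; cc <- t[3]; d <- t[4]
  m <- a + b                 # group 1 size
  n2 <- cc + d               # group 2 size
  k <- a + cc                # factor-positive total
  if ((m == 0 && n2 == 0) || (k == 0 && b + d == 0)) {
    stop("at least one row and one column margin must be positive",
         call. = FALSE)
  }
  support <- max(0L, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement between two binary classifications:
#' `kappa = (Po - Pe) / (1 - Pe)` with observed agreement `Po = (a + d) / N`
#' and expected agreement `Pe = ((a+b)(a+c) + (c+d)(b+d)) / N^2`. The
#' asymptotic standard error `sqrt(Po (1 - Po) / (N (1 - Pe)^2))` yields a
#' 95% Wald interval.
#'
#' @param t Cell counts as in [fisher_exact_2x2()]; `a` and `d` are the
#'   agreement cells.
#' @return A list of class `kappa_result`: `kappa`, `se`, `ci95` (length-2).
#' @export
cohens_kappa <- function(t) {
  t <- as_2x2(t)
  a <- t[1]; b <- t[2]; cc <- t[3]; d <- t[4]
  N <- sum(t)
  po <- (a + d) / N
  pe <- ((a + b) * (a + cc) + (cc + d) * (b + d)) / N^2
  if (pe >= 1) stop("kappa undefined: degenerate margins (Pe = 1)", call. = FALSE)
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (N * (1 - pe)^2))
  structure(list(kappa = kappa, se = se,
                 ci95 = c(kappa - 1.96 * se, kappa + 1.96 * se)),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.2f (95%% CI: %.2f-%.2f, se = %.3f)\n",
              x$kappa, x$ci95[1], x$ci95[2], x$se))
  invisible(x)
}

#' Associate cluster labels with sample metadata
#'
#' For each binary (or binarizable) factor of the sample sheet, builds the
#' 2x2 contingency table against the main-cluster contrast and — when subset
#' labels are present — against the subset contrast, and attaches the
#' two-sided Fisher exact p-value. Cell counts are always emitted so every p
#' is auditable. Factors constant across the contrasted samples are skipped
#' with a warning (e.g. a mutation present in every tumour is untestable).
#'
#' @param assign A `cluster_assignment` (or its `assignment` data.frame with
#'   columns `sample_id`, `main`, `subset`).
#' @param sheet Sample sheet data.frame with a `sample_id` column.
#' @param factors Character vector of sheet columns to test. Logical columns
#'   are used as-is; two-level character/factor columns are binarized against
#'   their (alphabetically) first level.
#' @return data.frame: `factor`, `contrast`, `a`, `b`, `c`, `d`, `p_value`,
#'   `p_rounded` (3 decimals, matching conventional reporting precision).
#' @export
associate_clusters_with_metadata <- function(assign, sheet, factors) {
  if (inherits(assign, "cluster_assignment")) assign <- assign$assignment
  sheet <- sheet[match(assign$sample_id, sheet$sample_id), , drop = FALSE]
  contrasts <- list()
  main_levels <- sort(unique(assign$main))
  if (length(main_levels) == 2L) {
    contrasts[[paste(main_levels, collapse = "_vs_")]] <-
      list(g1 = assign$main == main_levels[1],
           g2 = assign$main == main_levels[2])
  }
  sub_levels <- sort(unique(stats::na.omit(assign$subset)))
  if (length(sub_levels) == 2L) {
    contrasts[[paste(sub_levels, collapse = "_vs_")]] <-
      list(g1 = !is.na(assign$subset) & assign$subset == sub_levels[1],
           g2 = !is.na(assign$subset) & assign$subset == sub_levels[2])
  }
  rows <- list()
  for (cn in names(contrasts)) {
    g1 <- contrasts[[cn]]$g1
    g2 <- contrasts[[cn]]$g2
    for (f in factors) {
      v <- sheet[[f]]
      if (is.null(v)) stop("factor column not in sample sheet: ", f, call. = FALSE)
      yes <- binarize_factor(v)
      sel <- (g1 | g2) & !is.na(yes)
      if (length(unique(yes[sel])) < 2L) {
        warning("factor '", f, "' is constant across contrast ", cn,
                "; skipped", call. = FALSE)
        next
      }
      tab <- c(sum(yes & g1), sum(!yes & g1), sum(yes & g2), sum(!yes & g2))
      p <- fisher_exact_2x2(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f, contrast = cn,
        a = tab[1], b = tab[2], c = tab[3], d = tab[4],
        p_value = p, p_rounded = round(p, 3),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(factor = character(), contrast = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), p_value = numeric(),
                      p_rounded = numeric(), stringsAsFactors = FALSE)
  }
  out
}

binarize_factor <- function(v) {
  if (is.logical(v)) return(v)
  if (is.numeric(v)) return(v != 0)
  lv <- sort(unique(stats::na.omit(as.character(v))))
  if (length(lv) > 2L) {
    stop("factor has more than two levels; binarize it first", call. = FALSE)
  }
  as.character(v) == lv[1]
}
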