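# Unsupervised structure discovery: hierarchical clustering with a nested
# subset cut, and a t-SNE embedding.

#' Hierarchical clustering with an optional nested subset cut
#'
#' Clusters samples (columns) of a probe matrix by hierarchical agglomeration,
#' cuts the tree into `k_main` main clusters, and optionally re-cuts one main
#' cluster into `k_subset` subsets — mirroring the two main methylation
#' clusters and the two prominent subsets seen within the fusion-negative-like
#' cluster of the GEMM cohort. Main clusters are labelled C1, C2, ... in
#' decreasing size (ties broken by the lexicographically smallest member
#' sample id); subset labels are `<main>a`, `<main>b` under the same rule.
#'
#' @param matrix Numeric matrix, probes x samples, no missing values (impute
#'   upstream with [impute_probe_means()]).
#' @param k_main Number of main clusters (default 2).
#' @param subset_of Optional main cluster label (e.g. "C1") to re-cut.
#' @param k_subset Number of subsets for the nested cut (default 2).
#' @param distance Distance measure for [stats::dist()] (default "euclidean").
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   "ward.D2").
#' @return A list of class `cluster_assignment`: `assignment` (data.frame
#'   `sample_id`, `main`, `subset`), `tree` (the main hclust object),
#'   `subset_tree` (hclust of the re-cut cluster or NULL).
#' @export
hierarchical_cluster <- function(matrix, k_main = 2L, subset_of = NULL,
                                 k_subset = 2L, distance = "euclidean",
                                 linkage = "ward.D2") {
  n <- ncol(matrix)
  if (n < 4L) stop("need at least 4 samples to cluster", call. = FALSE)
  if (k_main > n) stop("k_main exceeds the number of samples", call. = FALSE)
  if (anyNA(matrix)) stop("matrix contains missing values; impute upstream",
                          call. = FALSE)
  d <- stats::dist(t(matrix), method = distance)
  tree <- stats::hclust(d, method = linkage)
  raw <- stats::cutree(tree, k = k_main)
  main <- relabel_clusters(raw, prefix = "C")
  assignment <- data.frame(sample_id = colnames(matrix), main = main,
                           subset = NA_character_, stringsAsFactors = FALSE)
  subset_tree <- NULL
  if (!is.null(subset_of)) {
    members <- assignment$sample_id[assignment$main == subset_of]
    if (length(members) < k_subset) {
      stop("k_subset exceeds the size of cluster ", subset_of, call. = FALSE)
    }
    sub_m <- matrix[, members, drop = FALSE]
    subset_tree <- stats::hclust(stats::dist(t(sub_m), method = distance),
                                 method = linkage)
    sub_raw <- stats::cutree(subset_tree, k = k_subset)
    sub_lab <- relabel_clusters(sub_raw, prefix = subset_of,
                                suffixes = letters)
    assignment$subset[match(members, assignment$sample_id)] <- sub_lab
  }
  structure(list(assignment = assignment, tree = tree,
                 subset_tree = subset_tree),
            class = "cluster_assignment")
}

# Deterministic relabelling: clusters ordered by decreasing size, ties by the
# smallest member name; labels prefix+1..k or prefix+suffixes.
relabel_clusters <- function(raw, prefix, suffixes = NULL) {
  sizes <- table(raw)
  firsts <- tapply(names(raw), raw, function(s) min(s))
  ord <- order(-as.vector(sizes), as.vector(firsts))
  ids <- names(sizes)[ord]
  labels <- if (is.null(suffixes)) {
    paste0(prefix, seq_along(ids))
  } else {
    paste0(prefix, suffixes[seq_along(ids)])
  }
  out <- labels[match(as.character(raw), ids)]
  names(out) <- names(raw)
  out
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Hierarchical cluster assignment:", nrow(x$assignment), "samples\n")
  print(table(main = x$assignment$main, useNA = "no"))
  if (any(!is.na(x$assignment$subset))) {
    print(table(subset = x$assignment$subset, useNA = "no"))
  }
  invisible(x)
}

#' Serialize a cluster dendrogram to Newick
#'
#' @param clust A `cluster_assignment` from [hierarchical_cluster()].
#' @param file Path to write; the main tree (and the subset tree, if present,
#'   as a second line).
#' @export
write_dendrogram_newick <- function(clust, file) {
  stopifnot(inherits(clust, "cluster_assignment"))
  lines <- ape::write.tree(ape::as.phylo(clust$tree))
  if (!is.null(clust$subset_tree)) {
    lines <- c(lines, ape::write.tree(ape::as.phylo(clust$subset_tree)))
  }
  writeLines(lines, file)
  invisible(file)
}

#' t-SNE embedding of samples
#'
#' Exact (dense) t-distributed stochastic neighbour embedding of the sample
#' columns into two dimensions: per-sample Gaussian bandwidths are calibrated
#' to the requested perplexity by binary search, the joint similarities are
#' symmetrized, and the embedding minimizes the Kullback-Leibler divergence by
#' momentum gradient descent with early exaggeration. The dense formulation is
#' the right tool at cohort scale (tens to low hundreds of samples).
#'
#' @param matrix Numeric matrix, probes x samples.
#' @param perplexity Effective neighbourhood size; must satisfy
#'   `perplexity < (n_samples - 1) / 3`.
#' @param seed Integer seed; the same seed reproduces coordinates exactly.
#' @param n_iter Gradient-descent iterations (default 500).
#' @return data.frame of class `tsne_embedding` with columns `sample_id`,
#'   `tsne1`, `tsne2`; perplexity and seed kept as attributes.
#' @export
tsne_embed <- function(matrix, perplexity = 5, seed = 1L, n_iter = 500L) {
  n <- ncol(matrix)
  max_perp <- (n - 1) / 3
  if (perplexity >= max_perp) {
    stop(sprintf("perplexity too large for %d samples; use < %.1f (e.g. %d)",
                 n, max_perp, max(1L, floor(max_perp) - 1L)), call. = FALSE)
  }
  if (anyNA(matrix)) stop("matrix contains missing values", call. = FALSE)
  X <- t(matrix)
  Y <- with_seed(seed, tsne_exact(X, perplexity = perplexity, n_iter = n_iter))
  out <- data.frame(sample_id = colnames(matrix), tsne1 = Y[, 1], tsne2 = Y[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "perplexity") <- perplexity
  attr(out, "seed") <- seed
  class(out) <- c("tsne_embedding", "data.frame")
  out
}

# Perplexity calibration: binary search for the Gaussian precision of each
# row of squared distances so that the conditional distribution has the
# requested Shannon perplexity.
tsne_p_matrix <- function(D2, perplexity, tol = 1e-5, max_iter = 60L) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in seq_len(max_iter)) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { p[] <- 1 / length(p); sp <- 1 }
      H <- log(sp) + beta * sum(di * p) / sp
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else          { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sp
  }
  P
}

tsne_exact <- function(X, perplexity, n_iter = 500L, eta = 200,
                       exaggeration = 12, exag_iter = 100L) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- tsne_p_matrix(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, .Machine$double.eps)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  momentum <- 0.5
  Pex <- P * exaggeration
  for (it in seq_len(n_iter)) {
    Pit <- if (it <= exag_iter) Pex else P
    if (it == exag_iter + 1L) momentum <- 0.8
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.eps)
    W <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- momentum * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
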