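# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a substream seed from a master seed, kept inside 32-bit integer range.
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

clip01 <- function(x, lo = 0.001, hi = 0.999) pmin(pmax(x, lo), hi)

# sample() treats a length-1 numeric x as 1:x; these wrappers never do.
pick_one <- function(v) v[sample.int(length(v), 1L)]
sample_exact <- function(v, k) v[sample.int(length(v), k)]

# Row variances with an unbiased (n-1) denominator; NA-aware.
row_vars <- function(m, na.rm = FALSE) {
  apply(m, 1L, stats::var, na.rm = na.rm)
}

# Vectorized Welch two-sample t-test across matrix rows.
# Returns delta (mean1 - mean2), t statistic, df, and two-sided p.
# Degenerate rows (both groups constant): p = 1 when the means are equal,
# p = 0 when they differ (an infinite signal with zero noise).
row_welch <- function(m, idx1, idx2) {
  x <- m[, idx1, drop = FALSE]
  y <- m[, idx2, drop = FALSE]
  n1 <- ncol(x)
  n2 <- ncol(y)
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1L)
  v2 <- rowSums((y - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  delta <- m1 - m2
  tstat <- delta / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  zero <- se2 == 0
  if (any(zero)) {
    p[zero] <- ifelse(abs(delta[zero]) > 0, 0, 1)
    tstat[zero] <- ifelse(abs(delta[zero]) > 0, Inf * sign(delta[zero]), 0)
    df[zero] <- NA_real_
  }
  data.frame(delta = delta, t = tstat, df = df, p_value = p,
             row.names = rownames(m))
}

assert_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop("beta matrix must be a numeric matrix", call. = FALSE)
  }
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("beta matrix must carry probe rownames and sample colnames",
         call. = FALSE)
  }
  invisible(beta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
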