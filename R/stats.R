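# Species-level summaries and the comparative statistics: PGLS under
# Brownian motion, Spearman correlation with exact small-n p-values, and
# Wilcoxon rank tests with exact (tie-aware) null distributions.

#' Per-species NUMT summary
#'
#' @param numts Labelled NUMT records ([label_types()]).
#' @param clusters Complex clusters ([cluster_complex()]), may be empty.
#' @param families `families` from [detect_duplicates()], may be empty.
#' @param genome_size Assembly size in bp (> 0).
#' @param species Optional species label.
#' @return One-row data frame: `species, n_numts, total_len, pct_genome,
#'   genome_size, n_insertion, n_duplicate, n_complex_clusters, mean_len`.
#'   `pct_genome` is `100 * total_len / genome_size`;
#'   `n_insertion + n_duplicate = n_numts` always holds.
#' @export
summarize_species <- function(numts, clusters = NULL, families = NULL,
                              genome_size, species = NA_character_) {
  if (genome_size <= 0) stop("genome_size must be positive")
  n <- nrow(numts)
  lens <- if (n) numts$end - numts$start else integer(0)
  data.frame(
    species = species, n_numts = n, total_len = sum(lens),
    pct_genome = 100 * sum(lens) / genome_size, genome_size = genome_size,
    n_insertion = sum(numts$type == "insertion"),
    n_duplicate = sum(numts$type == "duplicate"),
    n_complex_clusters = if (!is.null(clusters) && nrow(clusters))
      length(unique(clusters$cluster_id)) else 0L,
    mean_len = if (n) mean(lens) else 0,
    stringsAsFactors = FALSE)
}

#' Read a species trait table (TSV)
#'
#' Expects at least a `species` column; remaining columns are numeric
#' traits (e.g. `genome_size, n_numts, total_len, pct`).
#'
#' @param path TSV file.
#' @return Data frame with one row per species.
#' @export
read_traits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(df)) stop("trait table needs a 'species' column")
  df
}

# ---- PGLS -------------------------------------------------------------------

#' Phylogenetic generalized least squares under Brownian motion
#'
#' Fits `y ~ x` by GLS with error covariance proportional to the Brownian
#' covariance of the tree, `C[i, j]` = shared root-to-MRCA branch length of
#' tips i and j (Pagel's lambda fixed at 1). The estimate is
#' `beta = (X' C^-1 X)^-1 X' C^-1 y`, computed via the Cholesky factor of
#' `C`. `R2` is computed on the whitened scale as `1 - RSS/TSS`, with TSS
#' taken about the GLS mean; the slope p-value is a t-test with `n - 2`
#' degrees of freedom.
#'
#' @param y,x Numeric vectors named by tree tips (or in `tip.label` order).
#' @param tree Rooted `phylo` object with branch lengths.
#' @return A `pgls_fit` list: `beta` (intercept, slope), `se`, `sigma2`
#'   (BM rate, RSS/df), `R2`, `t_stat`, `p_value`, `df`, `C`, `residuals`
#'   (whitened).
#' @export
pgls_fit <- function(y, x, tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  tips <- tree$tip.label
  n <- length(tips)
  if (n < 3L) stop("PGLS needs at least 3 tips")
  align <- function(v, nm) {
    if (!is.null(names(v))) {
      if (!all(tips %in% names(v))) stop(nm, " is missing values for some tips")
      v[tips]
    } else {
      if (length(v) != n) stop(nm, " must have one value per tip")
      stats::setNames(v, tips)
    }
  }
  y <- align(y, "y"); x <- align(x, "x")
  if (anyNA(y) || anyNA(x)) stop("PGLS requires complete cases")
  C <- ape::vcv(tree)[tips, tips]
  R <- tryCatch(chol(C), error = function(e)
    stop("Brownian covariance is singular (zero-length branches?)"))
  X <- cbind(`(Intercept)` = 1, slope = x)
  yw <- backsolve(R, y, transpose = TRUE)
  Xw <- backsolve(R, X, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  fit0 <- stats::lm.fit(backsolve(R, matrix(1, n, 1), transpose = TRUE), yw)
  tss <- sum(fit0$residuals^2)
  df <- n - 2L
  sigma2 <- rss / df
  xtx_inv <- chol2inv(chol(crossprod(Xw)))
  se <- sqrt(sigma2 * diag(xtx_inv))
  t_stat <- unname(beta[2] / se[2])
  structure(list(beta = beta, se = stats::setNames(se, names(beta)),
                 sigma2 = sigma2,
                 R2 = if (tss > 0) 1 - rss / tss else NA_real_,
                 t_stat = t_stat,
                 p_value = 2 * stats::pt(-abs(t_stat), df),
                 df = df, C = C, residuals = fit$residuals,
                 model = "Brownian motion (lambda = 1)"),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS (", x$model, ")\n", sep = "")
  cat(sprintf("  intercept %.4g, slope %.4g (SE %.3g)\n",
              x$beta[1], x$beta[2], x$se[2]))
  cat(sprintf("  R2 = %.4f, t = %.3f, df = %d, p = %.4g, sigma2 = %.4g\n",
              x$R2, x$t_stat, x$df, x$p_value, x$sigma2))
  invisible(x)
}

# ---- Spearman ---------------------------------------------------------------

#' Spearman rank correlation with exact small-sample p-value
#'
#' `rho` is the Pearson correlation of the (average-tie) ranks. For
#' `n <= exact_max` the two-sided p-value is computed by enumerating all
#' `n!` permutations of one rank vector (conditional on the observed tie
#' pattern); otherwise the usual t approximation with `n - 2` df is used.
#'
#' @param x,y Numeric vectors, `n >= 4`, neither constant.
#' @param exact_max Largest n for exact enumeration (default 9).
#' @return List: `rho`, `p_value`, `n`, `method`.
#' @export
spearman_cor <- function(x, y, exact_max = 9L) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have the same length")
  if (n < 4L) stop("spearman_cor needs n >= 4")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    P <- all_permutations(n)
    ry_perm <- matrix(ry[P], nrow = nrow(P))
    num <- ry_perm %*% (rx - mean(rx))
    den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    rho_perm <- as.vector(num) / den
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

#' All permutations of 1..n as an n! x n matrix
#' @noRd
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    m <- sub
    m[m >= i] <- m[m >= i] + 1L
    cbind(rep(i, nrow(m)), m)
  }))
}

# ---- rank tests -------------------------------------------------------------

#' Wilcoxon rank tests with exact tie-aware null distributions
#'
#' Signed-rank test for paired differences (`paired = TRUE`, with `x` the
#' differences or `x`/`y` the paired samples) or rank-sum
#' (Mann-Whitney) test for two independent samples. For small samples the
#' exact conditional null distribution is enumerated by dynamic
#' programming over the observed (possibly tied, average) ranks; larger
#' samples use the normal approximation with tie correction and
#' continuity correction. Zero differences are dropped (signed-rank); if
#' all differences are zero the result is degenerate with `p = 1`.
#'
#' @param x Numeric vector: paired differences, or first sample.
#' @param y Optional second sample.
#' @param paired Signed-rank if `TRUE` (default when `y` is `NULL`).
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @param exact_max Use the exact distribution when the number of non-zero
#'   differences (signed-rank) or the total sample size (rank-sum) is at
#'   most this (defaults 25 and 30).
#' @return A `rank_test_result` list: `statistic` (V or W, the rank sum of
#'   the first sample), `p_value`, `n`, `test_name`, `alternative`,
#'   `method`, `degenerate`.
#' @export
rank_test <- function(x, y = NULL, paired = is.null(y),
                      alternative = c("two.sided", "greater", "less"),
                      exact_max = NULL) {
  alternative <- match.arg(alternative)
  if (paired) {
    d <- if (is.null(y)) x else x - y
    if (length(d) == 0L) stop("empty input")
    rank_test_signed(d, alternative,
                     if (is.null(exact_max)) 25L else exact_max)
  } else {
    if (is.null(y) || length(x) == 0L || length(y) == 0L)
      stop("rank-sum test needs two non-empty samples")
    rank_test_ranksum(x, y, alternative,
                      if (is.null(exact_max)) 30L else exact_max)
  }
}

#' @noRd
rank_test_signed <- function(d, alternative, exact_max) {
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  m <- length(nz)
  if (m == 0L) {
    return(structure(list(statistic = 0, p_value = 1,
                          n = c(n = length(d), nonzero = 0L),
                          test_name = "signed-rank",
                          alternative = alternative, method = "degenerate",
                          degenerate = TRUE), class = "rank_test_result"))
  }
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  if (m <= exact_max) {
    s2 <- as.integer(round(2 * r))
    f <- signed_rank_null(s2)          # P(2V = s), s = 0..sum(s2)
    v2 <- as.integer(round(2 * v))
    s <- seq_along(f) - 1L
    p_ge <- sum(f[s >= v2])
    p_le <- sum(f[s <= v2])
    p <- switch(alternative, greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sd <- sqrt(sum(r^2) / 4)
    p <- normal_tail((v - mu) / sd, correct = 0.5 / sd, alternative)
    method <- "normal-approx"
  }
  structure(list(statistic = v, p_value = p,
                 n = c(n = length(d), nonzero = m),
                 test_name = "signed-rank", alternative = alternative,
                 method = method, degenerate = FALSE),
            class = "rank_test_result")
}

#' Exact null of 2V for the signed-rank test: each doubled rank is included
#' independently with probability 1/2. Returns the pmf over 0..sum(s2).
#' @noRd
signed_rank_null <- function(s2) {
  f <- numeric(sum(s2) + 1L)
  f[1] <- 1
  for (s in s2) {
    g <- f / 2
    g[(s + 1L):length(f)] <- g[(s + 1L):length(f)] + f[1:(length(f) - s)] / 2
    f <- g
  }
  f
}

#' @noRd
rank_test_ranksum <- function(x, y, alternative, exact_max) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (N <= exact_max) {
    s2 <- as.integer(round(2 * r))
    f <- ranksum_null(s2, n1)          # P(2W = s) over k = n1 subsets
    w2 <- as.integer(round(2 * w))
    s <- seq_along(f) - 1L
    p_ge <- sum(f[s >= w2])
    p_le <- sum(f[s <= w2])
    p <- switch(alternative, greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact"
  } else {
    mu <- n1 * (N + 1) / 2
    sd <- sqrt(n1 * n2 / (N * (N - 1)) * sum((r - (N + 1) / 2)^2))
    p <- normal_tail((w - mu) / sd, correct = 0.5 / sd, alternative)
    method <- "normal-approx"
  }
  structure(list(statistic = w, p_value = p, n = c(n1 = n1, n2 = n2),
                 test_name = "rank-sum", alternative = alternative,
                 method = method, degenerate = FALSE),
            class = "rank_test_result")
}

#' Exact null of 2W: counts of k-subsets of the doubled ranks by sum,
#' normalised by choose(N, k). Dynamic programme over items.
#' @noRd
ranksum_null <- function(s2, k) {
  S <- sum(s2)
  cnt <- matrix(0, nrow = k + 1L, ncol = S + 1L)
  cnt[1L, 1L] <- 1
  for (s in s2) {
    for (kk in k:1) {
      nonzero <- which(cnt[kk, ] > 0)
      if (length(nonzero))
        cnt[kk + 1L, nonzero + s] <- cnt[kk + 1L, nonzero + s] + cnt[kk, nonzero]
    }
  }
  cnt[k + 1L, ] / choose(length(s2), k)
}

#' @noRd
normal_tail <- function(z, correct, alternative) {
  switch(alternative,
         greater = stats::pnorm(z - correct, lower.tail = FALSE),
         less = stats::pnorm(z + correct),
         two.sided = min(1, 2 * min(stats::pnorm(z + correct),
                                    stats::pnorm(z - correct,
                                                 lower.tail = FALSE))))
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat("Wilcoxon ", x$test_name, " test (", x$method, ", ",
      x$alternative, ")\n", sep = "")
  cat("  statistic =", x$statistic, " p =", format(x$p_value, digits = 4),
      " n =", paste(x$n, collapse = "/"), "\n")
  if (isTRUE(x$degenerate)) cat("  degenerate: all differences zero\n")
  invisible(x)
}

# ---- binned tables ----------------------------------------------------------

#' Binned length and identity tables for NUMT sets
#'
#' Length bins report counts and proportions of NUMTs; identity bins
#' report the mean NUMT length per bin (the classic display that longer
#' NUMTs are more similar to their mitochondrial source). Bins are
#' left-closed right-open with the last bin closed, so a value equal to an
#' interior edge falls in the bin that starts there.
#'
#' @param numts NUMT records with `length` (or `start`/`end`) and
#'   `identity` columns.
#' @param length_edges,identity_edges Strictly increasing bin edges
#'   covering the observed range.
#' @return List of data frames `length_bins` (`lo, hi, count, prop`) and
#'   `identity_bins` (`lo, hi, n, mean_length`).
#' @export
bin_length_similarity <- function(numts,
                                  length_edges = c(0, 500, 1000, 2000, 5000, Inf),
                                  identity_edges = seq(0.70, 1.00, by = 0.05)) {
  if (is.unsorted(length_edges, strictly = TRUE) ||
      is.unsorted(identity_edges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  len <- if ("length" %in% names(numts)) numts$length
  else numts$end - numts$start
  idt <- numts$identity
  bin_of <- function(v, edges) {
    if (length(v) && (any(v < edges[1]) || any(v > edges[length(edges)])))
      stop("values outside the bin range")
    findInterval(v, edges, rightmost.closed = TRUE)
  }
  lb <- bin_of(len, length_edges)
  nb <- length(length_edges) - 1L
  counts <- tabulate(lb, nbins = nb)
  length_bins <- data.frame(lo = length_edges[-length(length_edges)],
                            hi = length_edges[-1], count = counts,
                            prop = if (length(len)) counts / length(len)
                            else rep(NA_real_, nb))
  ib <- bin_of(idt, identity_edges)
  ni <- length(identity_edges) - 1L
  identity_bins <- data.frame(
    lo = identity_edges[-length(identity_edges)], hi = identity_edges[-1],
    n = tabulate(ib, nbins = ni),
    mean_length = vapply(seq_len(ni), function(k) {
      v <- len[ib == k]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)))
  list(length_bins = length_bins, identity_bins = identity_bins)
}
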