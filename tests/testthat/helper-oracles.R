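# Shared fixture builders and independent oracles. Oracles deliberately use
# different machinery from the implementation: Biostrings dynamic
# programming for alignment scores, brute-force enumeration for rank tests
# and Spearman, explicit shared-path covariance for PGLS.

rand_seq <- function(n, at = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}

rc_oracle <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

mutate_oracle <- function(s, d) {
  x <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(x)) < d)
  for (i in hit) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
  paste(x, collapse = "")
}

# Smith-Waterman optimum via Biostrings under the package scoring scheme
sw_oracle <- function(a, b, match = 1, mismatch = -2,
                      gap_open = 5, gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match, mismatch,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  Biostrings::score(pa)
}

# extract the nuclear and mitochondrial subsequences of a hit, oriented so
# that both are on the same strand
hit_seqs <- function(hit, mito, nuclear) {
  nseq <- substr(nuclear[[hit$scaffold]], hit$nuc_start + 1, hit$nuc_end)
  m <- nchar(mito)
  q <- if (hit$strand == "+") mito else rc_oracle(mito)
  qs <- if (hit$strand == "+") hit$mito_start else m - hit$mito_end
  qe <- if (hit$strand == "+") hit$mito_end else m - hit$mito_start
  list(nuc = nseq, mito = substr(q, qs + 1, qe))
}

# brute-force signed-rank p: enumerate all 2^m sign assignments
brute_signed_rank <- function(d, alternative) {
  nz <- d[d != 0]
  m <- length(nz)
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  vs <- as.vector(signs %*% r)
  p_ge <- mean(vs >= v - 1e-9)
  p_le <- mean(vs <= v + 1e-9)
  switch(alternative, greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# brute-force rank-sum p: enumerate all n1-subsets of pooled ranks
brute_ranksum <- function(x, y, alternative) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  cmb <- utils::combn(length(r), n1)
  ws <- apply(cmb, 2, function(ii) sum(r[ii]))
  p_ge <- mean(ws >= w - 1e-9)
  p_le <- mean(ws <= w + 1e-9)
  switch(alternative, greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# brute-force two-sided Spearman p over all permutations, plain loop + cor()
perms_oracle <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v)) {
    sub <- perms_oracle(v[-i])
    out <- rbind(out, cbind(v[i], sub))
  }
  out
}

brute_spearman <- function(x, y) {
  rho <- stats::cor(rank(x), rank(y))
  P <- perms_oracle(seq_along(y))
  ry <- rank(y)
  rhos <- apply(P, 1, function(p) stats::cor(rank(x), ry[p]))
  mean(abs(rhos) >= abs(rho) - 1e-12)
}

# PGLS oracle: covariance by explicit shared-path enumeration from node
# distances, estimate by direct matrix inversion
pgls_oracle_beta <- function(y, x, tree) {
  n <- length(tree$tip.label)
  D <- ape::dist.nodes(tree)
  root <- n + 1L
  C <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    C[i, j] <- (D[root, i] + D[root, j] - D[i, j]) / 2
  }
  X <- cbind(1, x[tree$tip.label])
  Ci <- solve(C)
  as.vector(solve(t(X) %*% Ci %*% X) %*% t(X) %*% Ci %*% y[tree$tip.label])
}

# reciprocal-overlap recovery of truth NUMTs among filtered hits
recovery_rate <- function(truth, hits, min_ro = 0.8) {
  if (nrow(truth) == 0L) return(NA_real_)
  rec <- vapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    h <- hits[hits$scaffold == tr$scaffold & hits$strand == tr$strand &
                hits$nuc_start < tr$end & hits$nuc_end > tr$start, ,
              drop = FALSE]
    if (!nrow(h)) return(FALSE)
    ov <- pmin(h$nuc_end, tr$end) - pmax(h$nuc_start, tr$start)
    any(ov / (tr$end - tr$start) >= min_ro &
          ov / (h$nuc_end - h$nuc_start) >= min_ro)
  }, logical(1))
  mean(rec)
}

# map each truth row to the detected record overlapping it (by >= 50% of
# the truth interval), NA if none
truth_to_record <- function(truth, recs) {
  vapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    h <- recs[recs$scaffold == tr$scaffold & recs$start < tr$end &
                recs$end > tr$start, , drop = FALSE]
    if (!nrow(h)) return(NA_character_)
    ov <- pmin(h$end, tr$end) - pmax(h$start, tr$start)
    best <- which.max(ov)
    if (ov[best] >= 0.5 * (tr$end - tr$start)) h$numt_id[best]
    else NA_character_
  }, character(1))
}
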