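# Internal sequence helpers. Sequences are plain uppercase character scalars
# over {A,C,G,T,N}; genomes are named character vectors. Coordinates are
# 0-based half-open everywhere inside the package; writers convert to the
# 1-based inclusive conventions of GFF3 / RepeatMasker / BLAST on output.

BASES <- c("A", "C", "G", "T")

#' @noRd
random_seq <- function(n, at) {
  if (n == 0L) return("")
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' @noRd
revcomp <- function(s) {
  if (nchar(s) == 0L) return(s)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Substitution-only mutation at per-site rate d (always to a different base)
#' @noRd
mutate_seq <- function(s, d) {
  if (d <= 0 || nchar(s) == 0L) return(s)
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(x)) < d)
  if (length(hit)) {
    x[hit] <- vapply(x[hit], function(b) sample(setdiff(BASES, b), 1L), character(1))
  }
  paste(x, collapse = "")
}

#' @noRd
at_fraction <- function(s) {
  if (nchar(s) == 0L) return(NA_real_)
  r <- charToRaw(s)
  mean(r == charToRaw("A") | r == charToRaw("T"))
}

#' Per-position AT indicator of a sequence, as integer 0/1
#' @noRd
at_indicator <- function(s) {
  r <- charToRaw(s)
  as.integer(r == charToRaw("A") | r == charToRaw("T"))
}

#' Mean AT of sliding windows of `width` (step 1): value i covers [i, i+width)
#' 0-based; returns vector of length nchar(s) - width + 1.
#' @noRd
at_windows <- function(s, width) {
  n <- nchar(s)
  if (n < width) return(numeric(0))
  cs <- c(0L, cumsum(at_indicator(s)))
  (cs[(width + 1L):(n + 1L)] - cs[1:(n - width + 1L)]) / width
}

#' @noRd
subseq_chr <- function(s, start, end) {
  # 0-based half-open
  if (end <= start) return("")
  substr(s, start + 1L, end)
}

#' Realized per-site mismatch fraction between equal-length sequences
#' @noRd
mismatch_fraction <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(NA_real_)
  mean(charToRaw(a) != charToRaw(b))
}

#' Build an insertion map for one scaffold.
#'
#' `points`/`lens`: background insertion points (sequence inserted *before*
#' original base `point`) and insert lengths, in background coordinates.
#' Returns shift functions for feature coordinates and the final chunk starts.
#' @noRd
insertion_map <- function(points, lens) {
  points <- as.integer(points)
  lens <- as.integer(lens)
  o <- order(points)
  points <- points[o]
  lens <- lens[o]
  cum <- cumsum(lens)
  shift_le <- function(x) {
    # total inserted length at points <= x (shifts a start coordinate x)
    i <- findInterval(x, points)
    ifelse(i == 0L, 0L, cum[pmax(i, 1L)])
  }
  shift_lt <- function(x) {
    # total inserted length at points < x (shifts a half-open end coordinate)
    i <- findInterval(x - 1L, points)
    ifelse(i == 0L, 0L, cum[pmax(i, 1L)])
  }
  chunk_start <- points + c(0L, cum[-length(cum)])
  list(order = o, points = points, lens = lens,
       map_start = function(x) x + shift_le(x),
       map_end = function(x) x + shift_lt(x),
       chunk_start = chunk_start)
}

#' Apply point insertions to one sequence; chunks in the order of `map$order`.
#' @noRd
apply_insertions_seq <- function(s, map, chunk_seqs) {
  if (length(map$points) == 0L) return(s)
  segs <- character(2L * length(map$points) + 1L)
  prev <- 0L
  for (i in seq_along(map$points)) {
    segs[2L * i - 1L] <- subseq_chr(s, prev, map$points[i])
    segs[2L * i] <- chunk_seqs[map$order][i]
    prev <- map$points[i]
  }
  segs[length(segs)] <- subseq_chr(s, prev, nchar(s))
  paste(segs, collapse = "")
}

#' Run RNG code under a fixed seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @noRd
empty_truth <- function() {
  data.frame(numt_id = character(0), scaffold = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             mito_start = integer(0), mito_end = integer(0),
             type = character(0), family_id = character(0),
             cluster_id = character(0), divergence = numeric(0),
             stringsAsFactors = FALSE)
}

#' @noRd
empty_te_annotation <- function() {
  data.frame(scaffold = character(0), start = integer(0), end = integer(0),
             te_name = character(0), superfamily = character(0),
             divergence = numeric(0), strand = character(0),
             stringsAsFactors = FALSE)
}

#' @noRd
empty_gene_models <- function() {
  g <- data.frame(gene_id = character(0), scaffold = character(0),
                  start = integer(0), end = integer(0), strand = character(0),
                  stringsAsFactors = FALSE)
  e <- data.frame(gene_id = character(0), scaffold = character(0),
                  start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  structure(list(genes = g, exons = e, cds = e), class = "gene_models")
}
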