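#' Parameters for the seed-and-extend NUMT search
#'
#' Scoring follows the megablast-style defaults (+1 match, -2 mismatch,
#' gap of length L costs `|gap_open| + L * |gap_extend|`). Statistical
#' significance uses the Karlin-Altschul formula `E = K * m * n * exp(-lambda * S)`
#' with the raw search-space product `m * n` (no edge correction), so
#' E-values close to a threshold may differ slightly from NCBI blastn's.
#'
#' @param word_size Exact-match seed length k (>= 4, default 11).
#' @param match,mismatch Match and mismatch scores (default +1 / -2).
#' @param gap_open,gap_extend Gap opening and per-residue extension scores
#'   (negative; default -5 / -2).
#' @param lambda,kappa Karlin-Altschul parameters (default 1.28 / 0.46,
#'   the ungapped values for +1/-2 scoring).
#' @param xdrop Ungapped extension x-drop (default 20).
#' @param evalue_max Keep hits with E strictly below this (default 1e-4).
#' @param min_len Minimum nuclear hit length in bp (default 50).
#' @param search_m,search_n Search-space sizes: query (mitochondrial) length
#'   and total nuclear length. `NA` (default) takes them from the scanned
#'   sequences.
#' @param max_window Cap on the gapped-alignment window per hit (bp).
#' @return A `search_params` list.
#' @export
search_params <- function(word_size = 11L, match = 1L, mismatch = -2L,
                          gap_open = -5L, gap_extend = -2L,
                          lambda = 1.28, kappa = 0.46, xdrop = 20L,
                          evalue_max = 1e-4, min_len = 50L,
                          search_m = NA_real_, search_n = NA_real_,
                          max_window = 16000L) {
  p <- list(word_size = as.integer(word_size), match = as.integer(match),
            mismatch = as.integer(mismatch), gap_open = as.integer(gap_open),
            gap_extend = as.integer(gap_extend), lambda = lambda,
            kappa = kappa, xdrop = as.integer(xdrop),
            evalue_max = evalue_max, min_len = as.integer(min_len),
            search_m = search_m, search_n = search_n,
            max_window = as.integer(max_window))
  if (p$word_size < 4L) stop("word_size must be >= 4")
  if (!(p$match > 0L && p$mismatch < 0L)) stop("need match > 0 > mismatch")
  if (p$lambda <= 0 || p$kappa <= 0) stop("lambda and kappa must be positive")
  if (p$evalue_max <= 0) stop("evalue_max must be positive")
  if (p$min_len < 1L) stop("min_len must be >= 1")
  class(p) <- "search_params"
  p
}

#' Karlin-Altschul expected number of chance alignments
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected count of local
#' alignments scoring at least `S` between random sequences of lengths
#' `m` (query) and `n` (database). Strictly decreasing in `S`.
#'
#' @param score Raw alignment score(s), >= 0.
#' @param params A [search_params()] with `search_m` and `search_n` set.
#' @return Numeric E-value(s).
#' @export
evalue <- function(score, params = search_params()) {
  if (any(score < 0)) stop("score must be >= 0")
  if (is.na(params$search_m) || is.na(params$search_n))
    stop("search_m and search_n must be set to compute E-values")
  params$kappa * params$search_m * params$search_n *
    exp(-params$lambda * score)
}

#' @noRd
bitscore <- function(score, params) {
  (params$lambda * score - log(params$kappa)) / log(2)
}

#' Scan nuclear scaffolds for mitochondrial homology (NUMT candidates)
#'
#' Seed-and-extend local alignment of the mitochondrial genome against each
#' nuclear scaffold, both strands: exact `word_size`-mer seeds, ungapped
#' x-drop extension, then optimal gapped (Smith-Waterman) alignment of the
#' extended region, so each hit's raw score is the local-alignment optimum
#' for its region. Hits with identical coordinates are reported once;
#' same-strand hits overlapping by more than half on the nuclear axis that
#' match the same mitochondrial region are collapsed to the best-scoring one.
#' Alignments scoring below the `evalue_max` significance floor (which
#' [filter_hits()] would discard anyway) are not enumerated.
#'
#' The mitochondrial sequence is treated as linear; hits touching either
#' mitochondrial terminus are flagged (`mito_terminal`) since a circular
#' origin-spanning NUMT would be split there.
#'
#' @param mito Mitochondrial sequence (character scalar or `DNAString`).
#' @param nuclear Named character vector / `DNAStringSet` of scaffolds.
#' @param params [search_params()].
#' @return Data frame of hits, one row per alignment:
#'   `scaffold, nuc_start, nuc_end, strand, mito_start, mito_end, score,
#'   bitscore, evalue, identity, aln_len, mito_terminal`, 0-based half-open,
#'   ordered by (scaffold, nuc_start). `strand` is the nuclear strand
#'   relative to the mitochondrial forward strand; `mito_start/mito_end`
#'   are always on the forward strand.
#' @export
scan_numts <- function(mito, nuclear, params = search_params()) {
  mito <- toupper(as.character(mito))
  if (is(nuclear, "DNAStringSet") || is(nuclear, "XStringSet"))
    nuclear <- as.character(nuclear)
  nuclear <- toupper(nuclear)
  if (length(mito) != 1L || nchar(mito) == 0L) stop("empty mitochondrial input")
  if (length(nuclear) == 0L || any(nchar(nuclear) == 0L))
    stop("empty nuclear input")
  if (is.null(names(nuclear)))
    names(nuclear) <- paste0("scaffold_", seq_along(nuclear))
  if (params$word_size > nchar(mito))
    stop("word_size exceeds the mitochondrial sequence length")
  m <- nchar(mito)
  if (is.na(params$search_m)) params$search_m <- m
  if (is.na(params$search_n)) params$search_n <- sum(as.numeric(nchar(nuclear)))

  # enumeration floor: alignments scoring below the evalue_max threshold
  # would be discarded by filter_hits() in any case, so they are not
  # enumerated (keeps the scan linear on AT-biased genomes)
  s_floor <- ceiling((log(params$kappa * params$search_m * params$search_n) -
                        log(params$evalue_max)) / params$lambda)
  min_score <- max(params$word_size * params$match, s_floor)

  mito_rc <- revcomp(mito)
  res <- list()
  for (scf in names(nuclear)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") mito else mito_rc
      df <- .scan_pair_cpp(nuclear[[scf]], q, params$word_size, params$match,
                           params$mismatch, abs(params$gap_open),
                           abs(params$gap_extend), params$xdrop, 50L,
                           as.integer(min_score), params$max_window)
      if (nrow(df) == 0L) next
      if (strand == "+") {
        ms <- df$qstart; me <- df$qend
      } else {
        ms <- m - df$qend; me <- m - df$qstart
      }
      res[[length(res) + 1L]] <- data.frame(
        scaffold = scf, nuc_start = df$sstart, nuc_end = df$send,
        strand = strand, mito_start = ms, mito_end = me,
        score = df$score, matches = df$matches, aln_len = df$alnlen,
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) return(empty_hits(params))
  hits <- do.call(rbind, res)
  hits$identity <- hits$matches / hits$aln_len
  hits$bitscore <- bitscore(hits$score, params)
  hits$evalue <- evalue(hits$score, params)
  hits <- suppress_redundant(hits)
  hits$mito_terminal <- hits$mito_start == 0L | hits$mito_end == m
  hits <- hits[order(hits$scaffold, hits$nuc_start, hits$nuc_end, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("scaffold", "nuc_start", "nuc_end", "strand", "mito_start",
           "mito_end", "score", "bitscore", "evalue", "identity", "aln_len",
           "mito_terminal")]
}

#' @noRd
empty_hits <- function(params = NULL) {
  data.frame(scaffold = character(0), nuc_start = integer(0),
             nuc_end = integer(0), strand = character(0),
             mito_start = integer(0), mito_end = integer(0),
             score = integer(0), bitscore = numeric(0), evalue = numeric(0),
             identity = numeric(0), aln_len = integer(0),
             mito_terminal = logical(0), stringsAsFactors = FALSE)
}

#' Collapse same-strand hits overlapping >50% on the nuclear axis that match
#' the same mitochondrial region, keeping the best score. Exact duplicates
#' are removed first. Non-overlapping hits are never merged.
#' @noRd
suppress_redundant <- function(hits) {
  hits <- hits[!duplicated(hits[, c("scaffold", "nuc_start", "nuc_end",
                                    "strand", "mito_start", "mito_end")]), ,
               drop = FALSE]
  o <- order(-hits$score, hits$scaffold, hits$nuc_start)
  hits <- hits[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  by_scf <- split(seq_len(nrow(hits)), paste(hits$scaffold, hits$strand))
  for (idx in by_scf) {
    kept <- integer(0)
    for (i in idx) {
      drop_i <- FALSE
      for (j in kept) {
        ov <- min(hits$nuc_end[i], hits$nuc_end[j]) -
          max(hits$nuc_start[i], hits$nuc_start[j])
        if (ov <= 0) next
        shorter <- min(hits$nuc_end[i] - hits$nuc_start[i],
                       hits$nuc_end[j] - hits$nuc_start[j])
        mov <- min(hits$mito_end[i], hits$mito_end[j]) -
          max(hits$mito_start[i], hits$mito_start[j])
        if (ov > 0.5 * shorter && mov > 0) { drop_i <- TRUE; break }
      }
      if (drop_i) keep[i] <- FALSE else kept <- c(kept, i)
    }
  }
  hits[keep, , drop = FALSE]
}

#' Apply the NUMT acceptance filters to alignment hits
#'
#' Keeps hits with `evalue < evalue_max` and nuclear segment length
#' `>= min_len` (defaults: E < 1e-4, length >= 50 bp), in stable
#' (scaffold, start) order.
#'
#' @param hits Data frame from [scan_numts()] or [read_blast_tab()].
#' @param params [search_params()].
#' @return Filtered hits data frame.
#' @export
filter_hits <- function(hits, params = search_params()) {
  if (nrow(hits) == 0L) return(hits)
  keep <- hits$evalue < params$evalue_max &
    (hits$nuc_end - hits$nuc_start) >= params$min_len
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$scaffold, out$nuc_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read BLAST tabular (outfmt 6) hits
#'
#' Expects the default 12 columns (`qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`) with the mitochondrial
#' genome as query and nuclear scaffolds as subject. 1-based inclusive
#' coordinates become 0-based half-open; a subject start greater than its
#' end encodes a minus-strand hit; percent identity becomes a fraction.
#'
#' @param path Tabular BLAST output file.
#' @return Hits data frame in the same layout as [scan_numts()] (without
#'   raw scores: `score` is `NA`).
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_hits())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L)
      stop("malformed BLAST tabular line ", i, ": expected 12 columns")
    num <- suppressWarnings(as.numeric(f[c(3, 4, 7, 8, 9, 10, 11, 12)]))
    if (anyNA(num))
      stop("malformed BLAST tabular line ", i, ": non-numeric field")
    qs <- as.integer(num[3]); qe <- as.integer(num[4])
    ss <- as.integer(num[5]); se <- as.integer(num[6])
    strand <- if (ss <= se) "+" else "-"
    data.frame(scaffold = f[2],
               nuc_start = min(ss, se) - 1L, nuc_end = max(ss, se),
               strand = strand, mito_start = qs - 1L, mito_end = qe,
               score = NA_integer_, bitscore = num[8], evalue = num[7],
               identity = num[1] / 100, aln_len = as.integer(num[2]),
               mito_terminal = NA, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$scaffold, out$nuc_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write hits as BED6 plus a companion TSV
#'
#' The BED file carries `scaffold start end numt_id bitscore strand`; the
#' TSV adds mitochondrial coordinates (1-based inclusive), identity and
#' E-value.
#'
#' @param hits Hits data frame (after [filter_hits()]).
#' @param bed_path,tsv_path Output files (`NULL` skips one of them).
#' @export
write_hits <- function(hits, bed_path = NULL, tsv_path = NULL) {
  ids <- sprintf("numt_%04d", seq_len(nrow(hits)))
  if (!is.null(bed_path)) {
    bed <- data.frame(hits$scaffold, hits$nuc_start, hits$nuc_end, ids,
                      round(hits$bitscore, 1), hits$strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    tsv <- data.frame(numt_id = ids, scaffold = hits$scaffold,
                      start = hits$nuc_start + 1L, end = hits$nuc_end,
                      strand = hits$strand, mito_start = hits$mito_start + 1L,
                      mito_end = hits$mito_end,
                      identity = round(hits$identity, 4),
                      evalue = hits$evalue, bitscore = round(hits$bitscore, 1))
    utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(ids)
}

#' Optimal local (Smith-Waterman) alignment of two sequences
#'
#' Gotoh affine-gap local alignment under the package scoring scheme;
#' used internally for NUMT-vs-NUMT and flank-vs-flank comparisons.
#'
#' @param a,b Sequences (character scalars).
#' @param params [search_params()] supplying the scoring scheme.
#' @return List: `score`, `a_start`, `a_end`, `b_start`, `b_end` (0-based
#'   half-open), `matches`, `alnlen`, `identity`.
#' @export
sw_align <- function(a, b, params = search_params()) {
  r <- .sw_align_cpp(toupper(a), toupper(b), params$match, params$mismatch,
                     abs(params$gap_open), abs(params$gap_extend))
  r$identity <- if (r$alnlen > 0) r$matches / r$alnlen else NA_real_
  r
}
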