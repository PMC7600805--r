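# Genomic context of NUMTs: AT profiles of flanks, intergenic/intronic/CDS
# assignment, NUMT/TE density tracks and TE vicinity. Overlap arithmetic
# goes through IRanges/GenomicRanges.

#' @noRd
granges_of <- function(df, start_col = "start", end_col = "end") {
  GenomicRanges::GRanges(df$scaffold,
                         IRanges::IRanges(df[[start_col]] + 1L, df[[end_col]]))
}

#' Mean AT content around NUMT boundaries (5 bp sliding windows)
#'
#' For each NUMT, four regions are profiled: the upstream flank
#' (`flank` bp), the first `end_len` bp inside the NUMT, the last `end_len`
#' bp inside, and the downstream flank. Each region is tiled with sliding
#' windows of `window` bp at step 1 and the per-window AT fraction is
#' averaged over NUMTs. Offsets are relative to the NUMT boundary:
#' upstream windows end at offset -1, downstream windows start at +1 (the
#' reported `offset` is the window start; interior offsets are relative to
#' the respective NUMT end). Flanks truncated by a scaffold edge contribute
#' only their defined windows; NUMTs shorter than `2 * end_len` contribute
#' a truncated interior. Results are invariant to NUMT input order.
#'
#' @param numts Data frame with `scaffold, start, end` (0-based half-open).
#' @param genome Named character vector of scaffolds.
#' @param flank Flank length profiled on each side (default 250).
#' @param end_len Interior length profiled at each NUMT end (default 50).
#' @param window Sliding window width (default 5).
#' @return Data frame `region, offset, mean_at, n` with
#'   `region` in `upstream, numt_start, numt_end, downstream`; attribute
#'   `n_numts` carries the number of NUMTs profiled.
#' @export
at_profile <- function(numts, genome, flank = 250L, end_len = 50L, window = 5L) {
  if (nrow(numts) == 0L) stop("at_profile needs at least one NUMT")
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  acc <- list()
  add <- function(region, offs, vals) {
    acc[[length(acc) + 1L]] <<- data.frame(region = region, offset = offs,
                                           at = vals, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(numts))) {
    s <- genome[[numts$scaffold[i]]]
    L <- nchar(s)
    st <- numts$start[i]; en <- numts$end[i]
    # upstream flank [st - flank, st): window at offset -flank .. -window
    u0 <- max(0L, st - flank)
    if (st - u0 >= window) {
      v <- at_windows(subseq_chr(s, u0, st), window)
      add("upstream", seq.int(u0 - st, by = 1L, length.out = length(v)), v)
    }
    ilen <- min(en - st, end_len)
    if (ilen >= window) {
      v <- at_windows(subseq_chr(s, st, st + ilen), window)
      add("numt_start", seq.int(0L, by = 1L, length.out = length(v)), v)
      v <- at_windows(subseq_chr(s, en - ilen, en), window)
      add("numt_end", seq.int(-ilen, by = 1L, length.out = length(v)), v)
    }
    d1 <- min(L, en + flank)
    if (d1 - en >= window) {
      v <- at_windows(subseq_chr(s, en, d1), window)
      add("downstream", seq.int(1L, by = 1L, length.out = length(v)), v)
    }
  }
  all <- do.call(rbind, acc)
  agg <- stats::aggregate(at ~ region + offset, all,
                          FUN = function(x) c(m = mean(x), n = length(x)))
  out <- data.frame(region = agg$region, offset = agg$offset,
                    mean_at = agg$at[, "m"], n = as.integer(agg$at[, "n"]),
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$region, c("upstream", "numt_start", "numt_end",
                                       "downstream")), out$offset), ]
  rownames(out) <- NULL
  attr(out, "n_numts") <- nrow(numts)
  out
}

#' Paired test of AT enrichment in immediate NUMT flanks
#'
#' For each NUMT, the AT content of its two `flank` bp flanks is paired
#' with the mean AT of the host scaffold (computed over the whole
#' scaffold, NUMTs included), and a one-sided (greater) Wilcoxon
#' signed-rank test is run over NUMTs: exact null distribution for up to
#' 25 non-zero differences, normal approximation with continuity and tie
#' correction otherwise. If every difference is zero the test is
#' degenerate and `p = 1` is reported with `degenerate = TRUE`.
#'
#' A flank's AT content is an integer count over `2 * flank` sites, so the
#' scaffold reference is quantized to the same lattice before pairing
#' (differences are computed as `AT count - round(n_sites * scaffold_AT)`).
#' Comparing lattice-valued counts against an off-lattice reference would
#' turn the entire probability mass at the reference cell into signed
#' noise and miscalibrate the signed-rank null; quantizing restores
#' symmetry without changing what is compared.
#'
#' @param numts Data frame with `scaffold, start, end` (>= 6 rows).
#' @param genome Named character vector of scaffolds.
#' @param flank Flank width in bp (default 10).
#' @return A `rank_test_result` (see [rank_test()]) with extra fields
#'   `flank_at` and `scaffold_at`.
#' @export
flank_at_test <- function(numts, genome, flank = 10L) {
  if (nrow(numts) < 6L) stop("flank_at_test needs at least 6 NUMTs")
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  scaffold_at <- vapply(genome, at_fraction, numeric(1))
  counts <- vapply(seq_len(nrow(numts)), function(i) {
    s <- genome[[numts$scaffold[i]]]
    L <- nchar(s)
    up <- subseq_chr(s, max(0L, numts$start[i] - flank), numts$start[i])
    dn <- subseq_chr(s, numts$end[i], min(L, numts$end[i] + flank))
    both <- paste0(up, dn)
    n <- nchar(both)
    c(at = if (n) sum(at_indicator(both)) else NA_integer_, n = n)
  }, c(at = 0, n = 0))
  sc <- scaffold_at[numts$scaffold]
  ok <- !is.na(counts["at", ]) & counts["n", ] > 0
  d <- counts["at", ok] - round(counts["n", ok] * sc[ok])
  res <- rank_test(d, paired = TRUE, alternative = "greater")
  res$flank_at <- unname(counts["at", ] / counts["n", ])
  res$scaffold_at <- unname(sc)
  res
}

#' Assign NUMTs to intergenic, intronic or coding space
#'
#' A NUMT is `coding` if it overlaps any CDS interval by at least 1 bp,
#' otherwise `intronic` if it overlaps any gene interval, otherwise
#' `intergenic` (precedence CDS > intron > intergenic). Overlapping gene
#' models are resolved by longest-gene precedence. `n_genes_hit` counts
#' distinct genes containing at least one intronic NUMT.
#'
#' @param numts Data frame with `scaffold, start, end`.
#' @param genes A [gene_models()] object.
#' @param scaffold_names Optional scaffold universe; NUMT or gene scaffolds
#'   outside it raise an error (guards against mismatched annotation).
#' @return List: `summary` (`n_total, n_intergenic, prop_intergenic,
#'   n_intronic, prop_intronic, n_cds, prop_cds, n_genes_hit`) and `labels`
#'   (per-NUMT data frame with `position` and `gene_id`).
#' @export
classify_position <- function(numts, genes, scaffold_names = NULL) {
  if (!is.null(scaffold_names)) {
    bad <- setdiff(unique(c(numts$scaffold, genes$genes$scaffold)),
                   scaffold_names)
    if (length(bad))
      stop("scaffold(s) absent from the stated universe: ",
           paste(bad, collapse = ", "))
  }
  n <- nrow(numts)
  position <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  if (n > 0L && nrow(genes$genes) > 0L) {
    ngr <- granges_of(numts)
    ggr <- granges_of(genes$genes)
    glen <- genes$genes$end - genes$genes$start
    hit <- GenomicRanges::findOverlaps(ngr, ggr)
    if (length(hit)) {
      qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
      # longest-gene precedence when gene models overlap
      best <- tapply(seq_along(qh), qh, function(ii) sh[ii][which.max(glen[sh[ii]])])
      qi <- as.integer(names(best))
      position[qi] <- "intronic"
      gene_id[qi] <- genes$genes$gene_id[unlist(best)]
    }
    if (nrow(genes$cds) > 0L) {
      cgr <- granges_of(genes$cds)
      in_cds <- unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(ngr, cgr)))
      position[in_cds] <- "coding"
    }
  }
  labels <- data.frame(numt_id = if ("numt_id" %in% names(numts))
    numts$numt_id else sprintf("numt_%04d", seq_len(n)),
    position = position, gene_id = gene_id, stringsAsFactors = FALSE)
  n_int <- sum(position == "intergenic")
  n_intr <- sum(position == "intronic")
  n_cds <- sum(position == "coding")
  summary <- data.frame(
    n_total = n, n_intergenic = n_int,
    prop_intergenic = if (n) n_int / n else NA_real_,
    n_intronic = n_intr, prop_intronic = if (n) n_intr / n else NA_real_,
    n_cds = n_cds, prop_cds = if (n) n_cds / n else NA_real_,
    n_genes_hit = length(unique(stats::na.omit(
      gene_id[position == "intronic"]))))
  list(summary = summary, labels = labels)
}

#' NUMT and TE coverage in windows along NUMT-bearing scaffolds
#'
#' Only scaffolds containing at least one NUMT are tiled, with
#' non-overlapping `window` bp tiles (the last tile is truncated at the
#' scaffold end; `step` can be lowered for overlapping windows). Coverage
#' is covered bp / tile width after flattening overlapping annotations.
#'
#' @param numts,tes Data frames with `scaffold, start, end`.
#' @param scaffold_lengths Named integer vector of scaffold lengths.
#' @param window Tile width in bp (default 50000).
#' @param step Tile step (default `window`, i.e. non-overlapping).
#' @return Data frame `scaffold, win_start, win_end, numt_coverage,
#'   te_coverage`.
#' @export
density_tracks <- function(numts, tes, scaffold_lengths, window = 50000L,
                           step = window) {
  scfs <- intersect(names(scaffold_lengths), unique(numts$scaffold))
  out <- list()
  cov_of <- function(df, scf, ws, we) {
    sub <- df[df$scaffold == scf, , drop = FALSE]
    if (!nrow(sub)) return(numeric(length(ws)))
    ir <- IRanges::reduce(IRanges::IRanges(sub$start + 1L, sub$end))
    vapply(seq_along(ws), function(k) {
      ov <- IRanges::intersect(ir, IRanges::IRanges(ws[k] + 1L, we[k]))
      sum(IRanges::width(ov)) / (we[k] - ws[k])
    }, numeric(1))
  }
  for (scf in scfs) {
    L <- scaffold_lengths[[scf]]
    ws <- seq.int(0L, max(0L, L - 1L), by = step)
    we <- pmin(ws + window, L)
    keep <- we > ws
    ws <- ws[keep]; we <- we[keep]
    out[[length(out) + 1L]] <- data.frame(
      scaffold = scf, win_start = ws, win_end = we,
      numt_coverage = cov_of(numts, scf, ws, we),
      te_coverage = cov_of(tes, scf, ws, we), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(scaffold = character(0), win_start = integer(0),
                      win_end = integer(0), numt_coverage = numeric(0),
                      te_coverage = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Transposable elements in the vicinity of NUMTs
#'
#' For each feature (a NUMT, or a whole complex cluster passed as one unit
#' via [cluster_spans()]), scans the two `window` bp flanks for annotated
#' TEs; with `include_interior = TRUE` (recommended for clusters) TEs
#' inside the feature span are counted as well. A TE overlapping the
#' region by >= 1 bp counts, so a TE whose edge gap is `window` bp or more
#' does not. The nearest TE is the one with minimum edge distance (0 if
#' overlapping); ties go to the larger overlap, then to the first by
#' coordinate.
#'
#' @param features Data frame `scaffold, start, end` (+ optional id column
#'   `numt_id` or `cluster_id`).
#' @param tes TE annotation data frame ([read_repeatmasker_out()]).
#' @param scaffold_lengths Named integer vector (flanks are truncated at
#'   scaffold ends).
#' @param window Flank width in bp (default 5000).
#' @param include_interior Also count TEs inside the feature span.
#' @return List: `per_feature` (`id, has_te, nearest_te, nearest_superfamily,
#'   nearest_distance`), `prop_with_te`, and `superfamily_props` (named
#'   fractions over features with a TE).
#' @export
te_vicinity <- function(features, tes, scaffold_lengths, window = 5000L,
                        include_interior = FALSE) {
  n <- nrow(features)
  id <- if ("numt_id" %in% names(features)) features$numt_id
  else if ("cluster_id" %in% names(features)) features$cluster_id
  else sprintf("feature_%04d", seq_len(n))
  per <- data.frame(id = id, has_te = logical(n),
                    nearest_te = NA_character_,
                    nearest_superfamily = NA_character_,
                    nearest_distance = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    scf <- features$scaffold[i]
    L <- scaffold_lengths[[scf]]
    st <- features$start[i]; en <- features$end[i]
    sub <- tes[tes$scaffold == scf, , drop = FALSE]
    if (!nrow(sub)) next
    reg <- rbind(c(max(0L, st - window), st), c(en, min(L, en + window)))
    if (include_interior) reg <- rbind(reg, c(st, en))
    ov_any <- rep(FALSE, nrow(sub))
    for (r in seq_len(nrow(reg)))
      ov_any <- ov_any | (sub$start < reg[r, 2] & sub$end > reg[r, 1])
    if (!any(ov_any)) next
    sub <- sub[ov_any, , drop = FALSE]
    # edge distance to the feature itself (0 when overlapping it)
    dist <- pmax(0L, pmax(st - sub$end, sub$start - en))
    ovl <- pmax(0L, pmin(sub$end, en) - pmax(sub$start, st))
    o <- order(dist, -ovl, sub$start)
    per$has_te[i] <- TRUE
    per$nearest_te[i] <- sub$te_name[o[1]]
    per$nearest_superfamily[i] <- sub$superfamily[o[1]]
    per$nearest_distance[i] <- dist[o[1]]
  }
  sf <- per$nearest_superfamily[per$has_te]
  props <- if (length(sf)) sort(table(sf) / length(sf), decreasing = TRUE)
  else table(character(0))
  list(per_feature = per,
       prop_with_te = if (n) mean(per$has_te) else NA_real_,
       superfamily_props = props)
}
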