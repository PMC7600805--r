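#' Parameters for NUMT classification
#'
#' Controls the complex-cluster chaining and the duplicate-type detection.
#' The 10 kb gap ceiling for complex clusters is the field's criterion for
#' fragments of one insertion event; the flank-homology settings quantify
#' the rule that nuclear duplication copies a NUMT *together with* its
#' flanking DNA, so duplication-linked NUMTs show flank homology of the
#' same degree of similarity as the NUMTs themselves.
#'
#' @param max_gap Maximum gap (bp) of non-mitochondrial DNA between
#'   consecutive members of a complex cluster (default 10000; membership
#'   requires gap strictly below this).
#' @param flank_len Nuclear flank length (bp) extracted beside each NUMT
#'   for duplicate detection (default 1000).
#' @param min_flank_homology Minimum length (bp) of a homologous flank
#'   segment contiguous with the NUMT boundary (default 100).
#' @param similarity_tolerance Maximum allowed difference between flank
#'   similarity and NUMT similarity (default 0.05).
#' @param dup_min_numt_similarity Minimum NUMT-vs-NUMT local-alignment
#'   identity before flanks are even compared (default 0.80).
#' @param boundary_slack Flank alignments must reach within this many bp of
#'   the NUMT boundary to count as contiguous (default 20).
#' @param synteny_slack Tolerated mitochondrial-interval overlap (bp)
#'   between consecutive cluster members (default 30): local alignment
#'   endpoints jitter a few bases past a fragmentation junction, while
#'   re-duplicated fragments overlap by far more and still break the chain.
#' @return A `classify_params` list.
#' @export
classify_params <- function(max_gap = 10000L, flank_len = 1000L,
                            min_flank_homology = 100L,
                            similarity_tolerance = 0.05,
                            dup_min_numt_similarity = 0.80,
                            boundary_slack = 20L,
                            synteny_slack = 30L) {
  p <- list(max_gap = as.integer(max_gap), flank_len = as.integer(flank_len),
            min_flank_homology = as.integer(min_flank_homology),
            similarity_tolerance = similarity_tolerance,
            dup_min_numt_similarity = dup_min_numt_similarity,
            boundary_slack = as.integer(boundary_slack),
            synteny_slack = as.integer(synteny_slack))
  if (any(c(p$max_gap, p$flank_len, p$min_flank_homology) <= 0L))
    stop("max_gap, flank_len and min_flank_homology must be positive")
  if (p$similarity_tolerance <= 0 || p$similarity_tolerance >= 1)
    stop("similarity_tolerance must lie in (0, 1)")
  class(p) <- "classify_params"
  p
}

#' Promote filtered hits to NUMT records
#'
#' Assigns stable identifiers and the classification columns
#' (`type = "unassigned"`, empty `cluster_id`/`family_id`).
#'
#' @param hits Filtered hits from [filter_hits()] (or [read_blast_tab()]).
#' @return Data frame of NUMT records ordered by (scaffold, start):
#'   `numt_id, scaffold, start, end, strand, mito_start, mito_end, identity,
#'   evalue, length, type, cluster_id, family_id`.
#' @export
numt_records <- function(hits) {
  hits <- hits[order(hits$scaffold, hits$nuc_start), , drop = FALSE]
  out <- data.frame(
    numt_id = sprintf("numt_%04d", seq_len(nrow(hits))),
    scaffold = hits$scaffold, start = hits$nuc_start, end = hits$nuc_end,
    strand = hits$strand, mito_start = hits$mito_start,
    mito_end = hits$mito_end, identity = hits$identity,
    evalue = hits$evalue, length = hits$nuc_end - hits$nuc_start,
    type = rep("unassigned", nrow(hits)),
    cluster_id = rep(NA_character_, nrow(hits)),
    family_id = rep(NA_character_, nrow(hits)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# ---- complex clusters -------------------------------------------------------

#' Group fragmented NUMTs into complex clusters
#'
#' Greedy left-to-right chaining per scaffold. A NUMT extends the current
#' chain iff all three criteria hold: (1) the gap of non-mitochondrial DNA
#' to the previous member is `< max_gap`; (2) synteny with the
#' mitochondrial genome is preserved (for "+" chains the mitochondrial
#' intervals advance along the scaffold, for "-" chains they retreat,
#' tolerating up to `synteny_slack` bp of alignment-edge overlap; members
#' with substantially overlapping mitochondrial intervals - re-duplicated
#' fragments - break the chain rather than joining it); (3) the strand is
#' consistent.
#' Chains of two or more members become clusters; each NUMT belongs to at
#' most one cluster.
#'
#' @param numts NUMT records ([numt_records()]), sorted per scaffold by
#'   start (an error otherwise).
#' @param params [classify_params()].
#' @return Data frame, one row per cluster member:
#'   `cluster_id, numt_id, scaffold, member_rank, strand, gap_before,
#'   mito_start, mito_end`; the per-cluster mitochondrial span can be
#'   recovered with [cluster_spans()].
#' @export
cluster_complex <- function(numts, params = classify_params()) {
  empty <- data.frame(cluster_id = character(0), numt_id = character(0),
                      scaffold = character(0), member_rank = integer(0),
                      strand = character(0), gap_before = integer(0),
                      mito_start = integer(0), mito_end = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(numts) == 0L) return(empty)
  if (any(unlist(tapply(numts$start, numts$scaffold, is.unsorted))))
    stop("numts must be sorted by start within each scaffold")
  chains <- list()
  for (scf in unique(numts$scaffold)) {
    sub <- numts[numts$scaffold == scf, , drop = FALSE]
    cur <- 1L
    chain <- list(cur)
    if (nrow(sub) > 1L) {
      for (i in 2:nrow(sub)) {
        prev <- chain[[length(chain)]]
        p <- prev[length(prev)]
        gap <- sub$start[i] - sub$end[p]
        same_strand <- sub$strand[i] == sub$strand[p]
        slack <- params$synteny_slack
        synteny <- if (sub$strand[i] == "+")
          sub$mito_start[i] >= sub$mito_end[p] - slack &&
            sub$mito_start[i] > sub$mito_start[p]
        else
          sub$mito_end[i] <= sub$mito_start[p] + slack &&
            sub$mito_end[i] < sub$mito_end[p]
        if (gap < params$max_gap && gap >= 0L && same_strand && synteny) {
          chain[[length(chain)]] <- c(prev, i)
        } else {
          chain[[length(chain) + 1L]] <- i
        }
      }
    }
    for (ch in chain) {
      if (length(ch) >= 2L)
        chains[[length(chains) + 1L]] <- list(scf = scf, idx = ch, sub = sub)
    }
  }
  if (length(chains) == 0L) return(empty)
  out <- lapply(seq_along(chains), function(ci) {
    ch <- chains[[ci]]
    sub <- ch$sub[ch$idx, , drop = FALSE]
    data.frame(cluster_id = sprintf("cluster_%03d", ci),
               numt_id = sub$numt_id, scaffold = ch$scf,
               member_rank = seq_along(ch$idx), strand = sub$strand,
               gap_before = c(NA_integer_,
                              sub$start[-1] - sub$end[-nrow(sub)]),
               mito_start = sub$mito_start, mito_end = sub$mito_end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Outermost genomic span of each complex cluster
#'
#' @param clusters Output of [cluster_complex()].
#' @param numts The NUMT records the clusters were built from.
#' @return Data frame `cluster_id, scaffold, start, end, strand, n_members,
#'   mito_start, mito_end`.
#' @export
cluster_spans <- function(clusters, numts) {
  if (nrow(clusters) == 0L)
    return(data.frame(cluster_id = character(0), scaffold = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_members = integer(0),
                      mito_start = integer(0), mito_end = integer(0),
                      stringsAsFactors = FALSE))
  pos <- numts[match(clusters$numt_id, numts$numt_id), c("start", "end")]
  agg <- lapply(split(seq_len(nrow(clusters)), clusters$cluster_id), function(ii) {
    data.frame(cluster_id = clusters$cluster_id[ii[1]],
               scaffold = clusters$scaffold[ii[1]],
               start = min(pos$start[ii]), end = max(pos$end[ii]),
               strand = clusters$strand[ii[1]], n_members = length(ii),
               mito_start = min(clusters$mito_start[ii]),
               mito_end = max(clusters$mito_end[ii]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$scaffold, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- duplicate families -----------------------------------------------------

#' Detect duplicate-type NUMT families via flanking-DNA homology
#'
#' For every NUMT pair whose local-alignment identity reaches
#' `dup_min_numt_similarity`, the nuclear flanks (`flank_len` bp each side,
#' truncated at scaffold ends) are aligned left-vs-left and right-vs-right
#' in mitochondrial orientation (flanks are swapped and
#' reverse-complemented for opposite-strand pairs). The pair is
#' duplication-linked iff at least one flank shows a homologous segment of
#' `>= min_flank_homology` bp contiguous with the NUMT boundary (within
#' `boundary_slack`) whose identity matches the NUMT identity to within
#' `similarity_tolerance`. Families are the connected components of the
#' resulting pair graph.
#'
#' @param numts NUMT records ([numt_records()]); ids must be unique.
#' @param genome Named character vector of scaffold sequences.
#' @param params [classify_params()].
#' @return List with `families` (data frame `family_id, numt_id`) and
#'   `evidence` (one row per linked pair: `family_id, numt_a, numt_b,
#'   numt_similarity, left_flank_similarity, right_flank_similarity,
#'   flank_homology_len`).
#' @export
detect_duplicates <- function(numts, genome, params = classify_params()) {
  if (anyDuplicated(numts$numt_id)) stop("NUMT ids must be unique")
  empty <- list(families = data.frame(family_id = character(0),
                                      numt_id = character(0),
                                      stringsAsFactors = FALSE),
                evidence = data.frame(family_id = character(0),
                                      numt_a = character(0),
                                      numt_b = character(0),
                                      numt_similarity = numeric(0),
                                      left_flank_similarity = numeric(0),
                                      right_flank_similarity = numeric(0),
                                      flank_homology_len = integer(0),
                                      stringsAsFactors = FALSE))
  n <- nrow(numts)
  if (n < 2L) return(empty)
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)

  # candidate pairs must share mitochondrial origin (>= 50% of the shorter
  # mitochondrial interval); duplication preserves the mitochondrial span
  cand <- list()
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      ov <- min(numts$mito_end[i], numts$mito_end[j]) -
        max(numts$mito_start[i], numts$mito_start[j])
      shorter <- min(numts$mito_end[i] - numts$mito_start[i],
                     numts$mito_end[j] - numts$mito_start[j])
      if (ov > 0.5 * shorter) cand[[length(cand) + 1L]] <- c(i, j)
    }
  }
  if (length(cand) == 0L) return(empty)

  # NUMT and flank sequences in mitochondrial orientation: "left" abuts the
  # mitochondrial-start end of the NUMT
  oriented <- function(i) {
    s <- genome[[numts$scaffold[i]]]
    st <- numts$start[i]; en <- numts$end[i]
    up <- subseq_chr(s, max(0L, st - params$flank_len), st)
    dn <- subseq_chr(s, en, min(nchar(s), en + params$flank_len))
    body <- subseq_chr(s, st, en)
    if (numts$strand[i] == "+") list(body = body, left = up, right = dn)
    else list(body = revcomp(body), left = revcomp(dn), right = revcomp(up))
  }
  seqs <- lapply(seq_len(n), oriented)

  flank_check <- function(a, b, side) {
    fa <- seqs[[a]][[side]]; fb <- seqs[[b]][[side]]
    if (nchar(fa) < params$min_flank_homology ||
        nchar(fb) < params$min_flank_homology)
      return(list(sim = NA_real_, len = 0L))
    r <- sw_align(fa, fb)
    if (r$alnlen == 0L) return(list(sim = NA_real_, len = 0L))
    len <- min(r$a_end - r$a_start, r$b_end - r$b_start)
    contiguous <- if (side == "left") {
      r$a_end >= nchar(fa) - params$boundary_slack &&
        r$b_end >= nchar(fb) - params$boundary_slack
    } else {
      r$a_start <= params$boundary_slack && r$b_start <= params$boundary_slack
    }
    list(sim = r$identity, len = if (contiguous) len else 0L)
  }

  links <- list()
  for (pr in cand) {
    i <- pr[1]; j <- pr[2]
    ra <- sw_align(seqs[[i]]$body, seqs[[j]]$body)
    if (ra$alnlen == 0L || ra$identity < params$dup_min_numt_similarity) next
    lf <- flank_check(i, j, "left")
    rf <- flank_check(i, j, "right")
    qual <- function(f) f$len >= params$min_flank_homology && !is.na(f$sim) &&
      abs(f$sim - ra$identity) <= params$similarity_tolerance
    if (qual(lf) || qual(rf)) {
      links[[length(links) + 1L]] <- data.frame(
        numt_a = numts$numt_id[i], numt_b = numts$numt_id[j],
        numt_similarity = ra$identity,
        left_flank_similarity = lf$sim, right_flank_similarity = rf$sim,
        flank_homology_len = max(lf$len, rf$len),
        i = i, j = j, stringsAsFactors = FALSE)
    }
  }
  if (length(links) == 0L) return(empty)
  links <- do.call(rbind, links)

  # connected components by union-find
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (r in seq_len(nrow(links))) {
    ri <- find(links$i[r]); rj <- find(links$j[r])
    if (ri != rj) parent[rj] <- ri
  }
  root <- vapply(seq_len(n), find, integer(1))
  members <- sort(unique(c(links$i, links$j)))
  roots <- sort(unique(root[members]))
  fam_ids <- stats::setNames(sprintf("fam_%03d", seq_along(roots)),
                             as.character(roots))
  families <- data.frame(
    family_id = unname(fam_ids[as.character(root[members])]),
    numt_id = numts$numt_id[members], stringsAsFactors = FALSE)
  families <- families[order(families$family_id, families$numt_id), ,
                       drop = FALSE]
  rownames(families) <- NULL
  evidence <- data.frame(
    family_id = unname(fam_ids[as.character(root[links$i])]),
    links[, c("numt_a", "numt_b", "numt_similarity",
              "left_flank_similarity", "right_flank_similarity",
              "flank_homology_len")],
    stringsAsFactors = FALSE)
  rownames(evidence) <- NULL
  list(families = families, evidence = evidence)
}

#' Label NUMTs as insertion type or duplicate type
#'
#' Within each duplicate family, the member most similar to the
#' mitochondrial genome is taken as the putative original and labelled
#' `insertion` (ties broken by lower E-value, then by scaffold and start);
#' the remaining members are `duplicate`. NUMTs outside any family are
#' `insertion`. With `mode = "family-duplicate"` entire families are
#' labelled `duplicate` instead, since the literature does not always state
#' which convention a count follows. Either way
#' `n_insertion + n_duplicate = n_total`.
#'
#' @param numts NUMT records.
#' @param families `families` data frame from [detect_duplicates()].
#' @param mode `"original-insertion"` (default) or `"family-duplicate"`.
#' @return The records with `type` and `family_id` filled in.
#' @export
label_types <- function(numts, families,
                        mode = c("original-insertion", "family-duplicate")) {
  mode <- match.arg(mode)
  numts$type <- "insertion"
  numts$family_id <- NA_character_
  if (!is.null(families) && nrow(families)) {
    for (fam in unique(families$family_id)) {
      ids <- families$numt_id[families$family_id == fam]
      sel <- which(numts$numt_id %in% ids)
      numts$family_id[sel] <- fam
      numts$type[sel] <- "duplicate"
      if (mode == "original-insertion") {
        o <- sel[order(-numts$identity[sel], numts$evalue[sel],
                       numts$scaffold[sel], numts$start[sel])]
        numts$type[o[1]] <- "insertion"
      }
    }
  }
  numts
}

#' Write classified NUMT records as TSV (1-based inclusive coordinates)
#'
#' @param numts Labelled records from [label_types()], optionally with
#'   `cluster_id` filled from [cluster_complex()].
#' @param path Output file.
#' @export
write_numt_table <- function(numts, path) {
  out <- numts
  out$start <- out$start + 1L
  out$mito_start <- out$mito_start + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
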