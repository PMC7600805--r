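#' Simulate a nuclear + mitochondrial genome with planted NUMTs
#'
#' Generates an AT-rich mitochondrial genome and a multi-scaffold nuclear
#' genome, then plants features with known truth: simple insertion-type
#' NUMTs (mutated copies of random mitochondrial segments), duplicate-type
#' NUMTs (copies of an existing NUMT plus carried nuclear flanks),
#' complex events (one insertion fragmented by TE insertion, fragments
#' syntenic and co-oriented), background transposable elements and
#' protein-coding gene models. All planted features are insertions into the
#' background sequence, so none overlap and none cross a scaffold boundary.
#'
#' The mitochondrial genome is simulated as linear; origin-spanning NUMTs
#' are not planted. Mutations are substitutions only, so truth intervals
#' are exact. Deterministic given the configuration (including its seed).
#'
#' @param config A [sim_config()].
#' @return An object of class `numt_sim`: a list with elements
#'   \describe{
#'     \item{mito}{mitochondrial sequence (character scalar)}
#'     \item{nuclear}{named character vector of scaffold sequences}
#'     \item{truth}{data frame of planted NUMTs (`numt_id, scaffold, start,
#'       end, strand, mito_start, mito_end, type, family_id, cluster_id,
#'       divergence`), 0-based half-open coordinates}
#'     \item{tes}{data frame of TE annotations}
#'     \item{genes}{`gene_models` object (genes/exons/cds data frames)}
#'     \item{te_library}{the TE library used}
#'     \item{config}{the input configuration}
#'   }
#' @examples
#' sim <- simulate_genome(sim_config(seed = 7, n_insertions = 3,
#'                                   scaffold_lengths = rep(50000L, 2),
#'                                   n_scaffolds = 2, min_spacing = 4000))
#' sim$truth
#' @export
simulate_genome <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  validate_sim_config(config)
  with_seed(config$seed, sim_impl(config))
}

#' @noRd
sim_impl <- function(cfg) {
  mito <- random_seq(cfg$mito_length, cfg$mito_at)
  scaff_names <- sprintf("scaffold_%02d", seq_len(cfg$n_scaffolds))
  bg <- vapply(cfg$scaffold_lengths, random_seq, character(1), at = cfg$nuclear_at)
  names(bg) <- scaff_names
  te_lib <- if (is.null(cfg$te_library)) random_te_library() else cfg$te_library

  margin <- max(300L, if (cfg$n_duplications > 0L) cfg$dup_flank_carry + 300L else 300L)
  genes_bg <- place_genes(bg, cfg, margin)

  chunks <- build_round1_chunks(mito, cfg, te_lib)
  chunks <- place_round1(chunks, bg, cfg, genes_bg, margin)

  asm <- assemble_round1(bg, chunks, genes_bg, te_lib, cfg)

  if (cfg$n_duplications > 0L) {
    asm <- add_duplications(asm, mito, cfg, margin)
  }
  if (!is.null(asm$truth) && nrow(asm$truth)) {
    asm$truth <- asm$truth[order(asm$truth$scaffold, asm$truth$start), , drop = FALSE]
    rownames(asm$truth) <- NULL
  }
  structure(list(mito = mito, nuclear = asm$nuclear, truth = asm$truth,
                 tes = asm$tes, genes = asm$genes, te_library = te_lib,
                 config = cfg),
            class = "numt_sim")
}

#' @export
print.numt_sim <- function(x, ...) {
  cat("numt_sim:", length(x$nuclear), "scaffolds (",
      sum(nchar(x$nuclear)), "bp ),", nchar(x$mito), "bp mito,",
      nrow(x$truth), "planted NUMTs,", nrow(x$tes), "TEs,",
      nrow(x$genes$genes), "genes\n")
  invisible(x)
}

# ---- gene placement (background coordinates) --------------------------------

#' @noRd
place_genes <- function(bg, cfg, margin) {
  gm <- empty_gene_models()
  if (cfg$n_genes == 0L) return(gm)
  lens <- nchar(bg)
  scf_idx <- sample.int(length(bg), cfg$n_genes, replace = TRUE,
                        prob = as.numeric(lens))
  genes <- exons <- list()
  placed <- lapply(seq_along(bg), function(i) cbind(integer(0), integer(0)))
  for (g in seq_len(cfg$n_genes)) {
    si <- scf_idx[g]
    L <- lens[si]
    glen <- sample(cfg$gene_length[1]:cfg$gene_length[2], 1L)
    ok <- FALSE
    for (att in seq_len(1000L)) {
      gs <- sample(margin:(L - margin - glen), 1L)
      prev <- placed[[si]]
      if (nrow(prev) == 0L ||
          all(gs + glen + 200L <= prev[, 1] | gs >= prev[, 2] + 200L)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place gene without overlap after 1000 attempts; ",
                  "scaffolds too small for the requested features")
    placed[[si]] <- rbind(placed[[si]], c(gs, gs + glen))
    ex <- gene_exons(gs, gs + glen)
    gid <- sprintf("gene_%03d", g)
    genes[[g]] <- data.frame(gene_id = gid, scaffold = names(bg)[si],
                             start = gs, end = gs + glen,
                             strand = sample(c("+", "-"), 1L),
                             stringsAsFactors = FALSE)
    exons[[g]] <- data.frame(gene_id = gid, scaffold = names(bg)[si],
                             start = ex[, 1], end = ex[, 2],
                             stringsAsFactors = FALSE)
  }
  # simulated genes are fully coding within their exons (cds == exons)
  gene_models(do.call(rbind, genes), do.call(rbind, exons))
}

#' 2-5 exons partitioning [gs, ge); alternating exon/intron, each segment >= 50 bp
#' @noRd
gene_exons <- function(gs, ge) {
  glen <- ge - gs
  k <- sample(2:5, 1L)
  nseg <- 2L * k - 1L
  for (att in 1:20) {
    cuts <- sort(sample((gs + 50L):(ge - 50L), nseg - 1L))
    b <- c(gs, cuts, ge)
    if (all(diff(b) >= 50L)) break
    if (att == 20L) b <- round(seq(gs, ge, length.out = nseg + 1L))
  }
  idx <- seq(1L, nseg, by = 2L)           # odd segments are exons
  cbind(b[idx], b[idx + 1L])
}

# ---- round-1 chunk construction ---------------------------------------------

#' @noRd
draw_divergence <- function(d, n) {
  if (identical(d$dist, "uniform")) stats::runif(n, d$min, d$max)
  else rep(d$value, n)
}

#' @noRd
build_round1_chunks <- function(mito, cfg, te_lib) {
  chunks <- list()
  mk_numt <- function(len, d, strand) {
    mstart <- sample.int(cfg$mito_length - len + 1L, 1L) - 1L
    mut <- mutate_seq(subseq_chr(mito, mstart, mstart + len), d)
    list(mstart = mstart, mend = mstart + len,
         seq = if (strand == "-") revcomp(mut) else mut)
  }
  # simple insertion-type NUMTs
  if (cfg$n_insertions > 0L) {
    lens <- sample(cfg$insertion_length[1]:cfg$insertion_length[2],
                   cfg$n_insertions, replace = TRUE)
    ds <- draw_divergence(cfg$divergence, cfg$n_insertions)
    strands <- sample(c("+", "-"), cfg$n_insertions, replace = TRUE)
    for (i in seq_len(cfg$n_insertions)) {
      nm <- mk_numt(lens[i], ds[i], strands[i])
      chunks[[length(chunks) + 1L]] <- list(
        kind = "insertion", seq = nm$seq, strand = strands[i],
        mito_start = nm$mstart, mito_end = nm$mend, divergence = ds[i])
    }
  }
  # complex events: one insertion fragmented by TE insertion(s)
  if (cfg$n_complex > 0L) {
    frag_choices <- cfg$complex_fragments
    ds <- draw_divergence(cfg$divergence, cfg$n_complex)
    for (i in seq_len(cfg$n_complex)) {
      k <- if (length(frag_choices) > 1L) sample(frag_choices, 1L) else frag_choices
      lo <- max(cfg$insertion_length[1], k * cfg$complex_min_fragment)
      if (lo > cfg$insertion_length[2])
        stop("insertion_length too short for ", k, " complex fragments of >= ",
             cfg$complex_min_fragment, " bp")
      len <- sample(lo:cfg$insertion_length[2], 1L)
      strand <- sample(c("+", "-"), 1L)
      mstart <- sample.int(cfg$mito_length - len + 1L, 1L) - 1L
      mut <- mutate_seq(subseq_chr(mito, mstart, mstart + len), ds[i])
      # fragment cut points, each fragment >= complex_min_fragment
      mf <- cfg$complex_min_fragment
      for (att in 1:50) {
        cuts <- sort(sample((mf):(len - mf), k - 1L))
        if (all(diff(c(0L, cuts, len)) >= mf)) break
        if (att == 50L) cuts <- round(seq_len(k - 1L) * len / k)
      }
      te_idx <- sample(seq_along(te_lib), k - 1L, replace = TRUE)
      # build the chunk in mito orientation, then reverse-complement if "-"
      b <- c(0L, cuts, len)
      comp <- list(); seqs <- character(0); off <- 0L
      for (j in seq_len(k)) {
        fseq <- substr(mut, b[j] + 1L, b[j + 1L])
        comp[[length(comp) + 1L]] <- list(kind = "numt", off = off,
                                          len = nchar(fseq),
                                          mito_start = mstart + b[j],
                                          mito_end = mstart + b[j + 1L])
        seqs <- c(seqs, fseq); off <- off + nchar(fseq)
        if (j < k) {
          tseq <- te_lib[[te_idx[j]]]$sequence
          comp[[length(comp) + 1L]] <- list(kind = "te", off = off,
                                            len = nchar(tseq),
                                            te_idx = te_idx[j])
          seqs <- c(seqs, tseq); off <- off + nchar(tseq)
        }
      }
      full <- paste(seqs, collapse = "")
      if (strand == "-") {
        tot <- nchar(full)
        full <- revcomp(full)
        comp <- lapply(comp, function(cm) {
          new_off <- tot - (cm$off + cm$len); cm$off <- new_off; cm
        })
        comp <- comp[order(vapply(comp, `[[`, integer(1), "off"))]
      }
      chunks[[length(chunks) + 1L]] <- list(
        kind = "complex", seq = full, strand = strand,
        mito_start = mstart, mito_end = mstart + len,
        divergence = ds[i], components = comp)
    }
  }
  # background TEs
  if (cfg$n_te_background > 0L) {
    idx <- sample(seq_along(te_lib), cfg$n_te_background, replace = TRUE)
    strands <- sample(c("+", "C"), cfg$n_te_background, replace = TRUE)
    for (i in seq_len(cfg$n_te_background)) {
      s <- te_lib[[idx[i]]]$sequence
      chunks[[length(chunks) + 1L]] <- list(
        kind = "te", seq = if (strands[i] == "C") revcomp(s) else s,
        te_idx = idx[i], te_strand = strands[i])
    }
  }
  chunks
}

# ---- round-1 placement ------------------------------------------------------

#' @noRd
place_round1 <- function(chunks, bg, cfg, genes_bg, margin) {
  if (length(chunks) == 0L) return(chunks)
  lens <- nchar(bg)
  is_numt <- vapply(chunks, function(ch) ch$kind %in% c("insertion", "complex"),
                    logical(1))
  scf <- sample.int(length(bg), length(chunks), replace = TRUE,
                    prob = as.numeric(lens))
  # per-scaffold forbidden mask and AT weights
  allowed <- lapply(seq_along(bg), function(si) {
    L <- lens[si]
    ok <- rep(TRUE, L)
    ok[seq_len(min(margin, L))] <- FALSE
    ok[max(1L, L - margin + 1L):L] <- FALSE
    if (!cfg$allow_exonic && nrow(genes_bg$exons)) {
      ex <- genes_bg$exons[genes_bg$exons$scaffold == names(bg)[si], , drop = FALSE]
      for (r in seq_len(nrow(ex))) {
        lo <- ex$start[r] + 2L; hi <- ex$end[r]       # forbid es < p < ee
        if (lo <= hi) ok[lo:hi] <- FALSE
      }
    }
    ok
  })
  at_w <- lapply(seq_along(bg), function(si) {
    L <- lens[si]
    w <- numeric(L)
    if (any(is_numt) && cfg$at_site_bias > 0) {
      aw <- at_windows(bg[[si]], 20L)                 # window start 0..L-20
      p <- 10:(L - 10L)                               # centre positions
      w[p + 1L] <- aw[p - 9L]^cfg$at_site_bias
    } else w[] <- 1
    w
  })
  numt_pts <- lapply(seq_along(bg), function(i) integer(0))
  all_pts <- lapply(seq_along(bg), function(i) integer(0))

  # batched weighted sampling: setting up sample() with a multi-Mb probability
  # vector is O(L), so draw candidates 128 at a time per scaffold
  wbuf <- vector("list", length(bg))
  eff_w <- lapply(seq_along(bg), function(si) {
    w <- at_w[[si]]
    w[!allowed[[si]]] <- 0
    w
  })
  draw_point <- function(si, weighted) {
    if (!weighted) {
      for (k in 1:50) {
        p <- sample.int(lens[si], 1L) - 1L
        if (allowed[[si]][p + 1L]) return(p)
      }
      stop("no admissible insertion site on ", names(bg)[si])
    }
    if (length(wbuf[[si]]) == 0L) {
      if (sum(eff_w[[si]]) == 0)
        stop("no admissible insertion site on ", names(bg)[si])
      wbuf[[si]] <<- sample.int(lens[si], 128L, replace = TRUE,
                                prob = eff_w[[si]]) - 1L
    }
    p <- wbuf[[si]][1L]
    wbuf[[si]] <<- wbuf[[si]][-1L]
    p
  }

  # NUMT-bearing chunks first (they constrain spacing), then TEs
  for (ci in order(!is_numt)) {
    si <- scf[ci]
    placed <- FALSE
    for (att in seq_len(1000L)) {
      if (is_numt[ci]) {
        p <- draw_point(si, weighted = TRUE)
        if (length(numt_pts[[si]]) &&
            min(abs(p - numt_pts[[si]])) < cfg$min_spacing) next
        if (length(all_pts[[si]]) && min(abs(p - all_pts[[si]])) < 200L) next
        numt_pts[[si]] <- c(numt_pts[[si]], p)
      } else {
        coloc <- cfg$te_numt_colocation > 0 &&
          stats::runif(1) < cfg$te_numt_colocation &&
          length(unlist(numt_pts)) > 0L
        if (coloc) {
          # place near a planted NUMT (shared preference for unstable regions)
          host <- sample(which(lengths(numt_pts) > 0L), 1L)
          anchor <- sample(numt_pts[[host]], 1L)
          off <- sample(c(-1L, 1L), 1L) *
            sample(300:cfg$te_colocation_window, 1L)
          p <- anchor + off
          si2 <- host
        } else {
          p <- draw_point(si, weighted = FALSE)
          si2 <- si
        }
        if (p < margin || p >= lens[si2] - margin) next
        if (!allowed[[si2]][p + 1L]) next
        if (length(all_pts[[si2]]) && min(abs(p - all_pts[[si2]])) < 200L) next
        si <- si2
      }
      all_pts[[si]] <- c(all_pts[[si]], p)
      chunks[[ci]]$scaffold <- names(bg)[si]
      chunks[[ci]]$point <- p
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place a planted feature after 1000 attempts; ",
           "scaffolds too small for the requested features")
  }
  chunks
}

# ---- round-1 assembly -------------------------------------------------------

#' @noRd
assemble_round1 <- function(bg, chunks, genes_bg, te_lib, cfg) {
  truth <- list(); tes <- list()
  nuclear <- bg
  genes <- genes_bg
  numt_counter <- 0L; cluster_counter <- 0L; te_counter <- 0L
  for (si in seq_along(bg)) {
    scf <- names(bg)[si]
    idx <- which(vapply(chunks, function(ch) identical(ch$scaffold, scf), logical(1)))
    if (length(idx) == 0L) next
    pts <- vapply(chunks[idx], `[[`, integer(1), "point")
    lns <- vapply(chunks[idx], function(ch) nchar(ch$seq), integer(1))
    map <- insertion_map(pts, lns)
    nuclear[[si]] <- apply_insertions_seq(bg[[si]],
                                          map,
                                          vapply(chunks[idx], `[[`, character(1), "seq"))
    ord_idx <- idx[map$order]
    for (j in seq_along(ord_idx)) {
      ch <- chunks[[ord_idx[j]]]
      fs <- map$chunk_start[j]
      if (ch$kind == "insertion") {
        numt_counter <- numt_counter + 1L
        truth[[length(truth) + 1L]] <- data.frame(
          numt_id = sprintf("numt_%04d", numt_counter), scaffold = scf,
          start = fs, end = fs + nchar(ch$seq), strand = ch$strand,
          mito_start = ch$mito_start, mito_end = ch$mito_end,
          type = "insertion", family_id = NA_character_,
          cluster_id = NA_character_, divergence = ch$divergence,
          stringsAsFactors = FALSE)
      } else if (ch$kind == "complex") {
        cluster_counter <- cluster_counter + 1L
        cid <- sprintf("cluster_%03d", cluster_counter)
        for (cm in ch$components) {
          if (cm$kind == "numt") {
            numt_counter <- numt_counter + 1L
            truth[[length(truth) + 1L]] <- data.frame(
              numt_id = sprintf("numt_%04d", numt_counter), scaffold = scf,
              start = fs + cm$off, end = fs + cm$off + cm$len,
              strand = ch$strand, mito_start = cm$mito_start,
              mito_end = cm$mito_end, type = "insertion",
              family_id = NA_character_, cluster_id = cid,
              divergence = ch$divergence, stringsAsFactors = FALSE)
          } else {
            te_counter <- te_counter + 1L
            ent <- te_lib[[cm$te_idx]]
            tes[[length(tes) + 1L]] <- data.frame(
              scaffold = scf, start = fs + cm$off, end = fs + cm$off + cm$len,
              te_name = ent$name, superfamily = ent$superfamily,
              divergence = 0, strand = if (ch$strand == "-") "C" else "+",
              stringsAsFactors = FALSE)
          }
        }
      } else {                                        # background TE
        te_counter <- te_counter + 1L
        ent <- te_lib[[ch$te_idx]]
        tes[[length(tes) + 1L]] <- data.frame(
          scaffold = scf, start = fs, end = fs + nchar(ch$seq),
          te_name = ent$name, superfamily = ent$superfamily,
          divergence = 0, strand = ch$te_strand, stringsAsFactors = FALSE)
      }
    }
    # shift gene models on this scaffold to assembled coordinates
    if (nrow(genes$genes)) {
      gsel <- genes$genes$scaffold == scf
      genes$genes$end[gsel] <- map$map_end(genes$genes$end[gsel])
      genes$genes$start[gsel] <- map$map_start(genes$genes$start[gsel])
      esel <- genes$exons$scaffold == scf
      sh <- map$map_start(genes$exons$start[esel])
      genes$exons$end[esel] <- genes$exons$end[esel] + (sh - genes$exons$start[esel])
      genes$exons$start[esel] <- sh
      genes$cds <- genes$exons
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else empty_truth()
  tes <- if (length(tes)) do.call(rbind, tes) else empty_te_annotation()
  list(nuclear = nuclear, truth = truth, tes = tes, genes = genes)
}

# ---- round 2: duplications --------------------------------------------------

#' @noRd
add_duplications <- function(asm, mito, cfg, margin) {
  src_pool <- which(asm$truth$type == "insertion" & is.na(asm$truth$cluster_id))
  if (length(src_pool) == 0L)
    stop("duplications require at least one simple insertion-type NUMT")
  nuclear <- asm$nuclear
  lens <- nchar(nuclear)
  src_idx <- sample(src_pool, cfg$n_duplications, replace = TRUE)
  carry <- cfg$dup_flank_carry

  # forbidden intervals per scaffold: near existing NUMTs (min_spacing),
  # near TEs (200 bp) and inside exons
  forb <- lapply(names(nuclear), function(scf) {
    f <- rbind(
      cbind(asm$truth$start[asm$truth$scaffold == scf] - cfg$min_spacing,
            asm$truth$end[asm$truth$scaffold == scf] + cfg$min_spacing),
      cbind(asm$tes$start[asm$tes$scaffold == scf] - 200L,
            asm$tes$end[asm$tes$scaffold == scf] + 200L),
      if (nrow(asm$genes$exons))
        cbind(asm$genes$exons$start[asm$genes$exons$scaffold == scf] - 1L,
              asm$genes$exons$end[asm$genes$exons$scaffold == scf])
      else NULL)
    f
  })
  names(forb) <- names(nuclear)

  dup <- list()
  for (i in seq_len(cfg$n_duplications)) {
    srow <- asm$truth[src_idx[i], ]
    ssc <- srow$scaffold
    ls <- max(0L, srow$start - carry)
    re <- min(lens[[ssc]], srow$end + carry)
    chunk <- mutate_seq(subseq_chr(nuclear[[ssc]], ls, re),
                        cfg$dup_extra_divergence)
    placed <- FALSE
    for (att in seq_len(1000L)) {
      si <- sample.int(length(nuclear), 1L, prob = as.numeric(lens))
      scf <- names(nuclear)[si]
      p <- sample((margin):(lens[si] - margin), 1L)
      f <- forb[[scf]]
      if (nrow(f) && any(p > f[, 1] & p < f[, 2])) next
      dup[[length(dup) + 1L]] <- list(scaffold = scf, point = p, seq = chunk,
                                      numt_off = srow$start - ls,
                                      numt_len = srow$end - srow$start,
                                      src = src_idx[i], strand = srow$strand,
                                      mito_start = srow$mito_start,
                                      mito_end = srow$mito_end)
      forb[[scf]] <- rbind(f, c(p - cfg$min_spacing, p + cfg$min_spacing))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place a duplicated NUMT after 1000 attempts; ",
           "scaffolds too small for the requested features")
  }

  # assign family ids grouped by source NUMT
  fam_of_src <- list()
  fam_counter <- 0L
  truth <- asm$truth
  new_rows <- list()
  maps <- list()
  for (si in seq_along(nuclear)) {
    scf <- names(nuclear)[si]
    idx <- which(vapply(dup, function(d) identical(d$scaffold, scf), logical(1)))
    if (length(idx) == 0L) { maps[[scf]] <- NULL; next }
    pts <- vapply(dup[idx], `[[`, integer(1), "point")
    lns <- vapply(dup[idx], function(d) nchar(d$seq), integer(1))
    map <- insertion_map(pts, lns)
    nuclear[[si]] <- apply_insertions_seq(nuclear[[si]], map,
                                          vapply(dup[idx], `[[`, character(1), "seq"))
    maps[[scf]] <- map
    ord_idx <- idx[map$order]
    for (j in seq_along(ord_idx)) {
      d <- dup[[ord_idx[j]]]
      key <- as.character(d$src)
      if (is.null(fam_of_src[[key]])) {
        fam_counter <- fam_counter + 1L
        fam_of_src[[key]] <- sprintf("fam_%03d", fam_counter)
      }
      fs <- map$chunk_start[j] + d$numt_off
      nseq <- substr(nuclear[[si]], fs + 1L, fs + d$numt_len)
      mseg <- subseq_chr(mito, d$mito_start, d$mito_end)
      realized <- mismatch_fraction(if (d$strand == "-") revcomp(nseq) else nseq,
                                    mseg)
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        numt_id = NA_character_, scaffold = scf, start = fs,
        end = fs + d$numt_len, strand = d$strand,
        mito_start = d$mito_start, mito_end = d$mito_end,
        type = "duplicate", family_id = fam_of_src[[key]],
        cluster_id = NA_character_, divergence = realized,
        stringsAsFactors = FALSE)
    }
  }
  # note: duplicate coordinates above are computed on the final sequence, but
  # round-1 features still need shifting through the round-2 insertions
  shift_df <- function(df, scf_col = "scaffold") {
    if (!nrow(df)) return(df)
    for (scf in unique(df[[scf_col]])) {
      map <- maps[[scf]]
      if (is.null(map)) next
      sel <- df[[scf_col]] == scf
      df$end[sel] <- map$map_end(df$end[sel])
      df$start[sel] <- map$map_start(df$start[sel])
    }
    df
  }
  # duplicate rows were computed against the *final* sequence only for their
  # own chunk; their start used post-insertion chunk_start, already final
  truth <- shift_df(truth)
  for (k in as.character(unique(src_idx))) {
    truth$family_id[as.integer(k)] <- fam_of_src[[k]]
  }
  asm$tes <- shift_df(asm$tes)
  if (nrow(asm$genes$genes)) {
    g <- asm$genes
    for (scf in unique(g$genes$scaffold)) {
      map <- maps[[scf]]
      if (is.null(map)) next
      gsel <- g$genes$scaffold == scf
      g$genes$end[gsel] <- map$map_end(g$genes$end[gsel])
      g$genes$start[gsel] <- map$map_start(g$genes$start[gsel])
      esel <- g$exons$scaffold == scf
      sh <- map$map_start(g$exons$start[esel])
      g$exons$end[esel] <- g$exons$end[esel] + (sh - g$exons$start[esel])
      g$exons$start[esel] <- sh
    }
    g$cds <- g$exons
    asm$genes <- g
  }
  dup_truth <- do.call(rbind, new_rows)
  dup_truth$numt_id <- sprintf("numt_%04d", nrow(truth) + seq_len(nrow(dup_truth)))
  asm$truth <- rbind(truth, dup_truth)
  asm$nuclear <- nuclear
  asm
}
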