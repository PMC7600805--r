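# Readers and writers for the standard interchange formats. Internal
# coordinates are 0-based half-open; GFF3, RepeatMasker .out and BLAST
# tabular files are 1-based inclusive and converted at the boundary.

#' Read a (multi-)FASTA file into a named character vector
#'
#' IUPAC ambiguity codes and any other non-ACGT characters are mapped to N.
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  s <- toupper(as.character(x))
  s <- gsub("[^ACGTN]", "N", s)
  names(s) <- sub("\\s.*$", "", names(x))
  s
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs Named character vector (or a single unnamed sequence).
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 60L)
  invisible(path)
}

# ---- gene models / GFF3 -----------------------------------------------------

#' Construct a gene_models object
#'
#' @param genes Data frame `gene_id, scaffold, start, end, strand`
#'   (0-based half-open).
#' @param exons,cds Data frames `gene_id, scaffold, start, end`. `cds`
#'   defaults to the exons.
#' @return `gene_models` object with components sorted by coordinate.
#' @export
gene_models <- function(genes, exons, cds = exons) {
  norm <- function(df, cols) {
    df <- df[, cols, drop = FALSE]
    df$start <- as.integer(df$start); df$end <- as.integer(df$end)
    df <- df[order(df$scaffold, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  g <- norm(genes, c("gene_id", "scaffold", "start", "end", "strand"))
  if (any(g$end <= g$start)) stop("gene intervals must satisfy end > start")
  e <- norm(exons, c("gene_id", "scaffold", "start", "end"))
  cc <- norm(cds, c("gene_id", "scaffold", "start", "end"))
  if (!all(e$gene_id %in% g$gene_id)) stop("exon with unknown gene_id")
  structure(list(genes = g, exons = e, cds = cc), class = "gene_models")
}

#' Write gene models as GFF3
#'
#' Emits gene / mRNA / exon / CDS features, 1-based inclusive.
#'
#' @param genes A [gene_models()] object.
#' @param path Output file.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- genes$genes
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    line <- function(type, s, e, attrs)
      sprintf("%s\tnumtatlas\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$scaffold[i], type, s + 1L, e, g$strand[i], attrs)
    writeLines(line("gene", g$start[i], g$end[i], paste0("ID=", gid)), con)
    tid <- paste0(gid, ".t1")
    writeLines(line("mRNA", g$start[i], g$end[i],
                    paste0("ID=", tid, ";Parent=", gid)), con)
    ex <- genes$exons[genes$exons$gene_id == gid, , drop = FALSE]
    for (j in seq_len(nrow(ex)))
      writeLines(line("exon", ex$start[j], ex$end[j],
                      paste0("ID=", tid, ".exon", j, ";Parent=", tid)), con)
    cd <- genes$cds[genes$cds$gene_id == gid, , drop = FALSE]
    for (j in seq_len(nrow(cd)))
      writeLines(line("CDS", cd$start[j], cd$end[j],
                      paste0("ID=", tid, ".cds", j, ";Parent=", tid)), con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Accepts gene/mRNA/exon/CDS rows; exons and CDS may point at either the
#' gene or one of its transcripts through `Parent`. Orphan exons (a Parent
#' that resolves to no gene) are an error.
#'
#' @param path GFF3 file.
#' @return A [gene_models()] object (0-based half-open coordinates).
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(empty_gene_models())
  df <- data.frame(scaffold = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   id = if (!is.null(gr$ID)) gr$ID else NA_character_,
                   stringsAsFactors = FALSE)
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else rep(NA_character_, nrow(df))
  df$parent <- parent

  gsel <- df$type == "gene"
  genes <- data.frame(gene_id = df$id[gsel], scaffold = df$scaffold[gsel],
                      start = df$start[gsel], end = df$end[gsel],
                      strand = df$strand[gsel], stringsAsFactors = FALSE)
  # transcript id -> gene id
  tsel <- df$type %in% c("mRNA", "transcript")
  tx2gene <- stats::setNames(df$parent[tsel], df$id[tsel])
  resolve <- function(p) {
    if (is.na(p)) return(NA_character_)
    if (p %in% genes$gene_id) return(p)
    if (p %in% names(tx2gene)) return(unname(tx2gene[[p]]))
    NA_character_
  }
  take <- function(type) {
    sel <- df$type == type
    if (!any(sel)) return(data.frame(gene_id = character(0),
                                     scaffold = character(0),
                                     start = integer(0), end = integer(0),
                                     stringsAsFactors = FALSE))
    gid <- vapply(df$parent[sel], resolve, character(1))
    if (anyNA(gid))
      stop("orphan ", type, " feature(s): Parent does not resolve to a gene")
    data.frame(gene_id = gid, scaffold = df$scaffold[sel],
               start = df$start[sel], end = df$end[sel],
               stringsAsFactors = FALSE)
  }
  ex <- take("exon")
  cd <- take("CDS")
  if (nrow(cd) == 0L) cd <- ex
  gene_models(genes, ex, cd)
}

# ---- RepeatMasker .out ------------------------------------------------------

#' Read RepeatMasker .out annotations
#'
#' Parses the standard 15-column `.out` table (3 header lines), keeping the
#' query interval, repeat name, class/family and divergence. 1-based
#' inclusive query coordinates are converted to 0-based half-open.
#'
#' @param path `.out` file.
#' @return Data frame `scaffold, start, end, te_name, superfamily,
#'   divergence, strand`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("not a RepeatMasker .out file (missing header)")
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) return(empty_te_annotation())
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) < 11L)
      stop("malformed RepeatMasker row at line ", i + 3L)
    qb <- suppressWarnings(as.integer(f[6])); qe <- suppressWarnings(as.integer(f[7]))
    dv <- suppressWarnings(as.numeric(f[2]))
    if (is.na(qb) || is.na(qe) || is.na(dv) || qe < qb)
      stop("malformed RepeatMasker row at line ", i + 3L)
    data.frame(scaffold = f[5], start = qb - 1L, end = qe,
               te_name = f[10], superfamily = f[11], divergence = dv,
               strand = f[9], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$scaffold, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write TE annotations in the RepeatMasker .out dialect
#'
#' @param tes Data frame as returned by [read_repeatmasker_out()].
#' @param path Output file.
#' @export
write_repeatmasker_out <- function(tes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "   SW   perc perc perc  query     position in query              matching       repeat           position in repeat",
    "score   div. del. ins.  sequence  begin end          (left)     repeat         class/family   begin  end    (left)     ID",
    ""), con)
  if (nrow(tes)) {
    tes <- tes[order(tes$scaffold, tes$start), , drop = FALSE]
    for (i in seq_len(nrow(tes))) {
      rlen <- tes$end[i] - tes$start[i]
      writeLines(sprintf(
        " 1000 %6.1f  0.0  0.0  %s %d %d (0) %s %s %s %s %s %s %d",
        tes$divergence[i], tes$scaffold[i], tes$start[i] + 1L, tes$end[i],
        tes$strand[i], tes$te_name[i], tes$superfamily[i],
        if (tes$strand[i] == "C") "(0)" else "1",
        if (tes$strand[i] == "C") as.character(rlen) else as.character(rlen),
        if (tes$strand[i] == "C") "1" else "(0)", i), con)
    }
  }
  invisible(path)
}

# ---- truth table ------------------------------------------------------------

#' Write the planted-NUMT truth table (TSV, 0-based half-open)
#' @param truth Truth data frame from [simulate_genome()].
#' @param path Output file.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  # full double precision so the table round-trips bit-exactly
  out$divergence <- sprintf("%.17g", out$divergence)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a planted-NUMT truth table
#' @param path TSV written by [write_truth()].
#' @return Truth data frame.
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(numt_id = "character",
                                         scaffold = "character",
                                         start = "integer", end = "integer",
                                         strand = "character",
                                         mito_start = "integer",
                                         mito_end = "integer",
                                         type = "character",
                                         family_id = "character",
                                         cluster_id = "character",
                                         divergence = "numeric"))
  if (nrow(df) == 0L) return(empty_truth())
  df
}

#' Write a simulated genome and its annotations as fixture files
#'
#' Emits `mito.fa`, `nuclear.fa`, `genes.gff3`, `repeats.out` and
#' `truth.tsv` into `outdir`. All files round-trip losslessly through the
#' package's own readers.
#'
#' @param sim A `numt_sim` from [simulate_genome()].
#' @param outdir Output directory (created if absent).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_fixture <- function(sim, outdir) {
  if (!inherits(sim, "numt_sim")) stop("sim must be a numt_sim")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mito = file.path(outdir, "mito.fa"),
             nuclear = file.path(outdir, "nuclear.fa"),
             genes = file.path(outdir, "genes.gff3"),
             repeats = file.path(outdir, "repeats.out"),
             truth = file.path(outdir, "truth.tsv"))
  write_fasta(c(mito = sim$mito), paths["mito"])
  write_fasta(sim$nuclear, paths["nuclear"])
  write_gff3(sim$genes, paths["genes"])
  write_repeatmasker_out(sim$tes, paths["repeats"])
  write_truth(sim$truth, paths["truth"])
  invisible(paths)
}
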