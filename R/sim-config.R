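#' Transposable-element library entry
#'
#' A named repeat consensus used by the simulator both for background TE
#' insertions and for fragmenting planted NUMTs into complex clusters.
#'
#' @param name Repeat name, e.g. `"Gypsy-1"`.
#' @param superfamily Class/family string in RepeatMasker style, e.g.
#'   `"LTR/Gypsy"` or `"LINE/Jockey"`.
#' @param sequence DNA string over `{A,C,G,T}`.
#' @return A `te_library_entry` list.
#' @export
te_library_entry <- function(name, superfamily, sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L || grepl("[^ACGT]", sequence))
    stop("TE sequence must be a non-empty string over {A,C,G,T}")
  structure(list(name = name, superfamily = superfamily, sequence = sequence),
            class = "te_library_entry")
}

#' Random TE library
#'
#' Draws random consensus sequences for a set of superfamilies. Uses the
#' current RNG state, so wrap in a seeded context for reproducibility.
#'
#' @param lengths Integer vector of consensus lengths.
#' @param superfamilies Character vector recycled against `lengths`. Defaults
#'   mirror the superfamilies most often seen next to NUMTs in insect
#'   genomes (Gypsy LTR retrotransposons and Jockey LINEs).
#' @param at AT fraction of the consensi.
#' @return List of [te_library_entry()] objects.
#' @export
random_te_library <- function(lengths = c(4000L, 3000L, 1500L),
                              superfamilies = c("LTR/Gypsy", "LINE/Jockey", "DNA/Tc1-Mariner"),
                              at = 0.55) {
  superfamilies <- rep_len(superfamilies, length(lengths))
  lapply(seq_along(lengths), function(i) {
    te_library_entry(
      name = paste0(sub("^.*/", "", superfamilies[i]), "-", i),
      superfamily = superfamilies[i],
      sequence = random_seq(lengths[i], at)
    )
  })
}

#' Simulation configuration for synthetic genomes with planted NUMTs
#'
#' Defines a nuclear + mitochondrial genome simulation in which NUMTs
#' (nuclear copies of mitochondrial segments), transposable elements and
#' protein-coding genes are planted with known coordinates, so that every
#' stage of the detection pipeline can be scored against truth.
#'
#' Planted features are *insertions*: each feature is spliced into the
#' background scaffold at a sampled point, so scaffolds grow and no feature
#' ever overlaps another or crosses a scaffold boundary. Insertion sites of
#' NUMTs are sampled with probability proportional to the AT fraction of the
#' surrounding 20 bp raised to `at_site_bias` (`0` = uniform, i.e. no bias).
#'
#' @param seed Integer seed; the simulation is byte-identical given the
#'   same configuration.
#' @param mito_length Mitochondrial genome length in bp. Insect
#'   mitochondrial genomes are ~15-16 kb; default 15800.
#' @param mito_at AT fraction of the mitochondrial genome (default 0.78,
#'   the AT-rich composition typical of insect mtDNA).
#' @param n_scaffolds,scaffold_lengths Number and lengths (bp) of nuclear
#'   scaffolds.
#' @param nuclear_at AT fraction of the nuclear background (default 0.65).
#' @param n_insertions Number of simple insertion-type NUMTs to plant.
#' @param insertion_length Length range (bp) of planted NUMTs, sampled
#'   uniformly.
#' @param divergence Per-site substitution probability of a planted NUMT
#'   relative to its mitochondrial source: `list(dist="uniform",min=,max=)`
#'   or `list(dist="fixed",value=)`. Substitutions only; truth intervals
#'   stay exact.
#' @param at_site_bias Non-negative exponent of the AT-weighted insertion
#'   site sampling; values much greater than 1 concentrate NUMTs in AT-rich
#'   sites, 0 gives uniform placement.
#' @param n_duplications Number of duplicate-type NUMTs: copies of an
#'   already planted NUMT *plus* `dup_flank_carry` bp of its nuclear flanks,
#'   re-inserted elsewhere after `dup_extra_divergence` further substitution.
#' @param dup_flank_carry Nuclear flank carried along with a duplicated
#'   NUMT (bp, default 1000).
#' @param dup_extra_divergence Extra per-site substitution applied to the
#'   duplicated chunk (default 0.02).
#' @param n_complex Number of complex NUMT events: a single insertion
#'   subsequently fragmented by TE insertion(s); fragments keep order and
#'   strand and share a truth `cluster_id`.
#' @param complex_fragments Fragments per complex event (integer, or range
#'   to sample from; default 2).
#' @param complex_min_fragment Minimum fragment length (bp).
#' @param te_library List of [te_library_entry()]; `NULL` draws a default
#'   library (Gypsy/Jockey/Mariner-like) from the seeded RNG.
#' @param n_te_background Number of background TE insertions.
#' @param te_numt_colocation Fraction of background TEs placed within
#'   `te_colocation_window` bp of a planted NUMT (models the shared
#'   preference of TEs and NUMTs for unstable genomic regions).
#' @param te_colocation_window See `te_numt_colocation`.
#' @param n_genes Number of protein-coding genes (2-5 exons each) placed
#'   uniformly without overlap.
#' @param gene_length Gene length range (bp).
#' @param min_spacing Minimum distance (bp) between planted NUMT insertion
#'   points; the default 12000 keeps independent events farther apart than
#'   the 10 kb complex-cluster chaining threshold, so only genuinely
#'   fragmented events form clusters.
#' @param allow_exonic If `TRUE`, insertion points may fall inside exons
#'   (negative-control use only; by default planted NUMTs never interrupt
#'   coding sequence).
#' @return A `sim_config` list, validated.
#' @seealso [simulate_genome()], [write_fixture()]
#' @export
sim_config <- function(seed = 1L,
                       mito_length = 15800L,
                       mito_at = 0.78,
                       n_scaffolds = 4L,
                       scaffold_lengths = rep(250000L, n_scaffolds),
                       nuclear_at = 0.65,
                       n_insertions = 20L,
                       insertion_length = c(100L, 3000L),
                       divergence = list(dist = "uniform", min = 0, max = 0.2),
                       at_site_bias = 1,
                       n_duplications = 0L,
                       dup_flank_carry = 1000L,
                       dup_extra_divergence = 0.02,
                       n_complex = 0L,
                       complex_fragments = 2L,
                       complex_min_fragment = 150L,
                       te_library = NULL,
                       n_te_background = 0L,
                       te_numt_colocation = 0,
                       te_colocation_window = 20000L,
                       n_genes = 0L,
                       gene_length = c(2000L, 8000L),
                       min_spacing = 12000L,
                       allow_exonic = FALSE) {
  cfg <- list(seed = as.integer(seed), mito_length = as.integer(mito_length),
              mito_at = mito_at, n_scaffolds = as.integer(n_scaffolds),
              scaffold_lengths = as.integer(scaffold_lengths),
              nuclear_at = nuclear_at, n_insertions = as.integer(n_insertions),
              insertion_length = as.integer(insertion_length),
              divergence = divergence, at_site_bias = at_site_bias,
              n_duplications = as.integer(n_duplications),
              dup_flank_carry = as.integer(dup_flank_carry),
              dup_extra_divergence = dup_extra_divergence,
              n_complex = as.integer(n_complex),
              complex_fragments = as.integer(complex_fragments),
              complex_min_fragment = as.integer(complex_min_fragment),
              te_library = te_library,
              n_te_background = as.integer(n_te_background),
              te_numt_colocation = te_numt_colocation,
              te_colocation_window = as.integer(te_colocation_window),
              n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              min_spacing = as.integer(min_spacing),
              allow_exonic = isTRUE(allow_exonic))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_scaffolds, cfg$n_insertions, cfg$n_duplications,
              cfg$n_complex, cfg$n_te_background, cfg$n_genes)
  if (any(counts < 0L)) stop("all counts must be >= 0")
  fr <- c(cfg$mito_at, cfg$nuclear_at, cfg$dup_extra_divergence,
          cfg$te_numt_colocation)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (cfg$at_site_bias < 0) stop("at_site_bias must be >= 0")
  if (cfg$mito_length < 1L) stop("mito_length must be positive")
  if (length(cfg$scaffold_lengths) != cfg$n_scaffolds)
    stop("scaffold_lengths must have n_scaffolds entries")
  if (length(cfg$insertion_length) != 2L ||
      cfg$insertion_length[1] > cfg$insertion_length[2] ||
      cfg$insertion_length[1] < 1L)
    stop("insertion_length must be an increasing positive range")
  d <- cfg$divergence
  if (!is.list(d) || is.null(d$dist)) stop("divergence must name a distribution")
  if (identical(d$dist, "uniform")) {
    if (d$min < 0 || d$max > 0.35 || d$min > d$max)
      stop("uniform divergence must satisfy 0 <= min <= max <= 0.35")
  } else if (identical(d$dist, "fixed")) {
    if (d$value < 0 || d$value > 0.35)
      stop("fixed divergence must lie in [0, 0.35]")
  } else stop("divergence$dist must be 'uniform' or 'fixed'")
  if (cfg$insertion_length[2] > cfg$mito_length)
    stop("insertion_length exceeds mito_length")
  if (!is.null(cfg$te_library)) {
    ok <- vapply(cfg$te_library, inherits, logical(1), what = "te_library_entry")
    if (!all(ok)) stop("te_library must be a list of te_library_entry objects")
  }
  # every scaffold must be able to host the largest feature with room to spare
  max_te <- if (is.null(cfg$te_library)) 4000L else
    max(vapply(cfg$te_library, function(e) nchar(e$sequence), integer(1)))
  max_feat <- max(
    cfg$insertion_length[2],
    if (cfg$n_complex > 0L)
      cfg$insertion_length[2] + (max(cfg$complex_fragments)) * max_te else 0L,
    if (cfg$n_duplications > 0L)
      cfg$insertion_length[2] + 2L * cfg$dup_flank_carry else 0L,
    if (cfg$n_genes > 0L) cfg$gene_length[2] else 0L,
    if (cfg$n_te_background > 0L) max_te else 0L)
  if (any(cfg$scaffold_lengths <= 2L * max_feat))
    stop("scaffold_lengths must all exceed twice the largest planted feature (",
         max_feat, " bp)")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_scaffolds, "scaffolds,",
      sum(x$scaffold_lengths), "bp nuclear |", x$mito_length, "bp mito\n")
  cat("  planted:", x$n_insertions, "insertions,", x$n_duplications,
      "duplications,", x$n_complex, "complex events,", x$n_te_background,
      "TEs,", x$n_genes, "genes\n")
  invisible(x)
}
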