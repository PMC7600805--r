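test_that("simulation is byte-identical given the same configuration", {
  cfg <- sim_config(seed = 42, n_scaffolds = 2, scaffold_lengths = rep(40000L, 2),
                    n_insertions = 4, insertion_length = c(150L, 800L),
                    n_genes = 2, gene_length = c(1500L, 3000L),
                    min_spacing = 3000L)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a$mito, b$mito)
  expect_identical(a$nuclear, b$nuclear)
  expect_identical(a$truth, b$truth)
  expect_identical(a$tes, b$tes)
  expect_identical(a$genes, b$genes)

  da <- withr::local_tempdir(); db <- withr::local_tempdir()
  write_fixture(a, da); write_fixture(b, db)
  for (f in c("mito.fa", "nuclear.fa", "genes.gff3", "repeats.out", "truth.tsv"))
    expect_identical(readLines(file.path(da, f)), readLines(file.path(db, f)))
})

test_that("a plant-free genome yields an empty truth table and no hits", {
  cfg <- sim_config(seed = 9, n_scaffolds = 1, scaffold_lengths = 60000L,
                    mito_length = 8000L, n_insertions = 0)
  sim <- simulate_genome(cfg)
  expect_identical(nrow(sim$truth), 0L)
  hits <- filter_hits(scan_numts(sim$mito, sim$nuclear))
  expect_identical(nrow(hits), 0L)
})

test_that("complex events record syntenic fragments separated by the TE length", {
  telib <- list(te_library_entry("Gypsy-4k", "LTR/Gypsy",
                                 local({ set.seed(1); rand_seq(4000, 0.55) })))
  cfg <- sim_config(seed = 21, n_scaffolds = 2, scaffold_lengths = rep(120000L, 2),
                    n_insertions = 0, n_complex = 3,
                    insertion_length = c(600L, 2000L),
                    complex_fragments = 2L, te_library = telib,
                    min_spacing = 12000L)
  sim <- simulate_genome(cfg)
  cids <- unique(sim$truth$cluster_id[!is.na(sim$truth$cluster_id)])
  expect_length(cids, 3L)
  for (cid in cids) {
    fr <- sim$truth[!is.na(sim$truth$cluster_id) & sim$truth$cluster_id == cid, ]
    fr <- fr[order(fr$start), ]
    expect_gte(nrow(fr), 2L)
    expect_length(unique(fr$strand), 1L)
    # inter-fragment gap equals the planted TE insert length
    expect_identical(fr$start[-1] - fr$end[-nrow(fr)], rep(4000L, nrow(fr) - 1L))
    # fragments partition one mitochondrial segment, syntenic with strand
    mi <- fr[order(fr$mito_start), ]
    expect_identical(mi$mito_start[-1], mi$mito_end[-nrow(mi)])
    if (fr$strand[1] == "+") expect_false(is.unsorted(fr$mito_start))
    else expect_false(is.unsorted(rev(fr$mito_start)))
  }
  # the fragmenting TEs are annotated inside the cluster span
  expect_identical(nrow(sim$tes), 3L)
  expect_true(all(sim$tes$superfamily == "LTR/Gypsy"))
})

test_that("planted divergence matches the realized per-site mismatch", {
  cfg <- sim_config(seed = 33, n_scaffolds = 1, scaffold_lengths = 150000L,
                    n_insertions = 10, insertion_length = c(500L, 2000L),
                    divergence = list(dist = "fixed", value = 0.1),
                    min_spacing = 6000L)
  sim <- simulate_genome(cfg)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    nseq <- substr(sim$nuclear[[tr$scaffold]], tr$start + 1, tr$end)
    if (tr$strand == "-") nseq <- rc_oracle(nseq)
    mseq <- substr(sim$mito, tr$mito_start + 1, tr$mito_end)
    obs <- mean(charToRaw(nseq) != charToRaw(mseq))
    len <- tr$end - tr$start
    expect_lt(abs(obs - 0.1), 3 * sqrt(0.1 * 0.9 / len))
  }
})

test_that("AT-biased site selection enriches AT in the immediate flanks", {
  cfg <- sim_config(seed = 77, n_scaffolds = 1, scaffold_lengths = 600000L,
                    n_insertions = 100, insertion_length = c(100L, 200L),
                    at_site_bias = 5, min_spacing = 1500L, nuclear_at = 0.6)
  sim <- simulate_genome(cfg)
  genome_at <- mean(charToRaw(sim$nuclear[[1]]) %in% charToRaw("AT"))
  flank_at <- vapply(seq_len(nrow(sim$truth)), function(i) {
    tr <- sim$truth[i, ]
    s <- sim$nuclear[[tr$scaffold]]
    fl <- paste0(substr(s, tr$start - 9, tr$start),
                 substr(s, tr$end + 1, tr$end + 10))
    mean(charToRaw(fl) %in% charToRaw("AT"))
  }, numeric(1))
  expect_gt(mean(flank_at), genome_at)
  # independent one-sided check against the genome mean
  wt <- stats::wilcox.test(flank_at, mu = genome_at, alternative = "greater")
  expect_lt(wt$p.value, 0.05)
})

test_that("no planted feature crosses a scaffold boundary or an exon", {
  cfg <- sim_config(seed = 13, n_scaffolds = 3, scaffold_lengths = rep(60000L, 3),
                    n_insertions = 6, insertion_length = c(100L, 600L),
                    n_te_background = 5, n_genes = 5,
                    gene_length = c(1500L, 4000L), min_spacing = 2500L)
  sim <- simulate_genome(cfg)
  lens <- nchar(sim$nuclear)
  within <- function(df) {
    all(df$start >= 0L & df$end <= lens[df$scaffold] & df$end > df$start)
  }
  expect_true(within(sim$truth))
  expect_true(within(sim$tes))
  expect_true(within(sim$genes$genes))
  expect_true(within(sim$genes$exons))
  # exons inside their gene, cds inside exons (equal here)
  for (g in seq_len(nrow(sim$genes$genes))) {
    gg <- sim$genes$genes[g, ]
    ex <- sim$genes$exons[sim$genes$exons$gene_id == gg$gene_id, ]
    expect_true(all(ex$start >= gg$start & ex$end <= gg$end))
  }
  # planted NUMTs never interrupt exons (default allow_exonic = FALSE)
  if (nrow(sim$truth) && nrow(sim$genes$exons)) {
    for (i in seq_len(nrow(sim$truth))) {
      tr <- sim$truth[i, ]
      ex <- sim$genes$exons[sim$genes$exons$scaffold == tr$scaffold, ]
      expect_false(any(tr$start < ex$end & tr$end > ex$start))
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_insertions = -1), "counts")
  expect_error(sim_config(mito_at = 1.2), "fractions")
  expect_error(sim_config(at_site_bias = -0.5), "at_site_bias")
  expect_error(sim_config(divergence = list(dist = "uniform", min = 0, max = 0.5)),
               "divergence")
  expect_error(sim_config(n_scaffolds = 1, scaffold_lengths = 4000L,
                          insertion_length = c(100L, 3000L)),
               "scaffold_lengths")
  # legal sizes but impossible spacing: placement gives up after 1000 tries
  cfg <- sim_config(seed = 1, n_scaffolds = 1, scaffold_lengths = 7000L,
                    n_insertions = 10, insertion_length = c(100L, 300L),
                    min_spacing = 3000L)
  expect_error(simulate_genome(cfg), "1000 attempts")
})
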