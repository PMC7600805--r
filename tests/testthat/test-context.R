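test_that("AT profile is exact on constructed sequences", {
  # all-A genome: every window is pure AT
  g1 <- c(s1 = strrep("A", 2000))
  n1 <- data.frame(scaffold = "s1", start = 500L, end = 700L)
  p1 <- at_profile(n1, g1)
  expect_true(all(p1$mean_at == 1))

  # AT flanks and GC-rich interior separate cleanly
  g2 <- c(s1 = paste0(strrep("G", 300), strrep("AT", 125), strrep("G", 200),
                      strrep("AT", 125), strrep("G", 300)))
  numt_start <- 300L + 250L
  numt_end <- numt_start + 200L
  n2 <- data.frame(scaffold = "s1", start = numt_start, end = numt_end)
  p2 <- at_profile(n2, g2)
  expect_true(all(p2$mean_at[p2$region == "upstream"] == 1))
  expect_true(all(p2$mean_at[p2$region == "numt_start"] == 0))
  expect_true(all(p2$mean_at[p2$region == "numt_end"] == 0))
  expect_true(all(p2$mean_at[p2$region == "downstream"] == 1))

  # invariant to input order
  set.seed(4)
  g3 <- c(s1 = rand_seq(5000, 0.6))
  n3 <- data.frame(scaffold = "s1", start = c(1000L, 2500L, 4000L),
                   end = c(1400L, 2900L, 4400L))
  pa <- at_profile(n3, g3)
  pb <- at_profile(n3[c(3, 1, 2), ], g3)
  expect_equal(pa, pb)

  expect_error(at_profile(n3[0, ], g3), "at least one")
})

test_that("flank AT test: degenerate and all-positive exact cases", {
  # uniform genome: all differences are zero -> degenerate, p = 1
  g <- c(s1 = strrep("A", 5000))
  numts <- data.frame(scaffold = "s1",
                      start = seq(500L, 2900L, by = 400L))
  numts$end <- numts$start + 100L
  res <- flank_at_test(numts, g)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)

  # G-rich scaffold with pure-AT pockets at every NUMT flank: all 20
  # differences positive, one-sided exact p = 2^-20
  n <- 20
  starts <- seq(1000L, by = 1000L, length.out = n)
  chars <- rep("G", 40000)
  for (s in starts) {
    chars[(s - 10 + 1):s] <- "A"          # 10 bp upstream flank of start s
    chars[(s + 3):(s + 12)] <- "A"        # 10 bp downstream flank of end s+2
  }
  g2 <- c(s1 = paste(chars, collapse = ""))
  numts2 <- data.frame(scaffold = "s1", start = starts, end = starts + 2L)
  res2 <- flank_at_test(numts2, g2)
  expect_identical(res2$method, "exact")
  expect_equal(res2$p_value, 2^-20)
  expect_lt(res2$p_value, 0.01)
})

test_that("position classification follows CDS > intron > intergenic", {
  gm <- gene_models(
    genes = data.frame(gene_id = c("g1", "g2"), scaffold = "s1",
                       start = c(1000L, 20000L), end = c(9000L, 26000L),
                       strand = "+"),
    exons = data.frame(gene_id = c("g1", "g1", "g2", "g2"), scaffold = "s1",
                       start = c(1000L, 8000L, 20000L, 25000L),
                       end = c(2000L, 9000L, 21000L, 26000L)))
  numts <- data.frame(numt_id = sprintf("n%d", 1:5), scaffold = "s1",
                      start = c(12000L, 3000L, 4000L, 5000L, 1500L),
                      end = c(12400L, 3400L, 4400L, 5400L, 2400L))
  res <- classify_position(numts, gm)
  expect_identical(res$labels$position,
                   c("intergenic", "intronic", "intronic", "intronic", "coding"))
  # three intronic NUMTs in one gene count that gene once
  expect_identical(res$summary$n_genes_hit, 1L)
  expect_identical(res$summary$n_intergenic + res$summary$n_intronic +
                     res$summary$n_cds, 5L)
  expect_equal(res$summary$prop_intergenic + res$summary$prop_intronic +
                 res$summary$prop_cds, 1)
  expect_error(classify_position(numts, gm, scaffold_names = "other"),
               "absent")
})

test_that("density windows tile scaffolds and flatten overlapping annotations", {
  numts <- data.frame(scaffold = "s1", start = 10000L, end = 15000L)
  tes <- data.frame(scaffold = "s1", start = c(0L, 20000L),
                    end = c(30000L, 60000L))
  dt <- density_tracks(numts, tes, c(s1 = 100000L), window = 50000L)
  expect_identical(nrow(dt), 2L)
  expect_equal(dt$numt_coverage, c(0.10, 0))
  # overlapping TEs [0,30k) and [20k,60k) flatten to [0,60k)
  expect_equal(dt$te_coverage, c(1.0, 0.2))
  expect_true(all(dt$numt_coverage >= 0 & dt$numt_coverage <= 1))
  # covered bp summed over windows equals the flattened annotation span
  expect_equal(sum(dt$te_coverage * (dt$win_end - dt$win_start)), 60000)
  # scaffolds without NUMTs are excluded
  dt2 <- density_tracks(numts, tes, c(s1 = 100000L, s2 = 80000L),
                        window = 50000L)
  expect_identical(unique(dt2$scaffold), "s1")
})

test_that("TE vicinity boundary sits exactly at the flank width", {
  scf <- c(s1 = 200000L)
  feat <- data.frame(numt_id = "n1", scaffold = "s1",
                     start = 50000L, end = 51000L)
  te_at <- function(gap) data.frame(scaffold = "s1", start = 51000L + gap,
                                    end = 51000L + gap + 2000L,
                                    te_name = "Gypsy-1",
                                    superfamily = "LTR/Gypsy",
                                    divergence = 1, strand = "+",
                                    stringsAsFactors = FALSE)
  expect_true(te_vicinity(feat, te_at(4999L), scf)$per_feature$has_te)
  expect_false(te_vicinity(feat, te_at(5000L), scf)$per_feature$has_te)
  expect_false(te_vicinity(feat, te_at(5001L), scf)$per_feature$has_te)
  # no TEs annotated at all
  expect_equal(te_vicinity(feat, te_at(0)[0, ], scf)$prop_with_te, 0)
  # interior TEs only count for cluster units
  inner <- data.frame(scaffold = "s1", start = 50200L, end = 50600L,
                      te_name = "Jockey-1", superfamily = "LINE/Jockey",
                      divergence = 1, strand = "+", stringsAsFactors = FALSE)
  expect_false(te_vicinity(feat, inner, scf)$per_feature$has_te)
  vi <- te_vicinity(feat, inner, scf, include_interior = TRUE)
  expect_true(vi$per_feature$has_te)
  expect_identical(vi$per_feature$nearest_superfamily, "LINE/Jockey")
})

test_that("complex clusters fragmented by Gypsy carry interior Gypsy TEs", {
  telib <- list(te_library_entry("Gypsy-sim", "LTR/Gypsy",
                                 local({ set.seed(3); rand_seq(3000, 0.55) })))
  cfg <- sim_config(seed = 41, n_scaffolds = 1, scaffold_lengths = 500000L,
                    n_insertions = 0, n_complex = 6,
                    insertion_length = c(500L, 1500L),
                    complex_fragments = 2L, te_library = telib,
                    min_spacing = 12000L)
  sim <- simulate_genome(cfg)
  recs <- numt_records(filter_hits(scan_numts(sim$mito, sim$nuclear)))
  cl <- cluster_complex(recs)
  spans <- cluster_spans(cl, recs)
  vi <- te_vicinity(spans, sim$tes, vapply(sim$nuclear, nchar, integer(1)),
                    include_interior = TRUE)
  expect_equal(vi$prop_with_te, 1.0)
  expect_identical(names(vi$superfamily_props)[1], "LTR/Gypsy")
})

test_that("co-planted TEs and NUMTs give positively correlated density tracks", {
  telib <- local({ set.seed(6); random_te_library(lengths = c(1500L, 1000L)) })
  cfg <- sim_config(seed = 51, n_scaffolds = 1, scaffold_lengths = 800000L,
                    n_insertions = 16, insertion_length = c(500L, 2000L),
                    n_te_background = 40, te_numt_colocation = 1,
                    te_colocation_window = 15000L, te_library = telib,
                    min_spacing = 30000L)
  sim <- simulate_genome(cfg)
  dt <- density_tracks(sim$truth, sim$tes,
                       vapply(sim$nuclear, nchar, integer(1)),
                       window = 50000L)
  expect_gt(stats::cor(dt$numt_coverage, dt$te_coverage,
                       method = "spearman"), 0)
})
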