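mk_recs <- function(start, end, strand, ms, me, scaffold = "s1",
                    identity = 0.95, evalue = 1e-20) {
  n <- length(start)
  data.frame(numt_id = sprintf("n%02d", seq_len(n)), scaffold = scaffold,
             start = as.integer(start), end = as.integer(end),
             strand = strand, mito_start = as.integer(ms),
             mito_end = as.integer(me), identity = identity, evalue = evalue,
             length = as.integer(end - start), type = "unassigned",
             cluster_id = NA_character_, family_id = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("complex clustering enforces gap, strand and synteny criteria", {
  # two same-strand hits 5 kb apart with advancing mitochondrial intervals
  ok <- mk_recs(c(1000, 6300), c(1300, 6700), c("+", "+"),
                c(100, 900), c(400, 1300))
  cl <- cluster_complex(ok)
  expect_identical(length(unique(cl$cluster_id)), 1L)
  expect_identical(nrow(cl), 2L)
  expect_identical(cl$gap_before[2], 5000L)

  # the same pair 12 kb apart: criterion (1) fails
  far <- mk_recs(c(1000, 13300), c(1300, 13700), c("+", "+"),
                 c(100, 900), c(400, 1300))
  expect_identical(nrow(cluster_complex(far)), 0L)

  # opposite strands: criterion (3) fails
  opp <- mk_recs(c(1000, 6300), c(1300, 6700), c("+", "-"),
                 c(100, 900), c(400, 1300))
  expect_identical(nrow(cluster_complex(opp)), 0L)

  # broken synteny: mitochondrial order reversed on a "+" pair
  bad <- mk_recs(c(1000, 6300), c(1300, 6700), c("+", "+"),
                 c(900, 100), c(1300, 400))
  expect_identical(nrow(cluster_complex(bad)), 0L)

  # minus-strand synteny: mitochondrial coordinates must retreat
  minus <- mk_recs(c(1000, 6300), c(1300, 6700), c("-", "-"),
                   c(900, 100), c(1300, 400))
  expect_identical(length(unique(cluster_complex(minus)$cluster_id)), 1L)

  # unsorted input is rejected
  expect_error(cluster_complex(ok[2:1, ]), "sorted")
})

test_that("re-duplicated fragments with overlapping mitochondrial intervals break chains", {
  # second member re-uses most of the first's mitochondrial interval
  dup <- mk_recs(c(1000, 6300), c(2000, 7300), c("+", "+"),
                 c(100, 150), c(1100, 1150))
  expect_identical(nrow(cluster_complex(dup)), 0L)
})

test_that("planted complex events are reconstructed with membership and order", {
  telib <- local({ set.seed(31); random_te_library(lengths = c(2000L, 5000L)) })
  cfg <- sim_config(seed = 61, n_scaffolds = 2, scaffold_lengths = rep(400000L, 2),
                    n_insertions = 0, n_complex = 5,
                    insertion_length = c(500L, 2500L),
                    divergence = list(dist = "uniform", min = 0, max = 0.08),
                    complex_fragments = 2:3, te_library = telib,
                    min_spacing = 12000L)
  sim <- simulate_genome(cfg)
  recs <- numt_records(filter_hits(scan_numts(sim$mito, sim$nuclear)))
  cl <- cluster_complex(recs)
  truth <- sim$truth
  truth$det <- truth_to_record(truth, recs)
  for (cid in unique(truth$cluster_id)) {
    fr <- truth[!is.na(truth$cluster_id) & truth$cluster_id == cid, ]
    fr <- fr[order(fr$start), ]
    det_cl <- unique(cl$cluster_id[cl$numt_id %in% fr$det])
    expect_length(det_cl, 1L)
    mem <- cl[cl$cluster_id == det_cl, ]
    expect_identical(mem$numt_id[order(mem$member_rank)], fr$det)
  }
})

test_that("shrinking max_gap never increases the number of clustered NUMTs", {
  set.seed(8)
  n <- 15
  starts <- cumsum(sample(c(2000:12000), n))
  recs <- mk_recs(starts, starts + 500, "+",
                  seq(0, by = 600, length.out = n),
                  seq(500, by = 600, length.out = n))
  sizes <- vapply(c(12000L, 10000L, 8000L, 5000L, 2000L), function(g) {
    nrow(cluster_complex(recs, classify_params(max_gap = g)))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("exact duplicated copies with shared flanks form one family", {
  set.seed(91)
  numt <- rand_seq(500, 0.7)
  flank_l <- rand_seq(1000, 0.5)
  flank_r <- rand_seq(1000, 0.5)
  unit <- paste0(flank_l, numt, flank_r)
  genome <- c(s1 = paste0(rand_seq(3000, 0.5), unit, rand_seq(3000, 0.5),
                          unit, rand_seq(3000, 0.5)))
  st <- c(3000 + 1000, 3000 + 2500 + 3000 + 1000)
  recs <- mk_recs(st, st + 500, c("+", "+"), 100, 600, scaffold = "s1")
  fam <- detect_duplicates(recs, genome)
  expect_identical(nrow(fam$families), 2L)
  expect_identical(length(unique(fam$families$family_id)), 1L)
  expect_equal(fam$evidence$left_flank_similarity, 1.0)
  expect_equal(fam$evidence$numt_similarity, 1.0)
})

test_that("similar NUMTs with unrelated flanks are not linked", {
  set.seed(92)
  numt <- rand_seq(500, 0.7)
  numt2 <- mutate_oracle(numt, 0.05)        # ~95% similar body
  genome <- c(s1 = paste0(rand_seq(4000, 0.5), numt, rand_seq(6000, 0.5),
                          numt2, rand_seq(4000, 0.5)))
  st <- c(4000, 4000 + 500 + 6000)
  recs <- mk_recs(st, st + 500, c("+", "+"), 100, 600)
  fam <- detect_duplicates(recs, genome)
  expect_identical(nrow(fam$families), 0L)
})

test_that("duplicate ids are rejected", {
  recs <- mk_recs(c(100, 9000), c(600, 9500), c("+", "+"), 100, 600)
  recs$numt_id <- c("x", "x")
  expect_error(detect_duplicates(recs, c(s1 = rand_seq(10000))), "unique")
})

test_that("families are true connected components of the link graph", {
  set.seed(93)
  # three copies of unit A (one family) and two of unit B, interleaved
  mkunit <- function() paste0(rand_seq(800, 0.5), rand_seq(400, 0.7),
                              rand_seq(800, 0.5))
  uA <- mkunit(); uB <- mkunit()
  parts <- list(rand_seq(2500, 0.5), uA, rand_seq(2500, 0.5), uB,
                rand_seq(2500, 0.5), uA, rand_seq(2500, 0.5), uB,
                rand_seq(2500, 0.5), uA, rand_seq(2500, 0.5))
  genome <- c(s1 = paste(unlist(parts), collapse = ""))
  offs <- cumsum(c(0, nchar(unlist(parts))))
  unit_starts <- offs[c(2, 4, 6, 8, 10)] + 800
  recs <- mk_recs(unit_starts, unit_starts + 400, "+",
                  c(100, 700, 100, 700, 100), c(500, 1100, 500, 1100, 500))
  fam <- detect_duplicates(recs, genome)
  # brute-force components from the reported evidence links
  edges <- fam$evidence[, c("numt_a", "numt_b")]
  adj <- split(c(edges$numt_b, edges$numt_a), c(edges$numt_a, edges$numt_b))
  comp_of <- function(id) {
    seen <- character(0); queue <- id
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% seen) next
      seen <- c(seen, v)
      queue <- c(queue, adj[[v]])
    }
    sort(seen)
  }
  for (f in unique(fam$families$family_id)) {
    mem <- sort(fam$families$numt_id[fam$families$family_id == f])
    expect_identical(comp_of(mem[1]), mem)
  }
  # A-copies and B-copies never share a family
  famA <- fam$families$family_id[fam$families$numt_id %in% c("n01", "n03", "n05")]
  famB <- fam$families$family_id[fam$families$numt_id %in% c("n02", "n04")]
  expect_length(intersect(famA, famB), 0L)
  expect_identical(length(unique(famA)), 1L)
  expect_identical(length(unique(famB)), 1L)
})

test_that("type labelling partitions NUMTs and respects the family original", {
  recs <- mk_recs(c(100, 8000, 16000), c(600, 8500, 16500), "+",
                  100, 600)
  recs$identity <- c(0.99, 0.95, 0.93)
  # no families: everything is insertion type
  lab0 <- label_types(recs, NULL)
  expect_true(all(lab0$type == "insertion"))

  fams <- data.frame(family_id = "fam_001", numt_id = recs$numt_id,
                     stringsAsFactors = FALSE)
  lab <- label_types(recs, fams)
  expect_identical(sum(lab$type == "insertion"), 1L)
  expect_identical(sum(lab$type == "duplicate"), 2L)
  # the most mtDNA-similar member is the putative original
  expect_identical(lab$type[lab$identity == 0.99], "insertion")
  expect_identical(sum(lab$type %in% c("insertion", "duplicate")), nrow(lab))

  labf <- label_types(recs, fams, mode = "family-duplicate")
  expect_identical(sum(labf$type == "duplicate"), 3L)
})

test_that("reported clusters satisfy all three criteria when re-checked", {
  set.seed(12)
  n <- 40
  starts <- cumsum(sample(3000:9000, n, replace = TRUE))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  ms <- sample(0:14000, n)
  recs <- mk_recs(starts, starts + sample(200:800, n, TRUE), strands,
                  ms, ms + sample(200:800, n, TRUE))
  cl <- cluster_complex(recs)
  if (nrow(cl)) {
    for (cid in unique(cl$cluster_id)) {
      mem <- cl[cl$cluster_id == cid, ]
      mem <- mem[order(mem$member_rank), ]
      pos <- recs[match(mem$numt_id, recs$numt_id), ]
      expect_length(unique(pos$strand), 1L)
      expect_true(all(pos$start[-1] - pos$end[-nrow(pos)] < 10000))
      if (pos$strand[1] == "+") expect_false(is.unsorted(pos$mito_start))
      else expect_false(is.unsorted(rev(pos$mito_start)))
    }
  }
})
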