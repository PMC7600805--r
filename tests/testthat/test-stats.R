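test_that("species summaries obey their arithmetic identities", {
  recs <- data.frame(numt_id = c("a", "b", "c"), scaffold = "s1",
                     start = c(0L, 1000L, 2000L),
                     end = c(100L, 1200L, 2300L),
                     type = c("insertion", "insertion", "duplicate"),
                     stringsAsFactors = FALSE)
  s <- summarize_species(recs, genome_size = 1e6)
  expect_identical(s$n_numts, 3L)
  expect_identical(s$total_len, 600L)
  expect_equal(s$pct_genome, 0.06)
  expect_equal(s$mean_len, 200)
  expect_identical(s$n_insertion + s$n_duplicate, s$n_numts)

  z <- summarize_species(recs[0, ], genome_size = 1e6)
  expect_identical(z$n_numts, 0L)
  expect_equal(z$pct_genome, 0)
  expect_error(summarize_species(recs, genome_size = 0), "positive")
})

test_that("PGLS on a star tree reproduces ordinary least squares", {
  set.seed(10)
  n <- 12
  tree <- ape::stree(n, type = "star")
  tree$edge.length <- rep(1, n)
  x <- stats::setNames(rnorm(n), tree$tip.label)
  y <- stats::setNames(2 + 0.7 * x + rnorm(n), tree$tip.label)
  fit <- pgls_fit(y, x, tree)
  ols <- stats::lm(y ~ x)
  sm <- summary(ols)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-12)
  expect_equal(fit$R2, sm$r.squared, tolerance = 1e-12)
  expect_equal(fit$p_value, sm$coefficients[2, 4], tolerance = 1e-12)
})

test_that("an exact linear relationship gives R2 = 1 on any tree", {
  set.seed(11)
  tree <- ape::rtree(8)
  x <- stats::setNames(rnorm(8), tree$tip.label)
  y <- 1.5 + 3 * x
  fit <- pgls_fit(y, x, tree)
  expect_equal(fit$R2, 1, tolerance = 1e-10)
  expect_equal(sum(fit$residuals^2), 0, tolerance = 1e-18)
})

test_that("PGLS estimates match the explicit shared-path-length oracle", {
  set.seed(12)
  tree <- ape::rtree(5)
  x <- stats::setNames(c(1.2, -0.5, 0.3, 2.2, -1.7), tree$tip.label)
  y <- stats::setNames(c(0.7, 0.1, -0.9, 1.8, -2.2), tree$tip.label)
  fit <- pgls_fit(y, x, tree)
  expect_equal(unname(fit$beta), pgls_oracle_beta(y, x, tree),
               tolerance = 1e-10)
})

test_that("PGLS rejects degenerate inputs", {
  tree <- ape::rtree(5)
  tree0 <- tree
  tree0$edge.length[] <- 0
  x <- stats::setNames(rnorm(5), tree$tip.label)
  y <- stats::setNames(rnorm(5), tree$tip.label)
  expect_error(pgls_fit(y, x, tree0), "singular")
  tree2 <- ape::rtree(2)
  expect_error(pgls_fit(y[1:2], x[1:2],
                        structure(tree2, class = "phylo")), "3 tips")
})

test_that("Spearman correlation: monotone, antisymmetric, exact p", {
  x <- c(1, 3, 4, 7, 9, 12)
  y <- x^2
  expect_equal(spearman_cor(x, y)$rho, 1)
  expect_equal(spearman_cor(rev(x), y)$rho, -1)
  set.seed(13)
  for (rep in 1:5) {
    a <- rnorm(8); b <- 0.5 * a + rnorm(8)
    r <- spearman_cor(a, b)
    expect_identical(r$method, "exact permutation")
    expect_equal(r$p_value, brute_spearman(a, b), tolerance = 1e-12)
  }
  # large-n t approximation agrees with the standard implementation
  a <- rnorm(30); b <- 0.4 * a + rnorm(30)
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                         exact = FALSE))
  expect_equal(spearman_cor(a, b)$p_value, ct$p.value, tolerance = 1e-10)
  expect_error(spearman_cor(rep(1, 6), rnorm(6)), "constant")
  expect_error(spearman_cor(1:3, 1:3), "n >= 4")
})

test_that("rank tests match brute-force enumeration for small n", {
  set.seed(14)
  for (rep in 1:6) {
    d <- sample(c(-4:-1, 1:6), 9, replace = TRUE)  # ties likely
    for (alt in c("two.sided", "greater", "less")) {
      r <- rank_test(d, paired = TRUE, alternative = alt)
      expect_identical(r$method, "exact")
      expect_equal(r$p_value, brute_signed_rank(d, alt), tolerance = 1e-12)
    }
    a <- sample(1:12, 5, replace = TRUE)
    b <- sample(1:12, 5, replace = TRUE)
    for (alt in c("two.sided", "greater", "less")) {
      r <- rank_test(a, b, paired = FALSE, alternative = alt)
      expect_equal(r$p_value, brute_ranksum(a, b, alt), tolerance = 1e-12)
    }
  }
})

test_that("rank tests agree with stats::wilcox.test in tie-free cases", {
  set.seed(15)
  d <- rnorm(12)
  r <- rank_test(d, paired = TRUE, alternative = "two.sided")
  w <- stats::wilcox.test(d, alternative = "two.sided", exact = TRUE)
  expect_equal(r$p_value, w$p.value, tolerance = 1e-12)
  a <- rnorm(8); b <- rnorm(9)
  r2 <- rank_test(a, b, paired = FALSE, alternative = "greater")
  w2 <- stats::wilcox.test(a, b, alternative = "greater", exact = TRUE)
  expect_equal(r2$p_value, w2$p.value, tolerance = 1e-12)
  # large samples: normal approximation with continuity correction
  a3 <- rnorm(40); b3 <- rnorm(45) + 0.3
  r3 <- rank_test(a3, b3, paired = FALSE, alternative = "two.sided")
  w3 <- stats::wilcox.test(a3, b3, exact = FALSE, correct = TRUE)
  expect_identical(r3$method, "normal-approx")
  expect_equal(r3$p_value, w3$p.value, tolerance = 1e-10)
})

test_that("rank test edge cases: no effect, complete separation, degeneracy", {
  # identical groups: the statistic sits at the null centre and p is ~1
  a <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  r <- rank_test(a, a, paired = FALSE, alternative = "two.sided")
  expect_gt(r$p_value, 0.9)
  # complete separation: one-sided exact p = 1 / choose(20, 10)
  b <- a + 100
  r2 <- rank_test(b, a, paired = FALSE, alternative = "greater")
  expect_equal(r2$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  # all-zero differences
  r3 <- rank_test(rep(0, 8), paired = TRUE)
  expect_true(r3$degenerate)
  expect_equal(r3$p_value, 1)
  expect_error(rank_test(numeric(0), paired = TRUE), "empty")
  expect_error(rank_test(1:3, numeric(0), paired = FALSE), "non-empty")
})

test_that("binned tables follow the left-closed right-open convention", {
  recs <- data.frame(length = rep(300L, 10), identity = seq(0.71, 0.98,
                                                            length.out = 10))
  bt <- bin_length_similarity(recs)
  expect_equal(bt$length_bins$prop[1], 1)
  expect_identical(sum(bt$length_bins$count), 10L)
  # a value equal to an interior edge falls in the bin starting there
  recs2 <- data.frame(length = c(499, 500, 1000), identity = c(0.8, 0.85, 1.0))
  bt2 <- bin_length_similarity(recs2)
  expect_identical(bt2$length_bins$count[1:3], c(1L, 1L, 1L))
  # identity exactly at the top edge stays in the last bin
  expect_identical(bt2$identity_bins$n[nrow(bt2$identity_bins)], 1L)
  expect_error(bin_length_similarity(recs, length_edges = c(0, 0, 10)),
               "strictly increasing")
  expect_error(bin_length_similarity(
    data.frame(length = 10, identity = 0.5)), "outside")
})
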