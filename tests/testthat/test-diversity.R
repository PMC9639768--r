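test_that("per-site diversity matches the pairwise definition", {
  # n = 4 alleles, j = 2 -> 2*2*2/(4*3) = 2/3
  expect_equal(site_pi(c(1L, 1L)), 2 / 3)
  expect_equal(site_pi(c(0L, 0L, 0L)), 0)
  expect_equal(site_pi(c(1L)), 1)          # n = 2, j = 1
  expect_equal(site_pi(c(0L, NA)), 0)      # one genotype still has 2 alleles
  expect_true(is.na(site_pi(c(NA, NA))))   # < 2 non-missing alleles

  withr::local_seed(101)
  for (i in 1:60) {
    genos <- sample(c(0L, 1L, 2L, NA), sample(2:12, 1), replace = TRUE)
    expect_equal(site_pi(genos), oracle_site_pi(genos))
  }
})

test_that("windowed diversity divides summed site pi by window span", {
  w <- make_windows(10000, 10000)
  # one site with pi = 2/3 in a 10 kb window
  h <- haplotype_matrix(matrix(c(1L, 1L, 0L, 0L), 4, 1), 500L)
  wp <- window_pi(as_gm(h), windows = w)
  expect_equal(wp$pi, (2 / 3) / 10000)
  expect_equal(wp$n_variants, 1L)

  # no variants -> 0
  h0 <- haplotype_matrix(matrix(integer(), 4, 0), integer())
  expect_equal(window_pi(as_gm(h0), windows = w)$pi, 0)

  # two sites with pi = 1 each over span 100
  w2 <- make_windows(100, 100)
  h2 <- haplotype_matrix(matrix(c(0L, 1L, 0L, 1L), 2, 2), c(10L, 20L))
  expect_equal(window_pi(as_gm(h2), windows = w2)$pi, 0.02)

  # oracle: fully sampled window equals total pairwise diffs/(pairs*span)
  withr::local_seed(55)
  for (i in 1:10) {
    h <- random_hapmat(8, 12)
    span <- max(h$positions)
    w <- make_windows(span, span)
    got <- window_pi(as_gm(h), windows = w)$pi
    exp_pi <- sum(vapply(seq_len(12), function(j)
      oracle_site_pi(as_gm(h)$genotypes[, j]), numeric(1))) / span
    expect_equal(got, exp_pi)
  }
})

test_that("log2 diversity ratio handles zeros with sentinels", {
  expect_equal(theta_pi_ratio(3e-3, 3e-3), 0)
  expect_equal(theta_pi_ratio(4e-3, 1e-3), 2)
  expect_equal(theta_pi_ratio(0, 1e-3), -Inf)
  expect_equal(theta_pi_ratio(1e-3, 0), Inf)
  expect_true(is.na(theta_pi_ratio(0, 0)))
  expect_error(theta_pi_ratio(-1, 1), "non-negative")
})

test_that("Weir-Cockerham components give theta = 1 at a fixed difference", {
  a <- matrix(rep(c(0L, 1L), each = 20), 40, 1)
  h <- haplotype_matrix(a, 100L)
  pm <- split_map(h, 10)
  comp <- wc_fst_site(as_gm(h), pm, c("A", "B"))
  expect_equal(comp$theta, 1)
  expect_equal(comp$b, 0)
  expect_equal(comp$c, 0)

  # a population with a single individual is skipped
  h1 <- haplotype_matrix(matrix(c(0L, 1L), 6, 1), 100L)
  pm1 <- split_map(h1, 1)
  expect_true(is.na(wc_fst_site(as_gm(h1), pm1, c("A", "B"))$theta))

  # identical populations: small theta, near zero in expectation
  withr::local_seed(9)
  a2 <- matrix(rbinom(40 * 80, 1L, 0.5), 40, 80)
  h2 <- haplotype_matrix(a2, sort(sample.int(1e5, 80)))
  comp2 <- wc_fst_site(as_gm(h2), split_map(h2, 10), c("A", "B"))
  expect_lt(abs(sum(comp2$a) / sum(comp2$a + comp2$b + comp2$c)), 0.05)
})

test_that("windowed FST is the ratio of sums and matches single-site theta", {
  w <- data.frame(chrom = "1", start = 1L, end = 1000L, window_id = 1L)
  comp <- data.frame(position = c(100L, 200L),
                     a = c(0.2, 0), b = c(0.1, 0.2), c = c(0.1, 0.2))
  wf <- window_fst(comp, w)
  expect_equal(wf$fst, 0.25)  # 0.2 / 0.8, not mean of ratios

  # single-site window equals the per-site theta
  wf1 <- window_fst(comp[1, ], w)
  expect_equal(wf1$fst, 0.2 / 0.4)

  # empty window flagged undefined
  wf0 <- window_fst(comp[0, ], w)
  expect_true(is.na(wf0$fst))
})

test_that("windowed FST is invariant to sample order and population labels", {
  withr::local_seed(31)
  h <- random_hapmat(24, 40)
  pm <- split_map(h, 6)
  w <- make_windows(max(h$positions), 2e4)
  f1 <- window_fst(wc_fst_site(as_gm(h), pm, c("A", "B")), w)$fst
  f2 <- window_fst(wc_fst_site(as_gm(h), pm, c("B", "A")), w)$fst
  expect_equal(f1, f2)
  perm <- sample(length(h$sample_ids))
  hp <- subset_samples(h, h$sample_ids[perm])
  pmp <- pm[match(hp$sample_ids, pm$sample), ]
  f3 <- window_fst(wc_fst_site(as_gm(hp), pmp, c("A", "B")), w)$fst
  expect_equal(f1, f3)
})

test_that("global pairwise FST hits closed-form limits", {
  a <- matrix(rep(c(0L, 1L), each = 20), 40, 5)
  h <- haplotype_matrix(a, c(10L, 20L, 30L, 40L, 50L))
  pm <- split_map(h, 10)
  res <- global_pairwise_fst(as_gm(h), pm)
  expect_equal(res$fst, 1)

  # a panmictic population split in half at random: |FST| < 0.05
  withr::local_seed(17)
  a2 <- matrix(rbinom(40 * 100, 1L, runif(100, 0.2, 0.8)[
    rep(1:100, each = 40)]), 40, 100)
  h2 <- haplotype_matrix(a2, sort(sample.int(1e6, 100)))
  res2 <- global_pairwise_fst(as_gm(h2), split_map(h2, 10))
  expect_lt(abs(res2$fst), 0.05)

  # empty mask -> undefined
  res3 <- global_pairwise_fst(as_gm(h), pm, snp_mask = rep(FALSE, 5))
  expect_true(is.na(res3$fst))
})

test_that("bootstrap FST p-values use the small-B correction and a seed", {
  a <- matrix(rep(c(0L, 1L), each = 10), 20, 6)
  h <- haplotype_matrix(a, c(1L, 5L, 9L, 13L, 17L, 21L) * 10L)
  pm <- split_map(h, 5)
  bt <- bootstrap_fst(as_gm(h), pm, c("A", "B"), n_boot = 100, seed = 4)
  expect_equal(bt$fst, 1)
  expect_equal(bt$p, 1 / 101)  # every replicate is 1 > 0
  expect_equal(bt$ci, c(1, 1))

  bt2 <- bootstrap_fst(as_gm(h), pm, c("A", "B"), n_boot = 100, seed = 4)
  expect_identical(bt$replicates, bt2$replicates)

  # identical populations: not significant
  withr::local_seed(23)
  a3 <- matrix(rbinom(24 * 60, 1L, 0.5), 24, 60)
  h3 <- haplotype_matrix(a3, sort(sample.int(1e5, 60)))
  bt3 <- bootstrap_fst(as_gm(h3), split_map(h3, 6), c("A", "B"),
                       n_boot = 100, seed = 5)
  expect_gt(bt3$p, 0.05)  # not significant
  expect_error(bootstrap_fst(as_gm(h3), split_map(h3, 6), c("A", "B"),
                             n_boot = 0), "n_boot")
})
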