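fake_winstat <- function(fst, ratio) {
  n <- length(fst)
  data.frame(chrom = "1", start = seq(1, by = 1e4, length.out = n),
             end = seq(1e4, by = 1e4, length.out = n),
             window_id = seq_len(n), fst = fst, theta_pi_ratio = ratio)
}

test_that("joint tails select the intersection of the two 5% tails", {
  withr::local_seed(12)
  ws <- fake_winstat(runif(100), runif(100))
  sel <- joint_tail_outliers(ws, 0.95)
  expect_lte(length(sel$fst$window_ids), 6)
  expect_lte(length(sel$theta_pi_ratio$window_ids), 6)
  expect_true(all(sel$joint_ids %in% sel$fst$window_ids))
  expect_true(all(sel$joint_ids %in% sel$theta_pi_ratio$window_ids))
  expect_equal(sel$fst$threshold, unname(quantile(ws$fst, 0.95)))
  # selected set is everything at or above the threshold
  expect_setequal(sel$fst$window_ids,
                  ws$window_id[ws$fst >= sel$fst$threshold])
  # non-finite windows are excluded, not imputed
  ws$theta_pi_ratio[1:5] <- Inf
  sel2 <- joint_tail_outliers(ws, 0.95)
  expect_false(any(1:5 %in% sel2$theta_pi_ratio$window_ids))
  expect_error(joint_tail_outliers(ws[1:10, ]), "fewer than 20")
})

test_that("independent statistics give a joint fraction near alpha^2", {
  withr::local_seed(99)
  fracs <- replicate(40, {
    ws <- fake_winstat(runif(200), runif(200))
    length(joint_tail_outliers(ws, 0.95)$joint_ids) / 200
  })
  # E = 0.0025 with discreteness (10/200 per tail realized); 3 SE band
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.05^2), 3 * se + 0.0005)
})

test_that("Mann-Whitney matches the enumeration oracle and conventions", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$W, 0)
  expect_equal(res$p_two_sided, 0.1)
  expect_true(res$exact)
  orc <- oracle_mw_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$W, orc$W)
  expect_equal(res$p_two_sided, orc$p)

  # identical samples: no shift
  expect_gte(mann_whitney_u(1:5, 1:5)$p_two_sided, 0.99)
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")

  # random small instances vs the full-enumeration oracle (no ties)
  withr::local_seed(77)
  for (i in 1:25) {
    x <- sample(seq(0, 1, length.out = 200), sample(3:7, 1))
    y <- sample(setdiff(seq(0, 1, length.out = 200), x), sample(3:7, 1))
    got <- mann_whitney_u(x, y)
    orc <- oracle_mw_exact(x, y)
    expect_equal(got$W, orc$W)
    expect_equal(got$p_two_sided, orc$p, tolerance = 1e-12)
  }

  # exact vs normal approximation agree within 0.01 at n >= 20
  withr::local_seed(78)
  for (i in 1:10) {
    x <- rnorm(25); y <- rnorm(25, 0.3)
    p_exact <- mann_whitney_u(x, y)$p_two_sided
    p_norm <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(p_exact - p_norm), 0.01)
  }

  # large shifted samples report the tiny-p regime
  big <- mann_whitney_u(rnorm(300), rnorm(300, 3))
  expect_lt(big$p_two_sided, 2.2e-16)
})

test_that("window merging unions overlapping/bookended windows only", {
  w <- data.frame(chrom = "1", start = c(1, 9001), end = c(10000, 19000))
  r <- merge_windows_to_regions(w)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(1, 19000))

  w2 <- data.frame(chrom = "1", start = c(1, 20001), end = c(10000, 30000))
  r2 <- merge_windows_to_regions(w2, max_gap = 0)
  expect_equal(nrow(r2), 2L)

  # chain of 3 overlapping 10 kb windows stepping 9 kb -> 28 kb region
  w3 <- data.frame(chrom = "1", start = c(1, 9001, 18001),
                   end = c(10000, 19000, 28000))
  r3 <- merge_windows_to_regions(w3)
  expect_equal(r3$width, 28000L)
  expect_equal(r3$n_windows, 3L)

  # idempotence
  r3b <- merge_windows_to_regions(r3[, c("chrom", "start", "end")])
  expect_equal(r3b$start, r3$start)
  expect_equal(r3b$end, r3$end)

  # SNPs counted once per region
  sc <- data.frame(position = c(9500, 9600, 25000),
                   p_value = c(1e-8, 1e-8, 1e-8))
  w4 <- data.frame(chrom = "1", start = c(1, 9001), end = c(10000, 19000))
  r4 <- merge_windows_to_regions(w4, scores = sc, p_threshold = 1e-6)
  expect_equal(r4$n_snps, 2L)
  expect_equal(r4$n_outlier_snps, 2L)
})

test_that("region extent equals the interval-union oracle", {
  withr::local_seed(41)
  for (i in 1:20) {
    starts <- sort(sample.int(5e4, 12))
    ends <- starts + sample.int(8e3, 12)
    w <- data.frame(chrom = "1", start = starts, end = ends)
    r <- merge_windows_to_regions(w)
    expect_equal(sum(r$width), oracle_union_extent(starts, ends))
  }
})

test_that("annotation attaches genes on any bp overlap, not abutment", {
  reg <- data.frame(chrom = "1", start = c(1000, 5000), end = c(2000, 6000))
  genes <- data.frame(chrom = "1", start = c(1500, 2001),
                      end = c(5000, 2100),
                      name = c("gA", "gB"), kind = "gene")
  ann <- annotate_regions(reg, genes)
  expect_equal(ann$genes[1], "gA")       # overlap
  expect_equal(ann$genes[2], "gA")       # gene spans into region 2
  expect_false(grepl("gB", ann$genes[1]))  # abuts region 1 ([1..2000] vs 2001)
  expect_setequal(attr(ann, "gene_universe"), "gA")
  # a gene overlapped by two regions appears once per region, once in universe
  expect_equal(sum(grepl("gA", ann$genes)), 2L)
})

test_that("gene-list intersections cover the Venn classes", {
  ix <- intersect_gene_lists(list(A = c("g1", "g2"), B = c("g2", "g3")))
  cls <- setNames(ix$classes$count, ix$classes$class)
  expect_equal(unname(cls["A"]), 1L)
  expect_equal(unname(cls["B"]), 1L)
  expect_equal(unname(cls["A&B"]), 1L)
  expect_equal(ix$full_intersection, "g2")

  # four identical sets: full intersection k, exclusive classes 0
  sets <- rep(list(paste0("g", 1:4)), 4)
  names(sets) <- LETTERS[1:4]
  ix2 <- intersect_gene_lists(sets)
  expect_setequal(ix2$full_intersection, paste0("g", 1:4))
  expect_equal(sum(ix2$classes$count), 4L)
  expect_equal(ix2$classes$count[ix2$classes$class == "A&B&C&D"], 4L)

  # four disjoint sets: empty full intersection is a reachable state
  sets3 <- list(A = "g1", B = "g2", C = "g3", D = "g4")
  ix3 <- intersect_gene_lists(sets3)
  expect_length(ix3$full_intersection, 0)

  expect_error(intersect_gene_lists(list("a", "b")), "named")
  sets6 <- setNames(rep(list(c("x", "y")), 6), LETTERS[1:6])
  expect_warning(ix6 <- intersect_gene_lists(sets6), "pairwise")
  expect_setequal(ix6$full_intersection, c("x", "y"))
})
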