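vcf_lines <- function(records, samples = c("s1", "s2")) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}

rec <- function(pos, ref, alt, ...) {
  paste(c("1", pos, ".", ref, alt, ".", "PASS", ".", "GT", ...),
        collapse = "\t")
}

test_that("phased VCF reading keeps biallelic SNPs, counts drops, errors on unphased", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines(c(rec(100, "A", "C", "0|1", "1|1"),
                         rec(200, "A", "AT", "0|1", "0|0"),   # indel
                         rec(300, "G", "T,C", "0|1", "0|0"),  # multi-allelic
                         rec(400, "G", "T", "0|0", "1|0"),
                         rec(500, "C", "G", ".|.", "0|1"))), f)
  hl <- read_phased_vcf(f)
  expect_equal(attr(hl, "n_dropped"), 2L)
  h <- hl[["1"]]
  expect_equal(dim(h$alleles), c(4L, 3L))
  expect_equal(h$positions, c(100L, 400L, 500L))
  expect_equal(h$alleles[, 1], c(0L, 1L, 1L, 1L))
  expect_true(all(is.na(h$alleles[1:2, 3])))
  expect_equal(h$sample_ids, c("s1", "s2"))

  f2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines(rec(123, "A", "T", "0/1", "0|0")), f2)
  expect_error(read_phased_vcf(f2), "1:123")

  f3 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines(c(rec(100, "A", "T", "0|1", "0|0"),
                         rec(100, "A", "G", "0|1", "0|0"))), f3)
  expect_error(read_phased_vcf(f3), "duplicate position")
})

test_that("VCF round-trip is exact on alleles, positions and sample order", {
  withr::local_seed(42)
  h <- random_hapmat(8, 20, miss_prob = 0.05)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf(h, f)
  h2 <- read_phased_vcf(f)[["1"]]
  expect_identical(unname(h2$alleles), unname(h$alleles))
  expect_identical(h2$positions, h$positions)
  expect_identical(h2$sample_ids, h$sample_ids)
  # byte-identical on rewrite
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf(h2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("empty variant set writes a header-only VCF", {
  h <- haplotype_matrix(matrix(integer(), nrow = 4, ncol = 0), integer())
  f <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf(h, f)
  lines <- readLines(f)
  expect_true(any(startsWith(lines, "#CHROM")))
  expect_false(any(!startsWith(lines, "#")))
})

test_that("haplotype matrix validates its invariants", {
  expect_error(haplotype_matrix(matrix(0L, 4, 2), c(10L, 10L)),
               "strictly increasing")
  expect_error(haplotype_matrix(matrix(2L, 4, 1), 5L), "0, 1 or NA")
  expect_error(haplotype_matrix(matrix(0L, 3, 1), 5L), "even")
  h <- haplotype_matrix(matrix(c(0L, 1L), 2, 3), c(1L, 5L, 9L))
  g <- as_genotype_matrix(h)
  # allele counts conserved when phase is forgotten
  expect_equal(colSums(g$genotypes), colSums(h$alleles))
})

test_that("interval reading normalizes coordinates and names lines in errors", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t2000\tgeneA", "chr2\t0\t500\tgeneB"), bed)
  iv <- read_intervals(bed, "bed")
  expect_equal(iv$start, c(1000L, 1L))
  expect_equal(iv$end, c(2000L, 500L))
  expect_equal(iv$name, c("geneA", "geneB"))

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=g1;Name=geneA"),
             gff)
  gi <- read_intervals(gff, "gff3")
  expect_equal(gi$start, 1000L)
  expect_equal(gi$end, 2000L)
  expect_equal(gi$name, "geneA")

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t500\tok", "chr1\t900\t300\tbad"), bad)
  expect_error(read_intervals(bad, "bed"), "line 2")
  bad2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\tnope", bad2)
  expect_error(read_intervals(bad2, "bed"), "line 1")
})

test_that("BED -> internal -> BED is the identity", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t2000\tgeneA", "chr1\t5000\t5001\tgeneB"), bed)
  iv <- read_intervals(bed, "bed")
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, out)
  expect_identical(readLines(out), readLines(bed))
})

test_that("window tiling covers the chromosome and respects overlaps", {
  w <- make_windows(25000, 10000, 10000)
  expect_equal(w$start, c(1L, 10001L, 20001L))
  expect_equal(w$end, c(10000L, 20000L, 25000L))

  w2 <- make_windows(25000, 10000, 9000)
  expect_equal(w2$start, c(1L, 9001L, 18001L))
  # adjacent windows share exactly 1000 bp
  expect_equal(w2$end[1] - w2$start[2] + 1L, 1000L)

  expect_error(make_windows(1000, 10000, 0), ">= 1")
  expect_error(make_windows(1000, 100, 200), "step")

  # property: step == size partitions [1, L] exactly
  withr::local_seed(1)
  for (i in 1:20) {
    len <- sample.int(1e5, 1) + 10
    size <- sample.int(len, 1)
    w <- make_windows(len, size, size)
    expect_equal(sum(w$end - w$start + 1), len)
    expect_true(all(diff(w$start) == size))
    expect_equal(w$start[-1], w$end[-nrow(w)] + 1L)
  }
})

test_that("population map reading and sample subsetting work", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tA", "s2\tA", "s3\tB"), f)
  m <- read_population_map(f)
  expect_equal(pop_samples(m, "A"), c("s1", "s2"))
  expect_error(pop_samples(m, "Z"), "no samples")

  withr::local_seed(7)
  h <- random_hapmat(6, 5)
  hs <- subset_samples(h, c("S3", "S1"))
  expect_equal(hs$sample_ids, c("S3", "S1"))
  expect_identical(hs$alleles[1:2, ], h$alleles[5:6, ])
  expect_error(subset_samples(h, "nope"), "unknown samples")
})
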