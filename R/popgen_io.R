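#' Phased haplotype matrix
#'
#' Container for phased biallelic SNP data on one chromosome: an integer
#' matrix of alleles (0 = REF, 1 = ALT, NA = missing) with haplotypes in
#' rows (two consecutive rows per diploid sample) and variants in columns.
#'
#' @param alleles integer matrix, haplotypes x variants, values in
#'   \{0, 1, NA\}.
#' @param positions integer vector of 1-based physical positions (bp),
#'   strictly increasing.
#' @param chrom chromosome name.
#' @param sample_ids character vector of sample names; row `2i-1`/`2i`
#'   hold the two phases of sample `i`. Defaults to `S1..Sn`.
#' @param ancestral_is_ref logical scalar or per-variant vector: is the
#'   REF allele the ancestral allele? `NA` = unknown. When no ancestral
#'   annotation exists REF is taken as ancestral (the bundled simulator
#'   emits the true ancestral allele as REF, making this exact).
#' @param ref,alt optional per-variant REF/ALT nucleotides (single bases);
#'   defaults `"A"`/`"T"`, used only when writing VCF.
#' @return An object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(alleles, positions, chrom = "1",
                             sample_ids = NULL, ancestral_is_ref = TRUE,
                             ref = NULL, alt = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.integer(positions)
  if (length(positions) != ncol(alleles))
    stop("positions length must equal the number of variant columns")
  if (ncol(alleles) > 1L && any(diff(positions) <= 0L))
    stop("positions must be strictly increasing")
  ok <- alleles %in% c(0L, 1L) | is.na(alleles)
  if (!all(ok)) stop("alleles must be 0, 1 or NA")
  if (nrow(alleles) %% 2L != 0L)
    stop("haplotype count must be even (two phases per diploid sample)")
  n_samp <- nrow(alleles) / 2L
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n_samp))
  if (length(sample_ids) != n_samp)
    stop("sample_ids length must equal nrow(alleles)/2")
  if (length(ancestral_is_ref) == 1L)
    ancestral_is_ref <- rep(as.logical(ancestral_is_ref), ncol(alleles))
  if (length(ancestral_is_ref) != ncol(alleles))
    stop("ancestral_is_ref must be scalar or one value per variant")
  if (is.null(ref)) ref <- rep("A", ncol(alleles))
  if (is.null(alt)) alt <- rep("T", ncol(alleles))
  structure(
    list(chrom = as.character(chrom), positions = positions,
         alleles = alleles, sample_ids = as.character(sample_ids),
         haplotype_ids = paste0(rep(sample_ids, each = 2L), "_",
                                rep(1:2, n_samp)),
         ancestral_is_ref = ancestral_is_ref,
         ref = as.character(ref), alt = as.character(alt)),
    class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: chrom %s, %d haplotypes (%d samples) x %d variants\n",
              x$chrom, nrow(x$alleles), length(x$sample_ids),
              ncol(x$alleles)))
  invisible(x)
}

#' @export
dim.haplotype_matrix <- function(x) dim(x$alleles)

#' Forget phase: haplotypes to genotype dosages
#'
#' Collapses a [haplotype_matrix] to per-sample ALT-allele dosages
#' (0/1/2); a genotype with either allele missing becomes `NA`. Allele
#' counts are conserved for fully observed genotypes.
#'
#' @param h a `haplotype_matrix`.
#' @return An object of class `genotype_matrix` with fields `chrom`,
#'   `positions`, `genotypes` (samples x variants dosage matrix) and
#'   `sample_ids`.
#' @export
as_genotype_matrix <- function(h) {
  stopifnot(inherits(h, "haplotype_matrix"))
  a1 <- h$alleles[seq(1L, nrow(h$alleles), by = 2L), , drop = FALSE]
  a2 <- h$alleles[seq(2L, nrow(h$alleles), by = 2L), , drop = FALSE]
  g <- a1 + a2
  rownames(g) <- h$sample_ids
  structure(list(chrom = h$chrom, positions = h$positions, genotypes = g,
                 sample_ids = h$sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: chrom %s, %d samples x %d variants\n",
              x$chrom, nrow(x$genotypes), ncol(x$genotypes)))
  invisible(x)
}

#' Subset a haplotype matrix to a set of samples
#'
#' @param h a `haplotype_matrix`.
#' @param samples sample names to keep (order preserved as given).
#' @return A `haplotype_matrix` with the selected samples.
#' @export
subset_samples <- function(h, samples) {
  stopifnot(inherits(h, "haplotype_matrix"))
  idx <- match(samples, h$sample_ids)
  if (anyNA(idx))
    stop("unknown samples: ", paste(samples[is.na(idx)], collapse = ", "))
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  haplotype_matrix(h$alleles[rows, , drop = FALSE], h$positions, h$chrom,
                   sample_ids = samples,
                   ancestral_is_ref = h$ancestral_is_ref,
                   ref = h$ref, alt = h$alt)
}

#' Samples belonging to a population
#'
#' @param pop_map data frame with columns `sample`, `population`.
#' @param population population label.
#' @return Character vector of sample names.
#' @export
pop_samples <- function(pop_map, population) {
  s <- pop_map$sample[pop_map$population == population]
  if (length(s) == 0L) stop("no samples in population ", population)
  s
}

#' Read a sample-to-population map
#'
#' Two-column TSV, `sample<TAB>population`; a header line
#' `sample  population` is tolerated and skipped.
#'
#' @param path file path.
#' @return data frame with columns `sample` and `population`.
#' @export
read_population_map <- function(path) {
  m <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("sample", "population"))
  if (nrow(m) > 0L && identical(tolower(unlist(m[1, ])),
                                c("sample", "population")))
    m <- m[-1, , drop = FALSE]
  rownames(m) <- NULL
  if (anyDuplicated(m$sample))
    stop("duplicate sample in population map")
  m
}

# parse one GT column of "a|b" strings into two allele rows
.parse_gt_phased <- function(gt, chrom, pos) {
  slash <- grepl("/", gt, fixed = TRUE)
  if (any(slash)) {
    k <- which(slash)[1]
    stop(sprintf("unphased genotype '%s' at %s:%d; phased '|' GT required",
                 gt[k], chrom, pos[k]))
  }
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  a1[a1 == "." | a1 == ""] <- NA
  a2[a2 == "." | a2 == ""] <- NA
  rbind(as.integer(a1), as.integer(a2))
}

#' Read phased biallelic SNPs from a VCF
#'
#' Keeps biallelic SNP records only; multi-allelic sites and indels are
#' dropped and counted. Genotypes must be phased (`|` separator); an
#' unphased record is an error naming its CHROM:POS. If the INFO field
#' carries an `AA=` ancestral-allele annotation it sets the per-variant
#' `ancestral_is_ref` flag, otherwise REF is assumed ancestral.
#'
#' @param path VCF file (plain or gzipped).
#' @param require_phased error on `/`-separated genotypes (default TRUE).
#' @return Named list with one [haplotype_matrix] per chromosome, with
#'   attribute `n_dropped` = count of excluded non-SNP/multi-allelic
#'   records.
#' @export
read_phased_vcf <- function(path, require_phased = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(v@fix) == 0L) {
    out <- list()
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !is.na(fix$ALT) & fix$ALT != "." & !grepl(",", fix$ALT, fixed = TRUE)
  n_dropped <- sum(!is_snp)
  gt_all <- vcfR::extract.gt(v)
  samples <- colnames(gt_all)
  fix <- fix[is_snp, , drop = FALSE]
  gt_all <- gt_all[is_snp, , drop = FALSE]
  pos_all <- as.integer(fix$POS)
  out <- list()
  for (chr in unique(fix$CHROM)) {
    sel <- fix$CHROM == chr
    pos <- pos_all[sel]
    if (anyDuplicated(pos))
      stop(sprintf("duplicate position %s:%d", chr,
                   pos[which(duplicated(pos))[1]]))
    o <- order(pos)
    gt <- gt_all[sel, , drop = FALSE][o, , drop = FALSE]
    pos <- pos[o]
    refs <- fix$REF[sel][o]
    alts <- fix$ALT[sel][o]
    info <- fix$INFO[sel][o]
    if (!require_phased) gt <- gsub("/", "|", gt, fixed = TRUE)
    mat <- matrix(NA_integer_, nrow = 2L * length(samples),
                  ncol = length(pos))
    for (s in seq_along(samples)) {
      two <- .parse_gt_phased(gt[, s], chr, pos)
      mat[c(2L * s - 1L, 2L * s), ] <- two
    }
    aa <- rep(TRUE, length(pos))
    has_aa <- !is.na(info) & grepl("AA=", info, fixed = TRUE)
    if (any(has_aa)) {
      anc <- sub(".*AA=([^;]+).*", "\\1", info[has_aa])
      aa[has_aa] <- toupper(anc) == toupper(refs[has_aa])
    }
    out[[chr]] <- haplotype_matrix(mat, pos, chrom = chr,
                                   sample_ids = samples,
                                   ancestral_is_ref = aa,
                                   ref = refs, alt = alts)
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a haplotype matrix as a phased VCF
#'
#' Emits a minimal VCF 4.2 with phased GT fields; missing alleles are
#' written as `.`. Reading the file back with [read_phased_vcf()]
#' reproduces alleles, positions and sample order exactly.
#'
#' @param h a `haplotype_matrix` (or list of them, one per chromosome).
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(h, path) {
  if (inherits(h, "haplotype_matrix")) h <- list(h)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=sweepscan",
               '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  for (hm in h)
    writeLines(sprintf("##contig=<ID=%s,length=%d>", hm$chrom,
                       max(hm$positions, 0L)), con)
  samples <- h[[1]]$sample_ids
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  for (hm in h) {
    if (!identical(hm$sample_ids, samples))
      stop("all chromosomes must share the same samples")
    m <- ncol(hm$alleles)
    if (m == 0L) next
    a <- hm$alleles
    achr <- matrix(as.character(a), nrow = nrow(a))
    achr[is.na(achr)] <- "."
    odd <- seq(1L, nrow(a), by = 2L)
    gt <- matrix(paste0(achr[odd, , drop = FALSE], "|",
                        achr[odd + 1L, , drop = FALSE]),
                 nrow = length(odd))
    anc <- ifelse(is.na(hm$ancestral_is_ref), ".",
                  ifelse(hm$ancestral_is_ref, hm$ref, hm$alt))
    lines <- paste(hm$chrom, hm$positions, ".", hm$ref, hm$alt, ".",
                   "PASS", paste0("AA=", anc), "GT",
                   apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read genomic intervals (BED, GFF3 or TSV)
#'
#' Coordinates are normalized to 1-based inclusive internally: BED
#' half-open 0-based records are shifted, GFF3 and TSV are kept as read.
#' Malformed lines (wrong field count, non-numeric or inverted
#' coordinates) raise an error naming the line number.
#'
#' @param path file path.
#' @param format one of `"bed"`, `"gff3"`, `"tsv"`. The TSV format has a
#'   header and columns `chrom`, `start`, `end`, `name` (and optionally
#'   `kind`).
#' @param kind default record kind (`"gene"`, `"QTL"`, `"other"`).
#' @return data frame (an interval set) with columns `chrom`, `start`,
#'   `end`, `name`, `kind`.
#' @export
read_intervals <- function(path, format = c("bed", "gff3", "tsv"),
                           kind = "gene") {
  format <- match.arg(format)
  raw <- readLines(path)
  body <- which(!grepl("^#", raw) & nzchar(trimws(raw)))
  if (format == "bed") {
    for (i in body) {
      f <- strsplit(raw[i], "\t| +")[[1]]
      if (length(f) < 3L)
        stop(sprintf("malformed BED line %d: fewer than 3 fields", i))
      s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
      if (is.na(s) || is.na(e))
        stop(sprintf("malformed BED line %d: non-numeric coordinates", i))
      if (s >= e)
        stop(sprintf("invalid interval on line %d: start >= end after normalization", i))
    }
    gr <- rtracklayer::import(path, format = "bed")
    nm <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("iv", seq_along(gr))
  } else if (format == "gff3") {
    for (i in body) {
      f <- strsplit(raw[i], "\t")[[1]]
      if (length(f) < 8L)
        stop(sprintf("malformed GFF3 line %d: fewer than 8 fields", i))
      s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
      if (is.na(s) || is.na(e))
        stop(sprintf("malformed GFF3 line %d: non-numeric coordinates", i))
      if (s > e)
        stop(sprintf("invalid interval on line %d: start > end", i))
    }
    gr <- rtracklayer::import(path, format = "gff3")
    nm <- as.character(if (!is.null(gr$Name)) gr$Name else gr$ID)
    nm[is.na(nm)] <- paste0("iv", which(is.na(nm)))
  } else {
    d <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "name")
    if (!all(need %in% names(d)))
      stop("TSV intervals need columns chrom, start, end, name")
    bad <- which(d$start > d$end)
    if (length(bad))
      stop(sprintf("invalid interval on line %d: start > end", bad[1] + 1L))
    out <- data.frame(chrom = as.character(d$chrom),
                      start = as.integer(d$start), end = as.integer(d$end),
                      name = as.character(d$name),
                      kind = if ("kind" %in% names(d)) d$kind else kind,
                      stringsAsFactors = FALSE)
    return(out)
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             name = nm, kind = kind, stringsAsFactors = FALSE)
}

#' Tile a chromosome with (possibly overlapping) windows
#'
#' Windows start at 1 and advance by `step`; the final window is
#' truncated at `chrom_length`. With `step == size` the windows
#' partition `[1, chrom_length]` exactly; with `step < size` adjacent
#' windows overlap by `size - step` bp (e.g. 10 kb windows overlapping
#' by 1 kb use `step = 9000`).
#'
#' @param chrom_length chromosome length in bp.
#' @param size window size in bp.
#' @param step step between window starts in bp (default `size`).
#' @param chrom chromosome name.
#' @return data frame with columns `chrom`, `start`, `end`, `window_id`.
#' @export
make_windows <- function(chrom_length, size, step = size, chrom = "1") {
  if (size < 1 || step < 1) stop("size and step must be >= 1")
  if (step > size) stop("step must not exceed size (windows would leave gaps)")
  starts <- seq(1L, as.integer(chrom_length), by = as.integer(step))
  ends <- pmin(starts + as.integer(size) - 1L, as.integer(chrom_length))
  data.frame(chrom = chrom, start = starts, end = ends,
             window_id = seq_along(starts), stringsAsFactors = FALSE)
}

# map variant positions onto windows; returns IRanges overlap hits
.window_hits <- function(positions, windows) {
  q <- IRanges::IRanges(start = positions, width = 1L)
  s <- IRanges::IRanges(start = windows$start, end = windows$end)
  IRanges::findOverlaps(q, s)
}

#' Export regions or windows as BED
#'
#' Converts internal 1-based inclusive coordinates to BED 0-based
#' half-open.
#'
#' @param x data frame with `chrom`, `start`, `end` (and optionally a
#'   `name` column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  nm <- if ("name" %in% names(x)) x$name else
    paste0("region", seq_len(nrow(x)))
  d <- data.frame(x$chrom, x$start - 1L, x$end, nm)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
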