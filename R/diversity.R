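#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity (average pairwise difference): with
#' `j` copies of the alternate allele among `n` non-missing alleles,
#' `pi = 2 j (n - j) / (n (n - 1))`, the fraction of differing unordered
#' allele pairs. Sites with fewer than two non-missing alleles are `NA`.
#'
#' @param genotype_column integer vector of ALT dosages (0/1/2, NA
#'   missing) for one site, or a matrix (samples x sites) for the
#'   vectorized form.
#' @return Numeric per-site diversity (vector when a matrix is given).
#' @export
site_pi <- function(genotype_column) {
  if (is.matrix(genotype_column)) {
    j <- colSums(genotype_column, na.rm = TRUE)
    n <- 2 * colSums(!is.na(genotype_column))
  } else {
    j <- sum(genotype_column, na.rm = TRUE)
    n <- 2 * sum(!is.na(genotype_column))
  }
  out <- ifelse(n >= 2, 2 * j * (n - j) / (n * pmax(n - 1, 1)), NA_real_)
  unname(out)
}

#' Windowed per-bp nucleotide diversity
#'
#' Sums [site_pi()] over the variant sites in each window and divides by
#' the window span in bp, so invariant positions contribute zero to the
#' numerator and their full length to the denominator (the convention of
#' the standard VCF windowed estimators). Sites with fewer than two
#' non-missing alleles are skipped; the skip count is attached as
#' attribute `n_skipped`.
#'
#' @param g a `genotype_matrix` (see [as_genotype_matrix()]).
#' @param pop_map data frame `sample`/`population`, or NULL to use all
#'   samples.
#' @param population population label (ignored when `pop_map` is NULL).
#' @param windows window table from [make_windows()].
#' @return `windows` with added columns `n_variants` and `pi`.
#' @export
window_pi <- function(g, pop_map = NULL, population = NULL, windows) {
  gm <- g$genotypes
  if (!is.null(pop_map)) {
    keep <- g$sample_ids %in% pop_samples(pop_map, population)
    gm <- gm[keep, , drop = FALSE]
  }
  pi_site <- site_pi(gm)
  usable <- !is.na(pi_site)
  hits <- .window_hits(g$positions[usable], windows)
  win_of <- S4Vectors::subjectHits(hits)
  pi_use <- pi_site[usable][S4Vectors::queryHits(hits)]
  span <- windows$end - windows$start + 1
  sums <- rep(0, nrow(windows))
  cnts <- rep(0L, nrow(windows))
  if (length(win_of)) {
    agg <- rowsum(pi_use, win_of)
    sums[as.integer(rownames(agg))] <- agg[, 1]
    tab <- table(win_of)
    cnts[as.integer(names(tab))] <- as.integer(tab)
  }
  out <- windows
  out$n_variants <- cnts
  out$pi <- sums / span
  attr(out, "n_skipped") <- sum(!usable)
  out
}

#' Log2 diversity ratio
#'
#' `log2(pi_pop / pi_ref)` comparing a population's diversity with the
#' focal population's: large positive values flag diversity loss in the
#' focal population. When only `pi_ref` is zero the result is `+Inf`
#' (flagged, kept out of quantile tails by the callers); when only
#' `pi_pop` is zero, `-Inf`; when both are zero, `NA` (undefined).
#'
#' @param pi_pop diversity of the comparison population (vectorized).
#' @param pi_ref diversity of the focal population.
#' @return Numeric vector of log2 ratios.
#' @export
theta_pi_ratio <- function(pi_pop, pi_ref) {
  if (any(pi_pop < 0 | pi_ref < 0, na.rm = TRUE))
    stop("diversities must be non-negative")
  out <- rep(NA_real_, length(pi_pop))
  both <- !is.na(pi_pop) & !is.na(pi_ref)
  pos <- both & pi_pop > 0 & pi_ref > 0
  out[pos] <- log2(pi_pop[pos] / pi_ref[pos])
  out[both & pi_pop > 0 & pi_ref == 0] <- Inf
  out[both & pi_pop == 0 & pi_ref > 0] <- -Inf
  out
}

# Weir & Cockerham (1984) two-level variance components for r = 2
# populations at each site, computed from sample sizes, allele
# frequencies and observed heterozygosity. Sites where either
# population has < 2 genotyped individuals get NA components.
.wc_components <- function(g1, g2) {
  r <- 2
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  p1 <- colSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- colSums(g2 == 1L, na.rm = TRUE) / n2
  nbar <- (n1 + n2) / r
  C <- n1 + n2
  nc <- (C - (n1^2 + n2^2) / C) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / C
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / C
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c_ <- hbar / 2
  bad <- n1 < 2 | n2 < 2
  a[bad] <- NA_real_; b[bad] <- NA_real_; c_[bad] <- NA_real_
  data.frame(a = a, b = b, c = c_)
}

#' Weir-Cockerham variance components per site
#'
#' The 1984 two-population diploid estimator: `a` (among populations),
#' `b` (among individuals within populations), `c` (within individuals).
#' The per-site estimate is `theta = a / (a + b + c)` where the
#' denominator is positive; monomorphic sites give components (0, 0, 0)
#' and so drop out of any ratio-of-sums. Sites where either population
#' has fewer than two genotyped individuals are returned as `NA`
#' (skipped).
#'
#' @param g a `genotype_matrix`.
#' @param pop_map data frame `sample`/`population`.
#' @param populations character vector of the two population labels.
#' @return data frame with `position`, `a`, `b`, `c` and `theta`.
#' @export
wc_fst_site <- function(g, pop_map, populations) {
  stopifnot(length(populations) == 2L)
  g1 <- g$genotypes[g$sample_ids %in% pop_samples(pop_map, populations[1]), ,
                    drop = FALSE]
  g2 <- g$genotypes[g$sample_ids %in% pop_samples(pop_map, populations[2]), ,
                    drop = FALSE]
  comp <- .wc_components(g1, g2)
  denom <- comp$a + comp$b + comp$c
  comp$theta <- ifelse(!is.na(denom) & denom > 0, comp$a / denom, NA_real_)
  cbind(data.frame(position = g$positions), comp)
}

#' Windowed Weir-Cockerham FST (ratio of sums)
#'
#' Aggregates per-site variance components within each window as
#' `sum(a) / sum(a + b + c)` -- the ratio of sums, not the mean of
#' per-site ratios. Windows whose component sum is zero (no usable
#' polymorphism) are `NA`.
#'
#' @param components output of [wc_fst_site()] (needs `position`, `a`,
#'   `b`, `c`).
#' @param windows window table from [make_windows()].
#' @return `windows` with added columns `n_variants` and `fst`.
#' @export
window_fst <- function(components, windows) {
  ok <- !is.na(components$a)
  comp <- components[ok, , drop = FALSE]
  hits <- .window_hits(comp$position, windows)
  win_of <- S4Vectors::subjectHits(hits)
  qi <- S4Vectors::queryHits(hits)
  num <- rep(0, nrow(windows))
  den <- rep(0, nrow(windows))
  cnts <- rep(0L, nrow(windows))
  if (length(win_of)) {
    agg_a <- rowsum(comp$a[qi], win_of)
    agg_t <- rowsum((comp$a + comp$b + comp$c)[qi], win_of)
    ii <- as.integer(rownames(agg_a))
    num[ii] <- agg_a[, 1]
    den[ii] <- agg_t[, 1]
    tab <- table(win_of)
    cnts[as.integer(names(tab))] <- as.integer(tab)
  }
  out <- windows
  out$n_variants <- cnts
  out$fst <- ifelse(den > 0, num / den, NA_real_)
  out
}

#' Windowed FST / diversity-ratio cross-analysis table
#'
#' One call per population pair: windowed Weir-Cockerham FST between the
#' focal and comparison populations, per-bp diversity for both, and the
#' log2 diversity ratio `log2(pi_comparison / pi_focal)`.
#'
#' @param g a `genotype_matrix`.
#' @param pop_map data frame `sample`/`population`.
#' @param focal focal population label (diversity-loss candidate).
#' @param comparison comparison population label.
#' @param windows window table from [make_windows()].
#' @return Window table with columns `n_variants`, `fst`, `pi_pop`
#'   (comparison), `pi_ref` (focal) and `theta_pi_ratio`.
#' @export
fst_pi_scan <- function(g, pop_map, focal, comparison, windows) {
  comp <- wc_fst_site(g, pop_map, c(comparison, focal))
  wf <- window_fst(comp, windows)
  pp <- window_pi(g, pop_map, comparison, windows)
  pr <- window_pi(g, pop_map, focal, windows)
  out <- wf
  out$pi_pop <- pp$pi
  out$pi_ref <- pr$pi
  out$theta_pi_ratio <- theta_pi_ratio(pp$pi, pr$pi)
  out
}

#' Global pairwise FST over a SNP subset
#'
#' Ratio-of-sums Weir-Cockerham estimate per population pair over an
#' arbitrary variant mask (e.g. synonymous sites). Pairs where either
#' population has fewer than two samples are `NA`. With `n_boot > 0` a
#' site bootstrap adds a p-value and percentile CI per pair (see
#' [bootstrap_fst()]).
#'
#' @param g a `genotype_matrix`.
#' @param pop_map data frame `sample`/`population`.
#' @param snp_mask logical or integer variant index mask; NULL = all.
#' @param populations labels to compare (default: all in `pop_map`).
#' @param n_boot bootstrap replicates (0 = none).
#' @param seed optional RNG seed for the bootstrap.
#' @return data frame with `pop1`, `pop2`, `fst` (and `boot_p`,
#'   `ci_lo`, `ci_hi`, `n_boot` when bootstrapped).
#' @export
global_pairwise_fst <- function(g, pop_map, snp_mask = NULL,
                                populations = NULL, n_boot = 0,
                                seed = NULL) {
  if (is.null(populations)) populations <- unique(pop_map$population)
  idx <- if (is.null(snp_mask)) seq_along(g$positions) else
    seq_along(g$positions)[snp_mask]
  pairs <- utils::combn(populations, 2)
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    p1 <- pairs[1, k]; p2 <- pairs[2, k]
    n1 <- sum(pop_map$population == p1)
    n2 <- sum(pop_map$population == p2)
    if (n1 < 2 || n2 < 2 || length(idx) == 0)
      return(data.frame(pop1 = p1, pop2 = p2, fst = NA_real_))
    comp <- wc_fst_site(g, pop_map, c(p1, p2))[idx, , drop = FALSE]
    ok <- !is.na(comp$a)
    fst <- sum(comp$a[ok]) / sum((comp$a + comp$b + comp$c)[ok])
    out <- data.frame(pop1 = p1, pop2 = p2, fst = fst)
    if (n_boot > 0) {
      bt <- .boot_fst_components(comp[ok, , drop = FALSE], n_boot)
      out$boot_p <- bt$p; out$ci_lo <- bt$ci[1]; out$ci_hi <- bt$ci[2]
      out$n_boot <- n_boot
    }
    out
  })
  do.call(rbind, res)
}

.boot_fst_components <- function(comp, n_boot) {
  m <- nrow(comp)
  tot <- comp$a + comp$b + comp$c
  reps <- vapply(seq_len(n_boot), function(i) {
    ii <- sample.int(m, m, replace = TRUE)
    sum(comp$a[ii]) / sum(tot[ii])
  }, numeric(1))
  list(p = (1 + sum(reps <= 0)) / (n_boot + 1),
       ci = unname(quantile(reps, c(0.025, 0.975), na.rm = TRUE)),
       reps = reps)
}

#' Bootstrap p-value for a pairwise FST
#'
#' Resamples sites with replacement `n_boot` times, recomputing the
#' ratio-of-sums FST; the p-value uses the small-B correction
#' `p = (1 + #\{replicates <= 0\}) / (n_boot + 1)` so it can never be
#' exactly zero, plus a percentile 95\% CI.
#'
#' @param g a `genotype_matrix`.
#' @param pop_map data frame `sample`/`population`.
#' @param pair character vector of two population labels.
#' @param n_boot number of bootstrap replicates (>= 1).
#' @param seed optional RNG seed; fixed seed gives bit-identical output.
#' @param snp_mask optional variant mask as in [global_pairwise_fst()].
#' @return List with `fst`, `p`, `ci` (length 2), `n_boot`, `replicates`.
#' @export
bootstrap_fst <- function(g, pop_map, pair, n_boot = 100, seed = NULL,
                          snp_mask = NULL) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  idx <- if (is.null(snp_mask)) seq_along(g$positions) else
    seq_along(g$positions)[snp_mask]
  comp <- wc_fst_site(g, pop_map, pair)[idx, , drop = FALSE]
  comp <- comp[!is.na(comp$a), , drop = FALSE]
  if (nrow(comp) < 2) stop("need at least 2 usable sites")
  if (!is.null(seed)) set.seed(seed)
  bt <- .boot_fst_components(comp, n_boot)
  list(fst = sum(comp$a) / sum(comp$a + comp$b + comp$c),
       p = bt$p, ci = bt$ci, n_boot = n_boot, replicates = bt$reps)
}
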