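# Independent brute-force oracles and small random fixtures.
# Every oracle enumerates explicitly and shares no code with the package
# implementations it checks.

# random phased haplotype matrix (no missing data unless asked)
random_hapmat <- function(n_hap, n_var, miss_prob = 0, chrom = "1") {
  n_hap <- 2L * ceiling(n_hap / 2)  # diploid pairs
  a <- matrix(rbinom(n_hap * n_var, 1L, runif(1, 0.2, 0.8)),
              nrow = n_hap)
  # resample per-column frequencies for variety
  for (j in seq_len(n_var))
    a[, j] <- rbinom(n_hap, 1L, runif(1, 0.05, 0.95))
  if (miss_prob > 0)
    a[matrix(runif(length(a)) < miss_prob, nrow = n_hap)] <- NA_integer_
  pos <- sort(sample.int(n_var * 1000L, n_var))
  haplotype_matrix(a, pos, chrom = chrom)
}

# average pairwise difference over all unordered allele pairs at a site
oracle_site_pi <- function(genos) {
  alleles <- unlist(lapply(genos[!is.na(genos)], function(g)
    c(as.integer(g >= 1), as.integer(g >= 2))))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diffs <- 0; pairs <- 0
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    pairs <- pairs + 1
    if (alleles[i] != alleles[j]) diffs <- diffs + 1
  }
  diffs / pairs
}

# EHH by hashing extended haplotype strings over the markers strictly
# between the core and x, inclusive of x
oracle_ehh <- function(alleles, core, carriers, x) {
  if (x == core) return(1)
  span <- if (x > core) (core + 1):x else x:(core - 1)
  n <- length(carriers)
  keys <- apply(alleles[carriers, span, drop = FALSE], 1,
                paste, collapse = ",")
  keys <- keys[!grepl("NA", keys)]
  cnt <- table(keys)
  sum(choose(cnt, 2)) / choose(n, 2)
}

# r^2 from the 2x2 haplotype table
oracle_r2 <- function(xi, xj) {
  ok <- !is.na(xi) & !is.na(xj)
  xi <- xi[ok]; xj <- xj[ok]
  n <- length(xi)
  p00 <- sum(xi == 0 & xj == 0) / n
  p1 <- mean(xi); q1 <- mean(xj)
  if (p1 %in% c(0, 1) || q1 %in% c(0, 1)) return(NA_real_)
  D <- p00 - (1 - p1) * (1 - q1)
  D^2 / (p1 * (1 - p1) * q1 * (1 - q1))
}

# exact two-sided Mann-Whitney p by enumerating all C(n1+n2, n1) labelings
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_stat <- function(xx, yy) sum(outer(xx, yy, ">")) +
    0.5 * sum(outer(xx, yy, "=="))
  obs <- u_stat(x, y)
  dev_obs <- abs(obs - n1 * n2 / 2)
  hits <- 0; total <- 0
  for (sel in utils::combn(n1 + n2, n1, simplify = FALSE)) {
    u <- u_stat(pooled[sel], pooled[-sel])
    total <- total + 1
    if (abs(u - n1 * n2 / 2) >= dev_obs - 1e-12) hits <- hits + 1
  }
  list(W = obs, p = hits / total)
}

# total bp covered by a union of intervals (interval arithmetic)
oracle_union_extent <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0; cur_s <- starts[1]; cur_e <- ends[1]
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= cur_e + 1) {
      cur_e <- max(cur_e, ends[k])
    } else {
      tot <- tot + cur_e - cur_s + 1
      cur_s <- starts[k]; cur_e <- ends[k]
    }
  }
  tot + cur_e - cur_s + 1
}

# genotype matrix built directly from a haplotype matrix's rows
as_gm <- function(h) as_genotype_matrix(h)

# small two-population map for a combined matrix
split_map <- function(h, n1) {
  data.frame(sample = h$sample_ids,
             population = rep(c("A", "B"),
                              c(n1, length(h$sample_ids) - n1)))
}
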