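#' Haplotype r-squared between two variants
#'
#' `r2 = D^2 / (p_i (1-p_i) p_j (1-p_j))` with `D = p_ij - p_i p_j`
#' from phased haplotype frequencies, using pairwise-complete
#' haplotypes. Undefined (`NA`) when either variant is monomorphic
#' after missing-data exclusion.
#'
#' @param h a [haplotype_matrix].
#' @param i,j variant column indices.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
haplotype_r2 <- function(h, i, j) {
  xi <- h$alleles[, i]
  xj <- h$alleles[, j]
  ok <- !is.na(xi) & !is.na(xj)
  if (sum(ok) < 2) return(NA_real_)
  xi <- xi[ok]; xj <- xj[ok]
  pi_ <- mean(xi); pj <- mean(xj)
  if (pi_ %in% c(0, 1) || pj %in% c(0, 1)) return(NA_real_)
  D <- mean(xi * xj) - pi_ * pj
  D^2 / (pi_ * (1 - pi_) * pj * (1 - pj))
}

# vectorized r2 for index pairs (no missing data fast path + masked path)
.r2_pairs <- function(A, ii, jj) {
  if (anyNA(A)) {
    Z <- A; Z[is.na(Z)] <- 0L
    M <- !is.na(A)
    n <- colSums(M[, ii, drop = FALSE] * M[, jj, drop = FALSE])
    sij <- colSums(Z[, ii, drop = FALSE] * Z[, jj, drop = FALSE])
    si <- colSums(Z[, ii, drop = FALSE] * M[, jj, drop = FALSE])
    sj <- colSums(Z[, jj, drop = FALSE] * M[, ii, drop = FALSE])
  } else {
    n <- rep(nrow(A), length(ii))
    sij <- colSums(A[, ii, drop = FALSE] * A[, jj, drop = FALSE])
    si <- colSums(A[, ii, drop = FALSE])
    sj <- colSums(A[, jj, drop = FALSE])
  }
  p_i <- si / n; p_j <- sj / n; p_ij <- sij / n
  D <- p_ij - p_i * p_j
  den <- p_i * (1 - p_i) * p_j * (1 - p_j)
  out <- ifelse(n >= 2 & den > 0, D^2 / den, NA_real_)
  unname(out)
}

#' LD-decay profile
#'
#' Mean haplotype r-squared in contiguous physical-distance bins over
#' all intra-chromosomal variant pairs up to `max_distance`. Above
#' `pair_budget` pairs a seeded uniform subsample is used. Bins with no
#' pairs are reported as `NA` (empty), not zero.
#'
#' @param h a [haplotype_matrix].
#' @param pop_map,population optional population restriction.
#' @param bin_size distance bin width in bp (default 10 kb).
#' @param max_distance largest pair distance in bp (default 250 kb).
#' @param pair_budget maximum number of pairs evaluated (default 2e5).
#' @param seed RNG seed for the pair subsample.
#' @return data frame with `bin_start`, `bin_end`, `mean_r2`, `n_pairs`.
#' @export
ld_decay_profile <- function(h, pop_map = NULL, population = NULL,
                             bin_size = 1e4, max_distance = 2.5e5,
                             pair_budget = 2e5, seed = NULL) {
  if (!is.null(pop_map))
    h <- subset_samples(h, pop_samples(pop_map, population))
  if (nrow(h$alleles) < 4) stop("need at least 4 haplotypes")
  pos <- h$positions
  m <- length(pos)
  hi <- findInterval(pos + max_distance, pos)
  cnt <- hi - seq_len(m)
  total <- sum(cnt)
  ii <- rep.int(seq_len(m), cnt)
  jj <- sequence(cnt) + ii
  if (total > pair_budget) {
    if (!is.null(seed)) set.seed(seed)
    keep <- sample.int(total, pair_budget)
    ii <- ii[keep]; jj <- jj[keep]
  }
  d <- pos[jj] - pos[ii]
  r2 <- .r2_pairs(h$alleles, ii, jj)
  ok <- !is.na(r2)
  bin <- pmin(ceiling(d[ok] / bin_size), ceiling(max_distance / bin_size))
  nb <- ceiling(max_distance / bin_size)
  mean_r2 <- rep(NA_real_, nb)
  n_pairs <- rep(0L, nb)
  if (any(ok)) {
    agg <- rowsum(r2[ok], bin)
    tab <- table(bin)
    idx <- as.integer(rownames(agg))
    n_pairs[idx] <- as.integer(tab)
    mean_r2[idx] <- agg[, 1] / as.integer(tab)
  }
  data.frame(bin_start = (seq_len(nb) - 1L) * bin_size,
             bin_end = seq_len(nb) * bin_size,
             mean_r2 = mean_r2, n_pairs = n_pairs)
}

#' Greedy LD pruning
#'
#' PLINK-style `indep-pairwise` pruning: within each window of
#' consecutive variants spanning `window` bp, each pair (in index
#' order) with `r2 > r2_max` loses its lower-minor-allele-frequency
#' member (tie: the later position is removed); the window then slides
#' by `step` variants. Deterministic.
#'
#' @param h a [haplotype_matrix].
#' @param window window span in bp (default 50 kb).
#' @param step slide in number of variants (default 5).
#' @param r2_max r-squared threshold (default 0.5).
#' @return Integer vector of kept variant column indices.
#' @export
ld_prune <- function(h, window = 5e4, step = 5, r2_max = 0.5) {
  A <- h$alleles
  pos <- h$positions
  m <- length(pos)
  if (m == 0) return(integer())
  f <- colMeans(A, na.rm = TRUE)
  maf <- pmin(f, 1 - f)
  keep <- rep(TRUE, m)
  s <- 1L
  while (s <= m) {
    e <- findInterval(pos[s] + window - 1, pos)
    idx <- seq.int(s, e)
    idx <- idx[keep[idx]]
    if (length(idx) >= 2) {
      prs <- utils::combn(idx, 2)
      r2 <- .r2_pairs(A, prs[1, ], prs[2, ])
      for (k in seq_len(ncol(prs))) {
        a <- prs[1, k]; b <- prs[2, k]
        if (!keep[a] || !keep[b]) next
        if (!is.na(r2[k]) && r2[k] > r2_max) {
          drop <- if (maf[a] < maf[b]) a
          else if (maf[b] < maf[a]) b
          else max(a, b)
          keep[drop] <- FALSE
        }
      }
    }
    s <- s + step
  }
  which(keep)
}
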