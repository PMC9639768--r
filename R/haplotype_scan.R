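#' Extended haplotype homozygosity profile from a core SNP
#'
#' EHH at marker `x` is the probability that two randomly drawn carrier
#' haplotypes are identical at every marker between the core and `x`:
#' `EHH(x) = sum_g C(n_g, 2) / C(n, 2)` over classes of extended
#' haplotypes, with the denominator fixed at the initial carrier count
#' `n`, so the profile starts at 1 at the core and is monotone
#' non-increasing outward. Haplotypes hitting a missing allele are
#' dropped from every class (counted as lost). The walk stops at the
#' chromosome ends and at inter-marker gaps larger than `max_gap`.
#'
#' @param h a [haplotype_matrix].
#' @param core_index column index of the core SNP.
#' @param carriers integer row indices of the carrier haplotypes
#'   (same-core-allele carriers for iHS, a whole population for xpEHH);
#'   at least 2.
#' @param max_gap largest tolerated inter-marker gap in bp (default
#'   `Inf`).
#' @return data frame with columns `side` (-1 left / +1 right, 0 core),
#'   `index`, `position`, `distance` (bp from core) and `ehh`, with
#'   attributes `gap_truncated_left`/`_right`.
#' @export
ehh_profile <- function(h, core_index, carriers, max_gap = Inf) {
  A <- h$alleles
  if (length(carriers) < 2)
    stop("need at least 2 carrier haplotypes")
  pos <- h$positions
  one_side <- function(dir) {
    n <- length(carriers)
    ids <- rep(1L, n)
    denom <- n * (n - 1) / 2
    idx <- core_index
    rows <- list()
    truncated <- FALSE
    repeat {
      nidx <- idx + dir
      if (nidx < 1L || nidx > ncol(A)) break
      if (abs(pos[nidx] - pos[idx]) > max_gap) { truncated <- TRUE; break }
      a <- A[carriers, nidx]
      ids[is.na(a)] <- NA_integer_
      key <- ids * 2L + a
      alive <- !is.na(key)
      ids[alive] <- match(key[alive], unique(key[alive]))
      cnt <- tabulate(ids[alive])
      e <- sum(cnt * (cnt - 1) / 2) / denom
      rows[[length(rows) + 1L]] <-
        data.frame(side = dir, index = nidx, position = pos[nidx],
                   distance = abs(pos[nidx] - pos[core_index]), ehh = e)
      if (e == 0) break
      idx <- nidx
    }
    list(df = if (length(rows)) do.call(rbind, rows) else
      data.frame(side = integer(), index = integer(), position = integer(),
                 distance = numeric(), ehh = numeric()),
      truncated = truncated)
  }
  left <- one_side(-1L)
  right <- one_side(+1L)
  core_row <- data.frame(side = 0L, index = core_index,
                         position = pos[core_index], distance = 0,
                         ehh = 1)
  out <- rbind(left$df[rev(seq_len(nrow(left$df))), , drop = FALSE],
               core_row, right$df)
  rownames(out) <- NULL
  attr(out, "gap_truncated_left") <- left$truncated
  attr(out, "gap_truncated_right") <- right$truncated
  out
}

#' Integrate an EHH profile into iHH
#'
#' Trapezoidal integration of EHH over physical distance on each side of
#' the core, truncated by linear interpolation at the first crossing of
#' `cutoff`. If a side ends (chromosome border) while EHH is still at or
#' above the cutoff the result carries `border = TRUE`; callers discard
#' such scores by default. A profile truncated by the gap rule is
#' integrated as far as it goes without the border flag.
#'
#' @param profile output of [ehh_profile()].
#' @param cutoff EHH level at which integration stops (default 0.05).
#' @return List with `ihh`, `ihh_left`, `ihh_right`, `border`.
#' @export
integrate_ihh <- function(profile, cutoff = 0.05) {
  int_side <- function(dir, gap_truncated) {
    side <- profile[profile$side == dir, , drop = FALSE]
    side <- side[order(side$distance), , drop = FALSE]
    d <- c(0, side$distance)
    e <- c(1, side$ehh)
    ihh <- 0
    for (k in seq_along(side$ehh)) {
      if (e[k + 1] < cutoff) {
        x <- d[k] + (e[k] - cutoff) * (d[k + 1] - d[k]) / (e[k] - e[k + 1])
        return(list(ihh = ihh + 0.5 * (e[k] + cutoff) * (x - d[k]),
                    border = FALSE))
      }
      ihh <- ihh + 0.5 * (e[k] + e[k + 1]) * (d[k + 1] - d[k])
    }
    list(ihh = ihh, border = !isTRUE(gap_truncated))
  }
  l <- int_side(-1L, attr(profile, "gap_truncated_left"))
  r <- int_side(+1L, attr(profile, "gap_truncated_right"))
  list(ihh = l$ihh + r$ihh, ihh_left = l$ihh, ihh_right = r$ihh,
       border = l$border || r$border)
}

#' Integrated haplotype score scan
#'
#' For each SNP passing the frequency filter, integrates EHH separately
#' over the carriers of the ancestral and of the derived allele
#' (polarized by the matrix's `ancestral_is_ref` flags) and forms
#' `unihs = ln(iHH_A / iHH_D)`. SNPs with an undefined polarization,
#' fewer than 2 carriers of either allele, a zero iHH, or (by default) a
#' chromosome-border truncation are skipped. With `standardize = TRUE`
#' the scores are bin-standardized by derived-allele frequency
#' ([standardize_ihs()]), which adds `ihs` and two-sided normal
#' p-values.
#'
#' @param h a [haplotype_matrix].
#' @param maf_min minor-allele-frequency filter (default 0.05).
#' @param cutoff EHH integration cutoff (default 0.05).
#' @param max_gap gap truncation in bp (default 200 kb).
#' @param discard_border drop SNPs whose EHH reaches a chromosome end at
#'   or above the cutoff (default TRUE; FALSE keeps the truncated
#'   integral).
#' @param standardize apply [standardize_ihs()] (default TRUE).
#' @param bin_width,min_bin_count passed to [standardize_ihs()].
#' @return data frame of per-SNP scores: `index`, `position`,
#'   `derived_freq`, `ihh_a`, `ihh_d`, `border`, `unihs` (and `ihs`,
#'   `p_value`, `log10_p` if standardized).
#' @export
ihs_scan <- function(h, maf_min = 0.05, cutoff = 0.05, max_gap = 2e5,
                     discard_border = TRUE, standardize = TRUE,
                     bin_width = 0.025, min_bin_count = 10) {
  anc <- ifelse(is.na(h$ancestral_is_ref), NA_integer_,
                ifelse(h$ancestral_is_ref, 0L, 1L))
  sc <- .scan_ihh_cpp(h$alleles, h$positions, anc, maf_min, cutoff,
                      max_gap, 2L)
  sc$border <- as.logical(sc$border)
  if (discard_border) sc <- sc[!sc$border, , drop = FALSE]
  sc <- sc[sc$ihh_a > 0 & sc$ihh_d > 0, , drop = FALSE]
  if (nrow(sc) == 0) {
    warning("no qualifying SNPs for iHS")
    sc$unihs <- numeric(0)
    return(sc)
  }
  sc$unihs <- log(sc$ihh_a / sc$ihh_d)
  rownames(sc) <- NULL
  if (standardize)
    sc <- standardize_ihs(sc, bin_width = bin_width,
                          min_bin_count = min_bin_count)
  sc
}

#' Standardize iHS scores within derived-allele-frequency bins
#'
#' Within each frequency bin (width `bin_width` on the derived-allele
#' frequency; bins holding fewer than `min_bin_count` SNPs are merged
#' with their neighbor toward 0.5), the unstandardized scores are
#' centered and scaled to mean 0 / sd 1. The two-sided p-value
#' `p = 2 (1 - Phi(|ihs|))` treats the standardized score as a standard
#' normal under neutrality.
#'
#' @param scores data frame with `unihs` and `derived_freq` columns.
#' @param bin_width frequency bin width (default 0.025).
#' @param min_bin_count minimum SNPs per bin before merging (default 10).
#' @return `scores` with added `ihs`, `p_value` and `log10_p` columns.
#' @export
standardize_ihs <- function(scores, bin_width = 0.025, min_bin_count = 10) {
  edges <- seq(0, 1, by = bin_width)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  bin <- findInterval(scores$derived_freq, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  # merge sparse bins toward the interior (toward frequency 0.5)
  centers <- (edges[-length(edges)] + edges[-1]) / 2
  repeat {
    ids <- sort(unique(bin))
    cnt <- table(factor(bin, levels = ids))
    sparse <- ids[cnt < min_bin_count]
    if (length(sparse) == 0 || length(ids) == 1) break
    b <- sparse[1]
    k <- which(ids == b)
    target <- if (centers[b] < 0.5) {
      if (k < length(ids)) ids[k + 1] else ids[k - 1]
    } else {
      if (k > 1) ids[k - 1] else ids[k + 1]
    }
    bin[bin == b] <- target
  }
  mu <- tapply(scores$unihs, bin, mean)
  sig <- tapply(scores$unihs, bin, sd)
  key <- as.character(bin)
  s <- sig[key]
  if (any(is.na(s) | s == 0)) {
    warning("bin with zero variance; scores undefined there")
    s[s == 0] <- NA_real_
  }
  scores$ihs <- (scores$unihs - mu[key]) / s
  scores$p_value <- 2 * pnorm(-abs(scores$ihs))
  scores$log10_p <- -log10(scores$p_value)
  rownames(scores) <- NULL
  scores
}

#' Cross-population EHH scan (xpEHH)
#'
#' For each SNP shared by the two populations' matrices (which must be
#' on the same variant grid), EHH is computed over all haplotypes of
#' each population (allele-agnostic: the partition starts as a single
#' class at the core). Both profiles are followed outward until both
#' fall below `cutoff`; each population's profile is integrated to the
#' shared stopping extent (the farther of the two interpolated cutoff
#' crossings), giving comparable integrals. The score
#' `unxpehh = ln(iHH_1 / iHH_2)` is positive when haplotypes are longer
#' (selection) in `h1`; it is standardized genome-wide to mean 0 / sd 1
#' with two-sided normal p-values.
#'
#' @param h1,h2 [haplotype_matrix] objects on identical positions
#'   (population 1 = the focal population).
#' @param maf_min minor-allele-frequency filter on the pooled frequency
#'   (default 0.05).
#' @param cutoff EHH cutoff (default 0.05).
#' @param max_gap gap truncation in bp (default 200 kb).
#' @param standardize standardize genome-wide and add p-values (default
#'   TRUE).
#' @return data frame with `index`, `position`, `ihh1`, `ihh2`,
#'   `unxpehh` (and `xpehh`, `p_value`, `log10_p` if standardized).
#' @export
xpehh_scan <- function(h1, h2, maf_min = 0.05, cutoff = 0.05,
                       max_gap = 2e5, standardize = TRUE) {
  if (!identical(h1$positions, h2$positions))
    stop("populations must share the same variant grid")
  pooled <- rbind(h1$alleles, h2$alleles)
  f <- colMeans(pooled, na.rm = TRUE)
  maf <- pmin(f, 1 - f)
  cores <- which(!is.na(maf) & maf >= maf_min)
  if (length(cores) == 0) {
    warning("no qualifying SNPs for xpEHH")
    return(data.frame(index = integer(), position = numeric(),
                      ihh1 = numeric(), ihh2 = numeric(),
                      unxpehh = numeric()))
  }
  sc <- .scan_xpehh_cpp(h1$alleles, h2$alleles, h1$positions,
                        as.integer(cores), cutoff, max_gap)
  sc$border <- as.logical(sc$border)
  sc <- sc[!sc$border & sc$ihh1 > 0 & sc$ihh2 > 0, , drop = FALSE]
  sc$border <- NULL
  sc$unxpehh <- log(sc$ihh1 / sc$ihh2)
  rownames(sc) <- NULL
  if (standardize && nrow(sc) > 1) {
    sc$xpehh <- (sc$unxpehh - mean(sc$unxpehh)) / sd(sc$unxpehh)
    sc$p_value <- 2 * pnorm(-abs(sc$xpehh))
    sc$log10_p <- -log10(sc$p_value)
  }
  sc
}

#' Call outlier windows from per-SNP scan p-values
#'
#' A window is a candidate when at least `min_snps` of its SNPs have
#' `p_value < p_threshold` (the scan thresholds used for selection
#' candidates: iHS `1e-6` with a minimum of 2 SNPs, xpEHH `1e-4` with a
#' minimum of 5, on 10 kb windows overlapping by 1 kb). SNPs falling in
#' several overlapping windows count in each; deduplication happens at
#' region merging.
#'
#' @param scores data frame with `position` and `p_value`.
#' @param windows window table from [make_windows()].
#' @param p_threshold p-value threshold.
#' @param min_snps minimum below-threshold SNPs per candidate window.
#' @return `windows` with `n_snps_total`, `n_snps_outlier`,
#'   `is_candidate`.
#' @export
call_outlier_windows <- function(scores, windows, p_threshold, min_snps) {
  hits <- .window_hits(scores$position, windows)
  win_of <- S4Vectors::subjectHits(hits)
  out_flag <- (scores$p_value < p_threshold)[S4Vectors::queryHits(hits)]
  n_tot <- rep(0L, nrow(windows))
  n_out <- rep(0L, nrow(windows))
  if (length(win_of)) {
    tab <- table(win_of)
    n_tot[as.integer(names(tab))] <- as.integer(tab)
    agg <- rowsum(as.integer(out_flag), win_of)
    n_out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out <- windows
  out$n_snps_total <- n_tot
  out$n_snps_outlier <- n_out
  out$is_candidate <- n_out >= min_snps
  out
}
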