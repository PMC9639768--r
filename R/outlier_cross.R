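#' Joint right-tail selection of FST and diversity-ratio windows
#'
#' Computes the empirical quantile threshold (linear-interpolation
#' quantile, R type 7) of windowed FST and of the log2 diversity ratio
#' over all windows where both are defined (finite), selects each
#' statistic's right tail, and intersects the two tails: windows
#' simultaneously in the top `1 - quantile` of genetic differentiation
#' and of focal-population diversity loss are the divergent-selection
#' candidates. Windows with undefined (non-finite) values are excluded,
#' not imputed.
#'
#' @param winstat window table from [fst_pi_scan()] (needs `fst` and
#'   `theta_pi_ratio`).
#' @param quantile right-tail quantile (default 0.95 = 5\% tail).
#' @return List with per-statistic selections (`statistic`, `quantile`,
#'   `threshold`, `window_ids`), `joint_ids` and the joint window table
#'   `joint`.
#' @export
joint_tail_outliers <- function(winstat, quantile = 0.95) {
  defined <- is.finite(winstat$fst) & is.finite(winstat$theta_pi_ratio)
  if (sum(defined) < 20)
    stop("fewer than 20 windows with defined statistics; quantile thresholds are meaningless")
  d <- winstat[defined, , drop = FALSE]
  thr_fst <- unname(stats::quantile(d$fst, quantile, type = 7))
  thr_ratio <- unname(stats::quantile(d$theta_pi_ratio, quantile, type = 7))
  sel_fst <- d$window_id[d$fst >= thr_fst]
  sel_ratio <- d$window_id[d$theta_pi_ratio >= thr_ratio]
  joint <- intersect(sel_fst, sel_ratio)
  list(fst = list(statistic = "fst", quantile = quantile,
                  threshold = thr_fst, window_ids = sel_fst),
       theta_pi_ratio = list(statistic = "theta_pi_ratio",
                             quantile = quantile, threshold = thr_ratio,
                             window_ids = sel_ratio),
       joint_ids = joint,
       joint = winstat[winstat$window_id %in% joint, , drop = FALSE],
       n_defined = sum(defined))
}

#' Mann-Whitney U test (outlier windows vs genomic background)
#'
#' Two-sided rank-sum test in the R `wilcox.test` convention
#' (`W = #\{pairs with x > y\} + #ties / 2`). The exact-enumeration
#' p-value is used when `n_x * n_y <= 10000` and there are no ties;
#' otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param outlier_values statistic values in the outlier windows.
#' @param background_values statistic values in the background (by the
#'   published convention the whole genome including the outliers).
#' @return List with `W`, `p_two_sided`, `exact`, `n_outlier`,
#'   `n_background`.
#' @export
mann_whitney_u <- function(outlier_values, background_values) {
  x <- outlier_values[!is.na(outlier_values)]
  y <- background_values[!is.na(background_values)]
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (as.double(length(x)) * length(y) <= 10000) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  list(W = unname(wt$statistic), p_two_sided = wt$p.value, exact = exact,
       n_outlier = length(x), n_background = length(y))
}

#' Merge candidate windows into non-overlapping regions
#'
#' Overlapping or bookended windows (inter-window gap `<= max_gap` bp)
#' are unioned per chromosome; merging is idempotent. When per-SNP
#' scores are supplied, SNPs are counted once per region regardless of
#' how many source windows contained them.
#'
#' @param windows candidate windows (rows of a window table; needs
#'   `chrom`, `start`, `end`).
#' @param max_gap largest gap (bp) between windows still merged
#'   (default 0: only overlapping/bookended windows).
#' @param scores optional per-SNP data frame with `position` (and
#'   `p_value`) for SNP counts.
#' @param p_threshold threshold used for `n_outlier_snps` when `scores`
#'   has p-values.
#' @return data frame of regions: `chrom`, `start`, `end`, `width`,
#'   `n_windows` (and `n_snps`, `n_outlier_snps` with scores).
#' @export
merge_windows_to_regions <- function(windows, max_gap = 0, scores = NULL,
                                     p_threshold = NULL) {
  if (nrow(windows) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), width = integer(),
                      n_windows = integer()))
  out <- lapply(split(windows, windows$chrom), function(w) {
    ir <- IRanges::IRanges(start = w$start, end = w$end)
    red <- IRanges::reduce(ir, min.gapwidth = max_gap + 1)
    hit <- IRanges::findOverlaps(ir, red)
    nw <- tabulate(S4Vectors::subjectHits(hit), length(red))
    data.frame(chrom = w$chrom[1], start = IRanges::start(red),
               end = IRanges::end(red), width = IRanges::width(red),
               n_windows = nw, stringsAsFactors = FALSE)
  })
  reg <- do.call(rbind, out)
  rownames(reg) <- NULL
  reg <- reg[order(reg$chrom, reg$start), , drop = FALSE]
  if (!is.null(scores)) {
    ir <- IRanges::IRanges(start = reg$start, end = reg$end)
    q <- IRanges::IRanges(start = scores$position, width = 1L)
    hit <- IRanges::findOverlaps(q, ir)
    reg$n_snps <- tabulate(S4Vectors::subjectHits(hit), nrow(reg))
    if (!is.null(p_threshold) && "p_value" %in% names(scores)) {
      flag <- scores$p_value[S4Vectors::queryHits(hit)] < p_threshold
      reg$n_outlier_snps <- as.integer(
        rowsum(as.integer(flag), S4Vectors::subjectHits(hit))[
          match(seq_len(nrow(reg)),
                sort(unique(S4Vectors::subjectHits(hit)))), 1])
      reg$n_outlier_snps[is.na(reg$n_outlier_snps)] <- 0L
    }
  }
  rownames(reg) <- NULL
  reg
}

#' Annotate candidate regions with overlapping intervals
#'
#' Any shared bp counts as overlap (abutting intervals do not). Gene
#' and QTL names are attached per region as comma-separated lists; the
#' union of genes hit by any region (the source's gene universe, used
#' for cross-comparison intersections) is attached as attribute
#' `gene_universe`.
#'
#' @param regions region table from [merge_windows_to_regions()].
#' @param genes,qtls interval sets from [read_intervals()] (or NULL).
#' @return `regions` with added `genes`, `n_genes`, `qtls` columns.
#' @export
annotate_regions <- function(regions, genes = NULL, qtls = NULL) {
  hit_names <- function(iv) {
    if (is.null(iv) || nrow(regions) == 0)
      return(list(per = rep("", nrow(regions)), all = character()))
    rg <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start, regions$end))
    gg <- GenomicRanges::GRanges(iv$chrom,
                                 IRanges::IRanges(iv$start, iv$end))
    hit <- GenomicRanges::findOverlaps(rg, gg)
    per <- vapply(seq_len(nrow(regions)), function(i) {
      nm <- iv$name[S4Vectors::subjectHits(hit)[S4Vectors::queryHits(hit) == i]]
      paste(unique(nm), collapse = ",")
    }, character(1))
    list(per = per,
         all = unique(iv$name[unique(S4Vectors::subjectHits(hit))]))
  }
  gh <- hit_names(genes)
  qh <- hit_names(qtls)
  regions$genes <- gh$per
  regions$n_genes <- ifelse(gh$per == "", 0L,
                            lengths(strsplit(gh$per, ",")))
  regions$qtls <- qh$per
  attr(regions, "gene_universe") <- gh$all
  regions
}

#' Intersection classes of named gene sets
#'
#' For 2-5 named sets, counts every non-empty exclusive intersection
#' class (the 2^n - 1 Venn classes) and returns the members of the full
#' intersection. With more than 5 sets only pairwise intersection counts
#' and the full intersection are reported.
#'
#' @param sets named list of character vectors.
#' @return List with `classes` (data frame `class`, `count`),
#'   `full_intersection` (character vector) and, for > 5 sets,
#'   `pairwise` counts instead of full classes.
#' @export
intersect_gene_lists <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  if (length(sets) < 2) stop("need at least 2 sets")
  sets <- lapply(sets, unique)
  full <- Reduce(intersect, sets)
  if (length(sets) > 5) {
    warning("more than 5 sets: reporting pairwise and full intersections only")
    pr <- utils::combn(names(sets), 2)
    pw <- data.frame(set1 = pr[1, ], set2 = pr[2, ],
                     count = apply(pr, 2, function(p)
                       length(intersect(sets[[p[1]]], sets[[p[2]]]))))
    return(list(pairwise = pw, full_intersection = full))
  }
  genes <- unique(unlist(sets))
  memb <- vapply(sets, function(s) genes %in% s,
                 logical(length(genes)))
  if (length(genes) == 1) memb <- matrix(memb, nrow = 1,
                                         dimnames = list(NULL, names(sets)))
  lab <- apply(memb, 1, function(m) paste(names(sets)[m], collapse = "&"))
  n <- length(sets)
  combos <- unlist(lapply(seq_len(n), function(k)
    utils::combn(names(sets), k, paste, collapse = "&")))
  cnt <- table(factor(lab, levels = combos))
  list(classes = data.frame(class = names(cnt),
                            count = as.integer(cnt),
                            stringsAsFactors = FALSE),
       full_intersection = full)
}
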