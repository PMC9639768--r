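#' Build a run configuration
#'
#' Declarative configuration for [run_pipeline()]. Either a `simulate`
#' block ([sim_config()] arguments) or an `input` block
#' (`vcf`, `sample_map`, optional `genes`/`qtls` interval files) must be
#' given. Analysis defaults follow the published procedure: 10 kb
#' FST/diversity windows stepping by their size, 10 kb haplotype-scan
#' windows overlapping by 1 kb (step 9 kb), joint 5\% right tails, iHS
#' threshold `1e-6` with >= 2 SNPs per window, xpEHH threshold `1e-4`
#' with >= 5 SNPs.
#'
#' @param focal focal population label.
#' @param comparisons comparison population labels.
#' @param simulate list of [sim_config()] arguments, or NULL.
#' @param input list with `vcf`, `sample_map`, optional `genes`, `qtls`
#'   paths, or NULL.
#' @param fstpi_window,fstpi_step FST/diversity window size/step (bp).
#' @param scan_window,scan_step haplotype-scan window size/step (bp).
#' @param tail_quantile joint-tail quantile.
#' @param ihs_p,ihs_min_snps iHS outlier-window rule.
#' @param xpehh_p,xpehh_min_snps xpEHH outlier-window rule.
#' @param max_gap region-merge gap (bp).
#' @param ld_bin,ld_max_dist LD-decay profile parameters (bp).
#' @param seed RNG seed for the whole run.
#' @return A `run_config` list.
#' @export
run_config <- function(focal, comparisons, simulate = NULL, input = NULL,
                       fstpi_window = 1e4, fstpi_step = 1e4,
                       scan_window = 1e4, scan_step = 9e3,
                       tail_quantile = 0.95, ihs_p = 1e-6,
                       ihs_min_snps = 2, xpehh_p = 1e-4,
                       xpehh_min_snps = 5, max_gap = 0, ld_bin = 1e4,
                       ld_max_dist = 2.5e5, seed = 1L) {
  if (is.null(simulate) && is.null(input))
    stop("either a simulate block or an input block is required")
  stopifnot(tail_quantile > 0, tail_quantile < 1, ihs_p > 0, ihs_p < 1,
            xpehh_p > 0, xpehh_p < 1)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [run_config()]; the `simulate`
#' and `input` blocks are nested maps.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

.log_line <- function(log, fmt, ...) c(log, sprintf(fmt, ...))

#' Run the full selection-signature pipeline
#'
#' Orchestrates simulate-or-load, the per-pair windowed FST/diversity
#' cross analysis (joint 5\% tails, Mann-Whitney validation, region
#' merging, annotation), the within-focal-population iHS scan, the
#' per-pair xpEHH scans, gene-list intersections across comparisons,
#' and LD-decay profiles, writing per-pair window tables, region
#' BED/TSV files, summary tables and a run log of every realized
#' threshold. Deterministic given the config seed; `threads` is
#' accepted for interface compatibility and never changes results (all
#' computation is single-threaded).
#'
#' @param config a `run_config` (or path to a YAML file).
#' @param out_dir output directory.
#' @param seed optional override of the config seed.
#' @param threads ignored (results are independent of thread count).
#' @return Invisibly, a list with all intermediate and summary objects.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, threads = 1L) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # ---- load or simulate ----------------------------------------------
  genes <- NULL; qtls <- NULL; truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    sim <- stage("simulate", simulate_wf(do.call(sim_config, sim_args)))
    h_all <- sim$combined
    pop_map <- sim$population_map
    truth <- sim$truth
    bundle <- stage("simulate", emit_truth_bundle(
      sim, file.path(out_dir, "sim")))
    genes <- read_intervals(bundle$genes, "bed", kind = "gene")
    qtls <- read_intervals(bundle$qtls, "tsv", kind = "QTL")
    log <- .log_line(log, "simulated %d variants (seed %d, %d restarts)",
                     length(h_all$positions), config$seed,
                     sim$truth$restarts)
  } else {
    inp <- config$input
    hl <- stage("load", read_phased_vcf(inp$vcf))
    if (length(hl) != 1)
      stop("multi-chromosome input: run per chromosome")
    h_all <- hl[[1]]
    pop_map <- stage("load", read_population_map(inp$sample_map))
    if (!is.null(inp$genes))
      genes <- read_intervals(inp$genes, "bed", kind = "gene")
    if (!is.null(inp$qtls))
      qtls <- read_intervals(inp$qtls, "tsv", kind = "QTL")
  }
  if (!config$focal %in% pop_map$population)
    stop(sprintf("focal population '%s' not present in the sample map",
                 config$focal))
  missing_cmp <- setdiff(config$comparisons, pop_map$population)
  if (length(missing_cmp))
    stop("unknown comparison population(s): ",
         paste(missing_cmp, collapse = ", "))

  chrom_len <- max(h_all$positions)
  g_all <- as_genotype_matrix(h_all)
  win_fstpi <- make_windows(chrom_len, config$fstpi_window,
                            config$fstpi_step, chrom = h_all$chrom)
  win_scan <- make_windows(chrom_len, config$scan_window,
                           config$scan_step, chrom = h_all$chrom)
  h_focal <- subset_samples(h_all, pop_samples(pop_map, config$focal))

  # ---- per-pair FST/pi cross analysis --------------------------------
  fstpi <- list(); table1 <- list(); xp_regions <- list()
  for (cmp in config$comparisons) {
    ws <- stage("scan-fstpi",
                fst_pi_scan(g_all, pop_map, config$focal, cmp, win_fstpi))
    tails <- stage("scan-fstpi",
                   joint_tail_outliers(ws, config$tail_quantile))
    def <- is.finite(ws$fst) & is.finite(ws$theta_pi_ratio)
    if (length(tails$joint_ids)) {
      mw_fst <- mann_whitney_u(ws$fst[ws$window_id %in% tails$joint_ids],
                               ws$fst[def])
      mw_ratio <- mann_whitney_u(
        ws$theta_pi_ratio[ws$window_id %in% tails$joint_ids],
        ws$theta_pi_ratio[def])
    } else {
      mw_fst <- mw_ratio <- list(W = NA_real_, p_two_sided = NA_real_,
                                 exact = NA, n_outlier = 0L,
                                 n_background = sum(def))
    }
    reg <- merge_windows_to_regions(tails$joint, max_gap = config$max_gap)
    reg <- annotate_regions(reg, genes, qtls)
    fstpi[[cmp]] <- list(windows = ws, tails = tails, regions = reg,
                         mw_fst = mw_fst, mw_ratio = mw_ratio)
    xp_regions[[cmp]] <- reg
    table1[[cmp]] <- data.frame(
      pair = paste(config$focal, "vs", cmp),
      threshold_fst = tails$fst$threshold,
      W_fst = mw_fst$W, p_fst = mw_fst$p_two_sided,
      threshold_ratio = tails$theta_pi_ratio$threshold,
      W_ratio = mw_ratio$W, p_ratio = mw_ratio$p_two_sided,
      outlier_extent_mb = sum(reg$width) / 1e6,
      n_regions = nrow(reg))
    log <- .log_line(log,
                     "xpFST/pi %s vs %s: thr_fst=%.4g thr_ratio=%.4g joint=%d regions=%d",
                     config$focal, cmp, tails$fst$threshold,
                     tails$theta_pi_ratio$threshold,
                     length(tails$joint_ids), nrow(reg))
    write.table(ws, file.path(out_dir, sprintf("fstpi_windows_%s.tsv", cmp)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(reg, file.path(out_dir, sprintf("fstpi_regions_%s.tsv", cmp)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(reg))
      write_bed(reg, file.path(out_dir, sprintf("fstpi_regions_%s.bed", cmp)))
  }
  table1 <- do.call(rbind, table1)
  write.table(table1, file.path(out_dir, "summary_fstpi.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # ---- iHS in the focal population -----------------------------------
  ihs <- stage("scan-ihs", ihs_scan(h_focal))
  ihs_windows <- call_outlier_windows(ihs, win_scan, config$ihs_p,
                                      config$ihs_min_snps)
  ihs_regions <- merge_windows_to_regions(
    ihs_windows[ihs_windows$is_candidate, , drop = FALSE],
    max_gap = config$max_gap, scores = ihs, p_threshold = config$ihs_p)
  ihs_regions <- annotate_regions(ihs_regions, genes, qtls)
  log <- .log_line(log, "iHS %s: %d scored SNPs, %d candidate windows, %d regions",
                   config$focal, nrow(ihs),
                   sum(ihs_windows$is_candidate), nrow(ihs_regions))
  write.table(ihs, file.path(out_dir, "ihs_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ihs_regions, file.path(out_dir, "ihs_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(ihs_regions))
    write_bed(ihs_regions, file.path(out_dir, "ihs_regions.bed"))

  # ---- xpEHH per pair -------------------------------------------------
  xpehh <- list(); table2 <- list()
  for (cmp in config$comparisons) {
    h_cmp <- subset_samples(h_all, pop_samples(pop_map, cmp))
    sc <- stage("scan-xpehh", xpehh_scan(h_focal, h_cmp))
    cw <- call_outlier_windows(sc, win_scan, config$xpehh_p,
                               config$xpehh_min_snps)
    reg <- merge_windows_to_regions(cw[cw$is_candidate, , drop = FALSE],
                                    max_gap = config$max_gap, scores = sc,
                                    p_threshold = config$xpehh_p)
    reg <- annotate_regions(reg, genes, qtls)
    xpehh[[cmp]] <- list(scores = sc, windows = cw, regions = reg)
    table2[[cmp]] <- data.frame(
      pair = paste(config$focal, "vs", cmp),
      n_regions = nrow(reg),
      extent_kb = sum(reg$width) / 1e3,
      n_snps = sum(reg$n_snps),
      n_outlier_snps = sum(reg$n_outlier_snps),
      n_genes = length(attr(reg, "gene_universe")))
    log <- .log_line(log, "xpEHH %s vs %s: %d scored SNPs, %d regions",
                     config$focal, cmp, nrow(sc), nrow(reg))
    write.table(sc, file.path(out_dir, sprintf("xpehh_scores_%s.tsv", cmp)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(reg, file.path(out_dir, sprintf("xpehh_regions_%s.tsv", cmp)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(reg))
      write_bed(reg, file.path(out_dir, sprintf("xpehh_regions_%s.bed", cmp)))
  }
  table2 <- do.call(rbind, table2)
  write.table(table2, file.path(out_dir, "summary_xpehh.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # ---- gene-list intersections across comparisons --------------------
  intersections <- list()
  if (length(config$comparisons) >= 2 && !is.null(genes)) {
    for (method in c("fstpi", "xpehh")) {
      src <- if (method == "fstpi") xp_regions else
        lapply(xpehh, `[[`, "regions")
      sets <- lapply(src, function(r) attr(r, "gene_universe"))
      ix <- intersect_gene_lists(sets)
      intersections[[method]] <- ix
      if (!is.null(ix$classes))
        write.table(ix$classes,
                    file.path(out_dir,
                              sprintf("gene_intersections_%s.tsv", method)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      log <- .log_line(log, "%s gene intersection: full overlap %d genes",
                       method, length(ix$full_intersection))
    }
  }

  # ---- LD decay per population ---------------------------------------
  ld <- list()
  for (p in unique(pop_map$population)) {
    prof <- stage("ld", ld_decay_profile(h_all, pop_map, p,
                                         bin_size = config$ld_bin,
                                         max_distance = config$ld_max_dist,
                                         seed = config$seed))
    ld[[p]] <- prof
    write.table(prof, file.path(out_dir, sprintf("ld_decay_%s.tsv", p)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(list(config = config, truth = truth, fstpi = fstpi,
                 table1 = table1, ihs = ihs, ihs_windows = ihs_windows,
                 ihs_regions = ihs_regions, xpehh = xpehh,
                 table2 = table2, intersections = intersections, ld = ld,
                 log = log))
}
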