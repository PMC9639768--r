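#' Drift-calibration study
#'
#' Runs replicate neutral two-population simulations under
#' [study_config_drift()] and measures, per replicate, the genome-wide
#' ratio-of-sums Weir-Cockerham FST between the daughter populations
#' and the per-bp nucleotide diversity of each. For populations at
#' mutation-drift equilibrium the expected FST is `t/(2N + t)` (0.167
#' at t = 40, N = 100; the mutation-free approximation
#' `1 - exp(-t/2N)` = 0.181 is slightly higher because it lets
#' within-population heterozygosity decay) and the expected diversity
#' is `4*N*mu` per bp (1e-3).
#'
#' @param n_rep number of replicates.
#' @param seed base seed; replicate r uses `seed + r`.
#' @return data frame with one row per replicate: `fst`, `pi_pop1`,
#'   `pi_pop2`, `n_variants`.
#' @export
run_drift_calibration_study <- function(n_rep = 10, seed = 1) {
  res <- lapply(seq_len(n_rep), function(r) {
    sim <- simulate_wf(study_config_drift(seed = seed + r))
    g <- as_genotype_matrix(sim$combined)
    comp <- wc_fst_site(g, sim$population_map, c("pop1", "pop2"))
    ok <- !is.na(comp$a)
    fst <- sum(comp$a[ok]) / sum((comp$a + comp$b + comp$c)[ok])
    L <- sim$config$chrom_length
    pi_of <- function(pop) {
      keep <- g$sample_ids %in% pop_samples(sim$population_map, pop)
      sum(site_pi(g$genotypes[keep, , drop = FALSE]), na.rm = TRUE) / L
    }
    data.frame(fst = fst, pi_pop1 = pi_of("pop1"), pi_pop2 = pi_of("pop2"),
               n_variants = length(g$positions))
  })
  do.call(rbind, res)
}

#' Hard-sweep recovery study
#'
#' Runs replicate two-population hard-sweep simulations under
#' [study_config_sweep()] and applies the full detection procedure to
#' each: the windowed FST / diversity-ratio cross analysis with joint
#' 5\% right tails (10 kb windows stepping by their size), and the iHS
#' and xpEHH scans with their windowed outlier rules (10 kb windows
#' overlapping by 1 kb; iHS p < 1e-6 with >= 2 SNPs, xpEHH p < 1e-4
#' with >= 5 SNPs) followed by region merging. A method recovers the
#' sweep when its joint window set (or a merged candidate region)
#' overlaps the known sweep position; candidate span not overlapping
#' the sweep position counts as false positive.
#'
#' @param n_rep number of replicates.
#' @param seed base seed; replicate r uses `seed + r`.
#' @return data frame with one row per replicate: logical hits
#'   `joint_fstpi`, `ihs`, `xpehh`; false-positive fractions of the
#'   chromosome `fp_frac_ihs`, `fp_frac_xpehh`; sweep final frequency
#'   and restart count.
#' @export
run_sweep_recovery_study <- function(n_rep = 10, seed = 1) {
  res <- lapply(seq_len(n_rep), function(r) {
    cfg <- study_config_sweep(seed = seed + r)
    sim <- simulate_wf(cfg)
    L <- cfg$chrom_length
    sweep_pos <- cfg$sweep$position
    hf <- sim$haplotypes$FOC
    hc <- sim$haplotypes$CMP
    g <- as_genotype_matrix(sim$combined)

    # (a) joint FST / diversity-ratio tails
    ws <- fst_pi_scan(g, sim$population_map, "FOC", "CMP",
                      make_windows(L, 1e4))
    tails <- joint_tail_outliers(ws, 0.95)
    sw_win <- ws$window_id[ws$start <= sweep_pos & ws$end >= sweep_pos]
    hit_joint <- sw_win %in% tails$joint_ids

    win_scan <- make_windows(L, 1e4, 9e3)
    region_eval <- function(scores, p_thr, min_snps) {
      cw <- call_outlier_windows(scores, win_scan, p_thr, min_snps)
      reg <- merge_windows_to_regions(cw[cw$is_candidate, , drop = FALSE],
                                      scores = scores, p_threshold = p_thr)
      if (nrow(reg) == 0) return(list(hit = FALSE, fp = 0))
      covers <- reg$start <= sweep_pos & reg$end >= sweep_pos
      list(hit = any(covers), fp = sum(reg$width[!covers]))
    }
    # (b) iHS in the focal population
    ihs <- ihs_scan(hf)
    ev_i <- region_eval(ihs, 1e-6, 2)
    # (c) xpEHH focal vs comparison
    xp <- xpehh_scan(hf, hc)
    ev_x <- region_eval(xp, 1e-4, 5)

    data.frame(joint_fstpi = hit_joint, ihs = ev_i$hit, xpehh = ev_x$hit,
               fp_frac_ihs = ev_i$fp / L, fp_frac_xpehh = ev_x$fp / L,
               final_freq = unname(sim$truth$sweep$final_freq["FOC"]),
               restarts = sim$truth$restarts)
  })
  do.call(rbind, res)
}

#' Bottleneck LD-contrast study
#'
#' Simulates the [study_config_bottleneck()] scenario and returns the
#' LD-decay profiles of the bottlenecked population and its
#' constant-size counterpart; the bottleneck raises mean r-squared at
#' every distance.
#'
#' @param seed RNG seed.
#' @return List with `bottleneck` and `control` profiles (see
#'   [ld_decay_profile()]).
#' @export
run_bottleneck_ld_study <- function(seed = 1) {
  sim <- simulate_wf(study_config_bottleneck(seed = seed))
  list(bottleneck = ld_decay_profile(sim$combined, sim$population_map,
                                     "pop1", seed = seed),
       control = ld_decay_profile(sim$combined, sim$population_map,
                                  "pop2", seed = seed))
}
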