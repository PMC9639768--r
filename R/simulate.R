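#' Configuration for the Wright-Fisher simulator
#'
#' Desk-scale forward-time simulation: population sizes are scaled down
#' (tens to hundreds of diploids) with per-bp mutation and recombination
#' rates scaled up so the population-scaled parameters `4N*mu` and
#' `4N*rec` stay in a realistic range (defaults give 1e-3 per bp,
#' i.e. pig-like SNP densities of roughly one SNP per 200 bp in a
#' moderate sample).
#'
#' @param chrom_length chromosome length in bp.
#' @param n_pops number of populations after the split.
#' @param N diploid population size(s); recycled to `n_pops`.
#' @param N_anc diploid size of the ancestral (burn-in) population
#'   (default `N[1]`); a smaller ancestral pool with larger daughters
#'   emulates expanding populations while keeping burn-in affordable.
#' @param split_time generations between the split and sampling.
#' @param mu per-bp per-generation mutation rate (infinite sites on
#'   integer positions, collisions re-drawn).
#' @param rec per-bp per-generation recombination rate (uniform; Poisson
#'   crossovers per gamete).
#' @param burnin_factor burn-in length as a multiple of the ancestral
#'   `N` (default 8, i.e. >= 8N generations before the split).
#' @param bottleneck optional `list(pop, start, duration, N)`: population
#'   `pop` has size `N` for the `duration` generations ending
#'   `start - duration` generations before sampling.
#' @param sweep optional `list(pop, position, s, h, time)`: a beneficial
#'   mutation with genotype fitnesses 1, 1+hs, 1+s injected on one
#'   haplotype of `pop` `time` generations before sampling; runs where
#'   the allele is lost are restarted from the introduction snapshot
#'   (new RNG draws, restart counted). An optional `min_freq` entry
#'   conditions the run on the allele ending at or above that frequency
#'   (sampling near fixation); runs ending below it are restarted and
#'   counted the same way.
#' @param sample_sizes diploid sample size(s) per population.
#' @param pop_names population labels.
#' @param seed RNG seed (fully determines the run).
#' @param max_restarts abort threshold for sweep-loss restarts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(chrom_length = 2e6, n_pops = 2, N = 200,
                       N_anc = NULL, split_time = 100, mu = 1.25e-6,
                       rec = 1.25e-6, burnin_factor = 8,
                       bottleneck = NULL, sweep = NULL,
                       sample_sizes = 20, pop_names = NULL, seed = NULL,
                       max_restarts = 500) {
  N <- rep_len(as.integer(N), n_pops)
  if (is.null(N_anc)) N_anc <- N[1]
  sample_sizes <- rep_len(as.integer(sample_sizes), n_pops)
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(n_pops))
  stopifnot(mu >= 0, rec >= 0, split_time >= 0, chrom_length >= 1)
  if (!is.null(sweep)) {
    stopifnot(sweep$position >= 1, sweep$position <= chrom_length,
              sweep$pop >= 1, sweep$pop <= n_pops)
    sweep$h <- if (is.null(sweep$h)) 0.5 else sweep$h
  }
  structure(list(chrom_length = as.integer(chrom_length), n_pops = n_pops,
                 N = N, N_anc = as.integer(N_anc),
                 split_time = as.integer(split_time), mu = mu,
                 rec = rec, burnin_factor = burnin_factor,
                 bottleneck = bottleneck, sweep = sweep,
                 sample_sizes = sample_sizes, pop_names = pop_names,
                 seed = seed, max_restarts = as.integer(max_restarts)),
            class = "sim_config")
}

# expected segregating sites in the pooled sample (Watterson), used as a
# desk-scale guard before running
.expected_segsites <- function(cfg) {
  n_hap <- 2 * sum(cfg$sample_sizes)
  if (n_hap < 2) return(0)
  4 * max(cfg$N_anc, cfg$N) * cfg$mu * cfg$chrom_length *
    sum(1 / seq_len(n_hap - 1))
}

#' Run the Wright-Fisher simulation
#'
#' Burn-in of `burnin_factor * N[1]` generations from a monomorphic
#' start, a split into `n_pops` daughter populations, `split_time`
#' further generations with optional bottleneck and hard sweep, then
#' sampling without replacement. Emitted haplotypes carry the true
#' ancestral allele as REF, so iHS polarization is exact. Fully
#' reproducible from `seed`.
#'
#' @param config a [sim_config()].
#' @return List with `haplotypes` (named list of [haplotype_matrix], one
#'   per population), `combined` (all samples in one matrix),
#'   `population_map`, `truth` (sweep position, s, per-population final
#'   frequency, fixed flags, restart count, generations to frequency
#'   0.9) and the echoed `config`.
#' @export
simulate_wf <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  es <- .expected_segsites(config)
  if (es > 1e5)
    stop(sprintf("expected segregating sites %.0f exceeds the desk-scale guard (1e5); reduce N, mu or chrom_length", es))
  if (!is.null(config$seed)) set.seed(config$seed)
  bn <- if (is.null(config$bottleneck)) NULL else
    as.integer(c(config$bottleneck$pop, config$bottleneck$start,
                 config$bottleneck$duration, config$bottleneck$N))
  sw <- config$sweep
  raw <- .wf_sim_cpp(config$chrom_length, config$N, config$N_anc,
                     config$split_time,
                     as.integer(ceiling(config$burnin_factor * config$N_anc)),
                     config$mu, config$rec, bn, sw, config$sample_sizes,
                     config$max_restarts, 25L)
  pos <- raw$positions
  pops <- list()
  samp_names <- character(0)
  samp_pop <- character(0)
  row0 <- 0L
  for (p in seq_len(config$n_pops)) {
    nh <- 2L * config$sample_sizes[p]
    rows <- row0 + seq_len(nh)
    row0 <- row0 + nh
    ids <- paste0(config$pop_names[p], "_", seq_len(config$sample_sizes[p]))
    pops[[config$pop_names[p]]] <-
      haplotype_matrix(raw$alleles[rows, , drop = FALSE], pos,
                       chrom = "1", sample_ids = ids,
                       ancestral_is_ref = TRUE)
    samp_names <- c(samp_names, ids)
    samp_pop <- c(samp_pop, rep(config$pop_names[p],
                                config$sample_sizes[p]))
  }
  combined <- haplotype_matrix(raw$alleles, pos, chrom = "1",
                               sample_ids = samp_names,
                               ancestral_is_ref = TRUE)
  truth <- list(
    sweep = if (is.null(sw)) NULL else
      list(position = sw$position, s = sw$s, h = sw$h, pop = sw$pop,
           time = sw$time,
           final_freq = setNames(as.numeric(raw$final_freq),
                                 config$pop_names),
           fixed = setNames(as.logical(raw$fixed), config$pop_names),
           gens_to_freq_0.9 = raw$gens_to_high),
    restarts = raw$restarts,
    n_variants = length(pos),
    seed = config$seed)
  list(haplotypes = pops, combined = combined,
       population_map = data.frame(sample = samp_names,
                                   population = samp_pop,
                                   stringsAsFactors = FALSE),
       truth = truth, config = config)
}

#' Write a simulation as a self-contained analysis bundle
#'
#' Emits a merged phased VCF (REF = true ancestral allele), the
#' sample-to-population map, a JSON truth/config record, and toy gene
#' and QTL interval files placing one interval over the sweep site (so
#' annotation paths are exercised) plus decoy intervals elsewhere.
#'
#' @param sim output of [simulate_wf()].
#' @param out_dir output directory (created if needed).
#' @return Named list of the file paths written.
#' @export
emit_truth_bundle <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(vcf = file.path(out_dir, "sim.vcf"),
                sample_map = file.path(out_dir, "samples.tsv"),
                truth = file.path(out_dir, "truth.json"),
                genes = file.path(out_dir, "genes.bed"),
                qtls = file.path(out_dir, "qtl.tsv"))
  write_phased_vcf(sim$combined, paths$vcf)
  write.table(sim$population_map, paths$sample_map, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  cfg <- sim$config
  cfg$bottleneck <- if (is.null(cfg$bottleneck)) NULL else cfg$bottleneck
  jsonlite::write_json(list(truth = sim$truth, config = unclass(cfg)),
                       paths$truth, auto_unbox = TRUE, digits = NA,
                       null = "null")
  L <- sim$config$chrom_length
  center <- if (!is.null(sim$config$sweep)) sim$config$sweep$position else
    round(L / 2)
  gene_start <- max(1, center - 5000)
  gene_end <- min(L, center + 5000)
  decoy <- round(L * c(0.1, 0.85))
  genes <- data.frame(chrom = "1",
                      start = c(gene_start, pmax(1, decoy - 3000)),
                      end = c(gene_end, pmin(L, decoy + 3000)),
                      name = c("sweep_gene", "decoy_gene1", "decoy_gene2"))
  write.table(data.frame(genes$chrom, genes$start - 1L, genes$end,
                         genes$name),
              paths$genes, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  qtls <- data.frame(chrom = "1",
                     start = max(1, center - 50000),
                     end = min(L, center + 50000),
                     name = "sweep_qtl", kind = "QTL")
  write.table(qtls, paths$qtls, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  paths
}

#' Study conditions: neutral drift calibration
#'
#' Two populations of 100 diploids splitting 40 generations before
#' sampling on a 500 kb chromosome with `4N*mu = 4N*rec = 1e-3`; at
#' mutation-drift equilibrium the expected genome-wide FST is
#' `t/(2N + t) = 0.167` and the expected neutral diversity is `4N*mu`
#' per bp.
#'
#' @param seed RNG seed.
#' @return A [sim_config()].
#' @export
study_config_drift <- function(seed = NULL) {
  sim_config(chrom_length = 5e5, n_pops = 2, N = 100, split_time = 40,
             mu = 2.5e-6, rec = 2.5e-6, sample_sizes = 20, seed = seed)
}

#' Study conditions: hard-sweep recovery
#'
#' Two expanding populations of 2500 diploids (ancestral pool of 500)
#' splitting 1000 generations before sampling (realized genome-wide
#' FST near 0.14, inside the empirical between-breed range), a 2 Mb
#' chromosome with per-bp mutation 5e-7 and
#' recombination 3.5e-7 per generation (about one SNP per 200 bp in the
#' pooled sample of 100 haplotypes per population), and a hard sweep
#' (s = 0.1, h = 0.5) introduced in the focal population at the
#' chromosome midpoint 285 generations before sampling -- slightly more
#' than the expected fixation time `(4/s) ln(2Ns) ~ 250` -- with the
#' run conditioned on a final frequency of at least 0.95
#' (restart-counted), so every replicate is a hard sweep sampled at or
#' near fixation. The scaled strength `2Ns = 500` keeps the sweep
#' haplotype long relative to the background extended-homozygosity
#' scale, the regime in which haplotype scans of whole-genome data
#' operate.
#'
#' @param seed RNG seed.
#' @return A [sim_config()].
#' @export
study_config_sweep <- function(seed = NULL) {
  sim_config(chrom_length = 2e6, n_pops = 2, N = 2500, N_anc = 500,
             split_time = 1000, mu = 5e-7, rec = 3.5e-7,
             sweep = list(pop = 1, position = 1e6, s = 0.1, h = 0.5,
                          time = 285, min_freq = 0.95),
             sample_sizes = 50, pop_names = c("FOC", "CMP"), seed = seed)
}

#' Study conditions: bottleneck vs constant-size LD contrast
#'
#' Two populations of 200 diploids; population 1 passes through a
#' 30-generation bottleneck of 20 diploids ending 10 generations before
#' sampling, which raises LD at every distance relative to its
#' constant-size counterpart.
#'
#' @param seed RNG seed.
#' @return A [sim_config()].
#' @export
study_config_bottleneck <- function(seed = NULL) {
  sim_config(chrom_length = 1e6, n_pops = 2, N = 200, split_time = 60,
             mu = 1.25e-6, rec = 1.25e-6,
             bottleneck = list(pop = 1, start = 40, duration = 30, N = 20),
             sample_sizes = 20, seed = seed)
}
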