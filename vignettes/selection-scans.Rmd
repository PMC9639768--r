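---
title: "Selection-signature scans: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection-signature scans: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements, the simulator that generates its test data, the parameter
choices that matter, and the limits of what desk-scale simulation can
show about whole-genome data.

## The detection problem

A small, recently isolated population (the *focal* population — think
of a free-ranging local breed sampled against a panel of reference
breeds) is screened for genomic regions under positive selection using
three complementary signals:

* **Divergent selection between populations** — windows where genetic
  differentiation (FST) is unusually high *and* diversity in the focal
  population is unusually reduced relative to a comparison population
  (the xpFST/θπ cross analysis). Sensitive to older, completed sweeps.
* **Long haplotypes within a population** — the integrated haplotype
  score (iHS), which contrasts the extent of haplotype homozygosity
  around the ancestral and derived alleles of each SNP. Sensitive to
  recent sweeps that have not reached fixation.
* **Long haplotypes relative to another population** — xpEHH, which
  contrasts integrated haplotype homozygosity between two populations
  at the same SNP. Sensitive to sweeps at or near fixation in one
  population.

All three feed a shared post-processing chain: windowed outlier
calling, merging of candidate windows into regions, interval
annotation, and gene-list intersection across comparisons.

## Estimators

### Nucleotide diversity

Per site, with `j` copies of the alternate allele among `n` non-missing
alleles, diversity is the fraction of differing unordered allele pairs,
`2 j (n - j) / (n (n - 1))`. Sites with fewer than two non-missing
alleles are skipped and counted. Per window, site values are summed and
divided by the window **span in bp**: invariant positions contribute
zero to the numerator and their full length to the denominator. This is
the convention of the standard windowed VCF tools; dividing by the
number of variant sites instead would make windows with little
variation look artificially diverse.

### Weir–Cockerham FST

Per site the 1984 two-level variance components are computed from
sample sizes, allele frequencies and observed heterozygosity: `a`
(among populations), `b` (among individuals within populations), `c`
(within individuals). Windows aggregate as a **ratio of sums**,
`Σa / Σ(a+b+c)` — not a mean of per-site ratios, which would be
dominated by low-information sites. Monomorphic sites yield components
(0,0,0) and drop out of any ratio automatically; sites where either
population has fewer than two genotyped individuals are skipped.
Negative per-window values are retained (clamping would bias the
genomic background against which outliers are tested); the right-tail
selection makes them irrelevant for candidate calling. Heterozygosity
enters through genotypes, so the estimator matches the genotype-based
tools used in practice rather than a haploid-frequency shortcut.

### The diversity ratio and joint tails

`theta_pi_ratio = log2(pi_comparison / pi_focal)` is positive where the
focal population has lost diversity. Zero-diversity windows produce
signed-infinity sentinels and are excluded from tail selection rather
than imputed: a quantile over a mixture of finite values and sentinels
would be arbitrary. Thresholds are the empirical 95% quantiles
(linear-interpolation quantile, R type 7) of each statistic over all
windows where both statistics are finite, pooled genome-wide, and the
joint candidate set is the intersection of the two right tails.
Requiring at least 20 defined windows guards against meaningless
quantiles. The Mann-Whitney background deliberately includes the
outlier windows (the genome-wide distribution), matching the published
convention; a flag allows excluding them.

### EHH, iHH, iHS and xpEHH

EHH from a core SNP is the probability that two random carrier
haplotypes are identical at every marker between the core and the
evaluation point: `EHH(x) = Σ_g C(n_g, 2) / C(n, 2)`. The denominator
is fixed at the initial carrier count, so haplotypes dropped at a
missing allele count as lost and the profile is monotone
non-increasing. iHH is the trapezoidal integral of EHH over physical
distance, truncated by **linear interpolation at the first crossing of
the cutoff** (default 0.05): stopping at the last marker above the
cutoff instead would make scores depend on marker spacing. A SNP whose
EHH is still at or above the cutoff at the chromosome end is flagged
and discarded by default (a truncated integral would be biased short);
inter-marker gaps above `max_gap` (default 200 kb) truncate the
integral without the flag, because a gap is missing data, not evidence
of homozygosity ending.

iHS standardization subtracts the mean and divides by the standard
deviation of `ln(iHH_A/iHH_D)` within derived-allele-frequency bins
(width 0.025; bins with fewer than 10 SNPs merge toward frequency 0.5).
The binning is essential, not cosmetic: under neutrality the
unstandardized score is strongly frequency-dependent — young (rare)
derived alleles sit on long haplotypes, so the raw mean is
systematically negative (about −1 in our simulations at every scale
tested). The standardized score is treated as standard normal under
neutrality, `p = 2(1 − Φ(|z|))`.

xpEHH computes EHH over **all** haplotypes of each population with the
partition starting as a single class at the core (the core allele
itself does not split haplotypes, so EHH(core) = 1 in both
populations). Both profiles are walked outward until both fall below
the cutoff; each population's profile is then integrated to the shared
stopping extent — the farther of the two interpolated crossings — so
the two integrals cover the same physical interval and their log ratio
is comparable. Standardization is genome-wide (single mean/sd), and the
sign convention is positive when haplotypes are longer (selection) in
the first (focal) population.

### Outlier windows, regions, annotation

Haplotype-scan windows are 10 kb overlapping by 1 kb, read literally as
adjacent windows sharing 1 kb (step 9 kb); the step is a parameter, so
the alternative reading (step 1 kb) is one argument away. A window is a
candidate when it holds at least `min_snps` SNPs below the p-value
threshold (iHS: 1e-6 and 2 SNPs; xpEHH: 1e-4 and 5 SNPs). Overlapping
or bookended candidate windows merge into regions (`max_gap = 0` by
default; merging is idempotent), SNPs are counted once per region, and
any shared bp with a gene or QTL interval attaches the annotation
(abutting intervals do not). Coordinates are 1-based inclusive
internally (the VCF convention); BED input/output converts at the
boundary.

### LD statistics

r² comes from phased haplotype frequencies with pairwise-complete
observations; monomorphic-after-missing pairs are undefined. The decay
profile bins all intra-chromosomal pairs up to 250 kb by distance
(10 kb bins), with a seeded uniform pair subsample above a budget.
Pruning is the greedy windowed rule: within each 50 kb window, scanning
pairs in position order, the lower-minor-allele-frequency member of any
pair with r² above 0.5 is removed (ties remove the later position),
then the window slides by 5 variants. The removal rule is declared, not
claimed to replicate any particular tool bit-for-bit.

### Pairwise FST bootstrap

Global pairwise FST over a caller-supplied SNP mask (in the motivating
study design, synonymous sites) uses the same ratio of sums. The
bootstrap resamples sites with replacement (default 100 replicates) and
reports `p = (1 + #{replicates ≤ 0}) / (B + 1)` — the small-B
correction that avoids p = 0 at 100 replicates — plus a percentile 95%
interval.

## The simulator

A discrete-generation Wright–Fisher model: haplotypes are sorted
integer vectors of derived-allele positions; each offspring gamete
recombines two parental haplotypes (Poisson number of crossovers,
uniform positions) and adds Poisson-distributed new mutations on
integer bp with collisions re-drawn (infinite sites; positions lost or
globally fixed are released for reuse, which is equivalent to a fresh
site on the updated ancestral state). A single ancestral population of
size `N_anc` burns in for `8 × N_anc` generations from a monomorphic
start — diversity converges to within ~2% of its equilibrium — then
splits into daughter populations that evolve independently (no
migration), with optional bottlenecks (a reduced size over a
generation interval) and one optional hard sweep: a beneficial
mutation with genotype fitnesses 1, 1+hs, 1+s injected on a single
random haplotype. If the allele is lost — or, when conditioning on a
near-fixation sample, ends below `min_freq` — the swept population
replays from a snapshot taken at the introduction, with fresh random
draws and the restart counted. Because populations are independent
after the split, a restart replays only the swept population.

Populations are scaled down (tens to thousands of diploids) with per-bp
mutation and recombination scaled up so that `4Nμ` and `4Nr` stay in a
realistic range; emitted VCFs use the true ancestral allele as REF, so
iHS polarization in tests is exact, and truth records (sweep position,
selection coefficient, final frequency per population, fixation flag,
restart count, generations to frequency 0.9) accompany every run. All
randomness flows through R's RNG: a seed fully determines the output,
and nothing is threaded, so results cannot depend on thread count.

### What the generator emulates, and what it does not

It reproduces the statistical structure the scans rely on: two or more
diverged populations with windowed FST in the 0.1–0.3 range, elevated
LD after a bottleneck, and localized hard sweeps that create joint
FST/θπ-ratio outliers and extreme haplotype scores. It does **not**
emulate migration or admixture, recombination-map heterogeneity,
selection on standing variation, genotyping error, or the demography of
any real breed; passing tests therefore show that the estimators and
the detection logic are correct and calibrated, not that any particular
empirical dataset would yield particular candidates.

## Study conditions

Three canned configurations hold the conditions under which the
package's own studies run; they are package API
(`study_config_drift()`, `study_config_sweep()`,
`study_config_bottleneck()`), used by the acceptance tests and by
`scripts/acceptance.R`.

**Drift calibration** — two populations of N = 100 splitting t = 40
generations before sampling, 500 kb, `4Nμ = 4Nr = 1e-3`, 20 diploids
sampled per population. At mutation–drift equilibrium within-population
heterozygosity stays at θ while between-population diversity grows by
2μt per site, so the expected genome-wide ratio-of-sums FST is

  E[FST] = 2μt / (θ + 2μt) = t / (2N + t) = 40/240 ≈ 0.167,

slightly below the mutation-free approximation `1 − exp(−t/2N) ≈ 0.181`
which lets heterozygosity decay instead. Simulations match the
equilibrium form within Monte-Carlo error (an independent Hudson-type
estimator agrees with the Weir–Cockerham value per replicate). Neutral
diversity is checked against `4Nμ` within 25%.

**Sweep recovery** — daughters of N = 2500 from an ancestral pool of
500 (an expanding-population history), split 1000 generations before
sampling (realized FST ≈ 0.14, inside the published between-breed
range), 2 Mb with μ = 5e-7 and r = 3.5e-7 per bp per generation (about
one SNP per 200 bp in the pooled sample, matching the SNP density of
whole-genome data), 50 diploids sampled per population, and a hard
sweep (s = 0.1, h = 0.5) introduced 285 generations before sampling —
just over its expected fixation time `(4/s) ln(2Ns) ≈ 250` — with the
run conditioned on a final frequency of at least 0.95, so every
replicate is a hard sweep sampled at or near fixation.

These values follow from the scales that govern detectability rather
than taste. The sweep's haplotype length is set by recombination over
the sweep duration, `~1/(r·T_sweep)`; the background
extended-homozygosity length is set by recent coalescence,
`~1/(0.1·N·r)` at the 0.05 EHH cutoff. Their ratio — independent of r —
grows as `~N/T_sweep = O(2Ns / ln 2Ns)`, so detection by haplotype
scans requires a large scaled selection strength: at `2Ns = 500` the
log-iHH contrasts clear the xpEHH outlier rule, while at
`2Ns ≤ 100` (N of a few hundred at s ≤ 0.1) they cannot, regardless of
implementation. The recombination rate is chosen so the diversity
trough of the sweep (`~1/(r·T_sweep)`) is as wide as the 10 kb
analysis window, which lets the window containing the sweep rank in
both right tails of the cross analysis.

**Bottleneck contrast** — two populations of 200, one passing through a
30-generation bottleneck of 20 diploids ending 10 generations before
sampling. The bottlenecked population shows a higher LD-decay profile
at every resolvable distance; beyond roughly 150 kb both profiles
converge to the finite-sample floor (mean r² ≈ 1/n_haplotypes), so the
comparison is made below that range, allowing one bin inversion as
noise.

## Known limitations

* **iHS outlier calling at desk scale.** The published rule — two-sided
  normal p < 1e-6, i.e. |z| > 4.89, with ≥ 2 such SNPs per window — is
  calibrated for scans of tens of millions of markers, where 1e-6
  corresponds to the top ~0.003% of the empirical distribution (and
  where, with 24.8M markers, ~24 SNPs would exceed it by chance alone).
  A desk-scale chromosome yields on the order of 1e4 scored SNPs, whose
  extreme order statistics under the standardized null sit near
  |z| ≈ 3.8–4.2; our simulated sweeps reach |z| of 3–5 at the swept
  locus but rarely place two SNPs beyond 4.89 in one window. iHS power
  is additionally lowest exactly at fixation, where the within-scan
  contrast hands over to xpEHH. The package asserts the rule as stated
  and documents that the corresponding recovery test does not pass at
  desk scale; the xpEHH and xpFST/θπ routes, which the same replicates
  do pass, carry the sweep-recovery evidence.
* Small carrier classes (2–4 haplotypes) produce noisy integrated
  haplotype lengths — a pair of closely related haplotypes keeps EHH
  above the cutoff over long distances. Larger samples per population
  tame this; the frequency filter keeps cores with at least two
  carriers of each allele, the floor at which the score is defined.
* The simulator's scaled-down populations compress the separation
  between sweep and background time scales (see above); conclusions
  about power at desk scale understate power on real whole-genome
  data.
* Phasing is assumed correct; phasing error would shorten apparent
  haplotypes for all methods. Unphased data are rejected, not
  approximated.

## Numerical and edge-case conventions

* Quantile thresholds: R type-7 (linear interpolation).
* Mann-Whitney: exact enumeration when `n1·n2 ≤ 10000` with no ties,
  else normal approximation with tie and continuity correction (the
  `wilcox.test` conventions; `W = #{x > y} + ties/2`).
* Bootstrap p-values are floored at `1/(B+1)`.
* Windows with no usable sites are `NA`, never zero; empty LD bins are
  `NA` with a zero pair count.
* LD pruning tie-break: equal minor-allele frequencies remove the later
  position, making the pruned set deterministic.
* Region merging with `max_gap = 0` unions overlapping *and* bookended
  windows; merging is idempotent.
* The VCF writer emits phased `|` genotypes and `.` for missing
  alleles; the reader refuses unphased records by name (CHROM:POS),
  drops non-SNP and multi-allelic records with a count, and errors on
  duplicated positions.
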