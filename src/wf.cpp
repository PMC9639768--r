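// Forward-time Wright-Fisher core: discrete generations, infinite-sites
// mutation on integer bp (collisions re-drawn), uniform recombination
// (Poisson crossovers per gamete), optional bottleneck and hard sweep
// with snapshot-restart when the beneficial allele is lost.
//
// All randomness goes through R's RNG so set.seed() in R fully
// determines the run. Single-threaded by design.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <vector>

using namespace Rcpp;

typedef std::vector<int> Hap;     // sorted positions of derived alleles
typedef std::vector<Hap> Pop;     // 2N haplotypes; individual i owns rows 2i, 2i+1

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static inline bool carries(const Hap &h, int pos) {
  return std::binary_search(h.begin(), h.end(), pos);
}

// Recombine parental haplotypes a/b and add new mutations.
static void make_gamete(const Hap &a, const Hap &b, double rec, double mu,
                        int L, std::unordered_set<int> &used, Hap &out) {
  out.clear();
  int k = (int)R::rpois(rec * L);
  std::vector<double> bps(k);
  for (int i = 0; i < k; ++i) bps[i] = 1.0 + unif_rand() * (L - 1);
  std::sort(bps.begin(), bps.end());
  bool use_a = unif_rand() < 0.5;
  double lo = 0.0;
  for (int seg = 0; seg <= k; ++seg) {
    double hi = (seg == k) ? (double)L + 1.0 : bps[seg];
    const Hap *cur = use_a ? &a : &b;
    Hap::const_iterator it0 =
        std::lower_bound(cur->begin(), cur->end(), (int)std::ceil(lo));
    Hap::const_iterator it1 =
        std::lower_bound(cur->begin(), cur->end(), (int)std::ceil(hi));
    out.insert(out.end(), it0, it1);
    use_a = !use_a;
    lo = hi;
  }
  int nm = (int)R::rpois(mu * L);
  if (nm > 0) {
    size_t base = out.size();
    for (int i = 0; i < nm; ++i) {
      int pos;
      do {
        pos = 1 + runif_int(L);
      } while (used.count(pos));
      used.insert(pos);
      out.push_back(pos);
    }
    std::sort(out.begin() + base, out.end());
    std::inplace_merge(out.begin(), out.begin() + base, out.end());
  }
}

static inline int pick_parent(const std::vector<double> &cw, double tot,
                              int N, bool weighted) {
  if (!weighted) return runif_int(N);
  double x = unif_rand() * tot;
  return (int)(std::lower_bound(cw.begin(), cw.end(), x) - cw.begin());
}

static void next_gen(const Pop &pop, Pop &np, int n_next, double rec,
                     double mu, int L, std::unordered_set<int> &used,
                     bool sel, int sweep_pos, double s, double h) {
  int n_cur = (int)pop.size() / 2;
  std::vector<double> cw;
  double tot = 0.0;
  if (sel) {
    cw.resize(n_cur);
    for (int i = 0; i < n_cur; ++i) {
      int cnt = (carries(pop[2 * i], sweep_pos) ? 1 : 0) +
                (carries(pop[2 * i + 1], sweep_pos) ? 1 : 0);
      double w = (cnt == 0) ? 1.0 : ((cnt == 1) ? 1.0 + h * s : 1.0 + s);
      tot += w;
      cw[i] = tot;
    }
  }
  // resize + clear keeps each vector's capacity across generations,
  // avoiding 2N reallocations per generation
  np.resize(2 * n_next);
  for (size_t i = 0; i < np.size(); ++i) np[i].clear();
  for (int i = 0; i < n_next; ++i) {
    int m = pick_parent(cw, tot, n_cur, sel);
    int f = pick_parent(cw, tot, n_cur, sel);
    make_gamete(pop[2 * m], pop[2 * m + 1], rec, mu, L, used, np[2 * i]);
    make_gamete(pop[2 * f], pop[2 * f + 1], rec, mu, L, used, np[2 * i + 1]);
  }
}

// Drop mutations fixed across every population (invisible in any sample)
// and rebuild the collision set `used` as the currently-segregating
// positions, releasing globally lost or fixed positions for reuse
// (fixation is absorbing, so pruning mid-phase is safe; a re-mutation at
// a released position is a fresh site on the updated ancestral state).
// The sweep position is exempt so its trajectory stays observable.
// `cnt` is a caller-owned flat count array of length L + 1, reused.
static void prune_fixed(std::vector<Pop> &pops, int sweep_pos,
                        std::vector<int> &cnt,
                        std::unordered_set<int> &used) {
  std::fill(cnt.begin(), cnt.end(), 0);
  long tot = 0;
  for (size_t p = 0; p < pops.size(); ++p) {
    tot += (long)pops[p].size();
    for (size_t i = 0; i < pops[p].size(); ++i)
      for (size_t j = 0; j < pops[p][i].size(); ++j) cnt[pops[p][i][j]]++;
  }
  bool any = false;
  for (size_t q = 0; q < cnt.size(); ++q)
    if (cnt[q] == tot && (int)q != sweep_pos) { any = true; break; }
  if (any) {
    for (size_t p = 0; p < pops.size(); ++p)
      for (size_t i = 0; i < pops[p].size(); ++i) {
        Hap &hp = pops[p][i];
        hp.erase(std::remove_if(hp.begin(), hp.end(),
                                [&](int q) {
                                  return cnt[q] == tot && q != sweep_pos;
                                }),
                 hp.end());
      }
  }
  used.clear();
  for (size_t q = 0; q < cnt.size(); ++q)
    if (cnt[q] > 0 && cnt[q] < tot) used.insert((int)q);
  if (sweep_pos >= 0) used.insert(sweep_pos);
}

static double sweep_freq(const Pop &pop, int sweep_pos) {
  long c = 0;
  for (size_t i = 0; i < pop.size(); ++i)
    if (carries(pop[i], sweep_pos)) ++c;
  return pop.empty() ? 0.0 : (double)c / (double)pop.size();
}

// [[Rcpp::export(name = ".wf_sim_cpp")]]
List wf_sim_cpp(int chrom_length, IntegerVector pop_sizes, int n_anc,
                int split_time, int burnin, double mu, double rec,
                Nullable<IntegerVector> bottleneck_, Nullable<List> sweep_,
                IntegerVector sample_sizes, int max_restarts,
                int prune_every) {
  int n_pops = pop_sizes.size();
  int L = chrom_length;

  bool has_bn = bottleneck_.isNotNull();
  int bn_pop = 0, bn_start = 0, bn_dur = 0, bn_N = 0;
  if (has_bn) {
    IntegerVector bn(bottleneck_);
    bn_pop = bn[0] - 1;
    bn_start = bn[1];
    bn_dur = bn[2];
    bn_N = bn[3];
  }

  bool has_sweep = sweep_.isNotNull();
  int sw_pop = 0, sw_pos = -1, sw_time = 0;
  double sw_s = 0.0, sw_h = 0.5, sw_minfreq = 0.0;
  if (has_sweep) {
    List sw(sweep_);
    sw_pop = as<int>(sw["pop"]) - 1;
    sw_pos = as<int>(sw["position"]);
    sw_s = as<double>(sw["s"]);
    sw_h = as<double>(sw["h"]);
    sw_time = as<int>(sw["time"]);
    if (sw.containsElementNamed("min_freq"))
      sw_minfreq = as<double>(sw["min_freq"]);
    if (sw_time > split_time)
      stop("sweep introduction time must not precede the split");
  }

  std::unordered_set<int> used;
  if (has_sweep) used.insert(sw_pos);
  std::vector<int> cntbuf(L + 1, 0);

  // burn-in: one ancestral population of size n_anc
  std::vector<Pop> pops(1);
  pops[0].assign(2 * n_anc, Hap());
  Pop buf;
  for (int g = 0; g < burnin; ++g) {
    next_gen(pops[0], buf, n_anc, rec, mu, L, used, false, -1, 0, 0);
    pops[0].swap(buf);
    if (prune_every > 0 && (g + 1) % prune_every == 0)
      prune_fixed(pops, sw_pos, cntbuf, used);
  }

  // split: each daughter population is a WF draw from the ancestral pool
  {
    std::vector<Pop> daughters(n_pops);
    for (int p = 0; p < n_pops; ++p)
      next_gen(pops[0], daughters[p], pop_sizes[p], rec, mu, L, used, false,
               -1, 0, 0);
    pops.swap(daughters);
  }

  // forward phase, g = generations before sampling, counting down.
  // Populations are independent after the split (no migration), so each
  // evolves separately; a sweep-loss restart then replays only the
  // swept population from its introduction snapshot.
  int restarts = 0;
  int gens_to_high = NA_INTEGER;
  int size_at; // bottleneck-aware size of the generation aged t_next
  for (int p = 0; p < n_pops; ++p) {
    if (has_sweep && p == sw_pop) continue;
    for (int g = split_time; g >= 1; --g) {
      int t_next = g - 1;
      size_at = pop_sizes[p];
      if (has_bn && p == bn_pop && t_next <= bn_start &&
          t_next > bn_start - bn_dur)
        size_at = bn_N;
      next_gen(pops[p], buf, size_at, rec, mu, L, used, false, -1, 0, 0);
      pops[p].swap(buf);
      if (prune_every > 0 && g % prune_every == 0)
        prune_fixed(pops, sw_pos, cntbuf, used);
    }
  }
  if (has_sweep) {
    int p = sw_pop;
    Pop snapshot;
    bool sweep_active = false;
    int g = split_time;
    while (g >= 1) {
      if (!sweep_active && g == sw_time) {
        snapshot = pops[p];  // deep copy for loss-restart
        int idx = runif_int((int)pops[p].size());
        Hap &hp = pops[p][idx];
        hp.insert(std::lower_bound(hp.begin(), hp.end(), sw_pos), sw_pos);
        sweep_active = true;
      }
      int t_next = g - 1;
      size_at = pop_sizes[p];
      if (has_bn && p == bn_pop && t_next <= bn_start &&
          t_next > bn_start - bn_dur)
        size_at = bn_N;
      next_gen(pops[p], buf, size_at, rec, mu, L, used, sweep_active,
               sw_pos, sw_s, sw_h);
      pops[p].swap(buf);
      if (sweep_active) {
        double f = sweep_freq(pops[p], sw_pos);
        // restart on loss, or (when conditioning on a near-fixation
        // sample) on ending below the required frequency
        if (f <= 0.0 || (g == 1 && f < sw_minfreq)) {
          if (++restarts > max_restarts)
            stop("sweep allele lost more than max_restarts times");
          pops[p] = snapshot;
          gens_to_high = NA_INTEGER;
          int idx = runif_int((int)pops[p].size());
          Hap &hp = pops[p][idx];
          hp.insert(std::lower_bound(hp.begin(), hp.end(), sw_pos), sw_pos);
          g = sw_time;  // redo from introduction
          continue;
        }
        if (gens_to_high == NA_INTEGER && f > 0.9)
          gens_to_high = sw_time - (g - 1);
      }
      if (prune_every > 0 && g % prune_every == 0)
        prune_fixed(pops, sw_pos, cntbuf, used);
      --g;
    }
  }
  prune_fixed(pops, sw_pos, cntbuf, used);

  // truth: beneficial-allele frequency in the full final populations
  NumericVector final_freq(n_pops);
  LogicalVector fixed_flag(n_pops);
  if (has_sweep) {
    for (int p = 0; p < n_pops; ++p) {
      final_freq[p] = sweep_freq(pops[p], sw_pos);
      fixed_flag[p] = final_freq[p] >= 1.0;
    }
  }

  // sample individuals without replacement, collect union of positions
  std::vector<std::vector<int> > chosen(n_pops);
  std::unordered_set<int> posset;
  int total_haps = 0;
  for (int p = 0; p < n_pops; ++p) {
    int N = (int)pops[p].size() / 2;
    int ss = sample_sizes[p];
    if (ss > N) stop("sample size exceeds population size");
    std::vector<int> idx(N);
    for (int i = 0; i < N; ++i) idx[i] = i;
    for (int i = 0; i < ss; ++i) {
      int j = i + runif_int(N - i);
      std::swap(idx[i], idx[j]);
    }
    idx.resize(ss);
    std::sort(idx.begin(), idx.end());
    chosen[p] = idx;
    total_haps += 2 * ss;
    for (int i = 0; i < ss; ++i)
      for (int r = 0; r < 2; ++r) {
        const Hap &hp = pops[p][2 * idx[i] + r];
        for (size_t j = 0; j < hp.size(); ++j) posset.insert(hp[j]);
      }
  }
  std::vector<int> positions(posset.begin(), posset.end());
  std::sort(positions.begin(), positions.end());
  std::unordered_map<int, int> colmap;
  for (size_t j = 0; j < positions.size(); ++j) colmap[positions[j]] = (int)j;

  IntegerMatrix alleles(total_haps, (int)positions.size());
  IntegerVector pop_index(total_haps);
  int row = 0;
  for (int p = 0; p < n_pops; ++p) {
    for (size_t i = 0; i < chosen[p].size(); ++i)
      for (int r = 0; r < 2; ++r) {
        const Hap &hp = pops[p][2 * chosen[p][i] + r];
        for (size_t j = 0; j < hp.size(); ++j)
          alleles(row, colmap[hp[j]]) = 1;
        pop_index[row] = p + 1;
        ++row;
      }
  }

  return List::create(
      _["alleles"] = alleles, _["positions"] = wrap(positions),
      _["pop_index"] = pop_index, _["restarts"] = restarts,
      _["final_freq"] = final_freq, _["fixed"] = fixed_flag,
      _["gens_to_high"] = gens_to_high);
}
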