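// EHH partition walk and iHH integration used by the iHS and xpEHH scans.
// EHH(x) = sum_g C(n_g,2) / C(n,2) over classes of haplotypes identical at
// every marker strictly between the core and x (inclusive of x); the
// denominator is fixed at the initial carrier count, so haplotypes dropped
// for missing data count as lost and EHH stays monotone non-increasing.
// iHH is the trapezoidal integral of EHH over physical distance, truncated
// by linear interpolation at the first crossing of `cutoff`; hitting the
// last marker with EHH >= cutoff sets a border flag; an inter-marker gap
// larger than `maxgap` truncates integration without flagging.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

struct SideResult {
  double ihh;
  bool border;
};

// Scratch buffers reused across refinement steps (single-threaded).
struct RefineBuf {
  std::vector<int> remap;  // key -> new id, stamped
  std::vector<int> stamp;
  std::vector<int> gcnt;
  int epoch;
  RefineBuf() : epoch(0) {}
  void ensure(int n) {
    if ((int)remap.size() < 2 * n + 2) {
      remap.assign(2 * n + 2, 0);
      stamp.assign(2 * n + 2, 0);
      gcnt.assign(n + 1, 0);
    }
  }
};

// One refinement step: split classes by the allele at column `col`.
// ids[i] < 0 marks a dropped haplotype. Returns EHH.
static double refine(const IntegerMatrix &A, const std::vector<int> &rows,
                     int col, std::vector<int> &ids, double denom,
                     RefineBuf &buf) {
  int n = (int)rows.size();
  buf.ensure(n);
  ++buf.epoch;
  const int *acol = A.begin() + (R_xlen_t)col * A.nrow();
  int next_id = 0;
  double pairs = 0.0;
  for (int i = 0; i < n; ++i) {
    if (ids[i] < 0) continue;
    int a = acol[rows[i]];
    if (a == NA_INTEGER) {
      ids[i] = -1;
      continue;
    }
    int key = ids[i] * 2 + a;
    int nid;
    if (buf.stamp[key] != buf.epoch) {
      buf.stamp[key] = buf.epoch;
      nid = buf.remap[key] = next_id++;
      buf.gcnt[nid] = 0;
    } else {
      nid = buf.remap[key];
    }
    ids[i] = nid;
    pairs += buf.gcnt[nid];  // joining a class of size g adds g pairs
    buf.gcnt[nid]++;
  }
  return pairs / denom;
}

static SideResult walk_side(const IntegerMatrix &A, const IntegerVector &pos,
                            int core, const std::vector<int> &rows, int dir,
                            double cutoff, double maxgap, RefineBuf &buf) {
  int M = A.ncol();
  int n0 = (int)rows.size();
  double denom = (double)n0 * (n0 - 1) / 2.0;
  std::vector<int> ids(n0, 0);
  double prev_e = 1.0, prev_d = 0.0, ihh = 0.0;
  int idx = core;
  SideResult res;
  while (true) {
    int nidx = idx + dir;
    if (nidx < 0 || nidx >= M) {
      res.ihh = ihh;
      res.border = true;
      return res;
    }
    if (std::abs((double)pos[nidx] - (double)pos[idx]) > maxgap) {
      res.ihh = ihh;
      res.border = false;
      return res;
    }
    double e = refine(A, rows, nidx, ids, denom, buf);
    double d = std::abs((double)pos[nidx] - (double)pos[core]);
    if (e < cutoff) {
      double x = prev_d + (prev_e - cutoff) * (d - prev_d) / (prev_e - e);
      ihh += 0.5 * (prev_e + cutoff) * (x - prev_d);
      res.ihh = ihh;
      res.border = false;
      return res;
    }
    ihh += 0.5 * (prev_e + e) * (d - prev_d);
    prev_e = e;
    prev_d = d;
    idx = nidx;
  }
}

// iHS scan: per qualifying SNP, iHH over ancestral-allele carriers and
// derived-allele carriers. anc[j] is the ancestral allele (0/1) or NA.
// [[Rcpp::export(name = ".scan_ihh_cpp")]]
DataFrame scan_ihh_cpp(IntegerMatrix A, IntegerVector pos, IntegerVector anc,
                       double maf_min, double cutoff, double maxgap,
                       int min_carriers) {
  int M = A.ncol(), H = A.nrow();
  RefineBuf buf;
  std::vector<int> out_idx;
  std::vector<double> out_pos, out_freq, out_a, out_d;
  std::vector<int> out_border;
  for (int j = 0; j < M; ++j) {
    if (anc[j] == NA_INTEGER) continue;
    int der = 1 - anc[j];
    std::vector<int> ca, cd;
    for (int i = 0; i < H; ++i) {
      int a = A(i, j);
      if (a == NA_INTEGER) continue;
      if (a == anc[j])
        ca.push_back(i);
      else
        cd.push_back(i);
    }
    int n = (int)(ca.size() + cd.size());
    if (n < 2) continue;
    double fd = (double)cd.size() / n;
    double maf = fd < 1.0 - fd ? fd : 1.0 - fd;
    if (maf < maf_min) continue;
    if ((int)ca.size() < min_carriers || (int)cd.size() < min_carriers)
      continue;
    SideResult al = walk_side(A, pos, j, ca, -1, cutoff, maxgap, buf);
    SideResult ar = walk_side(A, pos, j, ca, +1, cutoff, maxgap, buf);
    SideResult dl = walk_side(A, pos, j, cd, -1, cutoff, maxgap, buf);
    SideResult dr = walk_side(A, pos, j, cd, +1, cutoff, maxgap, buf);
    out_idx.push_back(j + 1);
    out_pos.push_back((double)pos[j]);
    out_freq.push_back(fd);
    out_a.push_back(al.ihh + ar.ihh);
    out_d.push_back(dl.ihh + dr.ihh);
    out_border.push_back(al.border || ar.border || dl.border || dr.border);
    (void)der;
  }
  return DataFrame::create(
      _["index"] = wrap(out_idx), _["position"] = wrap(out_pos),
      _["derived_freq"] = wrap(out_freq), _["ihh_a"] = wrap(out_a),
      _["ihh_d"] = wrap(out_d), _["border"] = wrap(out_border));
}

// Joint two-population walk for xpEHH. Both populations' EHH profiles are
// followed outward until both are below the cutoff; each population's
// profile is then integrated to the shared stopping extent (the farther of
// the two interpolated cutoff crossings).
struct XpSide {
  double ihh1, ihh2;
  bool border;
};

static double integrate_to(const std::vector<double> &d,
                           const std::vector<double> &e, double X) {
  // d[0] = 0, e[0] = 1; trapezoids with linear interpolation at X
  double ihh = 0.0;
  for (size_t k = 1; k < d.size(); ++k) {
    if (d[k] <= X) {
      ihh += 0.5 * (e[k - 1] + e[k]) * (d[k] - d[k - 1]);
    } else {
      double eX = e[k - 1] +
                  (e[k] - e[k - 1]) * (X - d[k - 1]) / (d[k] - d[k - 1]);
      ihh += 0.5 * (e[k - 1] + eX) * (X - d[k - 1]);
      break;
    }
  }
  return ihh;
}

static XpSide walk_side_xp(const IntegerMatrix &A1, const IntegerMatrix &A2,
                           const IntegerVector &pos, int core, int dir,
                           double cutoff, double maxgap, RefineBuf &b1,
                           RefineBuf &b2) {
  int M = pos.size();
  int n1 = A1.nrow(), n2 = A2.nrow();
  double den1 = (double)n1 * (n1 - 1) / 2.0;
  double den2 = (double)n2 * (n2 - 1) / 2.0;
  std::vector<int> rows1(n1), rows2(n2);
  for (int i = 0; i < n1; ++i) rows1[i] = i;
  for (int i = 0; i < n2; ++i) rows2[i] = i;
  std::vector<int> ids1(n1, 0), ids2(n2, 0);
  std::vector<double> d(1, 0.0), e1(1, 1.0), e2(1, 1.0);
  double cross1 = -1.0, cross2 = -1.0;
  int idx = core;
  XpSide res;
  res.border = false;
  while (true) {
    int nidx = idx + dir;
    bool gap_stop = false;
    if (nidx < 0 || nidx >= M) {
      // chromosome end with at least one population still >= cutoff
      if (cross1 < 0 || cross2 < 0) {
        res.ihh1 = res.ihh2 = 0.0;
        res.border = true;
        return res;
      }
      gap_stop = true;  // both already crossed: finish below
    } else if (std::abs((double)pos[nidx] - (double)pos[idx]) > maxgap) {
      gap_stop = true;
    }
    if (gap_stop) {
      double X = d.back();
      if (cross1 >= 0 && cross2 >= 0) X = std::max(cross1, cross2);
      res.ihh1 = integrate_to(d, e1, X);
      res.ihh2 = integrate_to(d, e2, X);
      return res;
    }
    double v1 = refine(A1, rows1, nidx, ids1, den1, b1);
    double v2 = refine(A2, rows2, nidx, ids2, den2, b2);
    double dist = std::abs((double)pos[nidx] - (double)pos[core]);
    if (cross1 < 0 && v1 < cutoff)
      cross1 = d.back() + (e1.back() - cutoff) * (dist - d.back()) /
                              (e1.back() - v1);
    if (cross2 < 0 && v2 < cutoff)
      cross2 = d.back() + (e2.back() - cutoff) * (dist - d.back()) /
                              (e2.back() - v2);
    d.push_back(dist);
    e1.push_back(v1);
    e2.push_back(v2);
    if (cross1 >= 0 && cross2 >= 0) {
      double X = std::max(cross1, cross2);
      res.ihh1 = integrate_to(d, e1, X);
      res.ihh2 = integrate_to(d, e2, X);
      return res;
    }
    idx = nidx;
  }
}

// [[Rcpp::export(name = ".scan_xpehh_cpp")]]
DataFrame scan_xpehh_cpp(IntegerMatrix A1, IntegerMatrix A2,
                         IntegerVector pos, IntegerVector cores,
                         double cutoff, double maxgap) {
  int K = cores.size();
  RefineBuf b1, b2;
  NumericVector out_pos(K), ihh1(K), ihh2(K);
  LogicalVector border(K);
  for (int k = 0; k < K; ++k) {
    int j = cores[k] - 1;
    XpSide left = walk_side_xp(A1, A2, pos, j, -1, cutoff, maxgap, b1, b2);
    XpSide right = walk_side_xp(A1, A2, pos, j, +1, cutoff, maxgap, b1, b2);
    out_pos[k] = (double)pos[j];
    ihh1[k] = left.ihh1 + right.ihh1;
    ihh2[k] = left.ihh2 + right.ihh2;
    border[k] = left.border || right.border;
  }
  return DataFrame::create(_["index"] = cores, _["position"] = out_pos,
                           _["ihh1"] = ihh1, _["ihh2"] = ihh2,
                           _["border"] = border);
}
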