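// Ancestral-recombination-graph simulator for a single diploid sample
// (two lineages) under a piecewise-constant demography and an arbitrary
// piecewise-linear genetic map.  This is Hudson's back-in-time algorithm
// realising the FULL ARG (trapped non-ancestral material recombines), not
// an SMC approximation: lineages far apart along the sequence can interact.
//
// Units: time in generations, physical positions in bases, genetic
// positions in Morgans.  Population sizes are diploid N, so a pair of
// lineages in the same population coalesces at rate 1/(2N) per generation.
//
// Optional extras:
//  * non-crossover gene conversion: tracts initiate uniformly on a
//    lineage's physical span at `gc_init` per base per generation with
//    exponentially distributed tract length (mean `gc_tract`);
//  * a two-population admixture scenario: each sampled lineage is assigned
//    to population 0 with probability `admix_frac` (else 1); the two
//    populations share the demography and merge `split_time` generations
//    ago; coalescence is only possible within a population.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct Seg {
  double a, b;  // physical half-open interval [a, b)
  int mask;     // 1 = ancestral to sample chromosome 1, 2 = chromosome 2
};

struct Lineage {
  std::vector<Seg> segs;  // sorted, non-overlapping, non-empty
  int pop;
  double pl, pr;          // physical extremes of ancestral material
  double gl, gr;          // genetic positions of the extremes (Morgans)
};

static inline double interp_vec(const std::vector<double>& xs,
                                const std::vector<double>& ys, double x) {
  size_t n = xs.size();
  size_t i = std::upper_bound(xs.begin(), xs.end(), x) - xs.begin();
  if (i == 0) return ys.front();
  if (i >= n) return ys.back();
  double x0 = xs[i - 1], x1 = xs[i];
  if (x1 == x0) return ys[i - 1];
  return ys[i - 1] + (ys[i] - ys[i - 1]) * (x - x0) / (x1 - x0);
}

class MapGrid {
public:
  std::vector<double> pos, mor;  // physical (bases), cumulative Morgans
  double gpos(double x) const { return interp_vec(pos, mor, x); }
  // inverse interpolation; plateaus (zero-rate stretches) return their
  // left edge, which is measure-zero for points drawn uniformly in
  // genetic length
  double ppos(double g) const { return interp_vec(mor, pos, g); }
};

static void refresh_extremes(Lineage& lin, const MapGrid& map) {
  lin.pl = lin.segs.front().a;
  lin.pr = lin.segs.back().b;
  lin.gl = map.gpos(lin.pl);
  lin.gr = map.gpos(lin.pr);
}

// merge two segment lists at a coalescence; intervals ancestral to both
// sample chromosomes have found their MRCA and are emitted as blocks
static std::vector<Seg> merge_coalesce(const std::vector<Seg>& A,
                                       const std::vector<Seg>& B,
                                       double t, double& found_len,
                                       std::vector<double>& blk_a,
                                       std::vector<double>& blk_b,
                                       std::vector<double>& blk_t) {
  std::vector<double> pts;
  pts.reserve(2 * (A.size() + B.size()));
  for (const Seg& s : A) { pts.push_back(s.a); pts.push_back(s.b); }
  for (const Seg& s : B) { pts.push_back(s.a); pts.push_back(s.b); }
  std::sort(pts.begin(), pts.end());
  pts.erase(std::unique(pts.begin(), pts.end()), pts.end());

  std::vector<Seg> out;
  size_t ia = 0, ib = 0;
  for (size_t i = 0; i + 1 < pts.size(); ++i) {
    double a = pts[i], b = pts[i + 1];
    double m = 0.5 * (a + b);
    while (ia < A.size() && A[ia].b <= m) ++ia;
    int ma = (ia < A.size() && A[ia].a <= m) ? A[ia].mask : 0;
    while (ib < B.size() && B[ib].b <= m) ++ib;
    int mb = (ib < B.size() && B[ib].a <= m) ? B[ib].mask : 0;
    int u = ma | mb;
    if (u == 3) {
      blk_a.push_back(a); blk_b.push_back(b); blk_t.push_back(t);
      found_len += b - a;
    } else if (u != 0) {
      if (!out.empty() && out.back().b == a && out.back().mask == u)
        out.back().b = b;
      else
        out.push_back({a, b, u});
    }
  }
  return out;
}

// split a segment list at x; reports whether x fell strictly inside a
// segment (a breakpoint on ancestral material: such events lie on the
// pedigree paths of the flanking sites with density exactly 2*T(x)*r,
// which is what the heterozygous-sites-per-block law refers to)
static bool split_at(const std::vector<Seg>& S, double x,
                     std::vector<Seg>& L, std::vector<Seg>& R) {
  L.clear(); R.clear();
  bool inside = false;
  for (const Seg& s : S) {
    if (s.b <= x) L.push_back(s);
    else if (s.a >= x) R.push_back(s);
    else {
      L.push_back({s.a, x, s.mask}); R.push_back({x, s.b, s.mask});
      inside = true;
    }
  }
  return inside;
}

// material inside/outside the gene-conversion tract [a, b)
static void extract_tract(const std::vector<Seg>& S, double a, double b,
                          std::vector<Seg>& inside, std::vector<Seg>& outside) {
  inside.clear(); outside.clear();
  for (const Seg& s : S) {
    double ia = std::max(s.a, a), ib = std::min(s.b, b);
    if (ia < ib) inside.push_back({ia, ib, s.mask});
    if (s.a < ia) outside.push_back({s.a, std::min(s.b, a), s.mask});
    if (s.b > ib && s.b > a) {
      double oa = std::max(s.a, b);
      if (oa < s.b) outside.push_back({oa, s.b, s.mask});
    }
  }
}

struct SimOut {
  std::vector<int> rep_id;
  std::vector<double> blk_a, blk_b, blk_t;
  std::vector<int> bp_rep;       // crossover breakpoints on ancestral
  std::vector<double> bp_x;      // material, per replicate
};

static void run_reps(const MapGrid& map_fixed,
                     const std::vector<double>& gprime, double alpha,
                     NumericVector epoch_start, NumericVector epoch_N,
                     int n_reps, double gc_init, double gc_tract,
                     double split_time, double admix_frac,
                     double max_events, SimOut& out) {
  const int n_ep = epoch_start.size();
  const bool perturb = alpha > 0.0;
  MapGrid map = map_fixed;
  const double L = map.pos.back();

  std::vector<int>& rep_id = out.rep_id;
  std::vector<double>& blk_a = out.blk_a;
  std::vector<double>& blk_b = out.blk_b;
  std::vector<double>& blk_t = out.blk_t;

  double events = 0.0;
  for (int rep = 0; rep < n_reps; ++rep) {
    if (perturb) {
      // fresh gamma realization of the interval lengths for this replicate
      double cum = 0.0;
      map.mor[0] = 0.0;
      for (size_t j = 0; j < gprime.size(); ++j) {
        double z = gprime[j] > 0.0
          ? R::rgamma(alpha * gprime[j], 1.0 / alpha)
          : 0.0;
        cum += z;
        map.mor[j + 1] = cum;
      }
      if (cum <= 0.0) { --rep; continue; }  // degenerate draw: redo
    }
    std::vector<Lineage> lin(2);
    for (int i = 0; i < 2; ++i) {
      lin[i].segs.assign(1, {0.0, L, i + 1});
      lin[i].pop = (split_time > 0.0 && R::unif_rand() >= admix_frac) ? 1 : 0;
      refresh_extremes(lin[i], map);
    }
    double t = 0.0, found = 0.0;
    int eidx = 0;
    size_t nblk0 = blk_a.size();

    while (found < L - 1e-6) {
      if (++events > max_events)
        stop("ARG simulation exceeded the event cap (%g)", max_events);
      while (eidx + 1 < n_ep && t >= epoch_start[eidx + 1]) ++eidx;
      double N = epoch_N[eidx];
      bool structured = (split_time > 0.0 && t < split_time);

      double Rtot = 0.0, Ptot = 0.0;
      int k0 = 0, k1 = 0;
      for (const Lineage& l : lin) {
        Rtot += l.gr - l.gl;
        Ptot += l.pr - l.pl;
        if (l.pop == 0) ++k0; else ++k1;
      }
      double npairs = structured
        ? 0.5 * (double(k0) * (k0 - 1) + double(k1) * (k1 - 1))
        : 0.5 * double(lin.size()) * (lin.size() - 1);
      double Ctot = (gc_init > 0.0) ? Ptot * gc_init : 0.0;
      double coal = npairs / (2.0 * N);
      double lambda = Rtot + Ctot + coal;

      double boundary = (eidx + 1 < n_ep) ? epoch_start[eidx + 1] : R_PosInf;
      if (structured && split_time < boundary) boundary = split_time;

      if (lambda <= 0.0) {
        if (!R_FINITE(boundary))
          stop("ARG simulation stalled: no events possible");
        t = boundary;
        if (!structured || t >= split_time) {
          if (t >= split_time) for (Lineage& l : lin) l.pop = 0;
        }
        continue;
      }
      double dt = R::exp_rand() / lambda;
      if (t + dt >= boundary) {
        t = boundary;
        if (split_time > 0.0 && t >= split_time)
          for (Lineage& l : lin) l.pop = 0;
        continue;
      }
      t += dt;

      double u = R::unif_rand() * lambda;
      if (u < Rtot) {
        // crossover recombination at a point uniform in genetic length
        double target = u;
        size_t i = 0; double acc = 0.0;
        for (; i < lin.size(); ++i) {
          acc += lin[i].gr - lin[i].gl;
          if (target < acc) break;
        }
        if (i >= lin.size()) i = lin.size() - 1;
        double g = lin[i].gr - (acc - target);
        if (g <= lin[i].gl || g >= lin[i].gr) continue;  // boundary draw
        double x = map.ppos(g);
        std::vector<Seg> Lseg, Rseg;
        bool inside = split_at(lin[i].segs, x, Lseg, Rseg);
        if (Lseg.empty() || Rseg.empty()) continue;
        if (inside) { out.bp_rep.push_back(rep + 1); out.bp_x.push_back(x); }
        Lineage right;
        right.segs = Rseg; right.pop = lin[i].pop;
        refresh_extremes(right, map);
        lin[i].segs = Lseg;
        refresh_extremes(lin[i], map);
        lin.push_back(std::move(right));
      } else if (u < Rtot + Ctot) {
        // gene-conversion tract
        double target = (u - Rtot) / gc_init;
        size_t i = 0; double acc = 0.0;
        for (; i < lin.size(); ++i) {
          acc += lin[i].pr - lin[i].pl;
          if (target < acc) break;
        }
        if (i >= lin.size()) i = lin.size() - 1;
        double x = lin[i].pr - (acc - target);
        double len = R::exp_rand() * gc_tract;
        std::vector<Seg> ins, outs;
        extract_tract(lin[i].segs, x, x + len, ins, outs);
        if (ins.empty() || outs.empty()) continue;
        Lineage tract;
        tract.segs = ins; tract.pop = lin[i].pop;
        refresh_extremes(tract, map);
        lin[i].segs = outs;
        refresh_extremes(lin[i], map);
        lin.push_back(std::move(tract));
      } else {
        // coalescence of a random (within-population) pair
        size_t i = 0, j = 0;
        for (int tries = 0; tries < 10000; ++tries) {
          i = (size_t)(R::unif_rand() * lin.size());
          j = (size_t)(R::unif_rand() * lin.size());
          if (i >= lin.size()) i = lin.size() - 1;
          if (j >= lin.size()) j = lin.size() - 1;
          if (i != j && (!structured || lin[i].pop == lin[j].pop)) break;
        }
        if (i == j || (structured && lin[i].pop != lin[j].pop)) continue;
        std::vector<Seg> merged =
          merge_coalesce(lin[i].segs, lin[j].segs, t, found, blk_a, blk_b, blk_t);
        int pop = lin[i].pop;
        if (i < j) std::swap(i, j);
        lin.erase(lin.begin() + i);
        lin.erase(lin.begin() + j);
        if (!merged.empty()) {
          Lineage m;
          m.segs = std::move(merged); m.pop = pop;
          refresh_extremes(m, map);
          lin.push_back(std::move(m));
        }
      }
    }
    for (size_t b = nblk0; b < blk_a.size(); ++b) rep_id.push_back(rep + 1);
  }
}

// [[Rcpp::export]]
List arg_sim_cpp(NumericVector map_pos, NumericVector map_morgans,
                 NumericVector epoch_start, NumericVector epoch_N,
                 int n_reps, double gc_init, double gc_tract,
                 double split_time, double admix_frac,
                 double max_events) {
  MapGrid map;
  map.pos.assign(map_pos.begin(), map_pos.end());
  map.mor.assign(map_morgans.begin(), map_morgans.end());
  SimOut out;
  run_reps(map, std::vector<double>(), -1.0, epoch_start, epoch_N, n_reps,
           gc_init, gc_tract, split_time, admix_frac, max_events, out);
  return List::create(_["rep"] = wrap(out.rep_id),
                      _["start"] = wrap(out.blk_a),
                      _["end"] = wrap(out.blk_b),
                      _["tmrca"] = wrap(out.blk_t),
                      _["bp_rep"] = wrap(out.bp_rep),
                      _["bp_x"] = wrap(out.bp_x));
}

// as arg_sim_cpp, but each replicate runs on a fresh gamma-perturbed map:
// interval j gets genetic length Gamma(alpha * gprime[j], rate alpha)
// [[Rcpp::export]]
List arg_sim_pert_cpp(NumericVector map_pos, NumericVector gprime_morgans,
                      double alpha,
                      NumericVector epoch_start, NumericVector epoch_N,
                      int n_reps, double gc_init, double gc_tract,
                      double split_time, double admix_frac,
                      double max_events) {
  MapGrid map;
  map.pos.assign(map_pos.begin(), map_pos.end());
  map.mor.assign(map_pos.size(), 0.0);
  std::vector<double> gprime(gprime_morgans.begin(), gprime_morgans.end());
  SimOut out;
  run_reps(map, gprime, alpha, epoch_start, epoch_N, n_reps,
           gc_init, gc_tract, split_time, admix_frac, max_events, out);
  return List::create(_["rep"] = wrap(out.rep_id),
                      _["start"] = wrap(out.blk_a),
                      _["end"] = wrap(out.blk_b),
                      _["tmrca"] = wrap(out.blk_t),
                      _["bp_rep"] = wrap(out.bp_rep),
                      _["bp_x"] = wrap(out.bp_x));
}
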