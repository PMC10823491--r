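// Structured-coalescent engine with migration and intralocus recombination.
//
// Hudson-style ancestral recombination graph over a continuous locus [0, L):
// lineages carry lists of ancestral segments; events are within-deme
// coalescence, migration between demes, and recombination (rate proportional
// to the bp span of carried material). Demographic events (population merges,
// size or migration changes) are applied at fixed times. Mutations fall on
// recorded edges under the infinite-sites model. All randomness is drawn from
// R's RNG so set.seed() gives bitwise-reproducible output.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const int MAXW = 4; // bitset words -> up to 256 sampled haplotypes

struct BSet {
  uint64_t w[MAXW];
  BSet() { for (int i = 0; i < MAXW; ++i) w[i] = 0; }
  void set(int b) { w[b >> 6] |= (uint64_t(1) << (b & 63)); }
  bool get(int b) const { return (w[b >> 6] >> (b & 63)) & 1; }
  BSet operator|(const BSet& o) const {
    BSet r;
    for (int i = 0; i < MAXW; ++i) r.w[i] = w[i] | o.w[i];
    return r;
  }
  bool operator==(const BSet& o) const {
    for (int i = 0; i < MAXW; ++i) if (w[i] != o.w[i]) return false;
    return true;
  }
  int count() const {
    int c = 0;
    for (int i = 0; i < MAXW; ++i) c += __builtin_popcountll(w[i]);
    return c;
  }
};

struct Seg {
  double l, r;
  int node;
  BSet bs;
};

struct Lin {
  int deme;
  std::vector<Seg> segs;
  double span() const { return segs.back().r - segs.front().l; }
};

struct Edge {
  double l, r;
  int child, parent;
  double tc, tp;
  BSet bs;
};

struct Mut {
  double pos;
  BSet bs;
};

struct ArgResult {
  std::vector<Edge> edges;
  std::vector<double> node_time;
  std::vector<Mut> muts;
};

// Simulate one locus; fills edges/node times and drops mutations.
static void sim_arg(const std::vector<int>& n_per_deme, double L, double recomb,
                    double mu, std::vector<double> ne, std::vector<double> mig,
                    const std::vector<double>& ev_time,
                    const std::vector<int>& ev_from, const std::vector<int>& ev_to,
                    const NumericMatrix& ev_ne, const NumericMatrix& ev_mig,
                    bool keep_edges, ArgResult& out) {
  const int D = (int)ne.size();
  int ntot = 0;
  for (int d = 0; d < D; ++d) ntot += n_per_deme[d];
  if (ntot > 64 * MAXW) stop("at most %d sampled haplotypes supported", 64 * MAXW);
  if (ntot < 2) stop("need at least 2 sampled haplotypes");

  std::vector<Lin> lins;
  lins.reserve(2 * ntot);
  out.edges.clear();
  out.node_time.assign(ntot, 0.0);
  out.muts.clear();

  int leaf = 0;
  for (int d = 0; d < D; ++d) {
    for (int i = 0; i < n_per_deme[d]; ++i) {
      Lin ln;
      ln.deme = d;
      Seg s;
      s.l = 0.0; s.r = L; s.node = leaf;
      s.bs.set(leaf);
      ln.segs.push_back(s);
      lins.push_back(ln);
      ++leaf;
    }
  }

  double t = 0.0;
  size_t next_ev = 0;
  const size_t E = ev_time.size();
  std::vector<int> kd(D);
  long iter = 0, max_iter = 100000000L;

  while (!lins.empty()) {
    if (++iter > max_iter) stop("coalescent simulation failed to terminate");
    std::fill(kd.begin(), kd.end(), 0);
    double span_tot = 0.0;
    for (const Lin& ln : lins) {
      ++kd[ln.deme];
      span_tot += ln.span();
    }
    double rate_coal = 0.0, rate_mig = 0.0;
    for (int d = 0; d < D; ++d) {
      if (kd[d] > 1) rate_coal += kd[d] * (kd[d] - 1) / 2.0 / (2.0 * ne[d]);
      double mo = 0.0;
      for (int j = 0; j < D; ++j) if (j != d) mo += mig[d * D + j];
      rate_mig += kd[d] * mo;
    }
    double rate_rec = recomb * span_tot;
    double tot = rate_coal + rate_mig + rate_rec;

    double dt = (tot > 0.0) ? R::rexp(1.0 / tot) : R_PosInf;
    if (next_ev < E && t + dt >= ev_time[next_ev]) {
      t = ev_time[next_ev];
      int from = ev_from[next_ev], to = ev_to[next_ev];
      if (from >= 0) {
        for (Lin& ln : lins) if (ln.deme == from) ln.deme = to;
      }
      for (int d = 0; d < D; ++d) ne[d] = ev_ne(next_ev, d);
      for (int d = 0; d < D * D; ++d) mig[d] = ev_mig(next_ev, d);
      ++next_ev;
      continue;
    }
    if (!(tot > 0.0)) stop("no possible events: lineages isolated with no pending merge");
    t += dt;

    double u = R::unif_rand() * tot;
    if (u < rate_coal) {
      // pick deme
      int d = -1;
      double acc = 0.0;
      for (int dd = 0; dd < D; ++dd) {
        if (kd[dd] > 1) acc += kd[dd] * (kd[dd] - 1) / 2.0 / (2.0 * ne[dd]);
        if (u < acc) { d = dd; break; }
      }
      if (d < 0) d = D - 1;
      // pick two distinct lineages in d
      int i1 = -1, i2 = -1;
      int a = (int)std::floor(R::unif_rand() * kd[d]);
      int b = (int)std::floor(R::unif_rand() * (kd[d] - 1));
      if (b >= a) ++b;
      int seen = 0;
      for (size_t i = 0; i < lins.size(); ++i) {
        if (lins[i].deme == d) {
          if (seen == a) i1 = (int)i;
          if (seen == b) i2 = (int)i;
          ++seen;
        }
      }
      int node = (int)out.node_time.size();
      out.node_time.push_back(t);
      std::vector<Seg>& A = lins[i1].segs;
      std::vector<Seg>& B = lins[i2].segs;
      std::vector<Seg> merged;
      merged.reserve(A.size() + B.size());
      size_t i = 0, j = 0;
      while (i < A.size() || j < B.size()) {
        if (j >= B.size() || (i < A.size() && A[i].r <= B[j].l)) { merged.push_back(A[i++]); continue; }
        if (i >= A.size() || B[j].r <= A[i].l) { merged.push_back(B[j++]); continue; }
        Seg& sa = A[i];
        Seg& sb = B[j];
        double lo = std::max(sa.l, sb.l), hi = std::min(sa.r, sb.r);
        if (sa.l < lo) { Seg p = sa; p.r = lo; merged.push_back(p); }
        if (sb.l < lo) { Seg p = sb; p.r = lo; merged.push_back(p); }
        Edge e1 = {lo, hi, sa.node, node, out.node_time[sa.node], t, sa.bs};
        Edge e2 = {lo, hi, sb.node, node, out.node_time[sb.node], t, sb.bs};
        out.edges.push_back(e1);
        out.edges.push_back(e2);
        BSet un = sa.bs | sb.bs;
        if (un.count() < ntot) {
          Seg p; p.l = lo; p.r = hi; p.node = node; p.bs = un;
          merged.push_back(p);
        }
        if (sa.r > hi) sa.l = hi; else ++i;
        if (sb.r > hi) sb.l = hi; else ++j;
      }
      // compact adjacent fragments of the same ancestor
      std::vector<Seg> comp;
      comp.reserve(merged.size());
      for (Seg& s : merged) {
        if (!comp.empty() && comp.back().node == s.node && comp.back().r == s.l &&
            comp.back().bs == s.bs)
          comp.back().r = s.r;
        else comp.push_back(s);
      }
      Lin nl;
      nl.deme = d;
      nl.segs.swap(comp);
      if (i1 > i2) std::swap(i1, i2);
      lins.erase(lins.begin() + i2);
      lins.erase(lins.begin() + i1);
      if (!nl.segs.empty()) lins.push_back(nl);
    } else if (u < rate_coal + rate_mig) {
      double v = u - rate_coal;
      double acc = 0.0;
      int li = -1, dest = -1;
      for (size_t i = 0; i < lins.size() && li < 0; ++i) {
        int d = lins[i].deme;
        for (int j = 0; j < D; ++j) {
          if (j == d) continue;
          acc += mig[d * D + j];
          if (v < acc) { li = (int)i; dest = j; break; }
        }
      }
      if (li < 0) { li = (int)lins.size() - 1; dest = (lins[li].deme + 1) % D; }
      lins[li].deme = dest;
    } else {
      // recombination: pick lineage weighted by span, split at uniform point
      double v = (u - rate_coal - rate_mig) / recomb;
      double acc = 0.0;
      int li = -1;
      for (size_t i = 0; i < lins.size(); ++i) {
        acc += lins[i].span();
        if (v < acc) { li = (int)i; break; }
      }
      if (li < 0) li = (int)lins.size() - 1;
      Lin& ln = lins[li];
      double left = ln.segs.front().l;
      double x = left + R::unif_rand() * ln.span();
      if (x <= left || x >= ln.segs.back().r) continue;
      std::vector<Seg> keep, off;
      for (Seg& s : ln.segs) {
        if (s.r <= x) keep.push_back(s);
        else if (s.l >= x) off.push_back(s);
        else {
          Seg a = s, b = s;
          a.r = x; b.l = x;
          keep.push_back(a);
          off.push_back(b);
        }
      }
      if (keep.empty() || off.empty()) continue;
      Lin nl;
      nl.deme = ln.deme;
      nl.segs.swap(off);
      ln.segs.swap(keep);
      lins.push_back(nl);
    }
  }

  // drop infinite-sites mutations on edges
  if (mu > 0.0 && !out.edges.empty()) {
    std::vector<double> cum(out.edges.size());
    double tot_area = 0.0;
    for (size_t i = 0; i < out.edges.size(); ++i) {
      tot_area += (out.edges[i].r - out.edges[i].l) * (out.edges[i].tp - out.edges[i].tc);
      cum[i] = tot_area;
    }
    int nmut = (int)R::rpois(mu * tot_area);
    out.muts.reserve(nmut);
    for (int m = 0; m < nmut; ++m) {
      double v = R::unif_rand() * tot_area;
      size_t e = std::lower_bound(cum.begin(), cum.end(), v) - cum.begin();
      if (e >= out.edges.size()) e = out.edges.size() - 1;
      Mut mt;
      mt.pos = out.edges[e].l + R::unif_rand() * (out.edges[e].r - out.edges[e].l);
      mt.bs = out.edges[e].bs;
      out.muts.push_back(mt);
    }
    std::sort(out.muts.begin(), out.muts.end(),
              [](const Mut& a, const Mut& b) { return a.pos < b.pos; });
  }
  if (!keep_edges) out.edges.clear();
}

static std::vector<int> as_ivec(const IntegerVector& v) {
  return std::vector<int>(v.begin(), v.end());
}
static std::vector<double> as_dvec(const NumericVector& v) {
  return std::vector<double>(v.begin(), v.end());
}

// [[Rcpp::export(name = ".cpp_simulate_arg")]]
List cpp_simulate_arg(IntegerVector n_per_deme, double L, double recomb, double mu,
                      NumericVector ne0, NumericVector mig0,
                      NumericVector ev_time, IntegerVector ev_from, IntegerVector ev_to,
                      NumericMatrix ev_ne, NumericMatrix ev_mig, bool return_tree) {
  ArgResult res;
  sim_arg(as_ivec(n_per_deme), L, recomb, mu, as_dvec(ne0), as_dvec(mig0),
          as_dvec(ev_time), as_ivec(ev_from), as_ivec(ev_to), ev_ne, ev_mig,
          return_tree, res);
  int ntot = 0;
  for (int i = 0; i < n_per_deme.size(); ++i) ntot += n_per_deme[i];
  int S = (int)res.muts.size();
  IntegerMatrix G(ntot, S);
  NumericVector pos(S);
  for (int s = 0; s < S; ++s) {
    pos[s] = res.muts[s].pos;
    for (int h = 0; h < ntot; ++h) G(h, s) = res.muts[s].bs.get(h) ? 1 : 0;
  }
  List out = List::create(_["genotypes"] = G, _["positions"] = pos);
  if (return_tree) {
    int ne_ = (int)res.edges.size();
    IntegerVector ec(ne_), ep(ne_);
    NumericVector el(ne_), er(ne_);
    for (int i = 0; i < ne_; ++i) {
      ec[i] = res.edges[i].child;
      ep[i] = res.edges[i].parent;
      el[i] = res.edges[i].l;
      er[i] = res.edges[i].r;
    }
    out["edge_child"] = ec;
    out["edge_parent"] = ep;
    out["edge_left"] = el;
    out["edge_right"] = er;
    out["node_time"] = NumericVector(res.node_time.begin(), res.node_time.end());
  }
  return out;
}

// Per-locus summary statistics over exactly three sampled populations,
// in the fixed order used by the feature vectors (see R/features.R):
// S per pop + total, pi per pop + total, thetaW per pop + total,
// Hudson Fst per pair, shared per pair, private per pop, private per pair,
// fixed-derived per pop, fixed differences per pair. Pairs: (1,2),(1,3),(2,3).
static void locus_stats(const ArgResult& res, const std::vector<int>& n_samp,
                        const std::vector<int>& off, double L, double* st) {
  const int NS = 30;
  for (int i = 0; i < NS; ++i) st[i] = 0.0;
  int n1 = n_samp[0], n2 = n_samp[1], n3 = n_samp[2];
  int nt = n1 + n2 + n3;
  double hw_sum[3] = {0, 0, 0}, hb_sum[3] = {0, 0, 0};
  const int pa[3] = {0, 0, 1}, pb[3] = {1, 2, 2};

  for (const Mut& m : res.muts) {
    int c[3];
    for (int p = 0; p < 3; ++p) {
      int cc = 0;
      for (int h = off[p]; h < off[p] + n_samp[p]; ++h) cc += m.bs.get(h) ? 1 : 0;
      c[p] = cc;
    }
    int ct = c[0] + c[1] + c[2];
    if (ct == 0 || ct == nt) continue; // not segregating in the sample
    bool poly[3];
    double h[3];
    for (int p = 0; p < 3; ++p) {
      int np = n_samp[p];
      poly[p] = c[p] > 0 && c[p] < np;
      h[p] = (np > 1) ? 2.0 * c[p] * (np - c[p]) / ((double)np * (np - 1)) : 0.0;
      if (poly[p]) { st[p] += 1.0; st[4 + p] += h[p]; }
    }
    st[3] += 1.0;                                             // S total
    st[7] += 2.0 * ct * (nt - ct) / ((double)nt * (nt - 1));  // pi total
    for (int q = 0; q < 3; ++q) {
      int p1 = pa[q], p2 = pb[q];
      double f1 = (double)c[p1] / n_samp[p1], f2 = (double)c[p2] / n_samp[p2];
      hw_sum[q] += 0.5 * (h[p1] + h[p2]);
      hb_sum[q] += f1 * (1.0 - f2) + f2 * (1.0 - f1);
      if (poly[p1] && poly[p2]) st[15 + q] += 1.0;  // shared
      if ((c[p1] == n_samp[p1] && c[p2] == 0) || (c[p1] == 0 && c[p2] == n_samp[p2]))
        st[27 + q] += 1.0;  // fixed difference in pair
    }
    for (int p = 0; p < 3; ++p) {
      int o1 = (p + 1) % 3, o2 = (p + 2) % 3;
      bool mono1 = !poly[o1], mono2 = !poly[o2];
      if (poly[p] && mono1 && mono2) st[18 + p] += 1.0;  // private polymorphism
      if (c[p] == n_samp[p] && c[o1] == 0 && c[o2] == 0) st[24 + p] += 1.0;  // fixed derived
    }
    for (int q = 0; q < 3; ++q) {  // pair-private derived allele
      int p1 = pa[q], p2 = pb[q], po = 3 - pa[q] - pb[q];
      if (c[p1] > 0 && c[p2] > 0 && c[po] == 0) st[21 + q] += 1.0;
    }
  }
  auto a1 = [](int n) {
    double s = 0.0;
    for (int i = 1; i < n; ++i) s += 1.0 / i;
    return s;
  };
  for (int p = 0; p < 3; ++p) {
    st[4 + p] /= L;
    st[8 + p] = st[p] / (a1(n_samp[p]) * L);
  }
  st[7] /= L;
  st[11] = st[3] / (a1(nt) * L);
  for (int q = 0; q < 3; ++q)
    st[12 + q] = (hb_sum[q] > 0) ? 1.0 - hw_sum[q] / hb_sum[q] : 0.0;
}

// [[Rcpp::export(name = ".cpp_sim_dataset_stats")]]
NumericMatrix cpp_sim_dataset_stats(int n_loci, IntegerVector n_per_deme, double L,
                                    double recomb, double mu, NumericVector ne0,
                                    NumericVector mig0, NumericVector ev_time,
                                    IntegerVector ev_from, IntegerVector ev_to,
                                    NumericMatrix ev_ne, NumericMatrix ev_mig) {
  std::vector<int> nv = as_ivec(n_per_deme);
  std::vector<int> samp, off;
  int cum = 0;
  for (size_t d = 0; d < nv.size(); ++d) {
    if (nv[d] > 0) { samp.push_back(nv[d]); off.push_back(cum); }
    cum += nv[d];
  }
  if (samp.size() != 3) stop("dataset statistics require exactly 3 sampled populations");
  NumericMatrix out(n_loci, 30);
  ArgResult res;
  double st[30];
  for (int i = 0; i < n_loci; ++i) {
    sim_arg(nv, L, recomb, mu, as_dvec(ne0), as_dvec(mig0), as_dvec(ev_time),
            as_ivec(ev_from), as_ivec(ev_to), ev_ne, ev_mig, false, res);
    locus_stats(res, samp, off, L, st);
    for (int s = 0; s < 30; ++s) out(i, s) = st[s];
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
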