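// Coalescent simulator: ancestral recombination graph over a finite sequence
// with piecewise-constant population sizes, asymmetric backward migration,
// mass-migration pulses/splits, and an optional structured selective-sweep
// phase driven by a pre-computed per-generation allele-frequency trajectory.
//
// Lineages carry their ancestral material as ordered segment lists; each
// segment stores the set of sampled haplotypes it subtends as a bitmask
// (<= 256 samples).  A segment subtending the full sample set has reached
// its marginal MRCA and is pruned, which guarantees termination.  Mutations
// are laid down during waiting intervals (infinite-sites on a continuous
// axis), so no tree reconstruction is needed.
//
// Time is measured backwards in generations; sizes are diploid Ne; migration
// rates are backward rates per lineage per generation (the fraction of the
// receiving population replaced per generation, as fitted by diffusion-based
// demographic inference).

#include <Rcpp.h>
#include <array>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const int NW = 4; // 4 x 64 = up to 256 sampled haplotypes

struct Bits {
  std::array<uint64_t, NW> w;
  Bits() { w.fill(0); }
  void set(int i) { w[i >> 6] |= (uint64_t(1) << (i & 63)); }
  bool get(int i) const { return (w[i >> 6] >> (i & 63)) & 1; }
  void orWith(const Bits& o) { for (int k = 0; k < NW; ++k) w[k] |= o.w[k]; }
  bool operator==(const Bits& o) const { return w == o.w; }
  int count() const {
    int c = 0;
    for (int k = 0; k < NW; ++k) {
#if defined(__GNUC__) || defined(__clang__)
      c += __builtin_popcountll(w[k]);
#else
      uint64_t v = w[k];
      while (v) { v &= v - 1; ++c; }
#endif
    }
    return c;
  }
  int countAnd(const Bits& o) const {
    int c = 0;
    for (int k = 0; k < NW; ++k) {
      uint64_t v = w[k] & o.w[k];
#if defined(__GNUC__) || defined(__clang__)
      c += __builtin_popcountll(v);
#else
      while (v) { v &= v - 1; ++c; }
#endif
    }
    return c;
  }
};

struct Seg {
  double l, r; // half-open [l, r)
  Bits b;
};

struct Lineage {
  int pop;
  int cls; // allelic class at the selected site during a sweep phase
  std::vector<Seg> segs;
  double matL() const { return segs.front().l; }
  double matR() const { return segs.back().r; }
  double span() const { return segs.empty() ? 0.0 : (matR() - matL()); }
  double matLen() const {
    double s = 0.0;
    for (const Seg& sg : segs) s += sg.r - sg.l;
    return s;
  }
};

struct TEvent {
  double t;
  int kind; // 0 = size change, 1 = migration change, 2 = mass migration
  int a, b;
  double x;
  bool record;
  int id;
};

struct Mut {
  double pos;
  Bits b;
};

struct TractRec {
  int evid;
  double l, r;
  Bits b;
};

// Merge the segment lists of two coalescing lineages.  Overlapping material
// ORs the descendant sets; any stretch now subtending all samples is pruned.
static void mergeSegs(const std::vector<Seg>& A, const std::vector<Seg>& B,
                      const Bits& full, std::vector<Seg>& out) {
  out.clear();
  std::vector<double> bp;
  bp.reserve(2 * (A.size() + B.size()));
  for (const Seg& s : A) { bp.push_back(s.l); bp.push_back(s.r); }
  for (const Seg& s : B) { bp.push_back(s.l); bp.push_back(s.r); }
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end()), bp.end());
  size_t ia = 0, ib = 0;
  for (size_t k = 0; k + 1 < bp.size(); ++k) {
    double l = bp[k], r = bp[k + 1];
    while (ia < A.size() && A[ia].r <= l) ++ia;
    while (ib < B.size() && B[ib].r <= l) ++ib;
    bool inA = ia < A.size() && A[ia].l <= l && A[ia].r >= r;
    bool inB = ib < B.size() && B[ib].l <= l && B[ib].r >= r;
    if (!inA && !inB) continue;
    Bits nb;
    if (inA) nb.orWith(A[ia].b);
    if (inB) nb.orWith(B[ib].b);
    if (nb == full) continue; // marginal MRCA reached: drop
    if (!out.empty() && out.back().r == l && out.back().b == nb)
      out.back().r = r;
    else {
      Seg s; s.l = l; s.r = r; s.b = nb;
      out.push_back(s);
    }
  }
}

class Engine {
public:
  double L, mu, rbp;
  int npop, nsam;
  std::vector<int> samplePop;
  std::vector<double> N;
  std::vector<std::vector<double>> mig;
  std::vector<TEvent> events;
  // sweep
  bool hasSweep = false;
  int sweepPop = 0;
  double sweepPos = 0.0;
  std::vector<double> traj; // traj[g] = derived frequency g generations ago
  std::vector<int> carriers;

  Bits full;
  std::vector<Lineage> lin;
  std::vector<Mut> muts;
  std::vector<TractRec> tracts;
  size_t eidx = 0;
  double t = 0.0;

  void init() {
    full = Bits();
    for (int i = 0; i < nsam; ++i) full.set(i);
    lin.clear(); muts.clear(); tracts.clear();
    eidx = 0; t = 0.0;
    for (int i = 0; i < nsam; ++i) {
      Lineage li;
      li.pop = samplePop[i];
      li.cls = 0;
      Seg s; s.l = 0.0; s.r = L; s.b = Bits(); s.b.set(i);
      li.segs.push_back(s);
      lin.push_back(li);
    }
    for (int c : carriers)
      if (c >= 0 && c < nsam) lin[c].cls = 1;
  }

  void applyEvent(const TEvent& ev) {
    if (ev.kind == 0) {
      N[ev.a] = ev.x;
    } else if (ev.kind == 1) {
      mig[ev.a][ev.b] = ev.x;
    } else { // mass migration: each lineage in pop a moves to pop b w.p. x
      for (Lineage& li : lin) {
        if (li.pop == ev.a && R::unif_rand() < ev.x) {
          if (ev.record) {
            for (const Seg& s : li.segs) {
              TractRec tr; tr.evid = ev.id; tr.l = s.l; tr.r = s.r; tr.b = s.b;
              tracts.push_back(tr);
            }
          }
          li.pop = ev.b;
          li.cls = 0;
        }
      }
    }
  }

  double totalMat() const {
    double s = 0.0;
    for (const Lineage& li : lin) s += li.matLen();
    return s;
  }

  void dropMutations(double dt) {
    double M = totalMat();
    if (M <= 0.0 || dt <= 0.0) return;
    int nm = (int) R::rpois(mu * M * dt);
    for (int k = 0; k < nm; ++k) {
      double u = R::unif_rand() * M, acc = 0.0;
      for (const Lineage& li : lin) {
        double ml = li.matLen();
        if (u < acc + ml) {
          double v = u - acc;
          for (const Seg& s : li.segs) {
            double len = s.r - s.l;
            if (v < len) {
              Mut m; m.pos = s.l + v; m.b = s.b;
              muts.push_back(m);
              break;
            }
            v -= len;
          }
          break;
        }
        acc += ml;
      }
    }
  }

  void coalescePair(int ia, int ib) {
    std::vector<Seg> merged;
    mergeSegs(lin[ia].segs, lin[ib].segs, full, merged);
    lin[ia].segs.swap(merged);
    if (ia != ib) {
      lin.erase(lin.begin() + ib);
      if (ib < ia) --ia;
    }
    if (lin[ia].segs.empty()) lin.erase(lin.begin() + ia);
  }

  // merge a random same-pop (and same-class, during sweeps) pair
  void coalesceRandom(int pop, int cls, bool useCls) {
    std::vector<int> idx;
    for (size_t i = 0; i < lin.size(); ++i)
      if (lin[i].pop == pop && (!useCls || lin[i].cls == cls))
        idx.push_back((int) i);
    int k = (int) idx.size();
    if (k < 2) return;
    int i = (int) (R::unif_rand() * k); if (i >= k) i = k - 1;
    int j = (int) (R::unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
    if (j >= i) ++j;
    coalescePair(idx[i], idx[j]);
  }

  void recombineLineage(size_t i, double xfreq, bool inSweep) {
    Lineage& li = lin[i];
    double a = li.matL(), b = li.matR();
    if (b - a <= 0.0) return;
    double u = a + R::unif_rand() * (b - a);
    std::vector<Seg> left, right;
    for (const Seg& s : li.segs) {
      if (s.r <= u) left.push_back(s);
      else if (s.l >= u) right.push_back(s);
      else {
        Seg sl = s; sl.r = u;
        Seg sr = s; sr.l = u;
        left.push_back(sl); right.push_back(sr);
      }
    }
    if (left.empty() || right.empty()) return;
    Lineage nw;
    nw.pop = li.pop;
    nw.cls = li.cls;
    bool leftHasSel = sweepPos < u;
    if (inSweep && li.pop == sweepPop) {
      // the side not linked to the selected site re-draws its class from
      // the current derived-allele frequency
      int freeCls = (R::unif_rand() < xfreq) ? 1 : 0;
      if (leftHasSel) { li.segs = left; nw.segs = right; nw.cls = freeCls; }
      else            { li.segs = right; nw.segs = left; nw.cls = freeCls; }
    } else {
      li.segs = left; nw.segs = right;
    }
    lin.push_back(nw);
  }

  int countPop(int pop, int cls, bool useCls) const {
    int k = 0;
    for (const Lineage& li : lin)
      if (li.pop == pop && (!useCls || li.cls == cls)) ++k;
    return k;
  }

  // Discrete-generation phase covering the sweep trajectory.
  void runDiscrete() {
    int G = (int) traj.size();
    for (int g = 0; g < G && !lin.empty(); ++g) {
      while (eidx < events.size() && events[eidx].t <= (double) g)
        applyEvent(events[eidx++]);
      dropMutations(1.0);
      double x = traj[g];
      // recombination
      for (size_t i = lin.size(); i-- > 0;) {
        double p = rbp * lin[i].span();
        if (p > 0.0 && R::unif_rand() < p) recombineLineage(i, x, true);
      }
      // migration (selected-class lineages do not migrate: the derived
      // allele segregates only in the swept population)
      for (Lineage& li : lin) {
        double mtot = 0.0;
        for (int q = 0; q < npop; ++q) mtot += mig[li.pop][q];
        if (mtot <= 0.0) continue;
        if (li.pop == sweepPop && li.cls == 1) continue;
        if (R::unif_rand() < mtot) {
          double u = R::unif_rand() * mtot, acc = 0.0;
          for (int q = 0; q < npop; ++q) {
            acc += mig[li.pop][q];
            if (u < acc) {
              li.pop = q;
              li.cls = (q == sweepPop && R::unif_rand() < x) ? 1 : 0;
              break;
            }
          }
        }
      }
      // coalescence
      for (int p = 0; p < npop; ++p) {
        if (p == sweepPop) {
          double nder = 2.0 * N[p] * x, nanc = 2.0 * N[p] * (1.0 - x);
          for (int cls = 0; cls <= 1; ++cls) {
            double sz = cls ? nder : nanc;
            int k = countPop(p, cls, true);
            if (k < 2) continue;
            if (sz < 1.0) { // class absorbed: force complete coalescence
              while (countPop(p, cls, true) >= 2) coalesceRandom(p, cls, true);
              continue;
            }
            double pr = std::min(1.0, 1.0 / sz);
            int nev = (int) R::rbinom(k * (k - 1) / 2.0, pr);
            for (int e = 0; e < nev && countPop(p, cls, true) >= 2; ++e)
              coalesceRandom(p, cls, true);
          }
        } else {
          int k = countPop(p, 0, false);
          if (k < 2) continue;
          double pr = std::min(1.0, 1.0 / (2.0 * N[p]));
          int nev = (int) R::rbinom(k * (k - 1) / 2.0, pr);
          for (int e = 0; e < nev && countPop(p, 0, false) >= 2; ++e)
            coalesceRandom(p, 0, false);
        }
      }
    }
    // sweep origin: remaining derived lineages descend from the single
    // originating chromosome
    while (countPop(sweepPop, 1, true) >= 2) coalesceRandom(sweepPop, 1, true);
    for (Lineage& li : lin) li.cls = 0;
    t = (double) G;
    while (eidx < events.size() && events[eidx].t <= t)
      applyEvent(events[eidx++]);
  }

  void runContinuous() {
    long iter = 0;
    while (!lin.empty()) {
      if (++iter > 200000000L) stop("coalescent simulation failed to terminate");
      double coalTot = 0.0, recTot = 0.0, migTot = 0.0;
      std::vector<double> coalRate(npop, 0.0);
      std::vector<int> kpop(npop, 0);
      for (const Lineage& li : lin) ++kpop[li.pop];
      for (int p = 0; p < npop; ++p) {
        coalRate[p] = kpop[p] * (kpop[p] - 1) / 2.0 / (2.0 * N[p]);
        coalTot += coalRate[p];
      }
      std::vector<double> recRate(lin.size(), 0.0);
      for (size_t i = 0; i < lin.size(); ++i) {
        recRate[i] = rbp * lin[i].span();
        recTot += recRate[i];
      }
      std::vector<double> migRatePop(npop, 0.0);
      for (int p = 0; p < npop; ++p) {
        double m = 0.0;
        for (int q = 0; q < npop; ++q) m += mig[p][q];
        migRatePop[p] = kpop[p] * m;
        migTot += migRatePop[p];
      }
      double lambda = coalTot + recTot + migTot;
      double tNext = (eidx < events.size()) ? events[eidx].t : R_PosInf;
      if (lambda <= 0.0) {
        if (!R_finite(tNext)) stop("stuck: no events possible and no scheduled changes");
        dropMutations(tNext - t);
        t = tNext;
        applyEvent(events[eidx++]);
        continue;
      }
      double dt = R::rexp(1.0 / lambda);
      if (t + dt >= tNext) {
        dropMutations(tNext - t);
        t = tNext;
        applyEvent(events[eidx++]);
        continue;
      }
      dropMutations(dt);
      t += dt;
      double u = R::unif_rand() * lambda;
      if (u < coalTot) {
        double acc = 0.0;
        for (int p = 0; p < npop; ++p) {
          acc += coalRate[p];
          if (u < acc) { coalesceRandom(p, 0, false); break; }
        }
      } else if (u < coalTot + recTot) {
        double v = u - coalTot, acc = 0.0;
        for (size_t i = 0; i < lin.size(); ++i) {
          acc += recRate[i];
          if (v < acc) { recombineLineage(i, 0.0, false); break; }
        }
      } else {
        double v = u - coalTot - recTot, acc = 0.0;
        for (size_t i = 0; i < lin.size(); ++i) {
          double m = 0.0;
          for (int q = 0; q < npop; ++q) m += mig[lin[i].pop][q];
          if (v < acc + m) {
            double w = v - acc, a2 = 0.0;
            for (int q = 0; q < npop; ++q) {
              a2 += mig[lin[i].pop][q];
              if (w < a2) { lin[i].pop = q; break; }
            }
            break;
          }
          acc += m;
        }
      }
    }
  }

  void run() {
    init();
    if (hasSweep && !traj.empty()) runDiscrete();
    runContinuous();
    std::sort(muts.begin(), muts.end(),
              [](const Mut& a, const Mut& b) { return a.pos < b.pos; });
  }
};

// [[Rcpp::export(name = ".cpp_sim_coalescent")]]
List cpp_sim_coalescent(double L, double mu, double rbp,
                        IntegerVector sample_pops, int npop,
                        NumericVector init_sizes, NumericMatrix init_mig,
                        DataFrame events, Nullable<List> sweep,
                        int nreps, int return_mode) {
  int nsam = sample_pops.size();
  if (nsam > 64 * NW) stop("at most 256 sampled haplotypes are supported");
  if (npop < 1) stop("need at least one population");

  Engine eng;
  eng.L = L; eng.mu = mu; eng.rbp = rbp;
  eng.npop = npop; eng.nsam = nsam;
  eng.samplePop = as<std::vector<int>>(sample_pops);
  for (int p : eng.samplePop)
    if (p < 0 || p >= npop) stop("sample population index out of range");

  std::vector<double> N0 = as<std::vector<double>>(init_sizes);
  if ((int) N0.size() != npop) stop("init_sizes must have one entry per population");
  std::vector<std::vector<double>> M0(npop, std::vector<double>(npop, 0.0));
  for (int i = 0; i < npop; ++i)
    for (int j = 0; j < npop; ++j)
      if (i != j) M0[i][j] = init_mig(i, j);

  std::vector<TEvent> evs;
  NumericVector et = events["time"];
  IntegerVector ek = events["kind"], ea = events["a"], eb = events["b"];
  NumericVector ex = events["x"];
  LogicalVector er = events["record"];
  for (int i = 0; i < et.size(); ++i) {
    TEvent e;
    e.t = et[i]; e.kind = ek[i]; e.a = ea[i]; e.b = eb[i];
    e.x = ex[i]; e.record = er[i]; e.id = i;
    if (e.a < 0 || e.a >= npop || e.b < 0 || e.b >= npop)
      stop("event population index out of range");
    evs.push_back(e);
  }
  std::stable_sort(evs.begin(), evs.end(),
                   [](const TEvent& a, const TEvent& b) { return a.t < b.t; });
  eng.events = evs;

  if (sweep.isNotNull()) {
    List sw(sweep);
    eng.hasSweep = true;
    eng.sweepPop = as<int>(sw["pop"]);
    eng.sweepPos = as<double>(sw["pos"]);
    eng.traj = as<std::vector<double>>(sw["freq"]);
    eng.carriers = as<std::vector<int>>(sw["carriers"]);
  }

  std::vector<int> repIdx;
  std::vector<double> positions;
  std::vector<Bits> bits;
  std::vector<int> trRep, trEv, trSample;
  std::vector<double> trL, trR;

  for (int rep = 0; rep < nreps; ++rep) {
    eng.N = N0;
    eng.mig = M0;
    eng.run();
    for (const Mut& m : eng.muts) {
      repIdx.push_back(rep + 1);
      positions.push_back(m.pos);
      bits.push_back(m.b);
    }
    for (const TractRec& tr : eng.tracts) {
      for (int s = 0; s < nsam; ++s) {
        if (tr.b.get(s)) {
          trRep.push_back(rep + 1);
          trEv.push_back(tr.evid + 1);
          trSample.push_back(s + 1);
          trL.push_back(tr.l);
          trR.push_back(tr.r);
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  int S = (int) positions.size();
  List out;
  out["rep"] = wrap(repIdx);
  out["pos"] = wrap(positions);
  if (return_mode == 1) {
    // per-population derived-allele counts
    IntegerMatrix cnt(S, npop);
    std::vector<Bits> popmask(npop);
    for (int i = 0; i < nsam; ++i) popmask[eng.samplePop[i]].set(i);
    for (int s = 0; s < S; ++s)
      for (int p = 0; p < npop; ++p)
        cnt(s, p) = bits[s].countAnd(popmask[p]);
    out["counts"] = cnt;
  } else {
    IntegerMatrix g(S, nsam);
    for (int s = 0; s < S; ++s)
      for (int i = 0; i < nsam; ++i)
        g(s, i) = bits[s].get(i) ? 1 : 0;
    out["geno"] = g;
  }
  out["tracts"] = DataFrame::create(
      _["rep"] = wrap(trRep), _["event"] = wrap(trEv),
      _["haplotype"] = wrap(trSample), _["left"] = wrap(trL),
      _["right"] = wrap(trR));
  return out;
}
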