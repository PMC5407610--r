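// Extended haplotype homozygosity profiles.
//
// EHH(x) for a core site and a set of "carrier" haplotypes is the
// probability that two randomly drawn carriers are identical at every
// site between the core and x.  Computed by progressive group refinement:
// haplotypes start in one group at the core and split whenever alleles
// differ at the next site outward.  Missing alleles (NA) are treated as a
// private allele, i.e. they always break haplotype identity.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static double groupHomozygosity(const std::vector<int>& grp) {
  std::unordered_map<int, int> cnt;
  for (int g : grp) ++cnt[g];
  double n = (double) grp.size();
  if (n < 2) return 0.0;
  double num = 0.0;
  for (auto& kv : cnt) num += kv.second * (kv.second - 1.0) / 2.0;
  return num / (n * (n - 1.0) / 2.0);
}

// geno: sites x haplotypes, values 0/1 (NA allowed)
// core: 0-based site index; keep: 0-based haplotype indices
// Walks outward in one direction until EHH < cutoff (the first value below
// the cutoff is included), past `limit` (0-based site bound, -1 = none),
// or the end of the matrix.
static void walk(const IntegerMatrix& geno, int core,
                 const std::vector<int>& keep, int dir, double cutoff,
                 int limit, std::vector<int>& sites, std::vector<double>& ehh) {
  int S = geno.nrow();
  int nc = (int) keep.size();
  std::vector<int> grp(nc, 0);
  int nextId = 1;
  for (int s = core + dir; s >= 0 && s < S; s += dir) {
    if (limit >= 0 && ((dir > 0 && s > limit) || (dir < 0 && s < limit)))
      break;
    std::unordered_map<long long, int> remap;
    for (int i = 0; i < nc; ++i) {
      int a = geno(s, keep[i]);
      int av = (a == NA_INTEGER) ? (2 + keep[i]) : a; // NA: private allele
      long long key = (long long) grp[i] * 1024LL + av;
      auto it = remap.find(key);
      if (it == remap.end()) {
        remap.emplace(key, nextId);
        grp[i] = nextId++;
      } else {
        grp[i] = it->second;
      }
    }
    double e = groupHomozygosity(grp);
    sites.push_back(s + 1);
    ehh.push_back(e);
    if (e < cutoff) break;
  }
}

// [[Rcpp::export(name = ".cpp_ehh_profile")]]
List cpp_ehh_profile(IntegerMatrix geno, int core, IntegerVector keep,
                     double cutoff, int limit_left = -1, int limit_right = -1) {
  std::vector<int> k;
  for (int i = 0; i < keep.size(); ++i) k.push_back(keep[i] - 1);
  std::vector<int> sL, sR;
  std::vector<double> eL, eR;
  walk(geno, core - 1, k, -1, cutoff,
       limit_left > 0 ? limit_left - 1 : -1, sL, eL);
  walk(geno, core - 1, k, +1, cutoff,
       limit_right > 0 ? limit_right - 1 : -1, sR, eR);
  return List::create(_["site_left"] = wrap(sL), _["ehh_left"] = wrap(eL),
                      _["site_right"] = wrap(sR), _["ehh_right"] = wrap(eR));
}
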