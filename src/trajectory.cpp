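// Wright-Fisher allele-frequency trajectory samplers for sweep scenarios.
//
// Backward sampler: from the sweep-conclusion frequency, apply the
// deterministic logistic decrement for genic selection (relative fitness
// 1 + s) plus binomial drift each generation until loss; trajectories that
// fix backwards are rejected (a segregating allele cannot have fallen from
// fixation without recurrent mutation).
//
// Forward sampler: from a single copy at the origin, selection plus
// binomial drift to the present, conditioned on the allele segregating
// (0 < x < 1) throughout.
//
// Population size per generation is supplied by the caller (piecewise
// demography), as haploid counts.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_traj_backward")]]
NumericVector cpp_traj_backward(double x_end, double s, NumericVector n2,
                                int max_attempts) {
  int maxg = n2.size(); // generations available beyond the conclusion
  for (int att = 0; att < max_attempts; ++att) {
    std::vector<double> xs;
    double x = x_end;
    bool ok = true;
    for (int g = 0; g < maxg; ++g) {
      double N2 = n2[g];
      double xprev = x / (1.0 + s - s * x);
      x = R::rbinom(N2, xprev) / N2;
      if (x >= 1.0) { ok = false; break; }
      xs.push_back(x);
      if (x <= 0.0) break;
    }
    if (!ok || (xs.empty() ? true : xs.back() > 0.0)) continue; // no loss
    return wrap(xs);
  }
  return NumericVector(0); // caller raises the error
}

// [[Rcpp::export(name = ".cpp_traj_forward")]]
NumericVector cpp_traj_forward(double s, NumericVector n2, int max_attempts) {
  int G = n2.size(); // n2[0] = size at the origin, n2[G-1] at the present
  for (int att = 0; att < max_attempts; ++att) {
    std::vector<double> xs(G + 1);
    double x = 1.0 / n2[0];
    xs[0] = x;
    bool ok = true;
    for (int g = 1; g <= G; ++g) {
      double N2 = n2[g - 1];
      double xsel = x * (1.0 + s) / (1.0 + s * x);
      x = R::rbinom(N2, xsel) / N2;
      if (x <= 0.0 || x >= 1.0) { ok = false; break; }
      xs[g] = x;
    }
    if (!ok) continue;
    return wrap(xs);
  }
  return NumericVector(0);
}
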