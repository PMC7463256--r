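// Serial-sample constant-size coalescent log-density (hot path of the MCMC).
// Sampling events at tied times are processed before coalescences.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
double coal_log_density_cpp(NumericVector tip_ages, NumericVector coal_ages,
                            double pop_size) {
  const int nt = tip_ages.size(), nc = coal_ages.size();
  const int m = nt + nc;
  std::vector<std::pair<double, int>> ev(m);  // (time, type): sample=0, coal=1
  for (int i = 0; i < nt; ++i) ev[i] = {tip_ages[i], 0};
  for (int i = 0; i < nc; ++i) ev[nt + i] = {coal_ages[i], 1};
  std::sort(ev.begin(), ev.end());
  double ld = 0.0, t_prev = ev[0].first;
  const double inv2n = 1.0 / (2.0 * pop_size), log_n = std::log(pop_size);
  int k = 0;
  for (int j = 0; j < m; ++j) {
    const double dt = ev[j].first - t_prev;
    if (dt > 0) ld -= k * (k - 1) * dt * inv2n;
    if (ev[j].second == 0) {
      ++k;
    } else {
      if (k < 2) return R_NegInf;
      ld -= log_n;
      --k;
    }
    t_prev = ev[j].first;
  }
  return ld;
}
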