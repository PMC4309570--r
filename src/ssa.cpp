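#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Direct-method Gillespie simulation of N independent receptors sharing one
// generator matrix Q (rows = from, columns = to, off-diagonal >= 0).
// Receptors are simulated sequentially; occupancy counts are accumulated on
// the fixed output grid `times` (strictly increasing, first element = start
// time). Uses R's RNG, so set.seed() on the R side gives reproducibility.
// [[Rcpp::export]]
List ssa_population(const NumericMatrix& Q, const IntegerVector& init,
                    const NumericVector& times, bool record_paths,
                    int max_path_events) {
  const int S = Q.nrow();
  const int T = times.size();
  const int N = init.size();
  if (Q.ncol() != S) stop("Q must be square");

  std::vector<double> exit_rate(S, 0.0);
  std::vector< std::vector<double> > cumw(S);
  std::vector< std::vector<int> > target(S);
  for (int s = 0; s < S; ++s) {
    double tot = 0.0;
    for (int j = 0; j < S; ++j) {
      if (j != s && Q(s, j) > 0.0) {
        tot += Q(s, j);
        cumw[s].push_back(tot);
        target[s].push_back(j);
      }
    }
    exit_rate[s] = tot;
  }

  IntegerMatrix counts(S, T);
  List paths(record_paths ? N : 0);
  RNGScope scope;

  for (int r = 0; r < N; ++r) {
    int s = init[r] - 1;
    if (s < 0 || s >= S) stop("invalid initial state index");
    double t = times[0];
    int ti = 0;
    std::vector<double> ptime;
    std::vector<int> pstate;
    if (record_paths) { ptime.push_back(t); pstate.push_back(s + 1); }
    for (;;) {
      const double rate = exit_rate[s];
      const double tnext =
          (rate > 0.0) ? t + R::rexp(1.0 / rate) : R_PosInf;
      while (ti < T && times[ti] <= tnext) { counts(s, ti) += 1; ++ti; }
      if (ti >= T) break;
      t = tnext;
      const double u = R::runif(0.0, rate);
      const std::vector<double>& cw = cumw[s];
      int k = 0;
      const int nk = (int) cw.size();
      while (k < nk - 1 && u > cw[k]) ++k;
      s = target[s][k];
      if (record_paths && (int) ptime.size() < max_path_events) {
        ptime.push_back(t);
        pstate.push_back(s + 1);
      }
    }
    if (record_paths)
      paths[r] = List::create(_["time"] = ptime, _["state"] = pstate);
  }
  return List::create(_["counts"] = counts, _["paths"] = paths);
}
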