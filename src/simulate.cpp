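#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// built-in update functions by id (must mirror builtin_update_functions())
static inline double gfun(int id, double u) {
  switch (id) {
  case 1: return 1.0 / (1.0 + std::exp(-u));
  case 2: return 0.5 * (1.0 + std::erf(u));
  case 3: return 0.5 * (1.0 + std::tanh(u));
  case 4: return 1.0 / (1.0 + std::exp(-u / 2.0));
  case 5: return 1.0 / (1.0 + 10.0 * std::exp(-u));
  case 6: return 10.0 / (10.0 + std::exp(-u));
  }
  return NA_REAL;
}

// One realization of aspiration dynamics. Graph in CSR layout:
// neighbors of vertex l are nbr[offset[l] .. offset[l+1]-1] (0-based) with
// weights wgt[...]. Two uniform draws per step (focal choice, switch
// decision) so the R reference path can reproduce the stream exactly.
// [[Rcpp::export]]
List simulate_aspiration_cpp(IntegerVector nbr, IntegerVector offset,
                             NumericVector wgt, NumericVector dstr,
                             IntegerVector s0, IntegerVector gid,
                             NumericVector alpha, int contingent,
                             double alphaA, double alphaB,
                             double a, double b, double c, double d,
                             double beta, double transient, double samples,
                             int accumulated, int nbatch) {
  const int N = dstr.size();
  const long long T = (long long)transient;
  const long long S = (long long)samples;
  std::vector<int> s(s0.begin(), s0.end());
  long long nA = 0;
  for (int i = 0; i < N; ++i) nA += s[i];

  const long long bsize = S / nbatch > 0 ? S / nbatch : 1;
  NumericVector batch_means(nbatch);
  long double acc = 0.0L, bacc = 0.0L;
  long long bcount = 0, bi = 0;

  RNGScope scope;
  for (long long t = 0; t < T + S; ++t) {
    double u1 = unif_rand();
    int l = (int)(u1 * N);
    if (l >= N) l = N - 1;
    double pay = 0.0;
    const int sl = s[l];
    for (int k = offset[l]; k < offset[l + 1]; ++k) {
      const int j = nbr[k];
      const double w = wgt[k];
      pay += w * (sl ? (s[j] ? a : b) : (s[j] ? c : d));
    }
    if (!accumulated) pay /= dstr[l];
    const double alp = contingent ? (sl ? alphaA : alphaB) : alpha[l];
    const double p = gfun(gid[l], beta * (alp - pay));
    const double u2 = unif_rand();
    if (u2 < p) {
      s[l] = 1 - sl;
      nA += s[l] ? 1 : -1;
    }
    if (t >= T) {
      const double x = (double)nA / N;
      acc += x;
      bacc += x;
      if (++bcount == bsize && bi < nbatch) {
        batch_means[bi++] = (double)(bacc / bcount);
        bacc = 0.0L;
        bcount = 0;
      }
    }
  }
  if (bcount > 0 && bi < nbatch) batch_means[bi++] = (double)(bacc / bcount);

  return List::create(
    _["mean_xA"] = (double)(acc / S),
    _["batch_means"] = batch_means[Rcpp::Range(0, bi - 1)],
    _["final_state"] = IntegerVector(s.begin(), s.end()));
}
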