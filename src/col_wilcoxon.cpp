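#include <Rcpp.h>
using namespace Rcpp;

// Column-wise Wilcoxon rank-sum on small non-negative integer count
// matrices (regulated rows vs background rows), midranks via counting sort,
// tie-corrected normal approximation with 0.5 continuity correction.
// alternative: 1 = greater (enrichment of the regulated group), 2 = two-sided.

// [[Rcpp::export]]
NumericVector col_wilcoxon_cpp(IntegerMatrix xreg, IntegerMatrix xbg,
                               int alternative) {
  const int nx = xreg.nrow(), ny = xbg.nrow(), W = xreg.ncol();
  if (xbg.ncol() != W) stop("column mismatch");
  if (nx == 0 || ny == 0) stop("empty sample");
  const double N = nx + ny;
  const double mu = (double)nx * ny / 2.0;

  int K = 2;
  for (int w = 0; w < W; ++w) {
    for (int r = 0; r < nx; ++r) if (xreg(r, w) + 1 > K) K = xreg(r, w) + 1;
    for (int r = 0; r < ny; ++r) if (xbg(r, w) + 1 > K) K = xbg(r, w) + 1;
  }
  std::vector<double> cnt(K), midr(K);
  NumericVector out(W);

  for (int w = 0; w < W; ++w) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    int kmax = 0;
    for (int r = 0; r < nx; ++r) { int v = xreg(r, w); cnt[v] += 1; if (v > kmax) kmax = v; }
    for (int r = 0; r < ny; ++r) { int v = xbg(r, w); cnt[v] += 1; if (v > kmax) kmax = v; }
    double cum = 0.0, tie = 0.0;
    for (int v = 0; v <= kmax; ++v) {
      midr[v] = cum + (cnt[v] + 1.0) / 2.0;
      cum += cnt[v];
      tie += cnt[v] * cnt[v] * cnt[v] - cnt[v];
    }
    double R1 = 0.0;
    for (int r = 0; r < nx; ++r) R1 += midr[xreg(r, w)];
    const double U = R1 - (double)nx * (nx + 1) / 2.0;
    const double sigma2 =
        (double)nx * ny / 12.0 * ((N + 1.0) - tie / (N * (N - 1.0)));
    if (sigma2 <= 0.0) {
      out[w] = (alternative == 2) ? 1.0 : 0.5;
    } else {
      const double s = std::sqrt(sigma2);
      if (alternative == 1) {
        out[w] = R::pnorm((U - mu - 0.5) / s, 0.0, 1.0, 0, 0);
      } else {
        double z = U - mu;
        z = (z - (z > 0 ? 0.5 : (z < 0 ? -0.5 : 0.0))) / s;
        double pl = R::pnorm(z, 0.0, 1.0, 1, 0);
        double pg = R::pnorm(z, 0.0, 1.0, 0, 0);
        out[w] = std::min(1.0, 2.0 * std::min(pl, pg));
      }
    }
  }
  return out;
}
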