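#include <Rcpp.h>
using namespace Rcpp;

// 1D diabat: type 0 = harmonic (p1 = k, p2 = x0), type 1 = Morse
// (p1 = D, p2 = a, p3 = r_eq); offset added; optional soft repulsion
// C exp(-b x) with C = rep_c (0 disables).
static inline double diabat_e(double x, const double *d) {
  double e;
  if (d[0] < 0.5) {
    double dx = x - d[2];
    e = 0.5 * d[1] * dx * dx;
  } else {
    double u = 1.0 - std::exp(-d[2] * (x - d[3]));
    e = d[1] * u * u;
  }
  e += d[4];
  if (d[5] != 0.0) e += d[5] * std::exp(-d[6] * x);
  return e;
}

// Metropolis random walk on the mapping potential
// V(x) = (1 - lam) * eps1(x) + lam * (eps2(x) + dalpha).
// Uses R's RNG so set.seed() in R gives bit-identical chains.
// [[Rcpp::export(name = ".metropolis_chain")]]
List metropolis_chain(double x0, double lam, double dalpha,
                      NumericVector d1, NumericVector d2,
                      double lo, double hi,
                      int n_steps, double step_size, double beta,
                      int burn_in, int stride) {
  if (n_steps <= burn_in || burn_in < 0 || stride < 1)
    stop("invalid sampler configuration");
  const double *p1 = REAL(d1), *p2 = REAL(d2);
  int n_keep = (n_steps - burn_in) / stride;
  NumericVector xs(n_keep), e1s(n_keep), e2s(n_keep);

  double x = x0;
  double e1 = diabat_e(x, p1), e2 = diabat_e(x, p2);
  double v = (1.0 - lam) * e1 + lam * (e2 + dalpha);
  long accepted = 0;
  int kept = 0;

  for (int i = 1; i <= n_steps; ++i) {
    double xp = x + step_size * norm_rand();
    if (xp >= lo && xp <= hi) {
      double e1p = diabat_e(xp, p1), e2p = diabat_e(xp, p2);
      double vp = (1.0 - lam) * e1p + lam * (e2p + dalpha);
      if (vp <= v || unif_rand() < std::exp(-beta * (vp - v))) {
        x = xp; e1 = e1p; e2 = e2p; v = vp;
        ++accepted;
      }
    }
    if (i > burn_in && (i - burn_in) % stride == 0 && kept < n_keep) {
      xs[kept] = x; e1s[kept] = e1; e2s[kept] = e2;
      ++kept;
    }
  }

  return List::create(_["x"] = xs, _["eps1"] = e1s, _["eps2"] = e2s,
                      _["accept_rate"] = (double)accepted / n_steps,
                      _["x_last"] = x);
}
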