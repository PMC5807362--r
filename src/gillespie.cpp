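#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation of the linear birth-death process.
// A population of k cells has aggregate birth rate k*lambda and death rate
// k*mu; waiting times are exponential, so the final count at time t is drawn
// from the exact Kendall-process law. Uses R's RNG: set.seed() on the R side
// makes runs reproducible.
//
// Signed combinatorial sum of the Kendall-process transition probability,
// evaluated in extended (long double) precision: the terms alternate in
// sign when 1 - alpha - beta < 0 and can exceed the result by several
// orders of magnitude, so double precision alone loses ~7-8 digits to
// cancellation at a ~ 20.
//
// [[Rcpp::export(name = ".bdp_transition_sum")]]
double bdp_transition_sum(int a, int b, double alpha, double beta) {
  long double la = (long double)alpha, lb = (long double)beta;
  long double g = 1.0L - la - lb;
  long double total = 0.0L;
  int jmax = a < b ? a : b;
  for (int j = 0; j <= jmax; ++j) {
    int ea = a - j, eb = b - j;
    if ((la == 0.0L && ea > 0) || (lb == 0.0L && eb > 0) ||
        (g == 0.0L && j > 0)) continue;
    long double lg = lgammal(a + 1.0L) - lgammal(j + 1.0L) -
      lgammal(a - j + 1.0L) +
      lgammal((long double)(a + b - j)) - lgammal((long double)a) -
      lgammal((long double)(b - j + 1));
    if (la > 0.0L) lg += ea * logl(la);
    if (lb > 0.0L) lg += eb * logl(lb);
    long double sign = 1.0L;
    if (g != 0.0L) {
      lg += j * logl(fabsl(g));
      if (g < 0.0L && (j % 2) == 1) sign = -1.0L;
    }
    long double term = sign * expl(lg);
    if (!std::isfinite((double)term))
      stop("transition probability overflowed at a=%d, b=%d", a, b);
    total += term;
  }
  if (total < 0.0L) total = 0.0L;
  if (total > 1.0L) total = 1.0L;
  return (double)total;
}

// [[Rcpp::export(name = ".bdp_gillespie")]]
NumericVector bdp_gillespie(int nsim, double n0, double lambda, double mu,
                            double t, double cap) {
  if (nsim < 1) stop("nsim must be >= 1");
  if (n0 < 0 || lambda < 0 || mu < 0 || t < 0)
    stop("n0, lambda, mu and t must be non-negative");
  NumericVector out(nsim);
  const double total = lambda + mu;
  for (int s = 0; s < nsim; ++s) {
    double k = n0;
    if (total > 0.0 && t > 0.0) {
      double time = 0.0;
      for (;;) {
        if (k <= 0.0) break;               // extinction is absorbing
        double rate = k * total;
        time += R::exp_rand() / rate;
        if (time > t) break;
        if (R::unif_rand() * total < lambda) {
          k += 1.0;
          if (k > cap)
            stop("population exceeded cap (%.0f cells); runaway growth", cap);
        } else {
          k -= 1.0;
        }
      }
    }
    out[s] = k;
    if (s % 4096 == 0) checkUserInterrupt();
  }
  return out;
}
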