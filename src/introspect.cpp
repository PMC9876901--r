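#include <Rcpp.h>
using namespace Rcpp;

// Traveler's Dilemma payoff to a player claiming a against b.
static inline double td_pay(int a, int b, double R) {
  if (a == b) return (double)a;
  if (a < b)  return (double)a + R;
  return (double)b - R;
}

// Simulate the two-player introspection chain: at each step one player is
// picked uniformly, a uniform alternative claim is proposed, and adopted
// with Fermi probability 1/(1 + exp(-beta * (pi_alt - pi_cur))) against the
// opponent's fixed claim. Uses R's RNG, so runs are reproducible under
// set.seed().
// [[Rcpp::export]]
IntegerMatrix simulate_introspection_cpp(int L, int U, double R, double beta,
                                         int steps, int n1_init, int n2_init) {
  int A = U - L + 1;
  IntegerMatrix out(steps + 1, 2);
  int n1 = n1_init, n2 = n2_init;
  out(0, 0) = n1; out(0, 1) = n2;
  for (int s = 1; s <= steps; ++s) {
    bool first = unif_rand() < 0.5;
    int alt = L + (int)(unif_rand() * A);
    if (alt > U) alt = U; // unif_rand() == 1.0 guard
    if (first) {
      double d = td_pay(alt, n2, R) - td_pay(n1, n2, R);
      if (unif_rand() < 1.0 / (1.0 + exp(-beta * d))) n1 = alt;
    } else {
      double d = td_pay(alt, n1, R) - td_pay(n2, n1, R);
      if (unif_rand() < 1.0 / (1.0 + exp(-beta * d))) n2 = alt;
    }
    out(s, 0) = n1; out(s, 1) = n2;
  }
  return out;
}
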