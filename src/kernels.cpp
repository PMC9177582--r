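#include <Rcpp.h>
using namespace Rcpp;

// Iterate P_{k+1} = A P_k from p0, storing every step.
// A is the one-step propagator: I + dt*Q for forward Euler, or expm(Q*dt)
// for the exact grid. Returns an n x (nsteps+1) matrix.
// [[Rcpp::export]]
NumericMatrix propagate_grid(NumericMatrix A, NumericVector p0, int nsteps) {
  const int n = p0.size();
  if (A.nrow() != n || A.ncol() != n)
    stop("propagator dimension mismatch");
  NumericMatrix out(n, nsteps + 1);
  std::vector<double> cur(p0.begin(), p0.end()), nxt(n);
  for (int i = 0; i < n; ++i) out(i, 0) = cur[i];
  for (int k = 1; k <= nsteps; ++k) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += A(i, j) * cur[j];
      nxt[i] = s;
    }
    std::copy(nxt.begin(), nxt.end(), cur.begin());
    for (int i = 0; i < n; ++i) out(i, k) = cur[i];
  }
  return out;
}

// Exact stochastic simulation of the 4-site seeding chain for each patient.
// theta = (tubo, tulu, tuli, tubr, luli, lubr), per year; ages in years.
// From the metastasis-free state, draws exponential waiting times at the
// current total exit rate and adds one site proportionally to its current
// rate (lung-secondary contributions included); stops when the clock passes
// the patient's age or all four sites are positive. Uses R's RNG.
// [[Rcpp::export]]
IntegerMatrix gillespie_states(NumericVector ages, NumericVector theta) {
  if (theta.size() != 6) stop("theta must have 6 components");
  const double tubo = theta[0], tulu = theta[1], tuli = theta[2],
               tubr = theta[3], luli = theta[4], lubr = theta[5];
  const int n = ages.size();
  IntegerMatrix out(n, 4);
  RNGScope scope;
  for (int p = 0; p < n; ++p) {
    int b = 0, l = 0, li = 0, br = 0;
    double t = 0.0;
    const double horizon = ages[p];
    for (;;) {
      const double rb  = b  ? 0.0 : tubo;
      const double rl  = l  ? 0.0 : tulu;
      const double rli = li ? 0.0 : (tuli + (l ? luli : 0.0));
      const double rbr = br ? 0.0 : (tubr + (l ? lubr : 0.0));
      const double tot = rb + rl + rli + rbr;
      if (tot <= 0.0) break;
      t += R::rexp(1.0 / tot);
      if (t > horizon) break;
      const double u = R::unif_rand() * tot;
      if (u < rb) b = 1;
      else if (u < rb + rl) l = 1;
      else if (u < rb + rl + rli) li = 1;
      else br = 1;
    }
    out(p, 0) = b; out(p, 1) = l; out(p, 2) = li; out(p, 3) = br;
  }
  colnames(out) = CharacterVector::create("bone", "lung", "liver", "brain");
  return out;
}
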