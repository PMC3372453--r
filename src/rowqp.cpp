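#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Projection onto { z >= 0, sum(z) <= t } (t > 0).
static vec proj_l1cap(const vec& z, double t) {
  vec zp = clamp(z, 0.0, datum::inf);
  if (accu(zp) <= t) return zp;
  // Euclidean projection onto the simplex { z >= 0, sum(z) = t }
  vec u = sort(z, "descend");
  vec cs = cumsum(u);
  uword rho = 0;
  for (uword j = 0; j < u.n_elem; ++j)
    if (u(j) - (cs(j) - t) / double(j + 1) > 0.0) rho = j;
  double theta = (cs(rho) - t) / double(rho + 1);
  return clamp(z - theta, 0.0, datum::inf);
}

// Minimise  a' Q a - 2 b' a + c' (u + v)   over  a = u - v,
// u, v >= 0, sum(u + v) <= 1  (the positive/negative-part lift of the
// weighted-L1, row-stability-constrained least-squares subproblem).
// Accelerated projected gradient with restart; returns the row estimate a
// plus the fixed-point residual and iteration count.
// [[Rcpp::export(name = ".row_qp_cpp")]]
Rcpp::List row_qp_cpp(const arma::mat& Q, const arma::vec& b,
                      const arma::vec& c, double lip,
                      double tol = 1e-9, int max_iter = 20000) {
  const uword n = Q.n_rows;
  vec z(2 * n, fill::zeros), y = z, z_old = z;
  double tk = 1.0;
  double step = 1.0 / lip;
  double res = datum::inf;
  int it = 0;

  auto gradient = [&](const vec& w) {
    vec a = w.head(n) - w.tail(n);
    vec ga = 2.0 * (Q * a - b);
    vec g(2 * n);
    g.head(n) = ga + c;
    g.tail(n) = -ga + c;
    return g;
  };
  auto objective = [&](const vec& w) {
    vec a = w.head(n) - w.tail(n);
    return dot(a, Q * a) - 2.0 * dot(b, a) + dot(c, w.head(n) + w.tail(n));
  };

  double f_old = objective(z);
  for (it = 1; it <= max_iter; ++it) {
    vec g = gradient(y);
    vec z_new = proj_l1cap(y - step * g, 1.0);
    double t_new = (1.0 + std::sqrt(1.0 + 4.0 * tk * tk)) / 2.0;
    y = z_new + ((tk - 1.0) / t_new) * (z_new - z);
    z_old = z; z = z_new; tk = t_new;

    if (it % 10 == 0) {
      double f = objective(z);
      if (f > f_old) { y = z; tk = 1.0; }  // restart on non-monotone step
      f_old = f;
      vec gz = gradient(z);
      res = norm(z - proj_l1cap(z - step * gz, 1.0), "inf");
      if (res <= tol) break;
    }
  }
  vec a = z.head(n) - z.tail(n);
  return Rcpp::List::create(Rcpp::Named("a") = a,
                            Rcpp::Named("residual") = res,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("converged") = res <= tol);
}
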