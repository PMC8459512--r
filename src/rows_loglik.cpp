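#include <Rcpp.h>
using namespace Rcpp;

// Marginal log-likelihood of a set of guide-sample rows, summing the
// latent infected-cell count over a precomputed block grid.
//
// Per row r and block k the summand is
//   LW(tilted prior block mass) + LX(initial-count factor, precomputed)
//   + log Pois(y_r | gp_r * mid * (1 - eps_r * phi_r)),
// where the block mass uses an exponential tilt matching the local slope
// of the read-count log-factors plus a Gaussian curvature correction (see
// block_logmass() on the R side for the algebra). Rows are combined by
// log-sum-exp over blocks and summed.
//
// [[Rcpp::export(name = ".rows_loglik_cpp")]]
double rows_loglik_cpp(NumericMatrix MID, NumericMatrix LO, NumericMatrix HI,
                       NumericMatrix LX, NumericMatrix XM, NumericMatrix QM,
                       Nullable<NumericMatrix> LW0_,
                       NumericVector y, NumericVector gp, NumericVector lgy,
                       NumericVector lam, NumericVector cells,
                       NumericVector gam_eff,
                       NumericVector eps, NumericVector phi,
                       bool uniform, bool exact) {
  const int R = MID.nrow(), K = MID.ncol();
  NumericMatrix LW0;
  if (exact) LW0 = NumericMatrix(LW0_.get());
  std::vector<double> buf(K);
  double total = 0.0;
  const bool eps_scalar = eps.size() == 1, phi_scalar = phi.size() == 1;

  for (int r = 0; r < R; ++r) {
    const double er = eps_scalar ? eps[0] : eps[r];
    const double pr = phi_scalar ? phi[0] : phi[r];
    const double surv = 1.0 - er * pr;
    const double rowfac = gp[r] * surv;
    const double yr = y[r], lgyr = lgy[r];
    const double shift = gam_eff[r] + rowfac;
    double mx = R_NegInf;
    for (int k = 0; k < K; ++k) {
      const double mid = MID(r, k);
      const double mu = mid * rowfac;
      double ly;
      if (yr > 0.0) {
        ly = (mu > 0.0) ? yr * std::log(mu) - mu - lgyr : R_NegInf;
      } else {
        ly = -mu;
      }
      double lw;
      if (exact) {
        lw = LW0(r, k);
      } else {
        double s = XM(r, k) - shift;
        if (s > 3.0) s = 3.0; else if (s < -3.0) s = -3.0;
        const double lo = LO(r, k), hi = HI(r, k);
        if (uniform) {
          const double len = hi - lo + 1.0;
          double gsum;
          if (std::fabs(s) < 1e-12) gsum = len;
          else gsum = std::expm1(s * len) / std::expm1(s);
          lw = (gsum > 0.0)
            ? -std::log(cells[r] + 1.0) + s * (lo - mid) + std::log(gsum)
            : R_NegInf;
        } else {
          const double lt = lam[r] * std::exp(s);
          const double qlo1 = R::ppois(lo - 1.0, lt, 0, 0);
          const double qhi = R::ppois(hi, lt, 0, 0);
          const double p0 = qlo1 - qhi;
          if (p0 <= 0.0) {
            lw = R_NegInf;
          } else {
            double base = lam[r] * std::expm1(s) - s * mid + std::log(p0);
            const double q = QM(r, k);
            if (q != 0.0) {
              // neighbouring upper-tail CDFs by pmf increments:
              // Q(k-1) = Q(k) + pmf(k)
              const double qlo2 = qlo1 + R::dpois(lo - 1.0, lt, 0);
              const double qhi1 = qhi + R::dpois(hi, lt, 0);
              const double qlo3 = qlo2 + R::dpois(lo - 2.0, lt, 0);
              const double qhi2 = qhi1 + R::dpois(hi - 1.0, lt, 0);
              const double m1 = lt * (qlo2 - qhi1);
              const double m2 = lt * lt * (qlo3 - qhi2);
              const double e2 = (m2 + m1 - 2.0 * mid * m1 +
                                 mid * mid * p0) / p0;
              double corr = 0.5 * q * e2;
              if (corr < 0.0) base += corr;
            }
            lw = base;
          }
        }
      }
      const double v = lw + LX(r, k) + ly;
      buf[k] = v;
      if (v > mx) mx = v;
    }
    if (mx == R_NegInf) {
      total += R_NegInf;
      continue;
    }
    double acc = 0.0;
    for (int k = 0; k < K; ++k) acc += std::exp(buf[k] - mx);
    total += mx + std::log(acc);
  }
  return total;
}
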