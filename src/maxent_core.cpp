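#include <Rcpp.h>
using namespace Rcpp;

// Coordinate-wise proximal ascent for the L1-penalized maximum-entropy
// objective
//   L(lambda) = sum_j lambda_j * pbar_j - log Z(lambda) - sum_j beta_j |lambda_j|
// with Z = sum_i bgw_i exp(eta_i), eta = F lambda, over background cells.
// Each coordinate takes a Newton-type step soft-thresholded at the L1
// subgradient, with step-halving so the penalized objective never
// decreases. Features are expected in [0, 1].
// [[Rcpp::export]]
List maxent_core(NumericMatrix F, NumericVector pbar, NumericVector beta,
                 NumericVector bgw, int max_iter, double tol,
                 double lambda_cap) {
  const int n = F.nrow(), p = F.ncol();
  NumericVector lambda(p);
  std::vector<double> q(n);
  double wsum = 0.0;
  for (int i = 0; i < n; ++i) wsum += bgw[i];
  for (int i = 0; i < n; ++i) q[i] = bgw[i] / wsum;
  double logZ = std::log(wsum);

  std::vector<double> obj_trace;
  bool converged = false, capped = false;
  int iter = 0;

  auto objective = [&](void) {
    double o = -logZ;
    for (int j = 0; j < p; ++j)
      o += lambda[j] * pbar[j] - beta[j] * std::fabs(lambda[j]);
    return o;
  };
  obj_trace.push_back(objective());

  for (iter = 1; iter <= max_iter; ++iter) {
    double maxviol = 0.0;
    for (int j = 0; j < p; ++j) {
      const double *fj = &F(0, j);
      double Ef = 0.0, Ef2 = 0.0;
      for (int i = 0; i < n; ++i) {
        Ef += q[i] * fj[i];
        Ef2 += q[i] * fj[i] * fj[i];
      }
      double g = pbar[j] - Ef;                 // unpenalized gradient
      double viol;
      if (lambda[j] != 0.0)
        viol = std::fabs(g - beta[j] * (lambda[j] > 0 ? 1.0 : -1.0));
      else
        viol = std::max(0.0, std::fabs(g) - beta[j]);
      if (viol > maxviol) maxviol = viol;
      if (viol <= tol) continue;

      double curv = std::max(Ef2 - Ef * Ef, 1e-8);
      double s = (lambda[j] != 0.0) ? (lambda[j] > 0 ? 1.0 : -1.0)
                                    : (g > 0 ? 1.0 : -1.0);
      double delta = (g - beta[j] * s) / curv;
      double lnew = lambda[j] + delta;
      if (lambda[j] != 0.0 && lnew * lambda[j] < 0.0) lnew = 0.0; // no sign flip
      if (lnew > lambda_cap) { lnew = lambda_cap; capped = true; }
      if (lnew < -lambda_cap) { lnew = -lambda_cap; capped = true; }
      delta = lnew - lambda[j];
      if (delta == 0.0) continue;

      // step-halving on the penalized objective change
      double dL = 0.0, zr = 0.0;
      for (int h = 0; h < 40; ++h) {
        zr = 0.0;
        for (int i = 0; i < n; ++i) zr += q[i] * std::exp(delta * fj[i]);
        dL = delta * pbar[j] - std::log(zr)
             - beta[j] * (std::fabs(lambda[j] + delta) - std::fabs(lambda[j]));
        if (dL >= -1e-12) break;
        delta *= 0.5;
      }
      if (dL < -1e-12) continue;              // no acceptable step

      lambda[j] += delta;
      double inv = 1.0 / zr;
      for (int i = 0; i < n; ++i) q[i] *= std::exp(delta * fj[i]) * inv;
      logZ += std::log(zr);
      // renormalize exactly to guard against drift
      double qs = 0.0;
      for (int i = 0; i < n; ++i) qs += q[i];
      for (int i = 0; i < n; ++i) q[i] /= qs;
      logZ += std::log(qs);
    }
    obj_trace.push_back(objective());
    if (maxviol <= tol) { converged = true; break; }
  }

  double H = 0.0;
  for (int i = 0; i < n; ++i)
    if (q[i] > 0) H -= q[i] * std::log(q[i]);

  return List::create(_["lambda"] = lambda,
                      _["q"] = NumericVector(q.begin(), q.end()),
                      _["logZ"] = logZ,
                      _["H"] = H,
                      _["iterations"] = iter,
                      _["converged"] = converged,
                      _["capped"] = capped,
                      _["objective"] = NumericVector(obj_trace.begin(),
                                                     obj_trace.end()));
}
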