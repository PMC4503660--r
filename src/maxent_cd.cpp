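#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// L1-regularized maximum-entropy (Gibbs) fit by cyclic coordinate descent.
//
// Objective over the fitting cell set (rows of F):
//   J(c) = logsumexp_i(eta_i) - mean_p(eta_p) + sum_j lambda_j |c_j|
// with eta = F c. Each coordinate takes a proximal-Newton step
// (soft-thresholded second-order step) safeguarded by backtracking on the
// true objective; the accepted decrease is accredited to that feature.
// One "iteration" is one sweep over the coordinates; after each full sweep
// the active (non-zero) set is iterated until it stops improving, which is
// the usual coordinate-descent acceleration for L1 paths.

static double logsumexp(const std::vector<double>& eta) {
  double m = eta[0];
  for (size_t i = 1; i < eta.size(); ++i) if (eta[i] > m) m = eta[i];
  double s = 0.0;
  for (size_t i = 0; i < eta.size(); ++i) s += std::exp(eta[i] - m);
  return m + std::log(s);
}

// [[Rcpp::export(name = ".maxent_cd")]]
List maxent_cd(NumericMatrix F, NumericMatrix Fp, NumericVector lambda,
               double tol, int max_iter) {
  const int N = F.nrow(), J = F.ncol(), P = Fp.nrow();
  if (J != Fp.ncol() || J != lambda.size())
    stop("feature dimension mismatch");

  std::vector<double> c(J, 0.0), eta(N, 0.0), fpbar(J, 0.0), gain(J, 0.0);
  for (int j = 0; j < J; ++j) {
    double s = 0.0;
    for (int p = 0; p < P; ++p) s += Fp(p, j);
    fpbar[j] = s / P;
  }

  double logZ = std::log((double)N);   // eta = 0
  double meanEtaP = 0.0, pen = 0.0;
  double obj = logZ - meanEtaP + pen;

  int iter = 0;
  bool converged = false;
  std::vector<int> order(J);
  for (int j = 0; j < J; ++j) order[j] = j;

  // one coordinate update; returns objective decrease
  auto update = [&](int j) -> double {
    // current cell distribution
    double m = eta[0];
    for (int i = 1; i < N; ++i) if (eta[i] > m) m = eta[i];
    double S = 0.0;
    std::vector<double> w(N);
    for (int i = 0; i < N; ++i) { w[i] = std::exp(eta[i] - m); S += w[i]; }
    const double* fj = &F(0, j);
    double Ef = 0.0, Ef2 = 0.0;
    for (int i = 0; i < N; ++i) {
      double qf = w[i] * fj[i];
      Ef += qf; Ef2 += qf * fj[i];
    }
    Ef /= S; Ef2 /= S;
    double g = Ef - fpbar[j];
    double h = Ef2 - Ef * Ef;
    if (h < 1e-12) h = 1e-12;
    // proximal step: minimize g d + h d^2/2 + lambda |c_j + d|
    double u = c[j] * h - g, lam = lambda[j], cnew;
    if (u > lam) cnew = (u - lam) / h;
    else if (u < -lam) cnew = (u + lam) / h;
    else cnew = 0.0;
    double d = cnew - c[j];
    if (std::fabs(d) < 1e-14) return 0.0;

    double t = 1.0, newobj = 0.0, newlogZ = 0.0, ct = 0.0;
    bool ok = false;
    std::vector<double> etaj(N);
    for (int ls = 0; ls < 40; ++ls) {
      ct = c[j] + t * d;
      for (int i = 0; i < N; ++i) etaj[i] = eta[i] + t * d * fj[i];
      newlogZ = logsumexp(etaj);
      double newMean = meanEtaP + t * d * fpbar[j];
      double newPen = pen - lam * std::fabs(c[j]) + lam * std::fabs(ct);
      newobj = newlogZ - newMean + newPen;
      if (newobj < obj - 1e-12) { ok = true; break; }
      t *= 0.5;
    }
    if (!ok) return 0.0;
    double dec = obj - newobj;
    for (int i = 0; i < N; ++i) eta[i] = etaj[i];
    meanEtaP += t * d * fpbar[j];
    pen += -lam * std::fabs(c[j]) + lam * std::fabs(ct);
    c[j] = ct;
    logZ = newlogZ;
    obj = newobj;
    gain[j] += dec;
    return dec;
  };

  while (iter < max_iter) {
    // full sweep
    double dec = 0.0;
    for (int j = 0; j < J; ++j) dec += update(j);
    ++iter;
    if (dec < tol) { converged = true; break; }
    // active-set sweeps
    while (iter < max_iter) {
      double adec = 0.0;
      int na = 0;
      for (int j = 0; j < J; ++j)
        if (c[j] != 0.0) { adec += update(j); ++na; }
      ++iter;
      if (na == 0 || adec < tol) break;
    }
  }

  // final distribution and entropy over the fitting cell set
  double m = eta[0];
  for (int i = 1; i < N; ++i) if (eta[i] > m) m = eta[i];
  double S = 0.0;
  std::vector<double> w(N);
  for (int i = 0; i < N; ++i) { w[i] = std::exp(eta[i] - m); S += w[i]; }
  logZ = m + std::log(S);
  double H = 0.0;
  for (int i = 0; i < N; ++i) {
    double q = w[i] / S;
    if (q > 0) H -= q * std::log(q);
  }

  return List::create(_["coef"] = NumericVector(c.begin(), c.end()),
                      _["logZ"] = logZ,
                      _["entropy"] = H,
                      _["objective"] = obj,
                      _["iterations"] = iter,
                      _["converged"] = converged,
                      _["feature_gain"] = NumericVector(gain.begin(),
                                                        gain.end()));
}
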