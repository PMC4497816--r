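// Marker-induction dynamics: plastic SC marker fields T^A, T^B are driven by
// the receptor profile delivered through the current weights (induced
// markers I^A, I^B), and weights grow according to the receptor/marker
// similarity Phi with presynaptic normalization. Per step, in order:
//   I^X_j  = sum_k W_kj R_X(k) / sum_k W_kj        (zero-afferent: carry I)
//   dT^A_j = (sigma (1 - zeta I^A_j T^A_j) + delta Lap(T^A)_j) dt
//   dT^B_j = (sigma (I^B_j - T^B_j)        + delta Lap(T^B)_j) dt
//   Phi_ij = exp(-[(zeta R_A(i) T^A_j - 1)^2 + (R_B(i) - T^B_j)^2]/(2 kappa^2))
//   W_ij  <- (W_ij + theta dt Phi_ij) / sum_k (W_ik + theta dt Phi_ik)
// Weights are stored as V_ij with implicit row normalization
// W_ij = V_ij / rowsum(V); Phi terms with exponent < `exp_floor` are dropped
// (exp(-45) ~ 3e-20, far below any weight that influences the map or the
// induced markers).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List willshaw_run_cpp(NumericVector R_A, NumericVector R_B,
                      NumericMatrix W0,
                      NumericVector TA0, NumericVector TB0,
                      IntegerVector adj_ptr, IntegerVector adj_idx,
                      double sigma, double delta, double theta,
                      double zeta, double kappa, double dt,
                      int n_steps, double exp_floor = -45.0) {
  int NR = W0.nrow(), NS = W0.ncol();
  // W is stored row-major as W_ij = g_i * V_ij; g starts at 1 so the
  // initial weights enter the first induced-marker and weight computations
  // unnormalized, exactly as written (rows sum to 1 only after the first
  // weight step)
  std::vector<double> V((size_t)NR * NS);
  std::vector<double> g(NR, 1.0), sumV(NR, 0.0);
  for (int i = 0; i < NR; i++) {
    double s = 0.0;
    for (int j = 0; j < NS; j++) { double v = W0(i, j); V[(size_t)i * NS + j] = v; s += v; }
    sumV[i] = s;
  }
  std::vector<double> TA(TA0.begin(), TA0.end()), TB(TB0.begin(), TB0.end());
  std::vector<double> IA(NS, 0.0), IB(NS, 0.0);
  std::vector<double> den(NS), numA(NS), numB(NS), dTA(NS), dTB(NS);
  std::vector<double> phiRow(NS);
  int log_n = std::max(1, n_steps / 200);
  std::vector<double> log_step, log_dT;
  double inv2k2 = 1.0 / (2.0 * kappa * kappa);

  for (int step = 0; step < n_steps; step++) {
    // induced markers
    std::fill(den.begin(), den.end(), 0.0);
    std::fill(numA.begin(), numA.end(), 0.0);
    std::fill(numB.begin(), numB.end(), 0.0);
    for (int i = 0; i < NR; i++) {
      double gi = g[i];
      double ga = gi * R_A[i], gb = gi * R_B[i];
      const double *v = &V[(size_t)i * NS];
      for (int j = 0; j < NS; j++) {
        double vj = v[j];
        den[j] += gi * vj; numA[j] += ga * vj; numB[j] += gb * vj;
      }
    }
    for (int j = 0; j < NS; j++) {
      if (den[j] > 0.0) { IA[j] = numA[j] / den[j]; IB[j] = numB[j] / den[j]; }
      // else: zero afferent weight, carry forward previous induced value
    }
    // marker production + diffusion on the pruned Delaunay graph
    double sum_abs_dT = 0.0;
    for (int j = 0; j < NS; j++) {
      double lapA = 0.0, lapB = 0.0;
      for (int e = adj_ptr[j]; e < adj_ptr[j + 1]; e++) {
        int q = adj_idx[e];
        lapA += TA[q] - TA[j];
        lapB += TB[q] - TB[j];
      }
      dTA[j] = (sigma * (1.0 - zeta * IA[j] * TA[j]) + delta * lapA) * dt;
      dTB[j] = (sigma * (IB[j] - TB[j]) + delta * lapB) * dt;
      sum_abs_dT += std::fabs(dTA[j]) + std::fabs(dTB[j]);
    }
    for (int j = 0; j < NS; j++) { TA[j] += dTA[j]; TB[j] += dTB[j]; }
    // weight update with implicit row normalization:
    // W' = (g V + td Phi) / s_i = g' V', with V' = V + td Phi / g and
    // g' = g / s_i, s_i = g * sumV' (so rows of W' sum to exactly 1)
    double td = theta * dt;
    for (int i = 0; i < NR; i++) {
      double za = zeta * R_A[i], rb = R_B[i];
      double addW = 0.0;
      double *v = &V[(size_t)i * NS];
      double gi = g[i];
      for (int j = 0; j < NS; j++) {
        double u = za * TA[j] - 1.0;
        double w = rb - TB[j];
        double arg = -(u * u + w * w) * inv2k2;
        if (arg > exp_floor) {
          double phi = std::exp(arg);
          v[j] += td * phi / gi;   // V-space equivalent of W += theta dt phi
          addW += phi;
        }
      }
      sumV[i] += td * addW / gi;
      g[i] = gi / (gi * sumV[i]); // = 1 / sumV[i]
    }
    // periodic refold: fold the scale into V, flush vanishing entries
    if ((step & 255) == 255 || step == n_steps - 1) {
      for (int i = 0; i < NR; i++) {
        double gi = g[i], s = 0.0;
        double *v = &V[(size_t)i * NS];
        for (int j = 0; j < NS; j++) {
          double w = v[j] * gi;
          if (w < 1e-250) w = 0.0;
          v[j] = w; s += w;
        }
        g[i] = 1.0; sumV[i] = s;
      }
    }
    if (step % log_n == 0) { log_step.push_back(step + 1); log_dT.push_back(sum_abs_dT); }
  }

  NumericMatrix W(NR, NS);
  for (int i = 0; i < NR; i++) {
    for (int j = 0; j < NS; j++) W(i, j) = V[(size_t)i * NS + j] * g[i];
  }
  return List::create(_["W"] = W,
                      _["TA"] = NumericVector(TA.begin(), TA.end()),
                      _["TB"] = NumericVector(TB.begin(), TB.end()),
                      _["log_step"] = NumericVector(log_step.begin(), log_step.end()),
                      _["log_sum_abs_dT"] = NumericVector(log_dT.begin(), log_dT.end()));
}
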