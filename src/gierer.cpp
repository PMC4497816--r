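// Gierer terminal-movement model: each RGC owns n_term terminals on SC
// neurons; per epoch every terminal (random order) may hop to the Delaunay
// neighbour of its current SC neuron with the lowest potential
//   p(i, j) = R_A(i) L_A(j) - R_B(i) L_B(j) + c(j),
// moving only if strictly lower than at its current position.
// The competition level follows dc/dt = eps * rho - eta * c with rho the
// live terminal count per SC neuron. Two discretizations:
//   continuous = true : exact piecewise-exponential integration between
//     terminal examinations (rho is constant between moves, so the ODE is
//     solved lazily per SC neuron when its c is read or its rho changes);
//     one epoch advances time by exactly 1.
//   continuous = false: one explicit-Euler step (dt = 1) after the sweep,
//     with c frozen during the sweep.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct CompField {
  std::vector<double> c;
  std::vector<long long> tlast; // in terminal-step units
  std::vector<int> *rho;
  double eps, eta, dt;          // dt = 1 / (terminals per epoch)
  long long now = 0;

  void touch(int j) {
    long long d = now - tlast[j];
    if (d == 0) return;
    double f = std::exp(-eta * dt * (double)d);
    c[j] = c[j] * f + (eps / eta) * (*rho)[j] * (1.0 - f);
    tlast[j] = now;
  }
  double read(int j) { touch(j); return c[j]; }
};

// [[Rcpp::export]]
List gierer_run_cpp(NumericVector R_A, NumericVector R_B,
                    NumericVector L_A, NumericVector L_B,
                    IntegerVector adj_ptr, IntegerVector adj_idx,
                    int n_term, double eps, double eta, int n_epochs,
                    IntegerVector init_assign, NumericVector c_init,
                    bool continuous = true) {
  int nR = R_A.size(), nSC = L_A.size();
  RNGScope scope;

  std::vector<int> assign(init_assign.begin(), init_assign.end()); // 0-based
  int nT = nR * n_term;
  std::vector<int> rho(nSC, 0);
  for (int t = 0; t < nT; t++) rho[assign[t]]++;

  CompField cf;
  cf.c.assign(c_init.begin(), c_init.end());
  cf.tlast.assign(nSC, 0);
  cf.rho = &rho;
  cf.eps = eps; cf.eta = eta; cf.dt = 1.0 / nT;

  std::vector<int> order(nT);
  for (int t = 0; t < nT; t++) order[t] = t;
  std::vector<int> ties; ties.reserve(16);

  NumericVector moves_log(n_epochs), conv_log(n_epochs);

  for (int ep = 0; ep < n_epochs; ep++) {
    // Fisher-Yates shuffle: fresh random order of all terminals
    for (int t = nT - 1; t > 0; t--) {
      int u = (int)(R::unif_rand() * (t + 1));
      if (u > t) u = t;
      std::swap(order[t], order[u]);
    }
    int moves = 0;
    for (int tt = 0; tt < nT; tt++) {
      if (continuous) cf.now++;
      int term = order[tt];
      int i = term / n_term;
      int j = assign[term];
      double ra = R_A[i], rb = R_B[i];
      double cj = continuous ? cf.read(j) : cf.c[j];
      double pcur = ra * L_A[j] - rb * L_B[j] + cj;
      double pmin = R_PosInf;
      ties.clear();
      for (int e = adj_ptr[j]; e < adj_ptr[j + 1]; e++) {
        int jn = adj_idx[e];
        double cn = continuous ? cf.read(jn) : cf.c[jn];
        double p = ra * L_A[jn] - rb * L_B[jn] + cn;
        if (p < pmin) { pmin = p; ties.clear(); ties.push_back(jn); }
        else if (p == pmin) ties.push_back(jn);
      }
      if (!ties.empty() && pmin < pcur) {
        int pick = ties[0];
        if (ties.size() > 1) {
          int u = (int)(R::unif_rand() * ties.size());
          if (u >= (int)ties.size()) u = (int)ties.size() - 1;
          pick = ties[u];
        }
        // c of both nodes is current (touched above), so rho may change now
        rho[j]--; rho[pick]++;
        assign[term] = pick;
        moves++;
      }
    }
    double sumdev = 0.0;
    if (continuous) {
      for (int j = 0; j < nSC; j++) {
        cf.touch(j);
        sumdev += std::fabs(cf.c[j] - (eps / eta) * rho[j]);
      }
    } else {
      for (int j = 0; j < nSC; j++) {
        cf.c[j] += eps * rho[j] - eta * cf.c[j];
        sumdev += std::fabs(cf.c[j] - (eps / eta) * rho[j]);
      }
    }
    moves_log[ep] = moves;
    conv_log[ep] = sumdev / nSC;  // mean |c - (eps/eta) rho| gauge
  }

  IntegerVector out_assign(assign.begin(), assign.end());
  NumericVector out_c(cf.c.begin(), cf.c.end());
  IntegerVector out_rho(rho.begin(), rho.end());
  return List::create(_["assign"] = out_assign, _["c"] = out_c,
                      _["rho"] = out_rho, _["moves"] = moves_log,
                      _["c_deviation"] = conv_log);
}
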