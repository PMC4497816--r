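// Koulakov stochastic synapse dynamics: minimize
//   E = E_chem + E_act + E_comp
// by alternating add / remove attempts, each accepted with probability
//   p = 1 / (1 + exp(4 dE)).
// E_chem = sum over synapses of (alpha R_A L_A - beta R_B L_B)
// E_act  = -(gamma/2) sum over ordered synapse pairs (self-pairs included)
//          of C(r,r') U(s,s'), C = exp(-d_ret / b), U = exp(-d_sc^2 / 2a^2)
// E_comp = sum_RGC (-500 n^0.5 + n^2) + sum_SC n^2
// Incremental dE for the activity term is accumulated over SC neurons within
// `cutoff * a` of the candidate SC neuron; U beyond 8a is ~1e-14 so the
// truncated increment matches the brute-force energy difference well below
// typical float tolerances (cutoff may be Inf for the exact sum).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct KState {
  std::vector<int> mu, nu;                 // synapse -> RGC / SC indices
  std::vector<int> nR, nSC;                // synapse counts per neuron
  std::vector<std::vector<int>> bySC;      // RGC indices of synapses on SC j
};

static inline double accept_prob(double dE) {
  double z = 4.0 * dE;
  if (z > 500.0) return 0.0;
  if (z < -500.0) return 1.0;
  return 1.0 / (1.0 + std::exp(z));
}

// [[Rcpp::export]]
double koulakov_accept_prob_cpp(double dE) { return accept_prob(dE); }

// activity sum: sum over existing synapses k of C(i, mu_k) U(j, nu_k),
// restricted to SC neurons within the cutoff of j; the retinal correlation
// C is read from a precomputed table (row i)
static double act_sum(const KState &st, int j,
                      const std::vector<std::vector<int>> &scNbr,
                      const std::vector<std::vector<double>> &scU,
                      const double *Crow) {
  double s = 0.0;
  const std::vector<int> &nbr = scNbr[j];
  const std::vector<double> &uu = scU[j];
  for (size_t q = 0; q < nbr.size(); q++) {
    const std::vector<int> &lst = st.bySC[nbr[q]];
    if (lst.empty()) continue;
    double u = uu[q], cs = 0.0;
    for (size_t m = 0; m < lst.size(); m++) cs += Crow[lst[m]];
    s += u * cs;
  }
  return s;
}

// [[Rcpp::export]]
List koulakov_run_cpp(NumericVector rx, NumericVector ry,
                      NumericVector sx, NumericVector sy,
                      NumericVector R_A, NumericVector R_B,
                      NumericVector L_A, NumericVector L_B,
                      double alpha, double beta, double gamma,
                      double b, double a, double cutoff,
                      int n_epochs, int iter_per_epoch,
                      bool trace = false, bool allow_duplicates = false) {
  int NR = rx.size(), NS = sx.size();
  RNGScope scope;
  // presence map for the no-duplicates convention
  std::vector<unsigned char> present;
  if (!allow_duplicates) present.assign((size_t)NR * NS, 0);

  // SC neighbour lists within cutoff * a, with precomputed U values
  double rad = cutoff * a;
  bool finite_cut = R_finite(rad);
  double rad2 = rad * rad, inv2a2 = 1.0 / (2.0 * a * a);
  std::vector<std::vector<int>> scNbr(NS);
  std::vector<std::vector<double>> scU(NS);
  for (int j = 0; j < NS; j++) {
    for (int q = 0; q < NS; q++) {
      double dx = sx[j] - sx[q], dy = sy[j] - sy[q];
      double d2 = dx * dx + dy * dy;
      if (!finite_cut || d2 <= rad2) {
        scNbr[j].push_back(q);
        scU[j].push_back(std::exp(-d2 * inv2a2));
      }
    }
  }

  // retinal correlation table C(i, k) = exp(-|r_i - r_k| / b)
  std::vector<double> C((size_t)NR * NR);
  for (int i = 0; i < NR; i++) {
    C[(size_t)i * NR + i] = 1.0;
    for (int k = i + 1; k < NR; k++) {
      double dx = rx[i] - rx[k], dy = ry[i] - ry[k];
      double c = std::exp(-std::sqrt(dx * dx + dy * dy) / b);
      C[(size_t)i * NR + k] = c;
      C[(size_t)k * NR + i] = c;
    }
  }

  KState st;
  st.nR.assign(NR, 0); st.nSC.assign(NS, 0);
  st.bySC.assign(NS, std::vector<int>());

  NumericVector rej_frac(n_epochs), mean_spread(n_epochs), syn_count(n_epochs);
  std::vector<int> tr_type; std::vector<int> tr_i, tr_j, tr_acc;
  std::vector<double> tr_dE;

  for (int ep = 0; ep < n_epochs; ep++) {
    int attempts = 0, rejected = 0;
    for (int k = 0; k < iter_per_epoch; k++) {
      // --- add attempt: uniform random (RGC, SC) pair (a pair that is
      // already connected is a no-op under the no-duplicates convention)
      int i = (int)(R::unif_rand() * NR); if (i >= NR) i = NR - 1;
      int j = (int)(R::unif_rand() * NS); if (j >= NS) j = NS - 1;
      if (!allow_duplicates && present[(size_t)i * NS + j]) {
        attempts++; rejected++;
      } else {
      double dE = alpha * R_A[i] * L_A[j] - beta * R_B[i] * L_B[j];
      dE += -gamma * act_sum(st, j, scNbr, scU, &C[(size_t)i * NR])
            - 0.5 * gamma; // self-pair
      int ni = st.nR[i], nj = st.nSC[j];
      dE += -500.0 * (std::sqrt(ni + 1.0) - std::sqrt((double)ni))
            + (2.0 * ni + 1.0) + (2.0 * nj + 1.0);
      attempts++;
      bool acc = (R::unif_rand() < accept_prob(dE));
      if (acc) {
        st.mu.push_back(i); st.nu.push_back(j);
        st.nR[i]++; st.nSC[j]++;
        st.bySC[j].push_back(i);
        if (!allow_duplicates) present[(size_t)i * NS + j] = 1;
      } else rejected++;
      if (trace) {
        tr_type.push_back(1); tr_i.push_back(i + 1); tr_j.push_back(j + 1);
        tr_dE.push_back(dE); tr_acc.push_back(acc ? 1 : 0);
      }
      }

      // --- remove attempt: uniform random existing synapse (skip if none)
      size_t ns = st.mu.size();
      if (ns == 0) continue;
      size_t s = (size_t)(R::unif_rand() * ns); if (s >= ns) s = ns - 1;
      int ri = st.mu[s], rj = st.nu[s];
      double S = act_sum(st, rj, scNbr, scU, &C[(size_t)ri * NR]);
      double dEr = -(alpha * R_A[ri] * L_A[rj] - beta * R_B[ri] * L_B[rj]);
      dEr += gamma * (S - 1.0) + 0.5 * gamma; // pairs with others + self
      int nri = st.nR[ri], nrj = st.nSC[rj];
      dEr += -500.0 * (std::sqrt(nri - 1.0) - std::sqrt((double)nri))
             - (2.0 * nri - 1.0) - (2.0 * nrj - 1.0);
      attempts++;
      bool accr = (R::unif_rand() < accept_prob(dEr));
      if (accr) {
        st.nR[ri]--; st.nSC[rj]--;
        if (!allow_duplicates) present[(size_t)ri * NS + rj] = 0;
        // remove from per-SC list (one instance)
        std::vector<int> &lst = st.bySC[rj];
        for (size_t m = 0; m < lst.size(); m++)
          if (lst[m] == ri) { lst[m] = lst.back(); lst.pop_back(); break; }
        st.mu[s] = st.mu.back(); st.mu.pop_back();
        st.nu[s] = st.nu.back(); st.nu.pop_back();
      } else rejected++;
      if (trace) {
        tr_type.push_back(2); tr_i.push_back(ri + 1); tr_j.push_back(rj + 1);
        tr_dE.push_back(dEr); tr_acc.push_back(accr ? 1 : 0);
      }
    }
    rej_frac[ep] = attempts > 0 ? (double)rejected / attempts : 0.0;
    syn_count[ep] = (double)st.mu.size();
    // mean per-RGC projection spread (RMS distance of targets to their mean)
    {
      std::vector<double> sxs(NR, 0), sys(NR, 0), sq(NR, 0);
      std::vector<int> cnt(NR, 0);
      for (size_t s2 = 0; s2 < st.mu.size(); s2++) {
        int i2 = st.mu[s2], j2 = st.nu[s2];
        sxs[i2] += sx[j2]; sys[i2] += sy[j2];
        sq[i2] += sx[j2] * sx[j2] + sy[j2] * sy[j2];
        cnt[i2]++;
      }
      double tot = 0; int nn = 0;
      for (int i2 = 0; i2 < NR; i2++) {
        if (cnt[i2] < 2) continue;
        double mx = sxs[i2] / cnt[i2], my = sys[i2] / cnt[i2];
        double v = sq[i2] / cnt[i2] - mx * mx - my * my;
        tot += std::sqrt(std::max(0.0, v)); nn++;
      }
      mean_spread[ep] = nn > 0 ? tot / nn : NA_REAL;
    }
  }

  IntegerVector mu(st.mu.size()), nu(st.nu.size());
  for (size_t s = 0; s < st.mu.size(); s++) { mu[s] = st.mu[s] + 1; nu[s] = st.nu[s] + 1; }
  List out = List::create(_["mu"] = mu, _["nu"] = nu,
                          _["rejection_fraction"] = rej_frac,
                          _["mean_spread"] = mean_spread,
                          _["synapse_count"] = syn_count);
  if (trace) {
    out["trace"] = DataFrame::create(
      _["type"] = IntegerVector(tr_type.begin(), tr_type.end()),
      _["i"] = IntegerVector(tr_i.begin(), tr_i.end()),
      _["j"] = IntegerVector(tr_j.begin(), tr_j.end()),
      _["dE"] = NumericVector(tr_dE.begin(), tr_dE.end()),
      _["accepted"] = IntegerVector(tr_acc.begin(), tr_acc.end()));
  }
  return out;
}
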