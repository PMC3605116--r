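// Simulation core for the coevolving chemostat.
//
// Mirrors the pure-R reference engine step for step: classical RK4 on
// (R, N, V) over the genotype grid, then stochastic mutation (Poisson
// counts from instantaneous production rates, normal effect sizes,
// binned), then the extinction cull. All derivative terms vanish at
// unoccupied bins, so loops run over the occupied index sets only; the
// occupied sets are fixed within a step. Random draws go through R's
// RNG (rpois, rnorm) in the same order as the R engine: hosts by
// ascending bin, then phage by ascending bin.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct MutEvent {
  bool host;
  int par;
  int off;
};

// [[Rcpp::export]]
List sim_engine_cpp(double R_init, NumericVector N0, NumericVector V0,
                    NumericMatrix delta_epochs, NumericVector epoch_times,
                    NumericVector theta_look, List par, int n_steps,
                    int output_stride) {
  const double omega = par["omega"], R0 = par["R0"], eps = par["eps"],
               gamma = par["gamma"], K = par["K"], beta = par["beta"],
               dt = par["dt"], M_B = par["M_B"], M_V = par["M_V"],
               sigma_B = par["sigma_B"], sigma_V = par["sigma_V"],
               L = par["L"], rho = par["rho"];
  const int nb = N0.size();
  const int n_ep = delta_epochs.nrow();

  std::vector<double> N(N0.begin(), N0.end());
  std::vector<double> V(V0.begin(), V0.end());
  double R = R_init;
  double t = 0.0;
  int cur_ep = 0;
  bool range_edge = false;

  // Stage temporaries (dense; only occupied entries are touched).
  std::vector<double> k1N(nb, 0), k2N(nb, 0), k3N(nb, 0), k4N(nb, 0);
  std::vector<double> k1V(nb, 0), k2V(nb, 0), k3V(nb, 0), k4V(nb, 0);
  std::vector<double> Ns(nb, 0), Vs(nb, 0), drow(nb, 0);
  std::vector<int> occH, occP;
  occH.reserve(nb); occP.reserve(nb);

  const int n_samp = n_steps / output_stride + 1;
  NumericVector times(n_samp), Rout(n_samp);
  NumericMatrix Nout(n_samp, nb), Vout(n_samp, nb);
  times[0] = 0; Rout[0] = R;
  for (int i = 0; i < nb; ++i) { Nout(0, i) = N[i]; Vout(0, i) = V[i]; }
  int samp = 0;

  RNGScope rng;

  // RHS at one stage; writes dN/dV only at occupied indices.
  auto rhs = [&](double Rs, const std::vector<double>& Nv,
                 const std::vector<double>& Vv, const double* delta,
                 double& dR, std::vector<double>& dN,
                 std::vector<double>& dV) {
    const double monod = (gamma * Rs) / (Rs + K);
    long double upsum = 0.0L;
    for (size_t a = 0; a < occH.size(); ++a) {
      const int ia = occH[a];
      const double up = (monod * Nv[ia]) * delta[ia];
      upsum += up;
      double lys = 0.0;
      for (size_t b = 0; b < occP.size(); ++b) {
        const int ib = occP[b];
        lys += theta_look[std::abs(ia - ib)] * Vv[ib];
      }
      dN[ia] = (-omega * Nv[ia] + up) - Nv[ia] * lys;
    }
    for (size_t b = 0; b < occP.size(); ++b) {
      const int ib = occP[b];
      double prod = 0.0;
      for (size_t a = 0; a < occH.size(); ++a) {
        const int ia = occH[a];
        prod += theta_look[std::abs(ia - ib)] * Nv[ia];
      }
      dV[ib] = -omega * Vv[ib] + (beta * Vv[ib]) * prod;
    }
    dR = -omega * (Rs - R0) - eps * (double)upsum;
  };

  std::vector<MutEvent> events;
  std::vector<double> rateH, rateP;

  for (int step = 1; step <= n_steps; ++step) {
    while (cur_ep + 1 < n_ep && epoch_times[cur_ep + 1] <= t) ++cur_ep;
    for (int j = 0; j < nb; ++j) drow[j] = delta_epochs(cur_ep, j);

    occH.clear(); occP.clear();
    for (int i = 0; i < nb; ++i) {
      if (N[i] > 0) occH.push_back(i);
      if (V[i] > 0) occP.push_back(i);
    }

    double k1R, k2R, k3R, k4R;
    rhs(R, N, V, drow.data(), k1R, k1N, k1V);
    for (int a : occH) Ns[a] = N[a] + (dt / 2) * k1N[a];
    for (int b : occP) Vs[b] = V[b] + (dt / 2) * k1V[b];
    rhs(R + (dt / 2) * k1R, Ns, Vs, drow.data(), k2R, k2N, k2V);
    for (int a : occH) Ns[a] = N[a] + (dt / 2) * k2N[a];
    for (int b : occP) Vs[b] = V[b] + (dt / 2) * k2V[b];
    rhs(R + (dt / 2) * k2R, Ns, Vs, drow.data(), k3R, k3N, k3V);
    for (int a : occH) Ns[a] = N[a] + dt * k3N[a];
    for (int b : occP) Vs[b] = V[b] + dt * k3V[b];
    rhs(R + dt * k3R, Ns, Vs, drow.data(), k4R, k4N, k4V);

    R = R + (dt / 6) * (((k1R + 2 * k2R) + 2 * k3R) + k4R);
    for (int a : occH)
      N[a] = N[a] + (dt / 6) * (((k1N[a] + 2 * k2N[a]) + 2 * k3N[a]) + k4N[a]);
    for (int b : occP)
      V[b] = V[b] + (dt / 6) * (((k1V[b] + 2 * k2V[b]) + 2 * k3V[b]) + k4V[b]);
    t += dt;
    while (cur_ep + 1 < n_ep && epoch_times[cur_ep + 1] <= t) ++cur_ep;
    for (int j = 0; j < nb; ++j) drow[j] = delta_epochs(cur_ep, j);

    if (!std::isfinite(R))
      stop("numerical failure at step %d: non-finite resource R", step);
    for (int a : occH)
      if (!std::isfinite(N[a]))
        stop("numerical failure at step %d: non-finite host density at bin %d",
             step, a);
    for (int b : occP)
      if (!std::isfinite(V[b]))
        stop("numerical failure at step %d: non-finite phage density at bin %d",
             step, b);

    // --- Mutation: rates from the post-step, pre-cull state. ---
    const double monod = (gamma * R) / (R + K);
    rateH.clear(); rateP.clear();
    for (int a : occH) {
      if (N[a] > 0)
        rateH.push_back((((M_B * L) * monod) * N[a]) * drow[a]);
      else
        rateH.push_back(0.0);
    }
    for (int b : occP) {
      double prod = 0.0;
      for (int a : occH) prod += theta_look[std::abs(a - b)] * N[a];
      if (V[b] > 0)
        rateP.push_back((((M_V * L) * beta) * V[b]) * prod);
      else
        rateP.push_back(0.0);
    }
    // NB: occupied sets were built pre-step; a strain whose density went
    // non-positive during the step contributes rate 0 (guards above).

    events.clear();
    auto draw = [&](const std::vector<int>& occ,
                    const std::vector<double>& rate, double sigma,
                    bool host) {
      for (size_t k = 0; k < occ.size(); ++k) {
        const double lam = rate[k] * dt;
        if (lam <= 0) continue;
        const int m = (int)R::rpois(lam);
        for (int q = 0; q < m; ++q) {
          const double offv = R::rnorm(0.0, sigma);
          const double g = occ[k] * rho + offv;
          const double bin = std::nearbyint(g / rho);
          if (bin < 0 || bin > nb - 1) { range_edge = true; continue; }
          const int ob = (int)bin;
          if (ob == occ[k]) continue;
          events.push_back(MutEvent{host, occ[k], ob});
        }
      }
    };
    draw(occH, rateH, sigma_B, true);
    draw(occP, rateP, sigma_V, false);

    const double amt = 1.0 / L;
    for (const MutEvent& e : events) {
      if (e.host) {
        N[e.off] += amt;
        N[e.par] -= std::min(N[e.par], amt);
      } else {
        V[e.off] += amt;
        V[e.par] -= std::min(V[e.par], amt);
      }
    }

    // --- Cull (strict inequality; exactly 1 per ml is retained). ---
    for (int i = 0; i < nb; ++i) {
      if (N[i] != 0 && N[i] < 1) N[i] = 0;
      if (V[i] != 0 && V[i] < 1) V[i] = 0;
    }

    if (step % output_stride == 0) {
      ++samp;
      times[samp] = t; Rout[samp] = R;
      for (int i = 0; i < nb; ++i) {
        Nout(samp, i) = N[i];
        Vout(samp, i) = V[i];
      }
    }
  }

  return List::create(_["times"] = times, _["R"] = Rout, _["N"] = Nout,
                      _["V"] = Vout, _["range_edge"] = range_edge);
}
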