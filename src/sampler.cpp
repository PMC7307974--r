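// Metropolis-within-Gibbs sampler for the spatio-temporal surveillance
// mixture models. Both model components (Common: BYM + RW1 national trend;
// Area-Specific: free per-area RW1 trends) are fitted to the full data, and
// the binary allocation field z is drawn from its exact full conditional
// given both component likelihoods, with no feedback from z into the
// component fits (cut factorization; see the methods vignette).
//
// All randomness comes from R's RNG, so set.seed() in R makes runs
// reproducible bit for bit.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Poisson log-likelihood kernel of one cell, dropping log(y!):
// y * x - e * exp(x), with x the log relative risk.
static inline double llCell(double y, double e, double x) {
  return y * x - e * std::exp(x);
}

// Adaptive random-walk step for one update block.
struct Block {
  double s;
  long acc, tries;       // post-burn-in bookkeeping
  long accW, triesW;     // current adaptation window
  explicit Block(double s0 = 0.1) : s(s0), acc(0), tries(0), accW(0), triesW(0) {}
  void record(bool accepted, bool burn) {
    if (burn) { triesW++; if (accepted) accW++; }
    else      { tries++;  if (accepted) acc++; }
  }
  void adaptStep() {
    if (triesW >= 50) {
      double rate = double(accW) / double(triesW);
      s *= std::exp(rate - 0.44);
      if (s < 1e-4) s = 1e-4;
      if (s > 10.0) s = 10.0;
      accW = 0; triesW = 0;
    }
  }
  double rate() const { return tries > 0 ? double(acc) / double(tries) : NA_REAL; }
};

// [[Rcpp::export]]
List cpp_run_sampler(int model,            // 0 = baseline, 1 = proposed
                     NumericMatrix Y, NumericMatrix E,
                     List adjW,            // 1-based neighbour lists
                     IntegerVector compW,  // component labels of W
                     int nIter, int burnIn, int thin,
                     bool adapt, double priorCommon,
                     bool storeKappa) {
  const int N = Y.nrow(), T = Y.ncol();
  const bool proposed = (model == 1);

  // adjacency, 0-based
  std::vector< std::vector<int> > adj(N);
  for (int i = 0; i < N; ++i) {
    IntegerVector nb = adjW[i];
    for (int k = 0; k < nb.size(); ++k) adj[i].push_back(nb[k] - 1);
  }
  int nCompW = 0;
  for (int i = 0; i < N; ++i) if (compW[i] > nCompW) nCompW = compW[i];
  const bool connectedW = (nCompW == 1);
  const double rankW = N - nCompW;   // ICAR rank of the spatial graph
  const double rankQ = T - 1;        // path graph is connected

  // ---- state ----------------------------------------------------------
  double sumY = 0.0, sumE = 0.0;
  for (int i = 0; i < N; ++i) for (int t = 0; t < T; ++t) {
    sumY += Y(i, t); sumE += E(i, t);
  }
  double alpha0 = std::log((sumY + 0.5) / sumE);
  std::vector<double> eta(N, 0.0), v(N, 0.0), gamma(T, 0.0);
  double s2eta = 0.1, s2v = 0.1, s2gamma = 0.1;

  std::vector<double> nu(N);
  NumericMatrix kappa(N, T);
  std::vector<double> s2kappa(N, 0.1);
  for (int i = 0; i < N; ++i) {
    double ry = 0.0, re = 0.0;
    for (int t = 0; t < T; ++t) { ry += Y(i, t); re += E(i, t); }
    nu[i] = std::log((ry + 0.5) / re);
    for (int t = 0; t < T; ++t) kappa(i, t) = 0.0;
  }
  double aHyp = std::log(0.1), bHyp = 1.0;   // baseline lognormal hyperprior

  NumericMatrix z(N, T);                     // baseline uses column 0 logic
  std::fill(z.begin(), z.end(), 1.0);
  std::vector<double> piF(N, 0.0), deltaF(T, 0.0);
  double tau = 0.95, s2pi = 0.1, s2delta = 0.1;

  // ---- blocks ---------------------------------------------------------
  Block bAlpha(0.05), bEta(0.1), bGamma(0.05), bNu(0.1), bKappa(0.2),
        bS2eta(0.5), bS2v(0.5), bS2gamma(0.5), bS2kappa(0.5), bB(0.3),
        bPi(0.5), bDelta(0.3), bTau(0.5), bS2pi(0.5), bS2delta(0.5);

  // ---- accumulators ---------------------------------------------------
  NumericMatrix fAcc(N, T);
  std::vector<double> etaAcc(N, 0.0), gammaAcc(T, 0.0), nuAcc(N, 0.0);
  NumericMatrix kappaAcc(N, T);
  long nPost = 0;

  const int nStore = (nIter - burnIn) / thin;
  NumericVector trAlpha(nStore), trS2eta(nStore), trS2v(nStore),
    trS2gamma(nStore), trA(nStore), trB(nStore), trTau(nStore),
    trS2pi(nStore), trS2delta(nStore);
  NumericMatrix trGamma(nStore, T);
  int stored = 0;

  const double sqrt1000 = std::sqrt(1000.0);

  for (int iter = 0; iter < nIter; ++iter) {
    const bool burn = iter < burnIn;

    // ---- Common block (full-data likelihood) --------------------------
    { // alpha0, flat prior
      double d = R::norm_rand() * bAlpha.s;
      double dll = 0.0;
      double em1 = std::exp(d) - 1.0;
      for (int i = 0; i < N; ++i) {
        double ai = alpha0 + eta[i];
        for (int t = 0; t < T; ++t)
          dll += Y(i, t) * d - E(i, t) * std::exp(ai + gamma[t]) * em1;
      }
      bool ok = std::log(R::unif_rand()) < dll;
      if (ok) alpha0 += d;
      bAlpha.record(ok, burn);
    }

    for (int i = 0; i < N; ++i) { // eta_i ~ N(v_i, s2eta), row likelihood
      double d = R::norm_rand() * bEta.s;
      double old = eta[i], prop = old + d;
      double dll = 0.0, em1 = std::exp(d) - 1.0;
      double ai = alpha0 + old;
      for (int t = 0; t < T; ++t)
        dll += Y(i, t) * d - E(i, t) * std::exp(ai + gamma[t]) * em1;
      dll += (-(prop - v[i]) * (prop - v[i]) + (old - v[i]) * (old - v[i])) /
             (2.0 * s2eta);
      bool ok = std::log(R::unif_rand()) < dll;
      if (ok) eta[i] = prop;
      bEta.record(ok, burn);
    }

    // v: conjugate Normal full conditional (ICAR x Normal(eta | v))
    for (int i = 0; i < N; ++i) {
      double ni = (double)adj[i].size();
      double prec = ni / s2v + 1.0 / s2eta;
      double m = eta[i] / s2eta;
      for (size_t k = 0; k < adj[i].size(); ++k) m += v[adj[i][k]] / s2v;
      m /= prec;
      v[i] = m + R::norm_rand() / std::sqrt(prec);
    }
    // identify v: exact level transfer into alpha0 when W is connected,
    // otherwise project onto the per-component sum-to-zero constraint
    if (connectedW) {
      double m = 0.0;
      for (int i = 0; i < N; ++i) m += v[i];
      m /= N;
      for (int i = 0; i < N; ++i) { v[i] -= m; eta[i] -= m; }
      alpha0 += m;
    } else {
      std::vector<double> cs(nCompW, 0.0); std::vector<int> cn(nCompW, 0);
      for (int i = 0; i < N; ++i) { cs[compW[i] - 1] += v[i]; cn[compW[i] - 1]++; }
      for (int i = 0; i < N; ++i) v[i] -= cs[compW[i] - 1] / cn[compW[i] - 1];
    }

    for (int t = 0; t < T; ++t) { // gamma_t, RW1 prior, column likelihood
      double d = R::norm_rand() * bGamma.s;
      double old = gamma[t], prop = old + d;
      double dll = 0.0, em1 = std::exp(d) - 1.0;
      for (int i = 0; i < N; ++i)
        dll += Y(i, t) * d - E(i, t) * std::exp(alpha0 + eta[i] + old) * em1;
      if (t > 0) {
        double nb = gamma[t - 1];
        dll += (-(prop - nb) * (prop - nb) + (old - nb) * (old - nb)) / (2.0 * s2gamma);
      }
      if (t < T - 1) {
        double nb = gamma[t + 1];
        dll += (-(prop - nb) * (prop - nb) + (old - nb) * (old - nb)) / (2.0 * s2gamma);
      }
      bool ok = std::log(R::unif_rand()) < dll;
      if (ok) gamma[t] = prop;
      bGamma.record(ok, burn);
    }
    { // recentre gamma, absorbing the level into alpha0 (exact move)
      double m = 0.0;
      for (int t = 0; t < T; ++t) m += gamma[t];
      m /= T;
      for (int t = 0; t < T; ++t) gamma[t] -= m;
      alpha0 += m;
    }

    // ---- Common-model variances (log-scale RW, half-Normal(0,1) prior) --
    { // s2eta
      double th = std::log(s2eta), thp = th + R::norm_rand() * bS2eta.s;
      double s2p = std::exp(thp);
      double dll = 0.0;
      for (int i = 0; i < N; ++i) {
        double r2 = (eta[i] - v[i]) * (eta[i] - v[i]);
        dll += -0.5 * std::log(s2p) - r2 / (2.0 * s2p)
               + 0.5 * std::log(s2eta) + r2 / (2.0 * s2eta);
      }
      dll += -(s2p * s2p - s2eta * s2eta) / 2.0;  // half-Normal(0,1) on variance
      dll += thp - th;                            // Jacobian of log transform
      bool ok = std::log(R::unif_rand()) < dll;
      if (ok) s2eta = s2p;
      bS2eta.record(ok, burn);
    }
    { // s2v
      double q = 0.0;
      for (int i = 0; i < N; ++i)
        for (size_t k = 0; k < adj[i].size(); ++k) {
          int j = adj[i][k];
          if (j > i) q += (v[i] - v[j]) * (v[i] - v[j]);
        }
      double th = std::log(s2v), thp = th + R::norm_rand() * bS2v.s;
      double s2p = std::exp(thp);
      double dll = -q / (2.0 * s2p) - (rankW / 2.0) * std::log(s2p)
                   + q / (2.0 * s2v) + (rankW / 2.0) * std::log(s2v)
                   - (s2p * s2p - s2v * s2v) / 2.0 + thp - th;
      bool ok = std::log(R::unif_rand()) < dll;
      if (ok) s2v = s2p;
      bS2v.record(ok, burn);
    }
    { // s2gamma
      double q = 0.0;
      for (int t = 1; t < T; ++t)
        q += (gamma[t] - gamma[t - 1]) * (gamma[t] - gamma[t - 1]);
      double th = std::log(s2gamma), thp = th + R::norm_rand() * bS2gamma.s;
      double s2p = std::exp(thp);
      double dll = -q / (2.0 * s2p) - (rankQ / 2.0) * std::log(s2p)
                   + q / (2.0 * s2gamma) + (rankQ / 2.0) * std::log(s2gamma)
                   - (s2p * s2p - s2gamma * s2gamma) / 2.0 + thp - th;
      bool ok = std::log(R::unif_rand()) < dll;
      if (ok) s2gamma = s2p;
      bS2gamma.record(ok, burn);
    }

    // ---- Area-Specific block (full-data likelihood) --------------------
    for (int i = 0; i < N; ++i) { // nu_i ~ N(0, 1000)
      double d = R::norm_rand() * bNu.s;
      double old = nu[i], prop = old + d;
      double dll = 0.0, em1 = std::exp(d) - 1.0;
      for (int t = 0; t < T; ++t)
        dll += Y(i, t) * d - E(i, t) * std::exp(old + kappa(i, t)) * em1;
      dll += R::dnorm(prop, 0.0, sqrt1000, 1) - R::dnorm(old, 0.0, sqrt1000, 1);
      bool ok = std::log(R::unif_rand()) < dll;
      if (ok) nu[i] = prop;
      bNu.record(ok, burn);
    }

    for (int i = 0; i < N; ++i) { // kappa row: per-cell RW1 updates
      for (int t = 0; t < T; ++t) {
        double d = R::norm_rand() * bKappa.s;
        double old = kappa(i, t), prop = old + d;
        double x = nu[i] + old;
        double dll = Y(i, t) * d - E(i, t) * std::exp(x) * (std::exp(d) - 1.0);
        if (t > 0) {
          double nb = kappa(i, t - 1);
          dll += (-(prop - nb) * (prop - nb) + (old - nb) * (old - nb)) /
                 (2.0 * s2kappa[i]);
        }
        if (t < T - 1) {
          double nb = kappa(i, t + 1);
          dll += (-(prop - nb) * (prop - nb) + (old - nb) * (old - nb)) /
                 (2.0 * s2kappa[i]);
        }
        bool ok = std::log(R::unif_rand()) < dll;
        if (ok) kappa(i, t) = prop;
        bKappa.record(ok, burn);
      }
      // recentre the row, moving the level into nu_i
      double m = 0.0;
      for (int t = 0; t < T; ++t) m += kappa(i, t);
      m /= T;
      for (int t = 0; t < T; ++t) kappa(i, t) -= m;
      nu[i] += m;
    }

    for (int i = 0; i < N; ++i) { // s2kappa_i
      double q = 0.0;
      for (int t = 1; t < T; ++t)
        q += (kappa(i, t) - kappa(i, t - 1)) * (kappa(i, t) - kappa(i, t - 1));
      double th = std::log(s2kappa[i]), thp = th + R::norm_rand() * bS2kappa.s;
      double s2p = std::exp(thp);
      double dll = -q / (2.0 * s2p) - (rankQ / 2.0) * std::log(s2p)
                   + q / (2.0 * s2kappa[i]) + (rankQ / 2.0) * std::log(s2kappa[i])
                   + thp - th;
      if (proposed) { // half-Normal(0, 1) on the variance
        dll += -(s2p * s2p - s2kappa[i] * s2kappa[i]) / 2.0;
      } else {        // lognormal(aHyp, bHyp^2)
        dll += R::dlnorm(s2p, aHyp, bHyp, 1) - R::dlnorm(s2kappa[i], aHyp, bHyp, 1);
      }
      bool ok = std::log(R::unif_rand()) < dll;
      if (ok) s2kappa[i] = s2p;
      bS2kappa.record(ok, burn);
    }

    if (!proposed) {
      // a: conjugate Normal given log(s2kappa_i) ~ N(a, b^2), a ~ N(0, 1000)
      double sl = 0.0;
      for (int i = 0; i < N; ++i) sl += std::log(s2kappa[i]);
      double prec = N / (bHyp * bHyp) + 1.0 / 1000.0;
      double mean = (sl / (bHyp * bHyp)) / prec;
      aHyp = mean + R::norm_rand() / std::sqrt(prec);
      // b: RW Metropolis, half-Normal(0, 2.5^2) prior
      double d = R::norm_rand() * bB.s;
      double prop = bHyp + d;
      if (prop > 0.0) {
        double dll = 0.0;
        for (int i = 0; i < N; ++i) {
          double l = std::log(s2kappa[i]);
          dll += R::dnorm(l, aHyp, prop, 1) - R::dnorm(l, aHyp, bHyp, 1);
        }
        dll += R::dnorm(prop, 0.0, 2.5, 1) - R::dnorm(bHyp, 0.0, 2.5, 1);
        bool ok = std::log(R::unif_rand()) < dll;
        if (ok) bHyp = prop;
        bB.record(ok, burn);
      } else {
        bB.record(false, burn);
      }
    }

    // ---- allocation field z (exact Gibbs, cut) -------------------------
    const double ltau = std::log(tau / (1.0 - tau));
    if (!proposed) {
      const double lpr = std::log((1.0 - priorCommon) / priorCommon);
      for (int i = 0; i < N; ++i) {
        double dLAS = 0.0; // LAS - LC over the whole row
        double ai = alpha0 + eta[i];
        for (int t = 0; t < T; ++t) {
          double xC = ai + gamma[t], xAS = nu[i] + kappa(i, t);
          dLAS += llCell(Y(i, t), E(i, t), xAS) - llCell(Y(i, t), E(i, t), xC);
        }
        double p = 1.0 / (1.0 + std::exp(lpr + dLAS)); // P(z_i = 1 | ...)
        double zi = (R::unif_rand() < p) ? 1.0 : 0.0;
        for (int t = 0; t < T; ++t) z(i, t) = zi;
      }
    } else {
      for (int i = 0; i < N; ++i) {
        double ai = alpha0 + eta[i];
        for (int t = 0; t < T; ++t) {
          double xC = ai + gamma[t], xAS = nu[i] + kappa(i, t);
          double dLAS = llCell(Y(i, t), E(i, t), xAS) -
                        llCell(Y(i, t), E(i, t), xC);
          double lphi = piF[i] + deltaF[t] + ltau;        // logit(phi_it)
          double p = 1.0 / (1.0 + std::exp(-lphi + dLAS)); // P(z_it = 1 | ...)
          z(i, t) = (R::unif_rand() < p) ? 1.0 : 0.0;
        }
      }

      // ---- hierarchical allocation layer -------------------------------
      // pi_i: ICAR(W, s2pi) prior, Bernoulli(z row) likelihood
      for (int i = 0; i < N; ++i) {
        double d = R::norm_rand() * bPi.s;
        double old = piF[i], prop = old + d;
        double dll = 0.0;
        for (int t = 0; t < T; ++t) {
          double lo = old + deltaF[t] + ltau, lp = prop + deltaF[t] + ltau;
          // z*log(phi) + (1-z)*log(1-phi) = z*logit(phi) - log(1+exp(logit))
          dll += z(i, t) * (lp - lo)
                 - R::log1pexp(lp) + R::log1pexp(lo);
        }
        for (size_t k = 0; k < adj[i].size(); ++k) {
          double nb = piF[adj[i][k]];
          dll += (-(prop - nb) * (prop - nb) + (old - nb) * (old - nb)) /
                 (2.0 * s2pi);
        }
        bool ok = std::log(R::unif_rand()) < dll;
        if (ok) piF[i] = prop;
        bPi.record(ok, burn);
      }
      { // project pi onto the per-component sum-to-zero constraint
        std::vector<double> cs(nCompW, 0.0); std::vector<int> cn(nCompW, 0);
        for (int i = 0; i < N; ++i) { cs[compW[i] - 1] += piF[i]; cn[compW[i] - 1]++; }
        for (int i = 0; i < N; ++i) piF[i] -= cs[compW[i] - 1] / cn[compW[i] - 1];
      }

      // delta_t: RW1 prior, Bernoulli(z column) likelihood
      for (int t = 0; t < T; ++t) {
        double d = R::norm_rand() * bDelta.s;
        double old = deltaF[t], prop = old + d;
        double dll = 0.0;
        for (int i = 0; i < N; ++i) {
          double lo = piF[i] + old + ltau, lp = piF[i] + prop + ltau;
          dll += z(i, t) * (lp - lo) - R::log1pexp(lp) + R::log1pexp(lo);
        }
        if (t > 0) {
          double nb = deltaF[t - 1];
          dll += (-(prop - nb) * (prop - nb) + (old - nb) * (old - nb)) /
                 (2.0 * s2delta);
        }
        if (t < T - 1) {
          double nb = deltaF[t + 1];
          dll += (-(prop - nb) * (prop - nb) + (old - nb) * (old - nb)) /
                 (2.0 * s2delta);
        }
        bool ok = std::log(R::unif_rand()) < dll;
        if (ok) deltaF[t] = prop;
        bDelta.record(ok, burn);
      }
      { // project delta
        double m = 0.0;
        for (int t = 0; t < T; ++t) m += deltaF[t];
        m /= T;
        for (int t = 0; t < T; ++t) deltaF[t] -= m;
      }

      { // tau: RW on the logit scale, Uniform(0.9, 1) prior
        double th = std::log(tau / (1.0 - tau));
        double thp = th + R::norm_rand() * bTau.s;
        double taup = 1.0 / (1.0 + std::exp(-thp));
        if (taup > 0.9 && taup < 1.0) {
          double ltp = thp; // logit(tau')
          double dll = 0.0;
          for (int i = 0; i < N; ++i)
            for (int t = 0; t < T; ++t) {
              double lo = piF[i] + deltaF[t] + ltau;
              double lp = piF[i] + deltaF[t] + ltp;
              dll += z(i, t) * (lp - lo) - R::log1pexp(lp) + R::log1pexp(lo);
            }
          // Jacobian of tau = plogis(theta)
          dll += std::log(taup * (1.0 - taup)) - std::log(tau * (1.0 - tau));
          bool ok = std::log(R::unif_rand()) < dll;
          if (ok) tau = taup;
          bTau.record(ok, burn);
        } else {
          bTau.record(false, burn);
        }
      }

      { // s2pi
        double q = 0.0;
        for (int i = 0; i < N; ++i)
          for (size_t k = 0; k < adj[i].size(); ++k) {
            int j = adj[i][k];
            if (j > i) q += (piF[i] - piF[j]) * (piF[i] - piF[j]);
          }
        double th = std::log(s2pi), thp = th + R::norm_rand() * bS2pi.s;
        double s2p = std::exp(thp);
        double dll = -q / (2.0 * s2p) - (rankW / 2.0) * std::log(s2p)
                     + q / (2.0 * s2pi) + (rankW / 2.0) * std::log(s2pi)
                     - (s2p * s2p - s2pi * s2pi) / 2.0 + thp - th;
        bool ok = std::log(R::unif_rand()) < dll;
        if (ok) s2pi = s2p;
        bS2pi.record(ok, burn);
      }
      { // s2delta
        double q = 0.0;
        for (int t = 1; t < T; ++t)
          q += (deltaF[t] - deltaF[t - 1]) * (deltaF[t] - deltaF[t - 1]);
        double th = std::log(s2delta), thp = th + R::norm_rand() * bS2delta.s;
        double s2p = std::exp(thp);
        double dll = -q / (2.0 * s2p) - (rankQ / 2.0) * std::log(s2p)
                     + q / (2.0 * s2delta) + (rankQ / 2.0) * std::log(s2delta)
                     - (s2p * s2p - s2delta * s2delta) / 2.0 + thp - th;
        bool ok = std::log(R::unif_rand()) < dll;
        if (ok) s2delta = s2p;
        bS2delta.record(ok, burn);
      }
    }

    if (adapt && burn) {
      bAlpha.adaptStep(); bEta.adaptStep(); bGamma.adaptStep(); bNu.adaptStep();
      bKappa.adaptStep(); bS2eta.adaptStep(); bS2v.adaptStep();
      bS2gamma.adaptStep(); bS2kappa.adaptStep(); bB.adaptStep();
      bPi.adaptStep(); bDelta.adaptStep(); bTau.adaptStep();
      bS2pi.adaptStep(); bS2delta.adaptStep();
    }

    // ---- accumulate / store -------------------------------------------
    if (!burn) {
      nPost++;
      for (int i = 0; i < N; ++i) {
        etaAcc[i] += eta[i]; nuAcc[i] += nu[i];
        for (int t = 0; t < T; ++t) {
          fAcc(i, t) += z(i, t);
          kappaAcc(i, t) += kappa(i, t);
        }
      }
      for (int t = 0; t < T; ++t) gammaAcc[t] += gamma[t];
      if ((iter - burnIn) % thin == 0 && stored < nStore) {
        trAlpha[stored] = alpha0;
        trS2eta[stored] = s2eta; trS2v[stored] = s2v; trS2gamma[stored] = s2gamma;
        trA[stored] = aHyp; trB[stored] = bHyp;
        trTau[stored] = tau; trS2pi[stored] = s2pi; trS2delta[stored] = s2delta;
        for (int t = 0; t < T; ++t) trGamma(stored, t) = gamma[t];
        stored++;
      }
    }
  }

  NumericMatrix f(N, T);
  for (int i = 0; i < N; ++i)
    for (int t = 0; t < T; ++t) f(i, t) = fAcc(i, t) / nPost;
  NumericVector etaM(N), nuM(N), gammaM(T);
  for (int i = 0; i < N; ++i) { etaM[i] = etaAcc[i] / nPost; nuM[i] = nuAcc[i] / nPost; }
  for (int t = 0; t < T; ++t) gammaM[t] = gammaAcc[t] / nPost;
  NumericMatrix kappaM;
  if (storeKappa) {
    kappaM = NumericMatrix(N, T);
    for (int i = 0; i < N; ++i)
      for (int t = 0; t < T; ++t) kappaM(i, t) = kappaAcc(i, t) / nPost;
  }

  NumericVector rates = NumericVector::create(
    _["alpha0"] = bAlpha.rate(), _["eta"] = bEta.rate(),
    _["gamma"] = bGamma.rate(), _["nu"] = bNu.rate(),
    _["kappa"] = bKappa.rate(), _["sigma2Eta"] = bS2eta.rate(),
    _["sigma2V"] = bS2v.rate(), _["sigma2Gamma"] = bS2gamma.rate(),
    _["sigma2Kappa"] = bS2kappa.rate(), _["b"] = bB.rate(),
    _["pi"] = bPi.rate(), _["delta"] = bDelta.rate(),
    _["tau"] = bTau.rate(), _["sigma2Pi"] = bS2pi.rate(),
    _["sigma2Delta"] = bS2delta.rate());

  List traces = List::create(
    _["alpha0"] = trAlpha, _["gamma"] = trGamma,
    _["sigma2Eta"] = trS2eta, _["sigma2V"] = trS2v,
    _["sigma2Gamma"] = trS2gamma, _["a"] = trA, _["b"] = trB,
    _["tau"] = trTau, _["sigma2Pi"] = trS2pi, _["sigma2Delta"] = trS2delta);

  return List::create(
    _["f"] = f, _["traces"] = traces, _["acceptanceRates"] = rates,
    _["etaMean"] = etaM, _["gammaMean"] = gammaM, _["nuMean"] = nuM,
    _["kappaMean"] = kappaM, _["nPost"] = (double)nPost);
}
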