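// Constant-volume / constant-number Monte Carlo solver for the stochastic
// size + NANOG population balance model, driven by interval-of-quiescence
// sampling. Random draws are consumed in a documented order per event:
// ran1 (interval), per-substep Gaussian SDE innovations in cell-index order,
// ran2 (dividing-cell selection), ran3 (size split), ran4 (NANOG split),
// ran5 (second-reporter split, dual-reporter scenario only), ran6
// (constant-number swap index once the ensemble cap is reached).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double HAZARD_CAP = 1e4;   // where the survivor function underflows
static const double T_EPS = 1e-12;

enum Scenario { FULL = 0, NO_EXPRESSION_NOISE = 1, BLOCKED_DIVISION = 2,
                DUAL_REPORTER = 3 };

struct Pars {
  double mu, sigma, q, alpha, d, delta, kgrow; // kgrow = ln2 / T_d
};

static inline double hazard(double x, const Pars& p) {
  if (p.kgrow <= 0.0) return 0.0;
  double surv = R::pnorm(x, p.mu, p.sigma, 0, 0); // upper tail, no log
  if (surv <= 0.0) return HAZARD_CAP;
  double g = R::dnorm(x, p.mu, p.sigma, 0);
  double rate = p.kgrow * x * g / surv;
  if (!(rate < HAZARD_CAP)) rate = HAZARD_CAP;
  return rate;
}

struct Engine {
  std::vector<double> size, nanog, nanog2;
  std::vector<char> arrested;
  Pars par;
  int scenario;
  int kmax;
  double dt;
  long nDivisions;
  int nArrested;
  bool dual;

  int K() const { return (int)size.size(); }

  double totalHazard() const {
    double lam = 0.0;
    for (int i = 0; i < K(); ++i)
      if (!arrested[i]) lam += hazard(size[i], par);
    return lam;
  }

  // Integral of the population hazard over a lookahead of length T, with
  // sizes advanced along the same explicit-Euler trajectories used by
  // advance(); left-rectangle quadrature on steps of at most dt.
  // Also reports the instantaneous hazard at the end of the lookahead
  // (the derivative used by the Newton iteration).
  double phi(double T, double& lamEnd) const {
    std::vector<double> tmp;
    tmp.reserve(size.size());
    for (int i = 0; i < K(); ++i) if (!arrested[i]) tmp.push_back(size[i]);
    double acc = 0.0, rem = T;
    double lam = 0.0;
    for (size_t i = 0; i < tmp.size(); ++i) lam += hazard(tmp[i], par);
    while (rem > T_EPS) {
      double h = rem < dt ? rem : dt;
      acc += lam * h;
      for (size_t i = 0; i < tmp.size(); ++i) tmp[i] += par.kgrow * tmp[i] * h;
      rem -= h;
      lam = 0.0;
      for (size_t i = 0; i < tmp.size(); ++i) lam += hazard(tmp[i], par);
    }
    lamEnd = lam;
    return acc;
  }

  // Solve phi(T) = target for the quiescence interval. Under the
  // left-rectangle quadrature along the explicit-Euler size trajectories,
  // phi is piecewise linear in T with slope equal to the start-of-step
  // hazard, so the inversion is exact segment by segment: march in steps
  // of at most dt, and stop inside the step whose hazard integral crosses
  // the target (the converged limit of a Newton iteration on the same
  // quadrature). Returns +Inf when no division occurs within `remaining`.
  double solveInterval(double target, double lam0, double remaining) const {
    // single-rectangle regime: phi(T) = lam0 * T exactly for T <= dt
    if (lam0 > 0.0 && target <= lam0 * dt) {
      double T = target / lam0;
      if (T <= remaining) return T;
    }
    std::vector<double> tmp;
    tmp.reserve(size.size());
    for (int i = 0; i < K(); ++i) if (!arrested[i]) tmp.push_back(size[i]);
    double acc = 0.0, elapsed = 0.0, lam = lam0;
    while (elapsed < remaining - T_EPS) {
      double h = remaining - elapsed;
      if (h > dt) h = dt;
      if (lam > 0.0 && acc + lam * h >= target)
        return elapsed + (target - acc) / lam;
      acc += lam * h;
      for (size_t i = 0; i < tmp.size(); ++i) tmp[i] += par.kgrow * tmp[i] * h;
      elapsed += h;
      lam = 0.0;
      for (size_t i = 0; i < tmp.size(); ++i) lam += hazard(tmp[i], par);
    }
    return std::numeric_limits<double>::infinity();
  }

  // Advance every cell by `interval` hours: explicit Euler for size
  // (frozen for arrested cells), Euler-Maruyama for NANOG with steps of at
  // most dt, reflecting the copy-number floor at zero.
  void advance(double interval) {
    double rem = interval;
    bool noise = (par.delta > 0.0) && (scenario != NO_EXPRESSION_NOISE);
    while (rem > T_EPS) {
      double h = rem < dt ? rem : dt;
      double sq = std::sqrt(h);
      for (int i = 0; i < K(); ++i) {
        if (!arrested[i]) size[i] += par.kgrow * size[i] * h;
        double N = nanog[i] + (par.alpha - par.d * nanog[i]) * h;
        if (noise) N += par.delta * sq * norm_rand();
        nanog[i] = N > 0.0 ? N : 0.0;
        if (dual) {
          double N2 = nanog2[i] + (par.alpha - par.d * nanog2[i]) * h;
          if (noise) N2 += par.delta * sq * norm_rand();
          nanog2[i] = N2 > 0.0 ? N2 : 0.0;
        }
      }
      rem -= h;
    }
  }

  static double betaFraction(double q) {
    double f = R::rbeta(q, q);
    if (f < 1e-12) f = 1e-12;
    if (f > 1.0 - 1e-12) f = 1.0 - 1e-12;
    return f;
  }

  // ran2-driven selection followed by division (or transfer to the blocked
  // pool). Cumulative-sum inversion over the current per-cell hazards.
  void divisionEvent() {
    int n = K();
    std::vector<double> haz(n);
    double lam = 0.0;
    for (int i = 0; i < n; ++i) {
      haz[i] = arrested[i] ? 0.0 : hazard(size[i], par);
      lam += haz[i];
    }
    if (lam <= 0.0) return; // no eligible cell (all arrested)
    double u2 = unif_rand() * lam;
    int j = 0;
    double acc = 0.0;
    for (; j < n; ++j) { acc += haz[j]; if (u2 <= acc) break; }
    if (j >= n) j = n - 1;

    if (scenario == BLOCKED_DIVISION) {
      arrested[j] = 1;
      ++nArrested;
      return;
    }

    double f3 = betaFraction(par.q);            // ran3: size split
    double f4 = betaFraction(par.q);            // ran4: NANOG split
    double f5 = dual ? betaFraction(par.q) : 0; // ran5: second reporter
    double x = size[j], N = nanog[j], N2 = dual ? nanog2[j] : 0.0;

    size[j] = f3 * x; nanog[j] = f4 * N;
    if (dual) nanog2[j] = f5 * N2;
    double x2 = (1.0 - f3) * x, Nb = (1.0 - f4) * N,
           N2b = dual ? (1.0 - f5) * N2 : NA_REAL;

    if (n < kmax) { // constant-volume phase: both daughters join
      size.push_back(x2); nanog.push_back(Nb);
      nanog2.push_back(dual ? N2b : NA_REAL);
      arrested.push_back(0);
    } else {        // constant-number phase: swap out a random other cell
      int r = (int)(unif_rand() * (n - 1)); // ran6
      if (r >= n - 1) r = n - 2;
      if (r >= j) ++r;
      size[r] = x2; nanog[r] = Nb;
      if (dual) nanog2[r] = N2b;
      arrested[r] = 0;
    }
    ++nDivisions;
  }

  List snapshot(double t) const {
    int n = K();
    NumericVector s(n), N(n), N2(n);
    LogicalVector a(n);
    for (int i = 0; i < n; ++i) {
      s[i] = size[i]; N[i] = nanog[i];
      N2[i] = dual ? nanog2[i] : NA_REAL;
      a[i] = (bool)arrested[i];
    }
    return List::create(
      _["time"] = t, _["size"] = s, _["nanog"] = N, _["nanog2"] = N2,
      _["arrested"] = a, _["nDivisions"] = (double)nDivisions,
      _["nArrested"] = nArrested);
  }
};

// [[Rcpp::export(name = ".mc_engine_run")]]
List mc_engine_run(NumericVector size0, NumericVector nanog0,
                   NumericVector nanog20, LogicalVector arrested0,
                   List parList, int scenario, int kmax, double tTotal,
                   double dt, NumericVector recordTimes) {
  Engine e;
  int n0 = size0.size();
  e.par.mu = as<double>(parList["mu"]);
  e.par.sigma = as<double>(parList["sigma"]);
  e.par.q = as<double>(parList["q"]);
  e.par.alpha = as<double>(parList["alpha"]);
  e.par.d = as<double>(parList["d"]);
  e.par.delta = as<double>(parList["delta"]);
  double Td = as<double>(parList["doublingTime"]);
  e.par.kgrow = std::isfinite(Td) ? std::log(2.0) / Td : 0.0;
  if (scenario == NO_EXPRESSION_NOISE) e.par.delta = 0.0;
  e.scenario = scenario;
  e.kmax = kmax;
  e.dt = dt;
  e.nDivisions = 0;
  e.dual = (scenario == DUAL_REPORTER);
  e.size.assign(size0.begin(), size0.end());
  e.nanog.assign(nanog0.begin(), nanog0.end());
  e.nanog2.resize(n0);
  for (int i = 0; i < n0; ++i)
    e.nanog2[i] = e.dual ? nanog20[i] : NA_REAL;
  e.arrested.resize(n0);
  e.nArrested = 0;
  for (int i = 0; i < n0; ++i) {
    e.arrested[i] = arrested0[i] ? 1 : 0;
    if (e.arrested[i]) ++e.nArrested;
  }

  std::vector<List> out;
  int nRec = recordTimes.size(), recIdx = 0;
  double t = 0.0;
  while (recIdx < nRec && recordTimes[recIdx] <= T_EPS) {
    out.push_back(e.snapshot(0.0));
    ++recIdx;
  }

  while (t < tTotal - T_EPS) {
    double lam0 = e.totalHazard();
    double tEvent = std::numeric_limits<double>::infinity();
    if (lam0 > 0.0 || e.nArrested < e.K()) {
      double u1 = unif_rand();                    // ran1
      double target = -std::log1p(-u1);
      double T = e.solveInterval(target, lam0, tTotal - t);
      tEvent = t + T;
    }
    double tStop = tEvent < tTotal ? tEvent : tTotal;
    // advance in chunks, pausing at snapshot times
    while (t < tStop - T_EPS) {
      double tNext = tStop;
      if (recIdx < nRec && recordTimes[recIdx] < tNext - 1e-9)
        tNext = recordTimes[recIdx];
      e.advance(tNext - t);
      t = tNext;
      while (recIdx < nRec && recordTimes[recIdx] <= t + 1e-9) {
        out.push_back(e.snapshot(recordTimes[recIdx]));
        ++recIdx;
      }
    }
    if (tEvent <= tTotal - T_EPS) e.divisionEvent();
  }
  while (recIdx < nRec) { // horizon-coincident snapshot times
    out.push_back(e.snapshot(recordTimes[recIdx]));
    ++recIdx;
  }

  List res(out.size());
  for (size_t i = 0; i < out.size(); ++i) res[i] = out[i];
  return res;
}
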