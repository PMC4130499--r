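// Adaptive explicit-Euler integrator for the protocell ion balance.
// All quantities SI: concentrations mol/m^3, fluxes mol/s, energies
// J/mol, potential V. Ion order: 0 H+, 1 OH-, 2 Na+, 3 K+, 4 Cl-.
// Mirrored by the pure-R reference stepper (compute_fluxes/step_state),
// which the test suite holds to step-by-step agreement.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
#include <sstream>
using namespace Rcpp;

namespace {

const int NI = 5;

struct Protein {
  int type;        // 1 atpase, 2 ech, 3 spap, 4 pump
  double max_flux; // N * turnover * efficiency * ions_per_cycle / N_A, mol/s
  double satK;     // hyperbolic half-saturation, J/mol
  int pump_ion;    // 0-based ion index (pump only)
  double f_h2;     // H2 / (H2 + K_H2)
  double K_pump;   // opposing-gradient scale, J/mol
};

inline double sat(double dG, double K) {
  double a = std::fabs(dG);
  return a / (a + K);
}

// GHK flux across one face, inward positive; u = zF dpsi / RT.
inline double ghk_flux1(double P, double A, double u,
                        double c_in, double c_out) {
  if (std::fabs(u) < 1e-8)
    return P * A * ((c_out - c_in) - u * (c_out + c_in) / 2.0);
  return P * A * u * (c_out - c_in * std::exp(u)) / (std::exp(u) - 1.0);
}

struct Derived {
  double dpsi;
  double dG[NI];      // inward transfer across acid face, J/mol
  double dG_chem[NI];
  double J[NI];       // total flux per ion, mol/s
  double lipid_acid_H, lipid_alk_H, prot_H;
  double lipid_acid_Na, lipid_alk_Na, prot_Na;
};

} // namespace

// [[Rcpp::export]]
List sim_core(NumericVector z, NumericVector P, LogicalVector carrier,
              NumericVector c_acid_in, NumericVector c_alk_in,
              NumericVector c0,
              double A_acid, double A_alk, double V,
              List proteins,
              double T, double F, double Rgas, double Kw,
              double dt0, double t_end,
              double steady_tol_J, double steady_window, double record_dt,
              double max_rel, double conc_floor,
              NumericMatrix sched, bool audit) {
  const double RT = Rgas * T;
  std::vector<double> c_acid(c_acid_in.begin(), c_acid_in.end());
  std::vector<double> c_alk(c_alk_in.begin(), c_alk_in.end());
  std::vector<double> c(c0.begin(), c0.end());
  std::vector<double> c_eff(NI);
  const double Atot = A_acid + A_alk;
  auto pool_eff = [&]() {
    for (int i = 0; i < NI; ++i)
      c_eff[i] = (c_acid[i] * A_acid + c_alk[i] * A_alk) / Atot;
  };
  pool_eff();

  std::vector<Protein> prot;
  for (int k = 0; k < proteins.size(); ++k) {
    List p = proteins[k];
    Protein q;
    q.type = as<int>(p["type"]);
    q.max_flux = as<double>(p["max_flux"]);
    q.satK = as<double>(p["satK"]);
    q.pump_ion = as<int>(p["pump_ion"]) - 1; // R 1-based -> 0-based
    q.f_h2 = as<double>(p["f_h2"]);
    q.K_pump = as<double>(p["K_pump"]);
    prot.push_back(q);
  }

  auto derive = [&](const std::vector<double>& ci, Derived& d) {
    // constant-field voltage over the bare (non-carrier) ions
    double num = 0.0, den = 0.0;
    for (int i = 0; i < NI; ++i) {
      if (carrier[i]) continue;
      if (z[i] > 0) { num += P[i] * c_eff[i]; den += P[i] * ci[i]; }
      else          { num += P[i] * ci[i];    den += P[i] * c_eff[i]; }
    }
    if (num <= 0.0 || den <= 0.0)
      stop("GHK voltage undefined: zero permeability-weighted side");
    d.dpsi = RT / F * std::log(num / den);
    d.lipid_acid_H = d.lipid_alk_H = d.prot_H = 0.0;
    d.lipid_acid_Na = d.lipid_alk_Na = d.prot_Na = 0.0;
    for (int i = 0; i < NI; ++i) {
      double ja, jk;
      if (carrier[i]) {   // electroneutral carrier: linear diffusion
        ja = P[i] * A_acid * (c_acid[i] - ci[i]);
        jk = P[i] * A_alk * (c_alk[i] - ci[i]);
      } else {
        double u = z[i] * F * d.dpsi / RT;
        ja = ghk_flux1(P[i], A_acid, u, ci[i], c_acid[i]);
        jk = ghk_flux1(P[i], A_alk, u, ci[i], c_alk[i]);
      }
      d.J[i] = ja + jk;
      if (i == 0) { d.lipid_acid_H = ja; d.lipid_alk_H = jk; }
      if (i == 2) { d.lipid_acid_Na = ja; d.lipid_alk_Na = jk; }
      d.dG_chem[i] = RT * std::log(ci[i] / c_acid[i]);
      d.dG[i] = z[i] * F * d.dpsi + d.dG_chem[i];
    }
    for (size_t k = 0; k < prot.size(); ++k) {
      const Protein& q = prot[k];
      if (q.type == 1 || q.type == 2) {          // promiscuous ATPase / Ech
        double wH = std::max(-d.dG[0], 0.0), wNa = std::max(-d.dG[2], 0.0);
        double s = wH + wNa;
        if (s > 0.0) {
          wH /= s; wNa /= s;
          double dG_eff = wH * (-d.dG[0]) + wNa * (-d.dG[2]);
          double tot = q.max_flux * sat(dG_eff, q.satK);
          d.J[0] += wH * tot;  d.prot_H += wH * tot;
          d.J[2] += wNa * tot; d.prot_Na += wNa * tot;
        }
      } else if (q.type == 3) {                  // electroneutral 1:1 SPAP
        double dG_net = d.dG_chem[0] - d.dG_chem[2];
        double r = q.max_flux * sat(dG_net, q.satK);
        double dirH = (dG_net < 0.0) ? 1.0 : (dG_net > 0.0 ? -1.0 : 0.0);
        d.J[0] += dirH * r;  d.prot_H += dirH * r;
        d.J[2] -= dirH * r;  d.prot_Na -= dirH * r;
      } else {                                   // H2-dependent pump, outward
        int i = q.pump_ion;
        double dG_opp = -d.dG[i];
        double j = q.max_flux * q.f_h2 *
          std::exp(-std::max(dG_opp, 0.0) / q.K_pump);
        d.J[i] -= j;
        if (i == 0) d.prot_H -= j;
        if (i == 2) d.prot_Na -= j;
      }
    }
  };

  // stability cap for the step: fastest passive exchange rate
  double lam = 0.0;
  for (int i = 0; i < NI; ++i) lam = std::max(lam, P[i] * Atot / V);
  const double dt_cap = std::min(dt0, (lam > 0.0) ? 0.5 / lam : dt0);
  const double dt_min = dt_cap * std::ldexp(1.0, -30);

  std::vector<double> rec_t, rec_rep;
  std::vector<std::array<double, 5>> rec_out;   // -dG_H,-dG_Na,-dG_rep,dpsi,pH
  std::vector<std::array<double, 5>> rec_conc;
  std::vector<std::array<double, 6>> rec_path;

  double t = 0.0, dt = dt_cap, next_rec = 0.0, max_resid = 0.0;
  long n_steps = 0;
  int sched_row = 0;
  std::string stop_reason = "t_end";
  Derived d;

  auto reported = [&](const Derived& dd) {
    double mH = -dd.dG[0] * 1e-3, mNa = -dd.dG[2] * 1e-3; // kJ/mol
    double wH = std::max(mH, 0.0), wNa = std::max(mNa, 0.0), s = wH + wNa;
    if (s <= 0.0) return std::max(mH, mNa);
    return (wH * mH + wNa * mNa) / s;
  };

  auto record = [&](const Derived& dd) {
    double rep = reported(dd);
    rec_t.push_back(t);
    rec_rep.push_back(rep);
    double pH = -std::log10(c[0] * 1e-3); // mol/m^3 -> mol/L
    rec_out.push_back({-dd.dG[0] * 1e-3, -dd.dG[2] * 1e-3, rep, dd.dpsi, pH});
    rec_conc.push_back({c[0], c[1], c[2], c[3], c[4]});
    if (audit)
      rec_path.push_back({dd.lipid_acid_H, dd.lipid_alk_H, dd.prot_H,
                          dd.lipid_acid_Na, dd.lipid_alk_Na, dd.prot_Na});
  };

  const double steady_tol_kJ = steady_tol_J * 1e-3;
  bool done = false;
  while (!done) {
    // external-pH schedule (piecewise constant)
    while (sched_row < sched.nrow() && t >= sched(sched_row, 0) - 1e-12) {
      c_acid[0] = sched(sched_row, 1); c_acid[1] = sched(sched_row, 2);
      c_alk[0] = sched(sched_row, 3);  c_alk[1] = sched(sched_row, 4);
      pool_eff();
      ++sched_row;
    }
    derive(c, d);
    if (t >= next_rec - 1e-12) {
      record(d);
      next_rec += record_dt;
      // steady-state check over the trailing window of records
      size_t n = rec_t.size();
      if (rec_t[n - 1] >= steady_window) {
        bool steady = true; bool seen = false;
        for (size_t j = n - 1; j-- > 0;) {
          if (rec_t[n - 1] - rec_t[j] > steady_window) break;
          seen = true;
          if (std::fabs(rec_rep[n - 1] - rec_rep[j]) >
              steady_tol_kJ * steady_window) { steady = false; break; }
        }
        if (seen && steady) { stop_reason = "steady"; break; }
      }
    }
    if (t >= t_end) { stop_reason = (stop_reason == "steady") ? stop_reason : "t_end"; break; }

    // attempt a step, halving dt until the move is acceptable
    int halvings = 0;
    while (true) {
      double dc[NI];
      for (int i = 0; i < NI; ++i) dc[i] = d.J[i] * dt / V;
      double pool = c[0] + c[1] + conc_floor;
      double dd_excess = dc[0] - dc[1];
      bool ok = std::fabs(dd_excess) <= max_rel * pool;
      double frac = std::fabs(dd_excess) / pool;
      for (int i = 2; i < NI && ok; ++i) {
        double denom = std::max(c[i], conc_floor);
        if (std::fabs(dc[i]) > max_rel * denom || c[i] + dc[i] < 0.0)
          ok = false;
        frac = std::max(frac, std::fabs(dc[i]) / denom);
      }
      if (ok) {
        double tot_H = c[0] + dc[0], tot_OH = c[1] + dc[1];
        double dex = tot_H - tot_OH;
        double s = std::sqrt(dex * dex + 4.0 * Kw);
        // stable quadratic root (no cancellation when |dex| >> sqrt(Kw))
        double H = (dex >= 0.0) ? (dex + s) / 2.0 : 2.0 * Kw / (s - dex);
        if (audit) {
          double dex_old = c[0] - c[1];
          double resid = std::fabs((dex - dex_old) * V -
                                   (d.J[0] - d.J[1]) * dt);
          double scale = std::max(std::fabs((d.J[0] - d.J[1]) * dt), 1e-300);
          max_resid = std::max(max_resid, resid / scale);
        }
        c[0] = H; c[1] = Kw / H;
        for (int i = 2; i < NI; ++i) c[i] += dc[i];
        t += dt; ++n_steps;
        if (frac < 0.25 * max_rel) dt = std::min(dt * 2.0, dt_cap);
        break;
      }
      dt *= 0.5; ++halvings;
      if (dt < dt_min || halvings > 60) {
        std::ostringstream msg;
        msg << "step failure at t = " << t << " s after repeated halvings; "
            << "state (mol/m^3): H " << c[0] << ", OH " << c[1]
            << ", Na " << c[2] << ", K " << c[3] << ", Cl " << c[4];
        stop(msg.str());
      }
    }
    if (n_steps % 262144 == 0) checkUserInterrupt();
  }

  // make sure the final state is on the record
  if (rec_t.empty() || rec_t.back() < t - 1e-12) {
    derive(c, d);
    record(d);
  }

  size_t n = rec_t.size();
  NumericMatrix out(n, 5), conc(n, 5), path(audit ? n : 0, 6);
  for (size_t r = 0; r < n; ++r) {
    for (int j = 0; j < 5; ++j) {
      out(r, j) = rec_out[r][j];
      conc(r, j) = rec_conc[r][j];
    }
    if (audit) for (int j = 0; j < 6; ++j) path(r, j) = rec_path[r][j];
  }
  return List::create(_["time"] = NumericVector(rec_t.begin(), rec_t.end()),
                      _["out"] = out, _["conc"] = conc,
                      _["n_steps"] = (double)n_steps,
                      _["stop_reason"] = stop_reason,
                      _["max_residual"] = max_resid,
                      _["pathway"] = path);
}
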