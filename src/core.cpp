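// Core stochastic machinery: force-dependent motor kinetics, the Gillespie
// stepping engine for mixed DDB/KIF16B teams on a 7-lane lattice, and the
// simulated-annealing change-point segmenter.  All randomness goes through
// R's RNG so results are reproducible under set.seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// kinetics helpers
// ---------------------------------------------------------------------------

// piecewise-Hookean spring with dead zone of half-width L
static inline double hook_force(double dx, double kappa, double L) {
  if (dx > L)  return kappa * (dx - L);
  if (dx < -L) return kappa * (dx + L);
  return 0.0;
}

struct Schnitzer {
  double kb0, pb, qb, pcat, qcat;
};

// Michaelis-Menten stepping rate with Boltzmann-distributed k_cat and k_b.
// Fres is the resisting force magnitude (>= 0); assisting loads are handled
// by the caller (rate at zero load).  atp may be Inf (saturating).
static double schnitzer_rate(double Fres, double atp, double kcat0,
                             const Schnitzer& sc, double delta, double kBT) {
  double boltz = std::exp(Fres * delta / kBT);
  double kcat = kcat0 / (sc.pcat + sc.qcat * boltz);
  if (!R_finite(atp)) return kcat;
  double kb = sc.kb0 / (sc.pb + sc.qb * boltz);
  return kcat * atp / (atp + kcat / kb);
}

// delta solving s(ATP, F_s; delta) = target (0.1/s) by bisection.
// Returns -1 if the zero-load rate is already below the target.
static double calibrate_delta_core(double Fs, double atp, double kcat0,
                                   const Schnitzer& sc, double kBT,
                                   double target = 0.1) {
  double lo = 0.0;
  double flo = schnitzer_rate(Fs, atp, kcat0, sc, lo, kBT) - target;
  if (flo < 0.0) return -1.0;
  double hi = 1.0;
  while (schnitzer_rate(Fs, atp, kcat0, sc, hi, kBT) > target) {
    hi *= 2.0;
    if (hi > 1e6) return -1.0;
  }
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    double fm = schnitzer_rate(Fs, atp, kcat0, sc, mid, kBT) - target;
    if (fm > 0.0) lo = mid; else hi = mid;
    if ((hi - lo) < 1e-14 * (1.0 + hi)) break;
  }
  return 0.5 * (lo + hi);
}

static inline double bell_rate(double k0, double Fabs, double Fd,
                               bool literal_sign) {
  if (!R_finite(Fd)) return k0;
  return literal_sign ? k0 * std::exp(-Fabs / Fd) : k0 * std::exp(Fabs / Fd);
}

// [[Rcpp::export]]
double cpp_stepping_rate(double Fres, double atp, double kcat0, double kb0,
                         double pb, double qb, double pcat, double qcat,
                         double delta, double kBT) {
  Schnitzer sc{kb0, pb, qb, pcat, qcat};
  return schnitzer_rate(Fres, atp, kcat0, sc, delta, kBT);
}

// [[Rcpp::export]]
double cpp_calibrate_delta(double Fs, double atp, double kcat0, double kb0,
                           double pb, double qb, double pcat, double qcat,
                           double kBT, double target) {
  Schnitzer sc{kb0, pb, qb, pcat, qcat};
  return calibrate_delta_core(Fs, atp, kcat0, sc, kBT, target);
}

// ---------------------------------------------------------------------------
// cargo relaxation: deterministic force balance + Metropolis thermal noise
// ---------------------------------------------------------------------------

// total spring energy at cargo position X
static double spring_energy(double X, const std::vector<double>& xh,
                            const std::vector<double>& kap,
                            const std::vector<double>& Lr) {
  double E = 0.0;
  for (size_t i = 0; i < xh.size(); ++i) {
    double dx = xh[i] - X;
    double f = hook_force(dx, kap[i], Lr[i]);
    if (f != 0.0) {
      double s = std::fabs(dx) - Lr[i];
      E += 0.5 * kap[i] * s * s;
    }
  }
  return E;
}

static double total_force(double X, const std::vector<double>& xh,
                          const std::vector<double>& kap,
                          const std::vector<double>& Lr) {
  double F = 0.0;
  for (size_t i = 0; i < xh.size(); ++i)
    F += hook_force(xh[i] - X, kap[i], Lr[i]);
  return F;
}

// nearest point to X0 where the net spring force vanishes (the energy is
// convex piecewise-quadratic, so the zero-force set is an interval)
static double force_balance_point(double X0, const std::vector<double>& xh,
                                  const std::vector<double>& kap,
                                  const std::vector<double>& Lr) {
  if (xh.empty()) return X0;
  double F0 = total_force(X0, xh, kap, Lr);
  if (F0 == 0.0) return X0;
  double Lmax = 0.0, lo, hi;
  for (double l : Lr) Lmax = std::max(Lmax, l);
  if (F0 > 0.0) { // net forward force: nearest zero lies to the right
    lo = X0;
    hi = *std::max_element(xh.begin(), xh.end()) + Lmax + 1.0;
    for (int it = 0; it < 80; ++it) {
      double mid = 0.5 * (lo + hi);
      if (total_force(mid, xh, kap, Lr) > 0.0) lo = mid; else hi = mid;
    }
  } else {
    hi = X0;
    lo = *std::min_element(xh.begin(), xh.end()) - Lmax - 1.0;
    for (int it = 0; it < 80; ++it) {
      double mid = 0.5 * (lo + hi);
      if (total_force(mid, xh, kap, Lr) < 0.0) hi = mid; else lo = mid;
    }
  }
  return 0.5 * (lo + hi);
}

static double relax_position(double X0, const std::vector<double>& xh,
                             const std::vector<double>& kap,
                             const std::vector<double>& Lr, double kBT,
                             int n_prop, double step) {
  if (xh.empty()) return X0;
  double X = force_balance_point(X0, xh, kap, Lr);
  double E = spring_energy(X, xh, kap, Lr);
  for (int p = 0; p < n_prop; ++p) {
    double Xn = X + step * (2.0 * unif_rand() - 1.0);
    double En = spring_energy(Xn, xh, kap, Lr);
    double dE = En - E;
    bool acc = dE <= 0.0 ||
      (kBT > 0.0 && unif_rand() < std::exp(-dE / kBT));
    if (acc) { X = Xn; E = En; }
  }
  return X;
}

// [[Rcpp::export]]
List cpp_relax_cargo(NumericVector head_pos, NumericVector kappa,
                     NumericVector rest_length, double x0, double kBT,
                     int n_proposals, double step_size) {
  std::vector<double> xh(head_pos.begin(), head_pos.end());
  std::vector<double> kap(kappa.begin(), kappa.end());
  std::vector<double> Lr(rest_length.begin(), rest_length.end());
  double e0 = spring_energy(x0, xh, kap, Lr);
  double x = relax_position(x0, xh, kap, Lr, kBT, n_proposals, step_size);
  double e1 = spring_energy(x, xh, kap, Lr);
  return List::create(_["x"] = x, _["energy_initial"] = e0,
                      _["energy_final"] = e1,
                      _["force"] = total_force(x, xh, kap, Lr));
}

// ---------------------------------------------------------------------------
// Gillespie engine
// ---------------------------------------------------------------------------

struct SpeciesPar {
  double kappa, L, Fs, Fd, ka, kd0, kdi, vb, d;
  double fin, fdiff, s0;
  Schnitzer sc;
  int pol;
  double vmax_meanlog, vmax_sdlog, vmax_fixed; // fixed used when finite
};

static SpeciesPar species_from_list(const List& p) {
  SpeciesPar s;
  s.kappa = as<double>(p["kappa"]);
  s.L = as<double>(p["rest_length"]);
  s.Fs = as<double>(p["stall_force"]);
  s.Fd = as<double>(p["detach_force"]);
  s.ka = as<double>(p["attach_rate"]);
  s.kd0 = as<double>(p["detach_rate_active"]);
  s.kdi = as<double>(p["detach_rate_inactive"]);
  s.vb = as<double>(p["back_velocity"]);
  s.d = as<double>(p["step_size"]);
  s.fin = as<double>(p["frac_inactive"]);
  s.fdiff = as<double>(p["frac_diffusive"]);
  s.s0 = as<double>(p["diffusive_rate"]);
  List sc = p["schnitzer"];
  s.sc.kb0 = as<double>(sc["k_b0"]);
  s.sc.pb = as<double>(sc["p_b"]);
  s.sc.qb = as<double>(sc["q_b"]);
  s.sc.pcat = as<double>(sc["p_cat"]);
  s.sc.qcat = as<double>(sc["q_cat"]);
  s.pol = as<int>(p["polarity"]);
  s.vmax_meanlog = as<double>(p["vmax_meanlog"]);
  s.vmax_sdlog = as<double>(p["vmax_sdlog"]);
  s.vmax_fixed = as<double>(p["vmax_fixed"]);
  return s;
}

enum Activity { ACT_ACTIVE = 0, ACT_INACTIVE = 1, ACT_DIFFUSIVE = 2 };

struct Motor {
  int species;          // 0 = DDB, 1 = KIF16B
  bool attached;
  int activity;
  int lane;
  long site;
  double vmax, delta;
  double t_attach;
  long site_attach;
};

struct Event { double rate; int motor; int type; };
enum EvType { EV_ATTACH, EV_DETACH, EV_FWD, EV_BWD, EV_DIFF_P, EV_DIFF_M };

static bool site_occupied(const std::vector<Motor>& mots, int lane, long site,
                          int self) {
  for (size_t i = 0; i < mots.size(); ++i) {
    if ((int)i == self) continue;
    if (mots[i].attached && mots[i].lane == lane && mots[i].site == site)
      return true;
  }
  return false;
}

static int draw_lane(const std::vector<double>& cum) {
  double u = unif_rand();
  int n = (int)cum.size();
  for (int i = 0; i < n; ++i) if (u <= cum[i]) return i - n / 2;
  return 0;
}

// [[Rcpp::export]]
List cpp_simulate_cargo(List ddb, List kif, List cfg) {
  SpeciesPar sp[2] = {species_from_list(ddb), species_from_list(kif)};
  const int n_ddb = as<int>(cfg["n_ddb"]);
  const int n_kif = as<int>(cfg["n_kif"]);
  const double atp = as<double>(cfg["atp"]);
  const double kBT = as<double>(cfg["kBT"]);
  const double lane_sigma = as<double>(cfg["lane_sigma"]);
  const int lane_cut = as<int>(cfg["lane_cut"]);
  const double relax_time = as<double>(cfg["relax_time"]);
  const double max_time = as<double>(cfg["max_time"]);
  const double dt_s = as<double>(cfg["sample_interval"]);
  const int met_n = as<int>(cfg["metropolis_n"]);
  const double met_step = as<double>(cfg["metropolis_step"]);
  const bool literal = as<bool>(cfg["bell_literal_sign"]);
  const bool validate = as<bool>(cfg["validate"]);
  const double stall_target = as<double>(cfg["stall_target"]);

  // lattice spacing shared between species (exclusion lives on one lattice)
  const double d = sp[0].d;
  if (std::fabs(sp[1].d - d) > 1e-9)
    stop("DDB and KIF16B step sizes must agree (shared lattice)");

  // truncated discrete Gaussian over lanes -cut..cut
  std::vector<double> lane_cum(2 * lane_cut + 1);
  {
    double tot = 0.0;
    for (int l = -lane_cut; l <= lane_cut; ++l)
      tot += std::exp(-0.5 * l * l / (lane_sigma * lane_sigma));
    double acc = 0.0;
    for (int l = -lane_cut; l <= lane_cut; ++l) {
      acc += std::exp(-0.5 * l * l / (lane_sigma * lane_sigma)) / tot;
      lane_cum[l + lane_cut] = acc;
    }
    lane_cum.back() = 1.0;
  }

  std::vector<Motor> mots(n_ddb + n_kif);
  for (int i = 0; i < n_ddb + n_kif; ++i) {
    mots[i].species = (i < n_ddb) ? 0 : 1;
    mots[i].attached = false;
  }

  double t = 0.0, X = 0.0;
  bool ever_attached = false;

  const int n_samp = (int)std::floor((max_time - relax_time) / dt_s + 1e-9) + 1;
  std::vector<double> s_t, s_x, s_f;
  std::vector<int> s_nd, s_nk;
  s_t.reserve(n_samp); s_x.reserve(n_samp);
  int samp_idx = 0;

  std::vector<int> r_species, r_activity, r_lane;
  std::vector<double> r_t0, r_t1, r_x0, r_x1;

  std::vector<Event> evs;
  std::vector<double> xh, kap, Lr; // attached-motor scratch for relaxation

  auto n_attached = [&](int species) {
    int n = 0;
    for (const Motor& m : mots)
      if (m.attached && (species < 0 || m.species == species)) ++n;
    return n;
  };
  auto cargo_force_abs = [&]() {
    double f = 0.0;
    for (const Motor& m : mots)
      if (m.attached)
        f += std::fabs(hook_force(m.site * d - X, sp[m.species].kappa,
                                  sp[m.species].L));
    return f;
  };
  auto flush_samples = [&](double upto) {
    while (samp_idx < n_samp) {
      double ts = relax_time + samp_idx * dt_s;
      if (ts > upto + 1e-12) break;
      s_t.push_back(ts - relax_time);
      s_x.push_back(X);
      s_nd.push_back(n_attached(0));
      s_nk.push_back(n_attached(1));
      s_f.push_back(cargo_force_abs());
      ++samp_idx;
    }
  };

  std::string status = "max_time";
  while (true) {
    // build event list
    evs.clear();
    double R = 0.0;
    for (size_t i = 0; i < mots.size(); ++i) {
      const Motor& m = mots[i];
      const SpeciesPar& s = sp[m.species];
      if (!m.attached) {
        if (s.ka > 0.0) { evs.push_back({s.ka, (int)i, EV_ATTACH}); R += s.ka; }
        continue;
      }
      double F = hook_force(m.site * d - X, s.kappa, s.L);
      double k0 = (m.activity == ACT_INACTIVE) ? s.kdi : s.kd0;
      double kd = bell_rate(k0, std::fabs(F), s.Fd, literal);
      if (kd > 0.0) { evs.push_back({kd, (int)i, EV_DETACH}); R += kd; }
      if (m.activity == ACT_ACTIVE) {
        double Fres = (s.pol * F > 0.0) ? std::fabs(F) : 0.0;
        if (Fres > s.Fs) { // super-stall: slow constant back-stepping
          long tgt = m.site - s.pol;
          if (!site_occupied(mots, m.lane, tgt, (int)i) && s.vb > 0.0) {
            double r = s.vb / s.d;
            evs.push_back({r, (int)i, EV_BWD}); R += r;
          }
        } else {
          long tgt = m.site + s.pol;
          if (!site_occupied(mots, m.lane, tgt, (int)i)) {
            double r = schnitzer_rate(Fres, atp, m.vmax / s.d, s.sc, m.delta,
                                      kBT);
            if (r > 0.0) { evs.push_back({r, (int)i, EV_FWD}); R += r; }
          }
        }
      } else if (m.activity == ACT_DIFFUSIVE) {
        double dx = m.site * d - X;
        double Fabs = std::fabs(F);
        // +1 lattice direction rate / -1 direction rate
        double rp = s.s0, rm = s.s0;
        if (dx > s.L) {        // tensed forward: equilibrium lies at -1
          rm = s.s0 * std::exp(Fabs * d / (2.0 * kBT));
          rp = s.s0 * std::exp(-Fabs * d / (2.0 * kBT));
        } else if (dx < -s.L) {
          rp = s.s0 * std::exp(Fabs * d / (2.0 * kBT));
          rm = s.s0 * std::exp(-Fabs * d / (2.0 * kBT));
        }
        if (rp > 0.0 && !site_occupied(mots, m.lane, m.site + 1, (int)i)) {
          evs.push_back({rp, (int)i, EV_DIFF_P}); R += rp;
        }
        if (rm > 0.0 && !site_occupied(mots, m.lane, m.site - 1, (int)i)) {
          evs.push_back({rm, (int)i, EV_DIFF_M}); R += rm;
        }
      }
    }

    if (R <= 0.0) { flush_samples(std::min(t, max_time)); status = "no_events"; break; }

    double dt = exp_rand() / R;
    double t_new = t + dt;
    if (t_new >= max_time) { flush_samples(max_time); t = max_time; break; }
    flush_samples(t_new);
    t = t_new;

    // pick event
    double u = unif_rand() * R, acc = 0.0;
    int pick = (int)evs.size() - 1;
    for (size_t e = 0; e < evs.size(); ++e) {
      acc += evs[e].rate;
      if (u <= acc) { pick = (int)e; break; }
    }
    Motor& m = mots[evs[pick].motor];
    const SpeciesPar& s = sp[m.species];
    bool changed = false;

    switch (evs[pick].type) {
    case EV_ATTACH: {
      int lane = draw_lane(lane_cum);
      long site = (long)std::llround(X / d);
      if (!site_occupied(mots, lane, site, evs[pick].motor)) {
        m.attached = true;
        m.lane = lane;
        m.site = site;
        // fresh identity drawn from the reservoir on every attachment
        double ua = unif_rand();
        if (ua < s.fin) m.activity = ACT_INACTIVE;
        else if (ua < s.fin + s.fdiff) m.activity = ACT_DIFFUSIVE;
        else m.activity = ACT_ACTIVE;
        m.vmax = R_finite(s.vmax_fixed)
          ? s.vmax_fixed
          : std::exp(s.vmax_meanlog + s.vmax_sdlog * norm_rand());
        m.delta = 0.0;
        if (m.activity == ACT_ACTIVE) {
          double del = calibrate_delta_core(s.Fs, atp, m.vmax / s.d, s.sc,
                                            kBT, stall_target);
          m.delta = (del > 0.0) ? del : 0.0;
        }
        m.t_attach = t;
        m.site_attach = m.site;
        ever_attached = true;
        changed = true;
      }
      break;
    }
    case EV_DETACH:
      r_species.push_back(m.species);
      r_activity.push_back(m.activity);
      r_lane.push_back(m.lane);
      r_t0.push_back(m.t_attach);
      r_t1.push_back(t);
      r_x0.push_back(m.site_attach * d);
      r_x1.push_back(m.site * d);
      m.attached = false;
      changed = true;
      break;
    case EV_FWD:  m.site += s.pol; changed = true; break;
    case EV_BWD:  m.site -= s.pol; changed = true; break;
    case EV_DIFF_P: m.site += 1; changed = true; break;
    case EV_DIFF_M: m.site -= 1; changed = true; break;
    }

    if (validate) {
      for (size_t i = 0; i < mots.size(); ++i)
        for (size_t j = i + 1; j < mots.size(); ++j)
          if (mots[i].attached && mots[j].attached &&
              mots[i].lane == mots[j].lane && mots[i].site == mots[j].site)
            stop("exclusion violated: two motors share a lattice site");
    }

    if (changed) {
      xh.clear(); kap.clear(); Lr.clear();
      for (const Motor& mm : mots)
        if (mm.attached) {
          xh.push_back(mm.site * d);
          kap.push_back(sp[mm.species].kappa);
          Lr.push_back(sp[mm.species].L);
        }
      // cargo position is carried by record-keeping only when nothing holds it
      if (!xh.empty()) X = relax_position(X, xh, kap, Lr, kBT, met_n, met_step);
    }

    if (ever_attached && t >= relax_time && n_attached(-1) == 0) {
      status = "unbound";
      break;
    }
  }

  return List::create(
    _["t"] = NumericVector(s_t.begin(), s_t.end()),
    _["x"] = NumericVector(s_x.begin(), s_x.end()),
    _["n_att_ddb"] = IntegerVector(s_nd.begin(), s_nd.end()),
    _["n_att_kif"] = IntegerVector(s_nk.begin(), s_nk.end()),
    _["f_cargo"] = NumericVector(s_f.begin(), s_f.end()),
    _["runs"] = List::create(
      _["species"] = IntegerVector(r_species.begin(), r_species.end()),
      _["activity"] = IntegerVector(r_activity.begin(), r_activity.end()),
      _["lane"] = IntegerVector(r_lane.begin(), r_lane.end()),
      _["t_attach"] = NumericVector(r_t0.begin(), r_t0.end()),
      _["t_detach"] = NumericVector(r_t1.begin(), r_t1.end()),
      _["x_attach"] = NumericVector(r_x0.begin(), r_x0.end()),
      _["x_detach"] = NumericVector(r_x1.begin(), r_x1.end())),
    _["status"] = status);
}

// ---------------------------------------------------------------------------
// lone motor on the lattice (single-molecule assay, zero load)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_single_molecules(int n, double step_rate, double k_d0, double d,
                          int polarity, double dt, double max_time) {
  std::vector<double> run_len(n), run_dur(n);
  std::vector<double> frames;     // head positions at frame boundaries
  std::vector<int> frame_run;     // run id per frame (1-based)
  for (int r = 0; r < n; ++r) {
    double t = 0.0;
    long steps = 0;
    double next_frame = 0.0;
    double Rtot = step_rate + k_d0;
    while (true) {
      double dtv = exp_rand() / Rtot;
      double tn = t + dtv;
      while (next_frame <= tn + 1e-12 && next_frame <= max_time + 1e-12) {
        frames.push_back(polarity * steps * d);
        frame_run.push_back(r + 1);
        next_frame += dt;
      }
      if (tn >= max_time) { t = max_time; break; }
      t = tn;
      if (unif_rand() < step_rate / Rtot) ++steps; else break; // detach
    }
    run_len[r] = steps * d;
    run_dur[r] = t;
  }
  return List::create(
    _["run_length"] = NumericVector(run_len.begin(), run_len.end()),
    _["run_duration"] = NumericVector(run_dur.begin(), run_dur.end()),
    _["frame_x"] = NumericVector(frames.begin(), frames.end()),
    _["frame_run"] = IntegerVector(frame_run.begin(), frame_run.end()));
}

// ---------------------------------------------------------------------------
// lone diffusive motor in its spring potential (for detailed-balance checks)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_diffusive_chain(int n_events, double s0, double d, double kappa,
                         double L, double kBT, double x_cargo, int site0) {
  std::vector<int> sites(n_events);
  std::vector<double> dwell(n_events);
  long site = site0;
  for (int e = 0; e < n_events; ++e) {
    double dx = site * d - x_cargo;
    double Fabs = std::fabs(hook_force(dx, kappa, L));
    double rp = s0, rm = s0;
    if (dx > L) {
      rm = s0 * std::exp(Fabs * d / (2.0 * kBT));
      rp = s0 * std::exp(-Fabs * d / (2.0 * kBT));
    } else if (dx < -L) {
      rp = s0 * std::exp(Fabs * d / (2.0 * kBT));
      rm = s0 * std::exp(-Fabs * d / (2.0 * kBT));
    }
    double R = rp + rm;
    sites[e] = (int)site;
    dwell[e] = exp_rand() / R;
    site += (unif_rand() < rp / R) ? 1 : -1;
  }
  return List::create(_["site"] = IntegerVector(sites.begin(), sites.end()),
                      _["dwell"] = NumericVector(dwell.begin(), dwell.end()));
}

// ---------------------------------------------------------------------------
// simulated-annealing change-point segmentation
// ---------------------------------------------------------------------------

struct AnnealState {
  const std::vector<double>& t;
  const std::vector<double>& x;
  std::vector<double> cpt, cpx; // including pinned endpoints

  AnnealState(const std::vector<double>& t_, const std::vector<double>& x_)
    : t(t_), x(x_) {}

  // sum of squared residuals for data points with t in [tL, tR]
  double err_window(double tL, double tR) const {
    size_t iL = std::lower_bound(t.begin(), t.end(), tL - 1e-12) - t.begin();
    double E = 0.0;
    size_t k = 0;
    for (size_t i = iL; i < t.size() && t[i] <= tR + 1e-12; ++i) {
      while (k + 2 < cpt.size() && cpt[k + 1] <= t[i]) ++k;
      while (k > 0 && cpt[k] > t[i]) --k;
      double f = cpx[k] + (cpx[k + 1] - cpx[k]) / (cpt[k + 1] - cpt[k]) *
        (t[i] - cpt[k]);
      double r = x[i] - f;
      E += r * r;
    }
    return E;
  }
};

// [[Rcpp::export]]
List cpp_anneal(NumericVector t_, NumericVector x_, double mu, double eps_x,
                double eps_t, int n_cp_init, double p_shift, double p_add,
                double p_remove, int equil_updates, int cooling_updates,
                double beta_init, double beta_final, int check_every) {
  std::vector<double> t(t_.begin(), t_.end());
  std::vector<double> x(x_.begin(), x_.end());
  const size_t N = t.size();
  if (N < 2) stop("track needs at least 2 samples");

  AnnealState st(t, x);
  // pinned endpoints, interior cps equally spaced in time on the track
  st.cpt.push_back(t.front()); st.cpx.push_back(x.front());
  double DT = t.back() - t.front();
  for (int k = 1; k <= n_cp_init; ++k) {
    double tc = t.front() + DT * k / (n_cp_init + 1.0);
    // place on the track: interpolate the data at tc
    size_t j = std::lower_bound(t.begin(), t.end(), tc) - t.begin();
    double xc;
    if (j == 0) xc = x.front();
    else if (j >= N) xc = x.back();
    else xc = x[j - 1] + (x[j] - x[j - 1]) * (tc - t[j - 1]) / (t[j] - t[j - 1]);
    st.cpt.push_back(tc); st.cpx.push_back(xc);
  }
  st.cpt.push_back(t.back()); st.cpx.push_back(x.back());

  double E = st.err_window(t.front(), t.back());
  double max_rel = 0.0;
  long n_acc = 0, n_upd = 0;

  auto ncp = [&]() { return (int)st.cpt.size() - 2; };

  auto do_updates = [&](double beta, int n_updates) {
    for (int u = 0; u < n_updates; ++u) {
      ++n_upd;
      double um = unif_rand();
      if (um < p_shift) {
        int nc = ncp();
        if (nc == 0) { /* counted no-op */ }
        else {
          int k = 1 + (int)std::floor(unif_rand() * nc);
          if (k > nc) k = nc;
          double tn = st.cpt[k] + eps_t * (unif_rand() - 0.5);
          double xn = st.cpx[k] + eps_x * (unif_rand() - 0.5);
          double a = st.cpt[k - 1], b = st.cpt[k + 1];
          if (tn <= a + 1e-12 || tn >= b - 1e-12) continue; // rejected outright
          double e_old = st.err_window(a, b);
          double to = st.cpt[k], xo = st.cpx[k];
          st.cpt[k] = tn; st.cpx[k] = xn;
          double dH = st.err_window(a, b) - e_old;
          if (dH <= 0.0 || unif_rand() < std::exp(-beta * dH)) {
            E += dH; ++n_acc;
          } else { st.cpt[k] = to; st.cpx[k] = xo; }
        }
      } else if (um < p_shift + p_add) {
        size_t j = (size_t)std::floor(unif_rand() * N);
        if (j >= N) j = N - 1;
        double tn = t[j], xn = x[j];
        size_t pos = std::lower_bound(st.cpt.begin(), st.cpt.end(), tn) -
          st.cpt.begin();
        if (pos == 0 || pos >= st.cpt.size()) continue;
        if (std::fabs(st.cpt[pos] - tn) < 1e-12 ||
            std::fabs(st.cpt[pos - 1] - tn) < 1e-12) continue;
        double a = st.cpt[pos - 1], b = st.cpt[pos];
        double e_old = st.err_window(a, b);
        st.cpt.insert(st.cpt.begin() + pos, tn);
        st.cpx.insert(st.cpx.begin() + pos, xn);
        double dH = st.err_window(a, b) - e_old + mu;
        if (dH <= 0.0 || unif_rand() < std::exp(-beta * dH)) {
          E += dH - mu; ++n_acc;
        } else {
          st.cpt.erase(st.cpt.begin() + pos);
          st.cpx.erase(st.cpx.begin() + pos);
        }
      } else {
        int nc = ncp();
        if (nc == 0) continue; // counted no-op
        int k = 1 + (int)std::floor(unif_rand() * nc);
        if (k > nc) k = nc;
        double a = st.cpt[k - 1], b = st.cpt[k + 1];
        double e_old = st.err_window(a, b);
        double to = st.cpt[k], xo = st.cpx[k];
        st.cpt.erase(st.cpt.begin() + k);
        st.cpx.erase(st.cpx.begin() + k);
        double dH = st.err_window(a, b) - e_old - mu;
        if (dH <= 0.0 || unif_rand() < std::exp(-beta * dH)) {
          E += dH + mu; ++n_acc;
        } else {
          st.cpt.insert(st.cpt.begin() + k, to);
          st.cpx.insert(st.cpx.begin() + k, xo);
        }
      }
      if (check_every > 0 && n_upd % check_every == 0) {
        double Ef = st.err_window(t.front(), t.back());
        double rel = std::fabs(E - Ef) / std::max(1.0, Ef);
        max_rel = std::max(max_rel, rel);
        E = Ef;
      }
    }
  };

  do_updates(beta_init, equil_updates);
  double beta = beta_init;
  while (beta < beta_final * 0.999999) {
    beta = std::min(beta * 10.0, beta_final);
    do_updates(beta, cooling_updates);
  }

  double Ef = st.err_window(t.front(), t.back());
  return List::create(
    _["cp_t"] = NumericVector(st.cpt.begin(), st.cpt.end()),
    _["cp_x"] = NumericVector(st.cpx.begin(), st.cpx.end()),
    _["E_err"] = Ef,
    _["H"] = Ef + mu * ncp(),
    _["max_incremental_rel_err"] = max_rel,
    _["acceptance_rate"] = (double)n_acc / std::max(1L, n_upd));
}
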