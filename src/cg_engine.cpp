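// Coarse-grained gas-phase engine: Go-like one-bead-per-residue model with
// harmonic Zn-S cross-links, BAOAB Langevin dynamics, moving-restraint
// steering and well-tempered metadynamics on a tabulated CV bias.
//
// Units: length A, time ps, energy kcal/mol, mass amu, temperature K.
// ACC converts (kcal/mol/A)/amu to A/ps^2.

#include <Rcpp.h>
#include <random>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

static const double ACC = 418.4;
static const double KB = 0.0019872041;   // kcal/mol/K
static const double KCOUL = 332.0636;    // kcal A / mol / e^2
static const double RMIN = 0.1;          // distance floor, keeps energies finite

struct Topology {
  int n;
  std::vector<double> mass, charge, sigma;
  std::vector<int> is_protein;
  NumericMatrix bonds, angles, contacts, znlinks;
  std::vector<char> excl;  // n*n pair-exclusion matrix
  double wca_eps, dielectric;
  // optional analytic double-well on the CV: V = h * ((s-c)^2 - w^2)^2 / w^4
  bool cv_pot;
  double cvp_h, cvp_c, cvp_w;
  int cv_kind;           // 0 none, 1 Rg (protein beads), 2 end-to-end
  int e2e_a, e2e_b;      // 0-based bead indices for end-to-end
};

static long long pkey(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * n + j;
}

static Topology parse_topology(const List &top) {
  Topology T;
  T.mass = as<std::vector<double>>(top["mass"]);
  T.n = T.mass.size();
  T.charge = as<std::vector<double>>(top["charge"]);
  T.sigma = as<std::vector<double>>(top["sigma"]);
  T.is_protein = as<std::vector<int>>(top["is_protein"]);
  T.bonds = as<NumericMatrix>(top["bonds"]);
  T.angles = as<NumericMatrix>(top["angles"]);
  T.contacts = as<NumericMatrix>(top["contacts"]);
  T.znlinks = as<NumericMatrix>(top["znlinks"]);
  T.wca_eps = as<double>(top["wca_eps"]);
  T.dielectric = as<double>(top["dielectric"]);
  NumericMatrix ex = as<NumericMatrix>(top["exclusions"]);
  T.excl.assign((size_t)T.n * T.n, 0);
  for (int k = 0; k < ex.nrow(); ++k) {
    int i = (int)ex(k, 0) - 1, j = (int)ex(k, 1) - 1;
    T.excl[(size_t)i * T.n + j] = 1;
    T.excl[(size_t)j * T.n + i] = 1;
  }
  List cvp = as<List>(top["cv_potential"]);
  T.cv_pot = as<bool>(cvp["enabled"]);
  T.cvp_h = as<double>(cvp["height"]);
  T.cvp_c = as<double>(cvp["centre"]);
  T.cvp_w = as<double>(cvp["halfwidth"]);
  T.cv_kind = as<int>(top["cv_kind"]);
  IntegerVector e2e = as<IntegerVector>(top["e2e_index"]);
  T.e2e_a = e2e[0] - 1;
  T.e2e_b = e2e[1] - 1;
  return T;
}

// collective variable and its gradient
static double compute_cv(const Topology &T, const std::vector<double> &x,
                         std::vector<double> &grad, int kind) {
  std::fill(grad.begin(), grad.end(), 0.0);
  if (kind == 2) {
    double d2 = 0, dv[3];
    for (int c = 0; c < 3; ++c) {
      dv[c] = x[3 * T.e2e_b + c] - x[3 * T.e2e_a + c];
      d2 += dv[c] * dv[c];
    }
    double d = std::sqrt(std::max(d2, 1e-12));
    for (int c = 0; c < 3; ++c) {
      grad[3 * T.e2e_b + c] = dv[c] / d;
      grad[3 * T.e2e_a + c] = -dv[c] / d;
    }
    return d;
  }
  // mass-weighted Rg over protein beads
  double M = 0, com[3] = {0, 0, 0};
  for (int i = 0; i < T.n; ++i) {
    if (!T.is_protein[i]) continue;
    M += T.mass[i];
    for (int c = 0; c < 3; ++c) com[c] += T.mass[i] * x[3 * i + c];
  }
  for (int c = 0; c < 3; ++c) com[c] /= M;
  double s2 = 0;
  for (int i = 0; i < T.n; ++i) {
    if (!T.is_protein[i]) continue;
    for (int c = 0; c < 3; ++c) {
      double d = x[3 * i + c] - com[c];
      s2 += T.mass[i] * d * d;
    }
  }
  double rg = std::sqrt(std::max(s2 / M, 1e-12));
  for (int i = 0; i < T.n; ++i) {
    if (!T.is_protein[i]) continue;
    for (int c = 0; c < 3; ++c)
      grad[3 * i + c] = T.mass[i] * (x[3 * i + c] - com[c]) / (M * rg);
  }
  return rg;
}

struct EnergyTerms {
  double bond = 0, angle = 0, contact = 0, wca = 0, coulomb = 0,
         znlink = 0, cvpot = 0;
  double total() const {
    return bond + angle + contact + wca + coulomb + znlink + cvpot;
  }
};

static void harmonic_pairs(const NumericMatrix &prs,
                           const std::vector<double> &x,
                           std::vector<double> &f, double &e) {
  for (int k = 0; k < prs.nrow(); ++k) {
    int i = (int)prs(k, 0) - 1, j = (int)prs(k, 1) - 1;
    double r0 = prs(k, 2), kk = prs(k, 3);
    double dv[3], r2 = 0;
    for (int c = 0; c < 3; ++c) {
      dv[c] = x[3 * j + c] - x[3 * i + c];
      r2 += dv[c] * dv[c];
    }
    double r = std::max(std::sqrt(r2), RMIN);
    double dr = r - r0;
    e += 0.5 * kk * dr * dr;       // V = k/2 (r - r0)^2
    double fr = -kk * dr / r;
    for (int c = 0; c < 3; ++c) {
      f[3 * j + c] += fr * dv[c];
      f[3 * i + c] -= fr * dv[c];
    }
  }
}

static EnergyTerms forces(const Topology &T, const std::vector<double> &x,
                          std::vector<double> &f,
                          std::vector<double> &cvgrad) {
  EnergyTerms E;
  std::fill(f.begin(), f.end(), 0.0);
  harmonic_pairs(T.bonds, x, f, E.bond);
  harmonic_pairs(T.znlinks, x, f, E.znlink);

  // harmonic angles
  for (int k = 0; k < T.angles.nrow(); ++k) {
    int i = (int)T.angles(k, 0) - 1, j = (int)T.angles(k, 1) - 1,
        l = (int)T.angles(k, 2) - 1;
    double th0 = T.angles(k, 3), kk = T.angles(k, 4);
    double a[3], b[3], la = 0, lb = 0, dot = 0;
    for (int c = 0; c < 3; ++c) {
      a[c] = x[3 * i + c] - x[3 * j + c];
      b[c] = x[3 * l + c] - x[3 * j + c];
      la += a[c] * a[c];
      lb += b[c] * b[c];
      dot += a[c] * b[c];
    }
    la = std::sqrt(la); lb = std::sqrt(lb);
    double ct = dot / std::max(la * lb, 1e-12);
    ct = std::min(1.0 - 1e-10, std::max(-1.0 + 1e-10, ct));
    double th = std::acos(ct), dth = th - th0;
    E.angle += 0.5 * kk * dth * dth;
    double st = std::sqrt(1.0 - ct * ct);
    double pref = kk * dth / st;
    for (int c = 0; c < 3; ++c) {
      double da = (b[c] / (la * lb) - ct * a[c] / (la * la));
      double db = (a[c] / (la * lb) - ct * b[c] / (lb * lb));
      f[3 * i + c] += pref * da;
      f[3 * l + c] += pref * db;
      f[3 * j + c] -= pref * (da + db);
    }
  }

  // native contacts: 12-10 Go potential, minimum -eps at r0
  for (int k = 0; k < T.contacts.nrow(); ++k) {
    int i = (int)T.contacts(k, 0) - 1, j = (int)T.contacts(k, 1) - 1;
    double r0 = T.contacts(k, 2), eps = T.contacts(k, 3);
    double dv[3], r2 = 0;
    for (int c = 0; c < 3; ++c) {
      dv[c] = x[3 * j + c] - x[3 * i + c];
      r2 += dv[c] * dv[c];
    }
    double r = std::max(std::sqrt(r2), RMIN);
    double q = r0 / r, q2 = q * q, q10 = q2 * q2 * q2 * q2 * q2,
           q12 = q10 * q2;
    E.contact += eps * (5.0 * q12 - 6.0 * q10);
    double fr = eps * 60.0 * (q12 - q10) / (r * r);  // -dV/dr / r
    for (int c = 0; c < 3; ++c) {
      f[3 * j + c] += fr * dv[c];
      f[3 * i + c] -= fr * dv[c];
    }
  }

  // WCA excluded volume + vacuum Coulomb over non-excluded pairs
  for (int i = 0; i < T.n; ++i) {
    for (int j = i + 1; j < T.n; ++j) {
      if (T.excl[(size_t)i * T.n + j]) continue;
      double dv[3], r2 = 0;
      for (int c = 0; c < 3; ++c) {
        dv[c] = x[3 * j + c] - x[3 * i + c];
        r2 += dv[c] * dv[c];
      }
      double r = std::max(std::sqrt(r2), RMIN);
      double sig = 0.5 * (T.sigma[i] + T.sigma[j]);
      double rc = sig * 1.122462048309373;
      if (r < rc && T.wca_eps > 0) {
        double q = sig / r, q2 = q * q, q6 = q2 * q2 * q2, q12 = q6 * q6;
        E.wca += 4.0 * T.wca_eps * (q12 - q6) + T.wca_eps;
        double fr = 24.0 * T.wca_eps * (2.0 * q12 - q6) / (r * r);
        for (int c = 0; c < 3; ++c) {
          f[3 * j + c] += fr * dv[c];
          f[3 * i + c] -= fr * dv[c];
        }
      }
      double qq = T.charge[i] * T.charge[j];
      if (qq != 0.0) {
        double e = KCOUL * qq / (T.dielectric * r);
        E.coulomb += e;
        double fr = e / (r * r);  // -d/dr (1/r) = 1/r^2, radial out
        for (int c = 0; c < 3; ++c) {
          f[3 * j + c] += fr * dv[c];
          f[3 * i + c] -= fr * dv[c];
        }
      }
    }
  }

  // analytic double-well acting on the CV (toy free-energy landscapes)
  if (T.cv_pot) {
    double s = compute_cv(T, x, cvgrad, T.cv_kind);
    double u = (s - T.cvp_c), w2 = T.cvp_w * T.cvp_w;
    double g = (u * u - w2);
    E.cvpot += T.cvp_h * g * g / (w2 * w2);
    double dVds = T.cvp_h * 4.0 * g * u / (w2 * w2);
    for (int i = 0; i < 3 * T.n; ++i) f[i] -= dVds * cvgrad[i];
  }
  return E;
}

// [[Rcpp::export]]
List cg_energy_cpp(NumericMatrix coords, List top) {
  Topology T = parse_topology(top);
  std::vector<double> x(3 * T.n), f(3 * T.n), cvg(3 * T.n);
  for (int i = 0; i < T.n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = coords(i, c);
  EnergyTerms E = forces(T, x, f, cvg);
  NumericMatrix fm(T.n, 3);
  for (int i = 0; i < T.n; ++i)
    for (int c = 0; c < 3; ++c) fm(i, c) = f[3 * i + c];
  return List::create(
      _["bond"] = E.bond, _["angle"] = E.angle, _["contact"] = E.contact,
      _["wca"] = E.wca, _["coulomb"] = E.coulomb, _["znlink"] = E.znlink,
      _["cv_potential"] = E.cvpot, _["total"] = E.total(),
      _["forces"] = fm);
}

// [[Rcpp::export]]
NumericMatrix cg_minimize_cpp(NumericMatrix coords, List top, int n_steps,
                              double max_step) {
  Topology T = parse_topology(top);
  std::vector<double> x(3 * T.n), f(3 * T.n), cvg(3 * T.n);
  for (int i = 0; i < T.n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = coords(i, c);
  for (int s = 0; s < n_steps; ++s) {
    forces(T, x, f, cvg);
    double fmax = 1e-12;
    for (int i = 0; i < 3 * T.n; ++i) fmax = std::max(fmax, std::fabs(f[i]));
    double sc = std::min(max_step / fmax, 0.02);
    for (int i = 0; i < 3 * T.n; ++i) x[i] += sc * f[i];
  }
  NumericMatrix out(T.n, 3);
  for (int i = 0; i < T.n; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = x[3 * i + c];
  return out;
}

// [[Rcpp::export]]
List cg_run_cpp(NumericMatrix coords, List top, List sched, List bias,
                int seed) {
  Topology T = parse_topology(top);
  double dt = as<double>(sched["dt_ps"]);
  double gamma = as<double>(sched["gamma_ps"]);
  IntegerVector seg_steps = as<IntegerVector>(sched["seg_steps"]);
  NumericVector seg_temp = as<NumericVector>(sched["seg_temp"]);
  int stride = as<int>(sched["store_stride"]);
  long total = 0;
  for (int s = 0; s < seg_steps.size(); ++s) total += seg_steps[s];

  int mode = as<int>(bias["mode"]);          // 0 none, 1 smd, 2 metad
  int cv_kind = as<int>(bias["cv_kind"]);    // 1 rg, 2 e2e
  double k_cv = as<double>(bias["k_cv"]);
  double tgt0 = as<double>(bias["target_start"]);
  double tgt1 = as<double>(bias["target_end"]);
  double h0 = as<double>(bias["hill_height"]);
  double hsig = as<double>(bias["hill_width"]);
  int hill_stride = as<int>(bias["hill_stride"]);
  double gb = as<double>(bias["bias_factor"]);
  double gmin = as<double>(bias["grid_min"]);
  double gmax = as<double>(bias["grid_max"]);
  int gn = as<int>(bias["grid_n"]);
  std::vector<double> vb(gn, 0.0), dvb(gn, 0.0);
  double gstep = (gmax - gmin) / (gn - 1);
  std::vector<double> hill_s, hill_h;

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<double> x(3 * T.n), v(3 * T.n), f(3 * T.n), cvg(3 * T.n);
  for (int i = 0; i < T.n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = coords(i, c);
  // Maxwell-Boltzmann start at the first segment temperature
  double T0 = seg_temp[0];
  for (int i = 0; i < T.n; ++i) {
    double vt = std::sqrt(KB * T0 * ACC / T.mass[i]);
    for (int c = 0; c < 3; ++c) v[3 * i + c] = vt * gauss(rng);
  }

  int nstore = (int)(total / stride);
  NumericVector frames(Dimension(T.n, 3, std::max(nstore, 1)));
  std::vector<double> st_time, st_temp, st_cv, st_ke, st_pe, st_bias_force,
      st_target, st_bond, st_contact, st_wca, st_coulomb, st_znlink,
      st_cvpot, st_angle;

  EnergyTerms E = forces(T, x, f, cvg);
  bool diverged = false;
  long step = 0;
  double c1 = std::exp(-gamma * dt), c2 = std::sqrt(1.0 - c1 * c1);
  int istore = 0;
  double cv = 0, bias_force = 0, target = 0;

  // add the bias contribution for the current positions to f; deposits a
  // well-tempered hill when the step index hits the deposition stride
  auto apply_bias = [&](long s, double temp) {
    if (mode == 0) return;
    cv = compute_cv(T, x, cvg, cv_kind);
    if (mode == 1) {
      double frac = total > 1 ? (double)s / (double)(total - 1) : 0.0;
      target = tgt0 + (tgt1 - tgt0) * frac;
      bias_force = -k_cv * (cv - target);
      for (int i = 0; i < 3 * T.n; ++i) f[i] += bias_force * cvg[i];
    } else {
      // no deposition while the CV is off-grid: clamping would pile
      // spurious hills onto the boundary bins
      if (s % hill_stride == 0 && cv >= gmin && cv <= gmax) {
        double s0 = cv;
        int gi = (int)((s0 - gmin) / gstep);
        double vs = vb[std::min(std::max(gi, 0), gn - 1)];
        double h = h0 * std::exp(-vs / ((gb - 1.0) * KB * temp));
        hill_s.push_back(s0);
        hill_h.push_back(h);
        for (int g = 0; g < gn; ++g) {
          double sg = gmin + g * gstep;
          double arg = (sg - s0) / hsig;
          double e = h * std::exp(-0.5 * arg * arg);
          vb[g] += e;
          dvb[g] += -e * (sg - s0) / (hsig * hsig);
        }
      }
      double sc = std::min(std::max(cv, gmin), gmax);
      double gi = (sc - gmin) / gstep;
      int g0 = std::min(std::max((int)gi, 0), gn - 2);
      double wfrac = gi - g0;
      double dV = dvb[g0] * (1 - wfrac) + dvb[g0 + 1] * wfrac;
      bias_force = -dV;
      for (int i = 0; i < 3 * T.n; ++i) f[i] += bias_force * cvg[i];
    }
  };

  apply_bias(0, seg_temp[0]);

  for (int seg = 0; seg < seg_steps.size() && !diverged; ++seg) {
    double temp = seg_temp[seg];
    for (int ss = 0; ss < seg_steps[seg] && !diverged; ++ss, ++step) {
      // BAOAB: B A O A (forces+bias) B
      for (int i = 0; i < T.n; ++i) {
        double a = ACC * dt * 0.5 / T.mass[i];
        for (int c = 0; c < 3; ++c) v[3 * i + c] += a * f[3 * i + c];
      }
      for (int i = 0; i < 3 * T.n; ++i) x[i] += 0.5 * dt * v[i];
      if (gamma > 0) {
        for (int i = 0; i < T.n; ++i) {
          double vt = std::sqrt(KB * temp * ACC / T.mass[i]);
          for (int c = 0; c < 3; ++c)
            v[3 * i + c] = c1 * v[3 * i + c] + c2 * vt * gauss(rng);
        }
      }
      for (int i = 0; i < 3 * T.n; ++i) x[i] += 0.5 * dt * v[i];
      E = forces(T, x, f, cvg);
      apply_bias(step + 1, temp);
      for (int i = 0; i < T.n; ++i) {
        double a = ACC * dt * 0.5 / T.mass[i];
        for (int c = 0; c < 3; ++c) v[3 * i + c] += a * f[3 * i + c];
      }

      if (!std::isfinite(E.total()) || std::fabs(E.total()) > 1e10) {
        diverged = true;
      }

      if ((step + 1) % stride == 0 && istore < nstore) {
        double ke = 0;
        for (int i = 0; i < T.n; ++i)
          for (int c = 0; c < 3; ++c)
            ke += 0.5 * T.mass[i] * v[3 * i + c] * v[3 * i + c] / ACC;
        if (mode == 0) cv = compute_cv(T, x, cvg, T.cv_kind ? T.cv_kind : 1);
        for (int i = 0; i < T.n; ++i)
          for (int c = 0; c < 3; ++c)
            frames[i + T.n * c + (long)T.n * 3 * istore] = x[3 * i + c];
        st_time.push_back((step + 1) * dt);
        st_temp.push_back(temp);
        st_cv.push_back(cv);
        st_ke.push_back(ke);
        st_pe.push_back(E.total());
        st_bond.push_back(E.bond);
        st_angle.push_back(E.angle);
        st_contact.push_back(E.contact);
        st_wca.push_back(E.wca);
        st_coulomb.push_back(E.coulomb);
        st_znlink.push_back(E.znlink);
        st_cvpot.push_back(E.cvpot);
        st_bias_force.push_back(bias_force);
        st_target.push_back(target);
        ++istore;
      }
    }
  }

  NumericMatrix final_coords(T.n, 3);
  for (int i = 0; i < T.n; ++i)
    for (int c = 0; c < 3; ++c) final_coords(i, c) = x[3 * i + c];

  return List::create(
      _["frames"] = frames, _["time_ps"] = st_time,
      _["temperature"] = st_temp, _["cv"] = st_cv, _["ke"] = st_ke,
      _["pe"] = st_pe, _["bond"] = st_bond, _["angle"] = st_angle,
      _["contact"] = st_contact, _["wca"] = st_wca,
      _["coulomb"] = st_coulomb, _["znlink"] = st_znlink,
      _["cv_potential"] = st_cvpot, _["bias_force"] = st_bias_force,
      _["target"] = st_target, _["hill_s"] = hill_s, _["hill_h"] = hill_h,
      _["bias_grid"] = vb, _["grid_min"] = gmin, _["grid_step"] = gstep,
      _["final_coords"] = final_coords, _["diverged"] = diverged,
      _["n_stored"] = istore);
}
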