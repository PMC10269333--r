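// Metropolis / overdamped-Langevin sampler for the parametric toy systems.
// One probed coordinate x (the switchable molecule), optional ligand
// coordinate y. Per-state energies, the enveloping reference energy, the
// harmonic boost and the lambda-derivative of the total Hamiltonian are
// recorded every save interval. Uses R's RNG so that set.seed() governs
// reproducibility.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct ToyParams {
  int n_states;
  std::vector<double> k, x0, c0, c1, g0, g1; // per state
  double w;                                   // well width
  bool has_restraint; double K0, K1;          // restraint on x
  bool has_ligand; double kL, dL, dEL;        // ligand coordinate y
  std::vector<double> S, b;                   // offset schedules
  bool boost; double e_min, e_max;            // acceleration
  double RT;
};

struct Eval {
  std::vector<double> H, dHdl_i, w;
  double e_r, e_r_star, slope, v_restraint, h_s;
  double dHs_dl, dVr_dl, dhdl_total, u_total;
  double grad_x, grad_y; // of the total boosted Hamiltonian
};

void evaluate(const ToyParams& p, double x, double y, double lambda,
              Eval& ev, bool need_grad) {
  const int n = p.n_states;
  ev.H.resize(n); ev.dHdl_i.resize(n); ev.w.resize(n);
  const double phi = std::exp(-x * x / (2.0 * p.w * p.w));
  std::vector<double> gstate(need_grad ? n : 0);
  for (int i = 0; i < n; ++i) {
    const double g = (1.0 - lambda) * p.g0[i] + lambda * p.g1[i];
    const double c = (1.0 - lambda) * p.c0[i] + lambda * p.c1[i];
    ev.H[i] = 0.5 * p.k[i] * (x - p.x0[i]) * (x - p.x0[i]) + c - g * phi;
    ev.dHdl_i[i] = (p.c1[i] - p.c0[i]) - (p.g1[i] - p.g0[i]) * phi;
    if (need_grad)
      gstate[i] = p.k[i] * (x - p.x0[i]) + g * x / (p.w * p.w) * phi;
  }
  // reference energy: overflow-safe log-sum-exp over -(H_i - dF_i)/RT
  double m = -1e300;
  std::vector<double> z(n);
  for (int i = 0; i < n; ++i) {
    const double dfi = p.S[i] * lambda + p.b[i];
    z[i] = -(ev.H[i] - dfi) / p.RT;
    if (z[i] > m) m = z[i];
  }
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(z[i] - m);
  ev.e_r = -p.RT * (m + std::log(s));
  for (int i = 0; i < n; ++i) ev.w[i] = std::exp(z[i] - m) / s;
  // harmonic boost
  if (p.boost && p.e_max > p.e_min) {
    const double span = p.e_max - p.e_min;
    if (ev.e_r <= p.e_min) { ev.e_r_star = ev.e_r; ev.slope = 1.0; }
    else if (ev.e_r >= p.e_max) {
      ev.e_r_star = 0.5 * (p.e_min + p.e_max); ev.slope = 0.0;
    } else {
      ev.e_r_star = ev.e_r - (ev.e_r - p.e_min) * (ev.e_r - p.e_min) / (2.0 * span);
      ev.slope = 1.0 - (ev.e_r - p.e_min) / span;
    }
  } else { ev.e_r_star = ev.e_r; ev.slope = 1.0; }
  // restraint and ligand (system) terms
  if (p.has_restraint) {
    const double K = (1.0 - lambda) * p.K0 + lambda * p.K1;
    ev.v_restraint = 0.5 * K * x * x;
    ev.dVr_dl = 0.5 * (p.K1 - p.K0) * x * x;
  } else { ev.v_restraint = 0.0; ev.dVr_dl = 0.0; }
  if (p.has_ligand) {
    const double dy = y - lambda * p.dL;
    ev.h_s = 0.5 * p.kL * dy * dy + lambda * p.dEL;
    ev.dHs_dl = -p.kL * p.dL * dy + p.dEL;
  } else { ev.h_s = 0.0; ev.dHs_dl = 0.0; }
  // dH/dlambda of the total Hamiltonian (system + restraint + boosted
  // reference with lambda-interpolated offsets)
  double dref = 0.0;
  for (int i = 0; i < n; ++i) dref += ev.w[i] * (ev.dHdl_i[i] - p.S[i]);
  ev.dhdl_total = ev.dHs_dl + ev.dVr_dl + ev.slope * dref;
  ev.u_total = ev.h_s + ev.v_restraint + ev.e_r_star;
  if (need_grad) {
    double gx = 0.0;
    for (int i = 0; i < n; ++i) gx += ev.w[i] * gstate[i];
    gx *= ev.slope;
    if (p.has_restraint)
      gx += ((1.0 - lambda) * p.K0 + lambda * p.K1) * x;
    ev.grad_x = gx;
    ev.grad_y = p.has_ligand ? p.kL * (y - lambda * p.dL) : 0.0;
  }
}

ToyParams unpack(const List& spec) {
  ToyParams p;
  NumericMatrix sp = spec["state_params"]; // n x 6: k,x0,c0,c1,g0,g1
  p.n_states = sp.nrow();
  for (int i = 0; i < p.n_states; ++i) {
    p.k.push_back(sp(i, 0)); p.x0.push_back(sp(i, 1));
    p.c0.push_back(sp(i, 2)); p.c1.push_back(sp(i, 3));
    p.g0.push_back(sp(i, 4)); p.g1.push_back(sp(i, 5));
  }
  p.w = as<double>(spec["well_width"]);
  NumericVector rs = spec["restraint"];
  p.has_restraint = rs.size() == 2;
  if (p.has_restraint) { p.K0 = rs[0]; p.K1 = rs[1]; }
  NumericVector lg = spec["ligand"];
  p.has_ligand = lg.size() == 3;
  if (p.has_ligand) { p.kL = lg[0]; p.dL = lg[1]; p.dEL = lg[2]; }
  NumericMatrix off = spec["offsets"]; // n x 2: S, b
  for (int i = 0; i < p.n_states; ++i) {
    p.S.push_back(off(i, 0)); p.b.push_back(off(i, 1));
  }
  NumericVector ac = spec["accel"]; // e_min, e_max, enabled
  p.boost = ac.size() == 3 && ac[2] > 0.5;
  if (p.boost) { p.e_min = ac[0]; p.e_max = ac[1]; }
  p.RT = as<double>(spec["RT"]);
  return p;
}

} // namespace

// [[Rcpp::export]]
List cpp_run_sampler(List spec, double lambda, int n_steps, int save_every,
                     int burn_in, double sigma, bool tune_sigma,
                     std::string mode, double dt, double gamma,
                     NumericVector init, double time_per_step) {
  ToyParams p = unpack(spec);
  double x = init[0];
  double y = init.size() > 1 ? init[1] : 0.0;
  const bool langevin = (mode == "langevin");
  Eval ev, evp;
  evaluate(p, x, y, lambda, ev, langevin);
  if (!std::isfinite(ev.u_total))
    stop("Non-finite energy at the initial configuration.");

  const int n_rec = n_steps / std::max(save_every, 1);
  const int ncol = 2 * p.n_states + 9; // see colnames in the R wrapper
  NumericMatrix frames(n_rec, ncol);
  int rec = 0;
  long accept = 0, tried = 0;
  int tune_acc = 0, tune_try = 0;

  // burn-in (discarded); optional proposal-width auto-tuning to 30-50%
  for (int step = 0; step < burn_in; ++step) {
    if (langevin) {
      const double pref = dt / gamma, noise = std::sqrt(2.0 * p.RT * dt / gamma);
      x += -pref * ev.grad_x + noise * norm_rand();
      if (p.has_ligand) y += -pref * ev.grad_y + noise * norm_rand();
      evaluate(p, x, y, lambda, ev, true);
    } else {
      const double xp = x + sigma * norm_rand();
      const double yp = p.has_ligand ? y + sigma * norm_rand() : y;
      evaluate(p, xp, yp, lambda, evp, false);
      ++tune_try;
      if (std::isfinite(evp.u_total) &&
          unif_rand() < std::exp(-(evp.u_total - ev.u_total) / p.RT)) {
        x = xp; y = yp; ev = evp; ++tune_acc;
      }
      if (tune_sigma && tune_try == 100) {
        const double r = tune_acc / 100.0;
        if (r > 0.50) sigma *= 1.15;
        else if (r < 0.30) sigma /= 1.15;
        tune_acc = 0; tune_try = 0;
      }
    }
  }
  evaluate(p, x, y, lambda, ev, langevin);

  for (int step = 1; step <= n_steps; ++step) {
    if (langevin) {
      const double pref = dt / gamma, noise = std::sqrt(2.0 * p.RT * dt / gamma);
      x += -pref * ev.grad_x + noise * norm_rand();
      if (p.has_ligand) y += -pref * ev.grad_y + noise * norm_rand();
      evaluate(p, x, y, lambda, ev, true);
      if (!std::isfinite(ev.u_total))
        stop("Non-finite energy at step %d.", step);
    } else {
      const double xp = x + sigma * norm_rand();
      const double yp = p.has_ligand ? y + sigma * norm_rand() : y;
      evaluate(p, xp, yp, lambda, evp, false);
      ++tried;
      if (std::isfinite(evp.u_total) &&
          unif_rand() < std::exp(-(evp.u_total - ev.u_total) / p.RT)) {
        x = xp; y = yp; ev = evp; ++accept;
      }
    }
    if (save_every > 0 && step % save_every == 0 && rec < n_rec) {
      int c = 0;
      frames(rec, c++) = step * time_per_step;
      frames(rec, c++) = lambda;
      for (int i = 0; i < p.n_states; ++i) frames(rec, c++) = ev.H[i];
      frames(rec, c++) = ev.e_r;
      frames(rec, c++) = ev.e_r_star;
      frames(rec, c++) = ev.v_restraint;
      frames(rec, c++) = ev.dHs_dl + ev.dVr_dl;
      for (int i = 0; i < p.n_states; ++i) frames(rec, c++) = ev.dHdl_i[i];
      frames(rec, c++) = ev.dhdl_total;
      frames(rec, c++) = x;
      frames(rec, c++) = y;
      ++rec;
    }
  }

  return List::create(
    _["frames"] = frames, _["x"] = x, _["y"] = y, _["sigma"] = sigma,
    _["accept_rate"] = tried > 0 ? double(accept) / double(tried) : NA_REAL);
}
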