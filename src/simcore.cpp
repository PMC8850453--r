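#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Compiled core of the self-propelled agent model. The force arithmetic
// mirrors the pure-R reference implementations in R/forces.R; the test
// suite asserts equality between the two paths.
//
// Wall contributions are accumulated as (E + W) + (N + S). Pairing the two
// x-facing and the two y-facing walls keeps the floating-point sum exactly
// equivariant under reflection about the x-axis (which swaps N and S), so
// mirrored runs are bitwise mirrors of the originals.

namespace {

struct Params {
  double mu, v_d, r0, A_p, B_p, eps, A_w1, A_w2, B_w, gamma, mass;
  double damping_range;
  bool tp_enabled;
  bool nearest_only;
};

Params unpack(const List& params) {
  Params p;
  p.mu = as<double>(params["mu"]);
  p.v_d = as<double>(params["v_d"]);
  p.r0 = as<double>(params["r0"]);
  p.A_p = as<double>(params["A_p"]);
  p.B_p = as<double>(params["B_p"]);
  p.eps = as<double>(params["eps"]);
  p.A_w1 = as<double>(params["A_w1"]);
  p.A_w2 = as<double>(params["A_w2"]);
  p.B_w = as<double>(params["B_w"]);
  p.gamma = as<double>(params["gamma"]);
  p.mass = as<double>(params["mass"]);
  p.damping_range = as<double>(params["damping_range"]);
  p.tp_enabled = as<bool>(params["tp_enabled"]);
  p.nearest_only = as<std::string>(params["wall_mode"]) == "nearest_only";
  return p;
}

// wall order E, N, W, S
const double NORMAL_X[4] = {-1.0, 0.0, 1.0, 0.0};
const double NORMAL_Y[4] = {0.0, -1.0, 0.0, 1.0};
// t_plus = inward normal rotated by -90 deg: (nx, ny) -> (ny, -nx)
const double TPLUS_X[4] = {0.0, -1.0, 0.0, 1.0};
const double TPLUS_Y[4] = {1.0, 0.0, -1.0, 0.0};

inline void wall_dists(double x, double y, double hw, double hh, double* d) {
  d[0] = hw - x;  // E
  d[1] = hh - y;  // N
  d[2] = x + hw;  // W
  d[3] = y + hh;  // S
}

// Repulsion + damping + turning from one wall.
inline void one_wall(int w, double riw, double vx, double vy,
                     double hx, double hy, int chir, const Params& p,
                     double* fx, double* fy) {
  const double nx = NORMAL_X[w], ny = NORMAL_Y[w];
  double fxa = 0.0, fya = 0.0;
  if (riw > p.r0) {
    double mag = p.A_w1 * std::exp(-(riw - p.r0) / p.B_w);
    if (riw - p.r0 <= p.damping_range) {
      double v_n = vx * nx + vy * ny;
      mag -= p.gamma * v_n;
    }
    fxa = mag * nx;
    fya = mag * ny;
  } else {
    double mag = p.eps * std::pow(1.0 - riw / p.r0, 1.5);
    fxa = mag * nx;
    fya = mag * ny;
  }
  if (p.tp_enabled && chir != 0) {
    // cos(alpha) against the approach direction toward the wall (-n_hat)
    double cos_a = -(hx * nx + hy * ny);
    if (cos_a > 0.0) {
      double tmag = p.A_w2 * std::exp(-(riw - p.r0) / p.B_w) * cos_a;
      double sgn = (chir > 0) ? 1.0 : -1.0;
      fxa += tmag * sgn * TPLUS_X[w];
      fya += tmag * sgn * TPLUS_Y[w];
    }
  }
  *fx = fxa;
  *fy = fya;
}

void compute_forces(int n, const double* px, const double* py,
                    const double* vx, const double* vy,
                    const double* hx, const double* hy,
                    const int* chir, const Params& p,
                    double hw, double hh,
                    double* fx, double* fy) {
  // propulsion
  for (int i = 0; i < n; ++i) {
    double sp = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i]);
    double mag = p.mu * (p.v_d - sp);
    fx[i] = mag * hx[i];
    fy[i] = mag * hy[i];
  }
  // pairwise repulsion (Newton's third law)
  const double two_r0 = 2.0 * p.r0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = px[i] - px[j];
      double dy = py[i] - py[j];
      double r = std::sqrt(dx * dx + dy * dy);
      if (r == 0.0) stop("coincident agent centres (agents %d and %d)", i + 1, j + 1);
      double mag;
      if (r > two_r0) {
        mag = p.A_p * std::exp(-(r - two_r0) / p.B_p);
      } else {
        mag = p.eps * std::pow(1.0 - r / two_r0, 1.5);
      }
      double gx = mag * dx / r;
      double gy = mag * dy / r;
      fx[i] += gx; fy[i] += gy;
      fx[j] -= gx; fy[j] -= gy;
    }
  }
  // walls
  double d[4], wfx[4], wfy[4];
  for (int i = 0; i < n; ++i) {
    wall_dists(px[i], py[i], hw, hh, d);
    int ci = chir ? chir[i] : 0;
    if (p.nearest_only) {
      int k = 0;
      for (int w = 1; w < 4; ++w) if (d[w] < d[k]) k = w;
      double gx, gy;
      one_wall(k, d[k], vx[i], vy[i], hx[i], hy[i], ci, p, &gx, &gy);
      fx[i] += gx; fy[i] += gy;
    } else {
      for (int w = 0; w < 4; ++w) {
        one_wall(w, d[w], vx[i], vy[i], hx[i], hy[i], ci, p, &wfx[w], &wfy[w]);
      }
      fx[i] += (wfx[0] + wfx[2]) + (wfx[1] + wfx[3]);
      fy[i] += (wfy[0] + wfy[2]) + (wfy[1] + wfy[3]);
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".forces_cpp")]]
NumericMatrix forces_cpp(NumericMatrix positions, NumericMatrix velocities,
                         NumericMatrix headings, IntegerVector chiralities,
                         List params, double width, double height) {
  const int n = positions.nrow();
  Params p = unpack(params);
  std::vector<double> fx(n), fy(n);
  const int* chir = (chiralities.size() == n) ? chiralities.begin() : nullptr;
  compute_forces(n, &positions(0, 0), &positions(0, 1),
                 &velocities(0, 0), &velocities(0, 1),
                 &headings(0, 0), &headings(0, 1),
                 chir, p, width / 2.0, height / 2.0, fx.data(), fy.data());
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = fx[i]; out(i, 1) = fy[i]; }
  return out;
}

// [[Rcpp::export(name = ".run_cpp")]]
List run_cpp(NumericMatrix positions, NumericMatrix velocities,
             NumericMatrix headings, IntegerVector chiralities,
             List params, double width, double height,
             double dt, int n_steps, int record_every,
             bool semi_implicit) {
  const int n = positions.nrow();
  const double hw = width / 2.0, hh = height / 2.0;
  const double speed_floor = 1e-6;
  Params p = unpack(params);

  std::vector<double> px(n), py(n), vx(n), vy(n), hx(n), hy(n);
  std::vector<int> chir(n, 0);
  bool has_chir = chiralities.size() == n;
  for (int i = 0; i < n; ++i) {
    px[i] = positions(i, 0); py[i] = positions(i, 1);
    vx[i] = velocities(i, 0); vy[i] = velocities(i, 1);
    hx[i] = headings(i, 0); hy[i] = headings(i, 1);
    if (has_chir) chir[i] = chiralities[i] == NA_INTEGER ? 0 : chiralities[i];
  }
  for (int i = 0; i < n; ++i) {
    if (!(std::abs(px[i]) < hw && std::abs(py[i]) < hh)) {
      stop("agent %d starts outside the arena", i + 1);
    }
  }

  const int n_rec = n_steps / record_every + 1;
  NumericMatrix rec_x(n_rec, n), rec_y(n_rec, n), rec_vx(n_rec, n), rec_vy(n_rec, n);
  NumericVector rec_t(n_rec);
  int r = 0;
  for (int i = 0; i < n; ++i) {
    rec_x(0, i) = px[i]; rec_y(0, i) = py[i];
    rec_vx(0, i) = vx[i]; rec_vy(0, i) = vy[i];
  }
  rec_t[0] = 0.0;
  r = 1;

  std::vector<double> fx(n), fy(n);
  const double inv_m_dt = dt / p.mass;
  for (int s = 1; s <= n_steps; ++s) {
    compute_forces(n, px.data(), py.data(), vx.data(), vy.data(),
                   hx.data(), hy.data(), has_chir ? chir.data() : nullptr,
                   p, hw, hh, fx.data(), fy.data());
    // forward Euler: position from the old velocity, then velocity update;
    // semi-implicit variant advances the position with the new velocity
    for (int i = 0; i < n; ++i) {
      if (semi_implicit) {
        vx[i] += inv_m_dt * fx[i];
        vy[i] += inv_m_dt * fy[i];
        px[i] += dt * vx[i];
        py[i] += dt * vy[i];
      } else {
        px[i] += dt * vx[i];
        py[i] += dt * vy[i];
        vx[i] += inv_m_dt * fx[i];
        vy[i] += inv_m_dt * fy[i];
      }
      double sp = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i]);
      if (sp > speed_floor) {
        hx[i] = vx[i] / sp;
        hy[i] = vy[i] / sp;
      }
      if (!(std::abs(px[i]) < hw && std::abs(py[i]) < hh)) {
        stop("agent %d left the arena at t = %.3f s (dt too large?)", i + 1, s * dt);
      }
    }
    if (s % record_every == 0) {
      for (int i = 0; i < n; ++i) {
        rec_x(r, i) = px[i]; rec_y(r, i) = py[i];
        rec_vx(r, i) = vx[i]; rec_vy(r, i) = vy[i];
      }
      rec_t[r] = s * dt;
      ++r;
    }
    if (s % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["t"] = rec_t, _["x"] = rec_x, _["y"] = rec_y,
                      _["vx"] = rec_vx, _["vy"] = rec_vy);
}
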