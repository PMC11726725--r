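#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Stochastic spatial multi-agent simulation of replicases (R), parasites
// (P), inhibitors (X), anti-inhibitors (Y) and their complexes (XY, XT) on a
// toroidal 2D arena.  Species codes: 1 R, 2 P, 3 X, 4 Y, 5 XY, 6 XT.
// Uses R's RNG throughout, so runs are reproducible under set.seed().
//
// Per-step phase order (fixed for reproducibility):
//   diffusion -> decay -> replication -> folding -> inhibition
// Inhibition: complex dissociation first (p2 for XT, p4 for XY), then
// binding (p1 inhibitor+target, p3 inhibitor+anti-inhibitor), with
// p_i = 1 - exp(-k_i * dt).  Agents released by a dissociation are not
// eligible to bind again until the next step; every agent takes part in at
// most one reaction per step.

namespace {

struct World {
  std::vector<int> sp;
  std::vector<double> x, y;
  std::vector<char> folded;
  std::vector<char> dead;
};

struct Pars {
  double sizeX, sizeY, radius;
  int Nmax;
  double d, aR, aP, lP, sdD, sdDp, delta, dt, K_repl;
  double p1, p2, p3, p4;
  int mode; // 0 only_P, 1 only_R
};

inline double wrap(double v, double size) {
  v -= size * std::floor(v / size);
  if (v < 0) v = 0;           // guard against rounding at the seam
  if (v >= size) v = 0;
  return v;
}

// shortest signed displacement from a to b on the torus
inline double tdiff(double a, double b, double size) {
  double d = b - a;
  if (d > 0.5 * size) d -= size;
  else if (d < -0.5 * size) d += size;
  return d;
}

inline double dist2(const World& w, int i, int j, const Pars& p) {
  double dx = tdiff(w.x[i], w.x[j], p.sizeX);
  double dy = tdiff(w.y[i], w.y[j], p.sizeY);
  return dx * dx + dy * dy;
}

// Uniform cell grid for neighbour queries within `radius`; cells are at
// least `radius` wide so the 3x3 block around a point covers the disk.
struct Grid {
  int nx, ny;
  double cw, ch;
  double sizeX, sizeY;
  std::vector<std::vector<int>> cells;

  Grid(double sX, double sY, double radius) : sizeX(sX), sizeY(sY) {
    nx = std::max(1, (int)std::floor(sX / radius));
    ny = std::max(1, (int)std::floor(sY / radius));
    nx = std::min(nx, 1024); ny = std::min(ny, 1024);
    cw = sX / nx; ch = sY / ny;
    cells.assign((size_t)nx * ny, {});
  }
  inline int cell_of(double px, double py) const {
    int cx = std::min((int)(px / cw), nx - 1);
    int cy = std::min((int)(py / ch), ny - 1);
    return cy * nx + cx;
  }
  void insert(int idx, double px, double py) {
    cells[cell_of(px, py)].push_back(idx);
  }
  // visit all indices in the 3x3 cell block around (px, py)
  template <typename F>
  void visit(double px, double py, F f) const {
    int cx = std::min((int)(px / cw), nx - 1);
    int cy = std::min((int)(py / ch), ny - 1);
    for (int oy = -1; oy <= 1; ++oy) {
      int yy = (cy + oy + ny) % ny;
      for (int ox = -1; ox <= 1; ++ox) {
        int xx = (cx + ox + nx) % nx;
        for (int idx : cells[(size_t)yy * nx + xx]) f(idx);
      }
    }
  }
};

void compact(World& w) {
  size_t out = 0;
  for (size_t i = 0; i < w.sp.size(); ++i) {
    if (!w.dead[i]) {
      if (out != i) {
        w.sp[out] = w.sp[i]; w.x[out] = w.x[i]; w.y[out] = w.y[i];
        w.folded[out] = w.folded[i];
      }
      ++out;
    }
  }
  w.sp.resize(out); w.x.resize(out); w.y.resize(out);
  w.folded.resize(out);
  w.dead.assign(out, 0);
}

void add_agent(World& w, int sp, double px, double py, char folded = 0) {
  w.sp.push_back(sp); w.x.push_back(px); w.y.push_back(py);
  w.folded.push_back(folded); w.dead.push_back(0);
}

void step_world(World& w, const Pars& p) {
  const double r2 = p.radius * p.radius;
  size_t n0 = w.sp.size();

  // --- diffusion: Gaussian displacement, variance D*dt (D' for complexes)
  for (size_t i = 0; i < n0; ++i) {
    double sd = (w.sp[i] >= 5) ? p.sdDp : p.sdD;
    w.x[i] = wrap(w.x[i] + norm_rand() * sd, p.sizeX);
    w.y[i] = wrap(w.y[i] + norm_rand() * sd, p.sizeY);
  }

  // --- decay of replicases and parasites.  Hydrolysis does not care about
  //     conformation or the short inhibitor duplex: free agents decay with
  //     probability d*dt, and a bound target decays at the same rate, in
  //     which case the complex falls apart and the inhibitor is released.
  const double pdecay = p.d * p.dt;
  for (size_t i = 0; i < n0; ++i) {
    if ((w.sp[i] == 1 || w.sp[i] == 2) && unif_rand() < pdecay) {
      w.dead[i] = 1;
    } else if (w.sp[i] == 6 && unif_rand() < pdecay) {
      w.dead[i] = 1;
      add_agent(w, 3, w.x[i], w.y[i]); // inhibitor survives the decay
    }
  }
  n0 = w.sp.size();

  // --- replication: template needs a free replicase within the interaction
  //     radius and fewer than Nmax RNA neighbours; offspring of a replicase
  //     template mutates to a parasite with probability delta
  {
    Grid g(p.sizeX, p.sizeY, p.radius);
    for (size_t i = 0; i < n0; ++i)
      if (!w.dead[i] && (w.sp[i] == 1 || w.sp[i] == 2))
        g.insert((int)i, w.x[i], w.y[i]);

    std::vector<char> used(n0, 0);
    struct Birth { int sp; double x, y; };
    std::vector<Birth> births;

    for (size_t t = 0; t < n0; ++t) {
      if (w.dead[t] || used[t]) continue;
      if (w.sp[t] != 1 && w.sp[t] != 2) continue; // any free R or P is a template

      int catalyst = -1, crowd = 0;
      double best = R_PosInf;
      g.visit(w.x[t], w.y[t], [&](int j) {
        if ((size_t)j == t || w.dead[j]) return;
        double d2 = dist2(w, (int)t, j, p);
        if (d2 > r2) return;
        ++crowd;
        if (w.sp[j] == 1 && d2 < best) { best = d2; catalyst = j; }
      });
      if (catalyst < 0 || crowd >= p.Nmax) continue;

      // a template is copied at most once per step; the catalysing
      // replicase is an enzyme and may serve several templates within one
      // (long) time step
      double a = (w.sp[t] == 1) ? p.aR : p.aP;
      if (unif_rand() < a * p.K_repl) {
        used[t] = 1;
        double ang = 2.0 * M_PI * unif_rand();
        double rad = p.radius * std::sqrt(unif_rand());
        double bx = wrap(w.x[t] + rad * std::cos(ang), p.sizeX);
        double by = wrap(w.y[t] + rad * std::sin(ang), p.sizeY);
        int sp_off = (w.sp[t] == 2 || unif_rand() < p.delta) ? 2 : 1;
        births.push_back({sp_off, bx, by});
      }
    }
    for (const auto& b : births) add_agent(w, b.sp, b.x, b.y);
  }

  // --- parasite folding (irreversible): the fold sequesters the short
  //     region the inhibitor would pair with, so a folded parasite cannot
  //     be bound by inhibitors.  The processive replicase is unaffected
  //     (folded parasites remain templates) and so is hydrolysis.
  for (size_t i = 0; i < n0; ++i) {
    if (!w.dead[i] && w.sp[i] == 2 && !w.folded[i] && unif_rand() < p.lP)
      w.folded[i] = 1;
  }

  // --- inhibition: dissociation, then binding.  The time step is long
  //     relative to the binding kinetics, so agents released by a
  //     dissociation immediately re-equilibrate: they are eligible to bind
  //     again in the same phase (a released pair sits at zero distance and
  //     usually re-forms, making sequestration effectively persistent).
  size_t n1 = w.sp.size();
  const int target_sp = (p.mode == 0) ? 2 : 1;
  for (size_t i = 0; i < n1; ++i) {
    if (w.dead[i]) continue;
    if (w.sp[i] == 6 && unif_rand() < p.p2) {
      w.dead[i] = 1;
      add_agent(w, 3, w.x[i], w.y[i]);
      add_agent(w, target_sp, w.x[i], w.y[i]);
    } else if (w.sp[i] == 5 && unif_rand() < p.p4) {
      w.dead[i] = 1;
      add_agent(w, 3, w.x[i], w.y[i]);
      add_agent(w, 4, w.x[i], w.y[i]);
    }
  }

  {
    size_t n2 = w.sp.size();
    Grid g(p.sizeX, p.sizeY, p.radius);
    for (size_t i = 0; i < n2; ++i) {
      if (w.dead[i]) continue;
      if (w.sp[i] == target_sp || w.sp[i] == 4)
        g.insert((int)i, w.x[i], w.y[i]);
    }
    std::vector<char> used(n2, 0);
    for (size_t i = 0; i < n2; ++i) {
      if (w.dead[i] || used[i] || w.sp[i] != 3) continue;
      int target = -1, anti = -1;
      double bestT = R_PosInf, bestY = R_PosInf;
      g.visit(w.x[i], w.y[i], [&](int j) {
        if (w.dead[j] || used[j]) return;
        double d2 = dist2(w, (int)i, j, p);
        if (d2 > r2) return;
        if (w.sp[j] == target_sp && !w.folded[j] && d2 < bestT) {
          bestT = d2; target = j;
        } else if (w.sp[j] == 4 && d2 < bestY) {
          bestY = d2; anti = j;
        }
      });
      int partner = -1, complex_sp = 0;
      if (target >= 0) {
        if (unif_rand() < p.p1) { partner = target; complex_sp = 6; }
      } else if (anti >= 0) {
        if (unif_rand() < p.p3) { partner = anti; complex_sp = 5; }
      }
      if (partner >= 0) {
        used[i] = used[partner] = 1;
        w.dead[i] = w.dead[partner] = 1;
        double mx = wrap(w.x[i] + 0.5 * tdiff(w.x[i], w.x[partner], p.sizeX),
                         p.sizeX);
        double my = wrap(w.y[i] + 0.5 * tdiff(w.y[i], w.y[partner], p.sizeY),
                         p.sizeY);
        add_agent(w, complex_sp, mx, my);
      }
    }
  }

  compact(w);
}

void census(const World& w, int* out) {
  // out: R, P, P_folded, X, Y, XY, XT
  for (int i = 0; i < 7; ++i) out[i] = 0;
  for (size_t i = 0; i < w.sp.size(); ++i) {
    switch (w.sp[i]) {
      case 1: out[0]++; break;
      case 2: if (w.folded[i]) out[2]++; else out[1]++; break;
      case 3: out[3]++; break;
      case 4: out[4]++; break;
      case 5: out[5]++; break;
      case 6: out[6]++; break;
    }
  }
}

} // namespace

// [[Rcpp::export]]
List mas_simulate_cpp(IntegerVector species, NumericVector xpos,
                      NumericVector ypos, LogicalVector folded,
                      List params, int n_steps) {
  Pars p;
  p.sizeX = as<double>(params["sizeX"]);
  p.sizeY = as<double>(params["sizeY"]);
  p.radius = 2.0 * as<double>(params["agent_size"]);
  p.Nmax = as<int>(params["Nmax"]);
  p.d = as<double>(params["d"]);
  p.aR = as<double>(params["aR"]);
  p.aP = as<double>(params["aP"]);
  p.lP = as<double>(params["lP"]);
  p.dt = as<double>(params["dt"]);
  p.sdD = std::sqrt(as<double>(params["D"]) * p.dt);
  p.sdDp = std::sqrt(as<double>(params["Dprime"]) * p.dt);
  p.delta = as<double>(params["delta"]);
  p.K_repl = as<double>(params["K_repl"]);
  p.p1 = 1.0 - std::exp(-as<double>(params["k1"]) * p.dt);
  p.p2 = 1.0 - std::exp(-as<double>(params["k2"]) * p.dt);
  p.p3 = 1.0 - std::exp(-as<double>(params["k3"]) * p.dt);
  p.p4 = 1.0 - std::exp(-as<double>(params["k4"]) * p.dt);
  p.mode = as<int>(params["mode"]);

  World w;
  const size_t n = species.size();
  w.sp.assign(species.begin(), species.end());
  w.x.assign(xpos.begin(), xpos.end());
  w.y.assign(ypos.begin(), ypos.end());
  w.folded.resize(n);
  for (size_t i = 0; i < n; ++i) w.folded[i] = folded[i] ? 1 : 0;
  w.dead.assign(n, 0);

  IntegerMatrix counts(n_steps + 1, 8);
  int c[7];
  census(w, c);
  counts(0, 0) = 0;
  for (int j = 0; j < 7; ++j) counts(0, j + 1) = c[j];

  int extinction_step = NA_INTEGER;
  int last = 0;
  for (int s = 1; s <= n_steps; ++s) {
    step_world(w, p);
    census(w, c);
    counts(s, 0) = s;
    for (int j = 0; j < 7; ++j) counts(s, j + 1) = c[j];
    last = s;
    int r_total = c[0] + (p.mode == 1 ? c[6] : 0);
    if (r_total == 0) { extinction_step = s; break; }
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix out(last + 1, 8);
  for (int s = 0; s <= last; ++s)
    for (int j = 0; j < 8; ++j) out(s, j) = counts(s, j);

  IntegerVector sp_out(w.sp.begin(), w.sp.end());
  NumericVector x_out(w.x.begin(), w.x.end());
  NumericVector y_out(w.y.begin(), w.y.end());
  LogicalVector f_out(w.folded.size());
  for (size_t i = 0; i < w.folded.size(); ++i) f_out[i] = w.folded[i] != 0;

  return List::create(
    _["counts"] = out,
    _["species"] = sp_out, _["x"] = x_out, _["y"] = y_out,
    _["folded"] = f_out,
    _["extinction_step"] = extinction_step,
    _["reaction_probs"] = NumericVector::create(p.p1, p.p2, p.p3, p.p4));
}
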