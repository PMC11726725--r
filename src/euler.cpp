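#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Forward-Euler integration of the five-species mass-action network with an
// optional forcing on the A balance.  Uses R's RNG (seedable from R) for the
// jump-noise draws.  Forcing kinds: 0 none, 1 jump_noise (p, lo, hi),
// 2 ramp_noise (s), 3 replication (kRR, dR).
// [[Rcpp::export]]
List euler_integrate_cpp(NumericVector state0, NumericVector k,
                         int fkind, NumericVector fpar,
                         double dt, int n_steps, int record_every,
                         bool has_ref, NumericVector ref,
                         double divergence_factor) {
  double A = state0[0], X = state0[1], Y = state0[2],
         AX = state0[3], XY = state0[4];
  const double k1 = k[0], k2 = k[1], k3 = k[2], k4 = k[3];
  const double cA0 = A + AX;
  const double scale = std::max(std::max(A + AX, X + AX + XY),
                                std::max(Y + XY, 1.0));
  const double neg_tol = 1e-12 * scale;
  const double A_limit = divergence_factor * cA0;

  const int ncol = has_ref ? 7 : 6;
  std::vector<double> rows;
  rows.reserve(ncol * (n_steps / record_every + 3));

  auto lyap = [&](double a, double y) {
    double dx = a - ref[0], dy = y - ref[1];
    return ref[3] * ref[1] * dx * dx + ref[2] * ref[0] * dy * dy;
  };
  auto record = [&](int step) {
    rows.push_back(step); rows.push_back(A); rows.push_back(X);
    rows.push_back(Y); rows.push_back(AX); rows.push_back(XY);
    if (has_ref) rows.push_back(lyap(A, Y));
  };

  record(0);
  bool div = false;
  int div_step = -1;

  for (int i = 1; i <= n_steps; ++i) {
    // forcing on the free-agent pool (changes cA)
    double extra = 0.0;
    if (fkind == 1) {
      if (unif_rand() < fpar[0]) {
        double jump = fpar[1] + (fpar[2] - fpar[1]) * unif_rand();
        double applied = std::max(jump, -A);
        A += applied;
      }
    } else if (fkind == 2) {
      A += fpar[0] * dt;
      if (A < 0) A = 0;
    } else if (fkind == 3) {
      extra = fpar[0] * A * A - fpar[1] * A;
    }

    const double fAX = k2 * AX - k1 * A * X;
    const double fXY = k4 * XY - k3 * X * Y;
    A  += dt * (fAX + extra);
    X  += dt * (fAX + fXY);
    Y  += dt * fXY;
    AX -= dt * fAX;
    XY -= dt * fXY;

    // divergence detection (expected under uncontrolled replication)
    if (!R_finite(A) || !R_finite(X) || !R_finite(Y) ||
        !R_finite(AX) || !R_finite(XY) || A > A_limit) {
      div = true;
      div_step = i;
      record(i);
      break;
    }

    // negativity guard: clip rounding noise, abort on real negativity
    double vals[5] = {A, X, Y, AX, XY};
    bool bad = false;
    for (int j = 0; j < 5; ++j) {
      if (vals[j] < 0) {
        if (vals[j] > -neg_tol) vals[j] = 0.0;
        else bad = true;
      }
    }
    A = vals[0]; X = vals[1]; Y = vals[2]; AX = vals[3]; XY = vals[4];
    if (bad) {
      if (fkind == 3) {            // blow-up invalidated the explicit step
        div = true;
        div_step = i;
        record(i);
        break;
      }
      stop("negative concentration beyond rounding tolerance at step %d: "
           "reduce dt", i);
    }

    if (i % record_every == 0 || i == n_steps) record(i);
  }

  const int nrow = rows.size() / ncol;
  NumericMatrix m(nrow, ncol);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c < ncol; ++c)
      m(r, c) = rows[r * ncol + c];

  return List::create(_["records"] = m,
                      _["diverged"] = div,
                      _["divergence_step"] = div_step);
}
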