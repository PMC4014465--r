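#include <Rcpp.h>
using namespace Rcpp;

// Asynchronous attention-field swarm dynamics.
//
// Each update: a random agent draws a uniform gaze direction, searches the
// angular sector of amplitude alpha (bisected by the gaze) for its nearest
// neighbour, and steps distance v toward it (if farther than the ideal
// distance D) or away from it (if closer), stopping exactly on the circle of
// radius D around the neighbour when the step would cross it.  All random
// numbers come from R's RNG so a set.seed() in R fixes trajectories exactly.

static const double TWOPI = 6.283185307179586476925286766559;

// Smallest absolute angular difference, result in [0, pi].
static inline double ang_diff(double a, double b) {
  double d = a - b;
  d -= TWOPI * std::floor(d / TWOPI); // reduce to [0, 2*pi)
  if (d > M_PI) d = TWOPI - d;
  return d;
}

// Nearest neighbour of agent i (1-based) inside the closed sector
// [gaze - alpha/2, gaze + alpha/2].  Returns 0 when the sector is empty.
// Ties in distance resolve to the lowest index (strict < while scanning up).
// [[Rcpp::export]]
int cpp_sector_nn(const NumericMatrix& pos, int i, double gaze, double alpha) {
  const int n = pos.nrow();
  const double half = alpha / 2.0;
  const double xi = pos(i - 1, 0), yi = pos(i - 1, 1);
  int best = 0;
  double bestd2 = R_PosInf;
  for (int k = 0; k < n; ++k) {
    if (k == i - 1) continue;
    const double dx = pos(k, 0) - xi, dy = pos(k, 1) - yi;
    const double d2 = dx * dx + dy * dy;
    if (d2 >= bestd2) continue;
    if (d2 == 0.0) { // coincident point: bearing undefined, treat as visible
      best = k + 1; bestd2 = 0.0; continue;
    }
    const double bearing = std::atan2(dy, dx);
    if (ang_diff(bearing, gaze) <= half) {
      best = k + 1;
      bestd2 = d2;
    }
  }
  return best;
}

struct MoveResult {
  double x, y, displacement;
  bool moved, clamped;
};

// Single movement of agent i relative to neighbour j.  dtol is the dead band
// around the ideal distance D inside which no movement occurs (required for
// the quiescence detector to fire once agents sit on the D-circle).
static MoveResult move_one(const NumericMatrix& pos, int i0, int j0,
                           double D, double v, double eta, double L,
                           double dtol) {
  MoveResult res;
  const double xi = pos(i0, 0), yi = pos(i0, 1);
  const double xj = pos(j0, 0), yj = pos(j0, 1);
  double wx = xi - xj, wy = yi - yj;
  const double d = std::sqrt(wx * wx + wy * wy);
  res.x = xi; res.y = yi; res.displacement = 0.0;
  res.moved = false; res.clamped = false;
  if (d == 0.0 || std::fabs(d - D) <= dtol) return res;

  // unit direction of motion: toward j when too far, away when too close
  double ux = (xj - xi) / d, uy = (yj - yi) / d;
  if (d < D) { ux = -ux; uy = -uy; }
  if (eta > 0.0) {
    const double th = (2.0 * unif_rand() - 1.0) * eta * M_PI;
    const double c = std::cos(th), s = std::sin(th);
    const double rx = c * ux - s * uy, ry = s * ux + c * uy;
    ux = rx; uy = ry;
  }

  // where (if at all) does the path xi + t*u cross the circle |x - xj| = D ?
  const double b = wx * ux + wy * uy;           // w . u
  const double cq = d * d - D * D;
  double t = v;                                  // full step by default
  bool stopped = false;
  if (d > D) {                                   // approach from outside
    const double disc = b * b - cq;
    if (disc >= 0.0) {
      const double t0 = -b - std::sqrt(disc);   // first crossing
      if (t0 > 0.0 && t0 <= v) { t = t0; stopped = true; }
    }
  } else {                                       // leave from inside
    const double t1 = -b + std::sqrt(b * b - cq); // unique forward exit
    if (t1 <= v) { t = t1; stopped = true; }
  }

  double nx = xi + t * ux, ny = yi + t * uy;
  if (stopped) { // renormalise so the final distance to j is exactly D
    double px = nx - xj, py = ny - yj;
    const double pn = std::sqrt(px * px + py * py);
    if (pn > 0.0) { nx = xj + D * px / pn; ny = yj + D * py / pn; }
  }
  // reflecting at nothing: agents simply stop at the box boundary
  double cx = std::min(std::max(nx, 0.0), L);
  double cy = std::min(std::max(ny, 0.0), L);
  if (cx != nx || cy != ny) res.clamped = true;
  const double ddx = cx - xi, ddy = cy - yi;
  res.displacement = std::sqrt(ddx * ddx + ddy * ddy);
  res.moved = res.displacement > 0.0;
  res.x = cx; res.y = cy;
  return res;
}

// [[Rcpp::export]]
List cpp_move_agent(const NumericMatrix& pos, int i, int j, double D,
                    double v, double eta, double L, double dtol) {
  MoveResult r = move_one(pos, i - 1, j - 1, D, v, eta, L, dtol);
  return List::create(_["x"] = r.x, _["y"] = r.y,
                      _["moved"] = r.moved,
                      _["displacement"] = r.displacement,
                      _["clamped"] = r.clamped);
}

// One time unit: P single-agent updates, asynchronous, each seeing the
// positions left by the previous updates.  `permute` selects the
// without-replacement (random permutation) variant; the default protocol is
// uniform selection with replacement.
static int sweep_inplace(NumericMatrix& pos, double L, double D, double v,
                         double alpha, double eta, bool permute, double dtol,
                         int* clamp_events) {
  const int P = pos.nrow();
  int moved = 0;
  IntegerVector order(P);
  if (permute) {
    for (int k = 0; k < P; ++k) order[k] = k;
    for (int k = P - 1; k > 0; --k) { // Fisher-Yates on R's RNG
      int m = (int)(unif_rand() * (k + 1));
      if (m > k) m = k;
      std::swap(order[k], order[m]);
    }
  }
  for (int k = 0; k < P; ++k) {
    int i;
    if (permute) {
      i = order[k];
    } else {
      i = (int)(unif_rand() * P);
      if (i >= P) i = P - 1;
    }
    const double gaze = unif_rand() * TWOPI;
    const int j = cpp_sector_nn(pos, i + 1, gaze, alpha);
    if (j == 0) continue; // empty attention sector: the agent stays put
    MoveResult r = move_one(pos, i, j - 1, D, v, eta, L, dtol);
    if (r.clamped && clamp_events) ++(*clamp_events);
    if (r.moved) {
      pos(i, 0) = r.x;
      pos(i, 1) = r.y;
      ++moved;
    }
  }
  return moved;
}

// [[Rcpp::export]]
List cpp_sweep(const NumericMatrix& pos, double L, double D, double v,
               double alpha, double eta, bool permute, double dtol) {
  NumericMatrix p = clone(pos);
  int clamps = 0;
  const int moved = sweep_inplace(p, L, D, v, alpha, eta, permute, dtol,
                                  &clamps);
  return List::create(_["positions"] = p, _["moved"] = moved,
                      _["clamp_events"] = clamps);
}

// Full simulation: iterate sweeps until qs_window consecutive sweeps move
// nobody (quasi-stationary) or max_sweeps is hit.  States are sampled every
// sample_every sweeps plus the final state.
// [[Rcpp::export]]
List cpp_run(const NumericMatrix& pos0, double L, double D, double v,
             double alpha, double eta, bool permute, int qs_window,
             int max_sweeps, int sample_every, double dtol) {
  NumericMatrix p = clone(pos0);
  std::vector<NumericMatrix> samples;
  std::vector<int> ts;
  IntegerVector moved_counts(max_sweeps);
  samples.push_back(clone(p));
  ts.push_back(0);
  int quiet = 0, t = 0, clamps = 0;
  bool converged = false;
  int t_conv = NA_INTEGER;
  while (t < max_sweeps) {
    const int moved = sweep_inplace(p, L, D, v, alpha, eta, permute, dtol,
                                    &clamps);
    ++t;
    moved_counts[t - 1] = moved;
    quiet = (moved == 0) ? quiet + 1 : 0;
    const bool done = (quiet >= qs_window);
    if (t % sample_every == 0 || done || t == max_sweeps) {
      samples.push_back(clone(p));
      ts.push_back(t);
    }
    if (done) {
      converged = true;
      t_conv = t - qs_window;
      break;
    }
  }
  return List::create(_["samples"] = wrap(samples),
                      _["ts"] = wrap(ts),
                      _["converged"] = converged,
                      _["t_conv"] = t_conv,
                      _["sweeps_run"] = t,
                      _["clamp_events"] = clamps,
                      _["moved_counts"] = moved_counts[Range(0, std::max(t, 1) - 1)]);
}
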