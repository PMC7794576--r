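#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Nearest midline vertex per query point; 1-based index, ties to the
// smaller index (strict improvement required).
// [[Rcpp::export]]
IntegerVector cpp_nearest_vertex(NumericVector px, NumericVector pz,
                                 NumericVector vx, NumericVector vz) {
  const int n = px.size(), m = vx.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf; int bj = 0;
    const double x = px[i], z = pz[i];
    for (int j = 0; j < m; ++j) {
      const double dx = vx[j] - x, dz = vz[j] - z;
      const double d2 = dx * dx + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    out[i] = bj + 1;
  }
  return out;
}

// Per-frame nearest-on-screen midline reference for a batch of gaze samples.
// For frame i the candidate references are the `window_n` midline vertices
// from the vehicle's own vertex forward (wrapping); each candidate is put
// through the pinhole camera (eye at height eye_h above the vehicle, looking
// along yaw, screen plane normalised by tan of the half field of view per
// axis) and the candidate minimising squared screen distance to the gaze
// point is returned. Candidates with non-positive forward depth are dropped;
// ties resolve to the smaller arc (scan order). Angular error is the visual
// angle between the gaze ray and the reference ray.
// [[Rcpp::export]]
List cpp_gaze_midline_refs(NumericVector veh_x, NumericVector veh_z,
                           NumericVector veh_yaw, IntegerVector veh_idx,
                           NumericVector gaze_x, NumericVector gaze_y,
                           NumericVector mid_x, NumericVector mid_z,
                           int window_n, double eye_h,
                           double tan_h, double tan_v) {
  const int n = veh_x.size(), m = mid_x.size();
  IntegerVector ref_off(n);
  NumericVector ang(n), ref_sx(n), ref_sy(n);
  for (int i = 0; i < n; ++i) {
    const double cy = std::cos(veh_yaw[i]), sy = std::sin(veh_yaw[i]);
    const double gx = gaze_x[i], gy = gaze_y[i];
    double best = R_PosInf, bsx = NA_REAL, bsy = NA_REAL;
    int bk = NA_INTEGER;
    const int base = veh_idx[i] - 1;
    for (int k = 0; k < window_n; ++k) {
      const int j = (base + k) % m;
      const double dx = mid_x[j] - veh_x[i], dz = mid_z[j] - veh_z[i];
      const double fwd = dx * cy + dz * sy;
      if (fwd <= 1e-9) continue;
      const double lat = dx * sy - dz * cy;   // rightward positive
      const double sx = 0.5 + (lat / fwd) / (2.0 * tan_h);
      const double syc = 0.5 + (-eye_h / fwd) / (2.0 * tan_v);
      const double ddx = sx - gx, ddy = syc - gy;
      const double d2 = ddx * ddx + ddy * ddy;
      if (d2 < best) { best = d2; bk = k; bsx = sx; bsy = syc; }
    }
    ref_off[i] = bk;
    ref_sx[i] = bsx; ref_sy[i] = bsy;
    if (bk == NA_INTEGER) { ang[i] = NA_REAL; continue; }
    // reconstruct rays on the unit-distance screen plane
    const double gX = (gx - 0.5) * 2.0 * tan_h, gY = (gy - 0.5) * 2.0 * tan_v;
    const double rX = (bsx - 0.5) * 2.0 * tan_h, rY = (bsy - 0.5) * 2.0 * tan_v;
    const double dot = gX * rX + gY * rY + 1.0;
    const double ng = std::sqrt(gX * gX + gY * gY + 1.0);
    const double nr = std::sqrt(rX * rX + rY * rY + 1.0);
    double c = dot / (ng * nr);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    ang[i] = std::acos(c) * 180.0 / M_PI;
  }
  return List::create(_["ref_offset"] = ref_off,
                      _["angular_error_deg"] = ang,
                      _["ref_screen_x"] = ref_sx,
                      _["ref_screen_y"] = ref_sy);
}

// Exact dynamic-programming minimisation of
//   sum over segments of SSE(segment) + penalty * (number of segments)
// for a multi-channel signal, each segment an independent per-channel OLS
// line against t. O(n^2) with O(1) interval cost from prefix sums.
// Returns 1-based inclusive segment index ranges.
// [[Rcpp::export]]
List cpp_segment_dp(NumericVector t, NumericMatrix y, double penalty,
                    int min_len) {
  const int n = t.size(), C = y.ncol();
  if (n < min_len) return List::create(_["start"] = IntegerVector(0),
                                       _["end"] = IntegerVector(0));
  // centre t and each channel for numerical stability of the moment sums
  std::vector<double> tc(n);
  double tmean = 0;
  for (int i = 0; i < n; ++i) tmean += t[i];
  tmean /= n;
  for (int i = 0; i < n; ++i) tc[i] = t[i] - tmean;

  std::vector<double> St(n + 1, 0.0), Stt(n + 1, 0.0);
  std::vector<std::vector<double> > Sy(C), Syy(C), Sty(C);
  for (int c = 0; c < C; ++c) {
    Sy[c].assign(n + 1, 0.0); Syy[c].assign(n + 1, 0.0);
    Sty[c].assign(n + 1, 0.0);
    double ym = 0;
    for (int i = 0; i < n; ++i) ym += y(i, c);
    ym /= n;
    for (int i = 0; i < n; ++i) {
      const double yv = y(i, c) - ym;
      Sy[c][i + 1] = Sy[c][i] + yv;
      Syy[c][i + 1] = Syy[c][i] + yv * yv;
      Sty[c][i + 1] = Sty[c][i] + tc[i] * yv;
    }
  }
  for (int i = 0; i < n; ++i) {
    St[i + 1] = St[i] + tc[i];
    Stt[i + 1] = Stt[i] + tc[i] * tc[i];
  }

  // cost of fitting one line per channel over samples [a, b] inclusive
  auto segcost = [&](int a, int b) -> double {
    const double len = b - a + 1;
    const double st = St[b + 1] - St[a], stt = Stt[b + 1] - Stt[a];
    const double sxx = stt - st * st / len;
    double cost = 0.0;
    for (int c = 0; c < C; ++c) {
      const double sy = Sy[c][b + 1] - Sy[c][a];
      const double syy = Syy[c][b + 1] - Syy[c][a];
      const double sty = Sty[c][b + 1] - Sty[c][a];
      const double syyc = syy - sy * sy / len;
      const double sxy = sty - st * sy / len;
      double sse = syyc;
      if (sxx > 1e-12) sse -= sxy * sxy / sxx;
      if (sse > 0) cost += sse;
    }
    return cost;
  };

  const double INF = R_PosInf;
  std::vector<double> F(n + 1, INF);
  std::vector<int> prev(n + 1, -1);
  F[0] = 0.0;
  for (int j = min_len; j <= n; ++j) {
    for (int a = 0; a + min_len <= j; ++a) {
      if (!R_FINITE(F[a])) continue;
      if (j - a < min_len) continue;
      const double v = F[a] + segcost(a, j - 1) + penalty;
      if (v < F[j]) { F[j] = v; prev[j] = a; }
    }
  }
  std::vector<int> starts, ends;
  int j = n;
  while (j > 0) {
    const int a = prev[j];
    starts.push_back(a + 1);
    ends.push_back(j);
    j = a;
  }
  std::reverse(starts.begin(), starts.end());
  std::reverse(ends.begin(), ends.end());
  return List::create(_["start"] = wrap(starts), _["end"] = wrap(ends));
}
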