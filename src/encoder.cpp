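// Compiled fast path of the scenario vision pipeline: subtended angle,
// angular position, full-containment occlusion, back-extrapolated
// derivative channels, and state discretisation. Mirrors the R
// implementations in R/geometry.R; the two paths are cross-checked in the
// test suite.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <string>
using namespace Rcpp;

namespace {

struct Obs {
  double psi, theta, dist;
  int idx; // 1-based neighbour index (the scenario id)
  bool visible;
};

inline double clamp1(double x) { return x > 1 ? 1 : (x < -1 ? -1 : x); }

// Subtended angle and covering arc of a rectangle seen from the origin.
// Corners at c +- (h/2) u +- (w/2) u_perp. Returns psi; fills arc start
// and width (minimal covering arc of the four corner bearings).
double rect_view(double cx, double cy, double ux, double uy,
                 double h, double w, double* arc_start, double* arc_width) {
  const double px = -uy, py = ux;
  double corx[4], cory[4];
  const double s1[4] = {-1, 1, -1, 1}, s2[4] = {1, -1, -1, 1};
  for (int i = 0; i < 4; ++i) {
    corx[i] = cx + s1[i] * h / 2 * ux + s2[i] * w / 2 * px;
    cory[i] = cy + s1[i] * h / 2 * uy + s2[i] * w / 2 * py;
  }
  // focal centre inside the rectangle -> full view (psi = pi); the
  // covering arc is still the minimal arc of the corner bearings, exactly
  // as the R path computes it
  const double along = -cx * ux - cy * uy, across = -cx * px - cy * py;
  const bool inside = std::fabs(along) <= h / 2 && std::fabs(across) <= w / 2;
  double psi = 0;
  if (!inside) for (int i = 0; i < 3; ++i)
    for (int j = i + 1; j < 4; ++j) {
      const double ni = std::sqrt(corx[i] * corx[i] + cory[i] * cory[i]);
      const double nj = std::sqrt(corx[j] * corx[j] + cory[j] * cory[j]);
      const double a = std::acos(clamp1((corx[i] * corx[j] +
                                         cory[i] * cory[j]) / (ni * nj)));
      if (a > psi) psi = a;
    }
  double b[4];
  for (int i = 0; i < 4; ++i) b[i] = std::atan2(cory[i], corx[i]);
  std::sort(b, b + 4);
  double gap_max = -1; int gi = 0;
  for (int i = 0; i < 4; ++i) {
    const double nxt = (i == 3) ? b[0] + 2 * M_PI : b[i + 1];
    if (nxt - b[i] > gap_max) { gap_max = nxt - b[i]; gi = i; }
  }
  *arc_start = (gi == 3) ? b[0] : b[gi + 1];
  *arc_width = 2 * M_PI - gap_max;
  return inside ? M_PI : psi;
}

// Observation of all neighbours from a focal agent at flx/fly; positions
// absolute in an unbounded patch.
void observe_patch(double flx, double fly, double fhx, double fhy,
                   const NumericMatrix& nl, const NumericMatrix& nhead,
                   const NumericVector& bh, const NumericVector& bw,
                   std::vector<Obs>& out,
                   std::vector<double>& arc_s, std::vector<double>& arc_w) {
  const int m = nl.nrow();
  out.resize(m); arc_s.resize(m); arc_w.resize(m);
  for (int i = 0; i < m; ++i) {
    const double dx = nl(i, 0) - flx, dy = nl(i, 1) - fly;
    const double d = std::sqrt(dx * dx + dy * dy);
    out[i].dist = d;
    out[i].idx = i + 1;
    out[i].psi = rect_view(dx, dy, nhead(i, 0), nhead(i, 1),
                           bh[i], bw[i], &arc_s[i], &arc_w[i]);
    out[i].theta = std::acos(clamp1((fhx * dx + fhy * dy) /
                                    (d > 0 ? d : 1)));
    out[i].visible = true;
  }
  // full-containment occlusion by strictly nearer neighbours
  for (int i = 0; i < m; ++i) {
    std::vector<std::pair<double, double> > iv;
    for (int j = 0; j < m; ++j) {
      if (out[j].dist >= out[i].dist) continue;
      double cs = arc_s[j] - arc_s[i];
      cs -= 2 * M_PI * std::floor(cs / (2 * M_PI));
      iv.push_back(std::make_pair(cs, cs + arc_w[j]));
      iv.push_back(std::make_pair(cs - 2 * M_PI, cs - 2 * M_PI + arc_w[j]));
    }
    if (iv.empty()) continue;
    std::sort(iv.begin(), iv.end());
    double covered = 0;
    bool hidden = false;
    for (size_t r = 0; r < iv.size(); ++r) {
      if (iv[r].second <= 0 || iv[r].first >= arc_w[i]) continue;
      if (iv[r].first > covered + 1e-12) break;
      if (iv[r].second > covered) covered = iv[r].second;
      if (covered >= arc_w[i] - 1e-12) { hidden = true; break; }
    }
    if (hidden) out[i].visible = false;
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_encode_patch(NumericVector focal_l, NumericVector focal_v,
                      NumericVector focal_heading,
                      NumericMatrix nb_l, NumericMatrix nb_v,
                      NumericMatrix nb_heading,
                      NumericVector body_h, NumericVector body_w,
                      int k, double bin_width) {
  const int m = nb_l.nrow();
  std::vector<Obs> cur, prev;
  std::vector<double> as, aw;
  // body_h/body_w are patch-wide: index 0 focal, 1..m neighbours
  NumericVector nbh(m), nbw(m);
  for (int i = 0; i < m; ++i) { nbh[i] = body_h[i + 1]; nbw[i] = body_w[i + 1]; }
  observe_patch(focal_l[0], focal_l[1], focal_heading[0], focal_heading[1],
                nb_l, nb_heading, nbh, nbw, cur, as, aw);
  // previous frame: whole scene rewound one tick (l - v); same visible set
  NumericMatrix pl(m, 2);
  for (int i = 0; i < m; ++i) {
    pl(i, 0) = nb_l(i, 0) - nb_v(i, 0);
    pl(i, 1) = nb_l(i, 1) - nb_v(i, 1);
  }
  observe_patch(focal_l[0] - focal_v[0], focal_l[1] - focal_v[1],
                focal_heading[0], focal_heading[1],
                pl, nb_heading, nbh, nbw, prev, as, aw);

  std::vector<Obs> vis;
  std::vector<double> psid, thd;
  for (int i = 0; i < m; ++i)
    if (cur[i].visible) {
      vis.push_back(cur[i]);
      psid.push_back(cur[i].psi - prev[i].psi);
      thd.push_back(cur[i].theta - prev[i].theta);
    }
  std::vector<int> ord(vis.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (vis[a].theta != vis[b].theta) return vis[a].theta < vis[b].theta;
    if (vis[a].dist != vis[b].dist) return vis[a].dist < vis[b].dist;
    return vis[a].idx < vis[b].idx;
  });
  const int SENT = 1000000;
  IntegerVector bins(4 * k, SENT);
  const int used = std::min((int)vis.size(), k);
  auto clip_pi = [](double x) {
    return x > M_PI ? M_PI : (x < -M_PI ? -M_PI : x);
  };
  for (int s = 0; s < used; ++s) {
    const Obs& o = vis[ord[s]];
    bins[4 * s] = (int)std::floor(o.psi / bin_width);
    bins[4 * s + 1] = (int)std::floor(clip_pi(psid[ord[s]]) / bin_width);
    bins[4 * s + 2] = (int)std::floor(o.theta / bin_width);
    bins[4 * s + 3] = (int)std::floor(clip_pi(thd[ord[s]]) / bin_width);
  }
  std::string key;
  key.reserve(8 * 4 * k);
  for (int i = 0; i < 4 * k; ++i) {
    if (i) key.push_back(',');
    key += std::to_string(bins[i]);
  }
  int n_psi = 0, n_th = 0;
  if (!vis.empty()) {
    int nearest = 0;
    for (size_t i = 1; i < vis.size(); ++i)
      if (vis[i].dist < vis[nearest].dist) nearest = i;
    n_psi = (int)std::floor(vis[nearest].psi / bin_width);
    n_th = (int)std::floor(vis[nearest].theta / bin_width);
  }
  return List::create(_["bins"] = bins, _["key"] = key,
                      _["n_visible"] = (int)vis.size(),
                      _["psi_bin"] = n_psi, _["theta_bin"] = n_th);
}
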