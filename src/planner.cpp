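// Genetic-algorithm action planner: eta-step patch rollouts scored by the
// local alignment + collision objective. The focal agent executes a gene's
// action sequence (heading-steering velocity update); neighbours move
// ballistically; the patch is unbounded (no wrap inside a rollout).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double wrap_pi(double x) {
  const double two_pi = 2.0 * M_PI;
  double y = x + M_PI;
  y -= two_pi * std::floor(y / two_pi);
  y -= M_PI;
  return (y == -M_PI) ? M_PI : y;
}

// Disorder metric over heading angles: mean squared wrapped deviation from
// the circular mean, scaled by 1/(2 pi).
static double order_metric(const std::vector<double>& ang) {
  const int n = ang.size();
  if (n == 0) return 0.0;
  double s = 0.0, c = 0.0;
  for (double a : ang) { s += std::sin(a); c += std::cos(a); }
  const double mu = std::atan2(s, c);
  double acc = 0.0;
  for (double a : ang) { double d = wrap_pi(a - mu); acc += d * d; }
  return acc / n / (2.0 * M_PI);
}

struct Patch {
  // index 0 = focal, 1..m = neighbours
  std::vector<double> lx, ly, vx, vy, hx, hy, bh, bw;
  int m; // neighbour count
};

static Patch make_patch(const NumericVector& focal_l,
                        const NumericVector& focal_v,
                        const NumericVector& focal_heading,
                        const NumericMatrix& nb_l,
                        const NumericMatrix& nb_v,
                        const NumericMatrix& nb_heading,
                        const NumericVector& body_h,
                        const NumericVector& body_w) {
  Patch p;
  p.m = nb_l.nrow();
  const int n = p.m + 1;
  p.lx.resize(n); p.ly.resize(n); p.vx.resize(n); p.vy.resize(n);
  p.hx.resize(n); p.hy.resize(n); p.bh.resize(n); p.bw.resize(n);
  p.lx[0] = focal_l[0]; p.ly[0] = focal_l[1];
  p.vx[0] = focal_v[0]; p.vy[0] = focal_v[1];
  p.hx[0] = focal_heading[0]; p.hy[0] = focal_heading[1];
  for (int i = 0; i < p.m; ++i) {
    p.lx[i + 1] = nb_l(i, 0); p.ly[i + 1] = nb_l(i, 1);
    p.vx[i + 1] = nb_v(i, 0); p.vy[i + 1] = nb_v(i, 1);
    p.hx[i + 1] = nb_heading(i, 0); p.hy[i + 1] = nb_heading(i, 1);
  }
  for (int i = 0; i < n; ++i) { p.bh[i] = body_h[i]; p.bw[i] = body_w[i]; }
  return p;
}

// zeta F_t + (1 - zeta) C_t of one patch snapshot.
static double snapshot_cost(const Patch& p, double zeta) {
  const int n = p.m + 1;
  std::vector<double> ang(n);
  for (int i = 0; i < n; ++i) ang[i] = std::atan2(p.hy[i], p.hx[i]);
  const double F = order_metric(ang);
  double C = 0.0;
  if (n >= 2) {
    int pairs = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        const double thr = std::max(p.bh[i] + p.bh[j],
                                    p.bw[i] + p.bw[j]) / 2.0;
        const double dx = p.lx[i] - p.lx[j], dy = p.ly[i] - p.ly[j];
        if (std::sqrt(dx * dx + dy * dy) <= thr) ++pairs;
      }
    C = std::min(1.0, (double)pairs / (double)(n / 2));
  }
  return zeta * F + (1.0 - zeta) * C;
}

// Rollout objective of one gene: mean snapshot cost over t = 0..eta.
static double gene_objective(Patch p, const int* gene, int eta,
                             const NumericMatrix& dirs, double delta,
                             double zeta, bool renorm) {
  double acc = snapshot_cost(p, zeta);
  for (int t = 0; t < eta; ++t) {
    // focal steering update
    const int a = gene[t];
    const double ax = dirs(a, 0), ay = dirs(a, 1);
    const double v0 = std::sqrt(p.vx[0] * p.vx[0] + p.vy[0] * p.vy[0]);
    double nvx = p.vx[0] + delta * ax, nvy = p.vy[0] + delta * ay;
    if (renorm && v0 > 0) {
      const double nv = std::sqrt(nvx * nvx + nvy * nvy);
      if (nv > 0) { nvx *= v0 / nv; nvy *= v0 / nv; }
    }
    p.vx[0] = nvx; p.vy[0] = nvy;
    p.lx[0] += nvx; p.ly[0] += nvy;
    const double sp = std::sqrt(nvx * nvx + nvy * nvy);
    if (sp > 0) { p.hx[0] = nvx / sp; p.hy[0] = nvy / sp; }
    // ballistic neighbours
    for (int i = 1; i <= p.m; ++i) { p.lx[i] += p.vx[i]; p.ly[i] += p.vy[i]; }
    acc += snapshot_cost(p, zeta);
  }
  return acc / (eta + 1);
}

// [[Rcpp::export]]
NumericVector cpp_gene_objectives(NumericVector focal_l, NumericVector focal_v,
                                  NumericVector focal_heading,
                                  NumericMatrix nb_l, NumericMatrix nb_v,
                                  NumericMatrix nb_heading,
                                  NumericVector body_h, NumericVector body_w,
                                  IntegerMatrix genes, NumericMatrix dirs,
                                  double delta, double zeta, bool renorm) {
  const Patch p = make_patch(focal_l, focal_v, focal_heading, nb_l, nb_v,
                             nb_heading, body_h, body_w);
  const int tau = genes.nrow(), eta = genes.ncol();
  NumericVector out(tau);
  std::vector<int> gene(eta);
  for (int i = 0; i < tau; ++i) {
    for (int t = 0; t < eta; ++t) gene[t] = genes(i, t);
    out[i] = gene_objective(p, gene.data(), eta, dirs, delta, zeta, renorm);
  }
  return out;
}

static inline int runif_int(int n) { // uniform on 0..n-1
  int k = (int)std::floor(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// [[Rcpp::export]]
List cpp_plan(NumericVector focal_l, NumericVector focal_v,
              NumericVector focal_heading,
              NumericMatrix nb_l, NumericMatrix nb_v,
              NumericMatrix nb_heading,
              NumericVector body_h, NumericVector body_w,
              NumericMatrix dirs, double delta, double zeta, bool renorm,
              int tau, int generations, int eta, double elite_frac,
              double mut_mean, double mut_sd, bool trace) {
  const Patch patch = make_patch(focal_l, focal_v, focal_heading, nb_l, nb_v,
                                 nb_heading, body_h, body_w);
  const int n_actions = dirs.nrow();
  const int n_elite = std::max(1, (int)std::floor(elite_frac * tau));

  std::vector<std::vector<int> > pop(tau, std::vector<int>(eta));
  for (int i = 0; i < tau; ++i)
    for (int t = 0; t < eta; ++t) pop[i][t] = runif_int(n_actions);

  std::vector<double> obj(tau);
  NumericVector tr_best(trace ? generations : 0),
                tr_mean(trace ? generations : 0);
  std::vector<int> best_gene;
  double best_obj = R_PosInf;

  for (int gen = 0; gen < generations; ++gen) {
    double mean_obj = 0.0;
    for (int i = 0; i < tau; ++i) {
      obj[i] = gene_objective(patch, pop[i].data(), eta, dirs, delta, zeta,
                              renorm);
      mean_obj += obj[i];
      if (obj[i] < best_obj) { best_obj = obj[i]; best_gene = pop[i]; }
    }
    if (trace) { tr_best[gen] = best_obj; tr_mean[gen] = mean_obj / tau; }
    if (gen == generations - 1) break;

    // rank by ascending objective (stable: earlier index wins ties)
    std::vector<int> rank(tau);
    for (int i = 0; i < tau; ++i) rank[i] = i;
    std::stable_sort(rank.begin(), rank.end(),
                     [&](int a, int b) { return obj[a] < obj[b]; });

    std::vector<std::vector<int> > next;
    next.reserve(tau);
    for (int e = 0; e < n_elite; ++e) next.push_back(pop[rank[e]]);

    // fitness-proportionate selection on the complement score
    std::vector<double> wsel(tau);
    double wtot = 0.0;
    for (int i = 0; i < tau; ++i) {
      wsel[i] = std::max(0.0, 1.0 - obj[i]);
      wtot += wsel[i];
    }
    const int n_rest = tau - n_elite;
    std::vector<std::vector<int> > chosen;
    chosen.reserve(n_rest);
    for (int s = 0; s < n_rest; ++s) {
      int pick;
      if (wtot <= 0) pick = runif_int(tau);
      else {
        double u = unif_rand() * wtot, acc = 0.0;
        pick = tau - 1;
        for (int i = 0; i < tau; ++i) {
          acc += wsel[i];
          if (u <= acc) { pick = i; break; }
        }
      }
      chosen.push_back(pop[pick]);
    }
    // single-point crossover on consecutive pairs, cut uniform on [2, eta]
    for (int s = 0; s + 1 < n_rest; s += 2) {
      if (eta >= 2) {
        const int cut = 2 + runif_int(eta - 1); // 1-based cut in [2, eta]
        for (int t = cut - 1; t < eta; ++t)
          std::swap(chosen[s][t], chosen[s + 1][t]);
      }
    }
    // mutation: per-gene probability ~ clipped Normal(mut_mean, mut_sd);
    // one uniformly chosen position replaced by a different action
    for (int s = 0; s < n_rest; ++s) {
      double pmut = mut_mean + mut_sd * norm_rand();
      pmut = std::min(1.0, std::max(0.0, pmut));
      if (unif_rand() < pmut) {
        const int pos = runif_int(eta);
        if (n_actions > 1) {
          int repl = runif_int(n_actions - 1);
          if (repl >= chosen[s][pos]) ++repl;
          chosen[s][pos] = repl;
        }
      }
      next.push_back(chosen[s]);
    }
    pop.swap(next);
  }

  double score = 1.0 - best_obj;
  if (score < 0) score = 0;
  if (score > 1) score = 1;
  List out = List::create(
    _["action"] = best_gene.empty() ? 0 : best_gene[0],
    _["score"] = score,
    _["objective"] = best_obj,
    _["best_gene"] = IntegerVector(best_gene.begin(), best_gene.end()));
  if (trace) {
    out["trace_best"] = tr_best;
    out["trace_mean"] = tr_mean;
  }
  return out;
}
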