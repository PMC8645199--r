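// Reversible-jump MCMC for the multivariate variable-rates Brownian-motion
// model: per-trait ancestral state (alpha, uniform prior) and base rate
// (sigma2, uniform prior), plus a set of branch- or clade-scoped rate
// scalars shared across traits. The likelihood is evaluated by Felsenstein
// pruning on the rescaled tree; contrast structure is cached so alpha /
// sigma2 updates are O(1) and only topology-of-rates changes trigger a
// re-prune.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Shift {
  int slot;       // slot id: edge + scope * n_edge
  double scalar;  // relative-rate multiplier, > 0
};

struct PruneCache {
  double logV;            // sum of log contrast variances + log root variance
  double v_root;          // residual variance at the root
  std::vector<double> s2; // per trait: sum of squared standardized contrasts
  std::vector<double> xroot; // per trait: pruned root value
};

class VRModel {
public:
  int n_tip, n_edge, n_internal, K, n_slots;
  std::vector<double> edge_len;
  // children-first internal-node schedule: child node ids and edge indices
  std::vector<int> nd_id, c1, c2, e1, e2;
  int root;
  std::vector<std::vector<int>> clade_edges; // per edge: edges in its clade
  std::vector<std::vector<double>> traits;   // [node][trait] working values
  std::vector<double> tip_vals;              // n_tip * K, row-major by node
  bool allow_clade, prior_only;

  std::vector<double> rel;      // per-edge relative rate
  std::vector<Shift> shifts;
  std::vector<char> occupied;   // per slot
  PruneCache cache;

  void rebuild_rel() {
    std::fill(rel.begin(), rel.end(), 1.0);
    for (const Shift& s : shifts) {
      int e = s.slot % n_edge, scope = s.slot / n_edge;
      if (scope == 0) {
        rel[e] *= s.scalar;
      } else {
        for (int ee : clade_edges[e]) rel[ee] *= s.scalar;
      }
    }
  }

  // full pruning pass over the rescaled tree; fills `cache`
  void prune() {
    int n_nodes = n_tip + n_internal;
    std::vector<double> vx(n_nodes, 0.0);
    std::vector<std::vector<double>> vals(n_nodes, std::vector<double>(K));
    for (int i = 0; i < n_tip; ++i)
      for (int k = 0; k < K; ++k) vals[i][k] = tip_vals[i * K + k];
    cache.logV = 0.0;
    cache.s2.assign(K, 0.0);
    for (int i = 0; i < n_internal; ++i) {
      int a = c1[i], b = c2[i];
      double v1 = edge_len[e1[i]] * rel[e1[i]] + vx[a];
      double v2 = edge_len[e2[i]] * rel[e2[i]] + vx[b];
      double vs = v1 + v2;
      cache.logV += std::log(vs);
      int nd = nd_id[i];
      double w1 = v2 / vs, w2 = v1 / vs;
      for (int k = 0; k < K; ++k) {
        double diff = vals[a][k] - vals[b][k];
        cache.s2[k] += diff * diff / vs;
        vals[nd][k] = w1 * vals[a][k] + w2 * vals[b][k];
      }
      vx[nd] = v1 * v2 / vs;
    }
    cache.v_root = vx[root];
    cache.logV += std::log(cache.v_root);
    cache.xroot = vals[root];
  }

  // log-likelihood of trait k given cached pruning stats
  double loglik_k(int k, double alpha, double sigma2) const {
    if (prior_only) return 0.0;
    double dev = cache.xroot[k] - alpha;
    return -0.5 * (n_tip * std::log(2.0 * M_PI * sigma2) + cache.logV +
                   (cache.s2[k] + dev * dev / cache.v_root) / sigma2);
  }

  double loglik_all(const std::vector<double>& alpha,
                    const std::vector<double>& sigma2) const {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += loglik_k(k, alpha[k], sigma2[k]);
    return s;
  }
};

double reflect(double v, double lo, double hi) {
  double width = hi - lo, period = 2.0 * width;
  double u = v - lo;
  double t = u - period * std::floor(u / period);  // u mod period, in [0, period)
  return (t <= width) ? lo + t : hi - (t - width);
}

// truncated log-normal draw for a shift magnitude
double draw_scalar(double meanlog, double sdlog, double lo, double hi) {
  for (int tries = 0; tries < 10000; ++tries) {
    double s = std::exp(R::rnorm(meanlog, sdlog));
    if (s > lo && s < hi) return s;
  }
  return std::exp(meanlog);
}

} // namespace

// [[Rcpp::export(name = ".vr_mcmc_cpp")]]
List vr_mcmc_cpp(IntegerMatrix schedule,     // n_internal x 5: node,c1,c2,e1,e2 (1-based)
                 NumericVector edge_len,
                 List clade_edges_r,         // per edge, 1-based edge ids
                 NumericMatrix traits,       // n_tip x K, rows in tip-number order
                 NumericVector alpha_lo, NumericVector alpha_hi,
                 NumericVector sigma2_lo, NumericVector sigma2_hi,
                 double n_iter_d, double burnin_d, int thin,
                 double lambda, double mag_meanlog, double mag_sdlog,
                 double mag_lo, double mag_hi,
                 bool allow_clade, bool prior_only,
                 NumericVector alpha_window, NumericVector sigma2_window,
                 double scalar_walk_sd, NumericVector move_weights) {
  long long n_iter = (long long)n_iter_d, burnin = (long long)burnin_d;
  VRModel m;
  m.n_tip = traits.nrow();
  m.K = traits.ncol();
  m.n_edge = edge_len.size();
  m.n_internal = schedule.nrow();
  m.allow_clade = allow_clade;
  m.prior_only = prior_only;
  m.n_slots = allow_clade ? 2 * m.n_edge : m.n_edge;
  m.edge_len.assign(edge_len.begin(), edge_len.end());
  m.nd_id.resize(m.n_internal); m.c1.resize(m.n_internal); m.c2.resize(m.n_internal);
  m.e1.resize(m.n_internal); m.e2.resize(m.n_internal);
  for (int i = 0; i < m.n_internal; ++i) {
    m.nd_id[i] = schedule(i, 0) - 1;
    m.c1[i] = schedule(i, 1) - 1;
    m.c2[i] = schedule(i, 2) - 1;
    m.e1[i] = schedule(i, 3) - 1;
    m.e2[i] = schedule(i, 4) - 1;
  }
  m.root = m.nd_id[m.n_internal - 1];
  m.clade_edges.resize(m.n_edge);
  for (int e = 0; e < m.n_edge; ++e) {
    IntegerVector ce = clade_edges_r[e];
    m.clade_edges[e].assign(ce.begin(), ce.end());
    for (int& x : m.clade_edges[e]) x -= 1;
  }
  m.tip_vals.resize((size_t)m.n_tip * m.K);
  for (int i = 0; i < m.n_tip; ++i)
    for (int k = 0; k < m.K; ++k) m.tip_vals[i * m.K + k] = traits(i, k);
  m.rel.assign(m.n_edge, 1.0);
  m.occupied.assign(m.n_slots, 0);
  m.prune();

  if (move_weights.size() != 5) stop("need 5 move weights");
  double wsum = 0.0;
  for (double w : move_weights) {
    if (w < 0 || !R_finite(w)) stop("invalid move weights");
    wsum += w;
  }
  if (wsum <= 0) stop("invalid move weights");
  std::vector<double> cumw(5);
  double acc = 0.0;
  for (int i = 0; i < 5; ++i) { acc += move_weights[i] / wsum; cumw[i] = acc; }

  std::vector<double> alpha(m.K), sigma2(m.K);
  for (int k = 0; k < m.K; ++k) {
    alpha[k] = 0.5 * (alpha_lo[k] + alpha_hi[k]);
    sigma2[k] = 0.5 * (sigma2_lo[k] + sigma2_hi[k]);
  }
  double logL = m.loglik_all(alpha, sigma2);

  long long n_samp = (n_iter - burnin) / thin;
  NumericMatrix samp_par(n_samp, 2 + 2 * m.K);
  NumericMatrix samp_rel(n_samp, m.n_edge);
  CharacterVector samp_shifts(n_samp);
  NumericVector samp_iter(n_samp);
  std::vector<long long> prop(5, 0), accn(5, 0);

  long long si = 0;
  for (long long iter = 1; iter <= n_iter; ++iter) {
    double u = R::unif_rand();
    int mv = 4;
    for (int i = 0; i < 5; ++i) if (u <= cumw[i]) { mv = i; break; }
    prop[mv]++;
    int k_shift = (int)m.shifts.size();
    if (mv == 0) { // alpha
      int k = (int)std::floor(R::unif_rand() * m.K);
      double a_new = reflect(alpha[k] + R::runif(-alpha_window[k], alpha_window[k]),
                             alpha_lo[k], alpha_hi[k]);
      double dl = m.loglik_k(k, a_new, sigma2[k]) - m.loglik_k(k, alpha[k], sigma2[k]);
      if (std::log(R::unif_rand()) < dl) { alpha[k] = a_new; logL += dl; accn[mv]++; }
    } else if (mv == 1) { // sigma2
      int k = (int)std::floor(R::unif_rand() * m.K);
      double s_new = reflect(sigma2[k] + R::runif(-sigma2_window[k], sigma2_window[k]),
                             sigma2_lo[k], sigma2_hi[k]);
      if (s_new > 0) {
        double dl = m.loglik_k(k, alpha[k], s_new) - m.loglik_k(k, alpha[k], sigma2[k]);
        if (std::log(R::unif_rand()) < dl) { sigma2[k] = s_new; logL += dl; accn[mv]++; }
      }
    } else if (mv == 2) { // scalar random walk
      if (k_shift > 0) {
        int j = (int)std::floor(R::unif_rand() * k_shift);
        double s_old = m.shifts[j].scalar;
        double s_new = s_old * std::exp(R::rnorm(0.0, scalar_walk_sd));
        if (s_new > mag_lo && s_new < mag_hi) {
          double lo_ratio = // prior ratio (log-normal) + Jacobian of the walk
            (-std::pow(std::log(s_new) - mag_meanlog, 2) +
              std::pow(std::log(s_old) - mag_meanlog, 2)) / (2.0 * mag_sdlog * mag_sdlog);
          m.shifts[j].scalar = s_new;
          m.rebuild_rel();
          PruneCache old_cache = m.cache;
          m.prune();
          double newL = m.loglik_all(alpha, sigma2);
          if (std::log(R::unif_rand()) < newL - logL + lo_ratio) {
            logL = newL; accn[mv]++;
          } else {
            m.shifts[j].scalar = s_old;
            m.rebuild_rel();
            m.cache = old_cache;
          }
        }
      }
    } else if (mv == 3) { // birth
      int n_free = m.n_slots - k_shift;
      if (n_free > 0) {
        int pick = (int)std::floor(R::unif_rand() * n_free), slot = -1;
        for (int s = 0, free_seen = 0; s < m.n_slots; ++s) {
          if (!m.occupied[s] && free_seen++ == pick) { slot = s; break; }
        }
        double sc = draw_scalar(mag_meanlog, mag_sdlog, mag_lo, mag_hi);
        m.shifts.push_back({slot, sc});
        m.rebuild_rel();
        PruneCache old_cache = m.cache;
        m.prune();
        double newL = m.loglik_all(alpha, sigma2);
        double log_acc = newL - logL + std::log(lambda / (k_shift + 1.0));
        if (std::log(R::unif_rand()) < log_acc) {
          logL = newL; m.occupied[slot] = 1; accn[mv]++;
        } else {
          m.shifts.pop_back();
          m.rebuild_rel();
          m.cache = old_cache;
        }
      }
    } else { // death
      if (k_shift > 0) {
        int j = (int)std::floor(R::unif_rand() * k_shift);
        Shift removed = m.shifts[j];
        m.shifts.erase(m.shifts.begin() + j);
        m.rebuild_rel();
        PruneCache old_cache = m.cache;
        m.prune();
        double newL = m.loglik_all(alpha, sigma2);
        double log_acc = newL - logL + std::log(k_shift / lambda);
        if (std::log(R::unif_rand()) < log_acc) {
          logL = newL; m.occupied[removed.slot] = 0; accn[mv]++;
        } else {
          m.shifts.insert(m.shifts.begin() + j, removed);
          m.rebuild_rel();
          m.cache = old_cache;
        }
      }
    }

    if (iter > burnin && (iter - burnin) % thin == 0 && si < n_samp) {
      samp_iter[si] = (double)iter;
      samp_par(si, 0) = logL;
      samp_par(si, 1) = (double)m.shifts.size();
      for (int k = 0; k < m.K; ++k) {
        samp_par(si, 2 + k) = alpha[k];
        samp_par(si, 2 + m.K + k) = sigma2[k];
      }
      for (int e = 0; e < m.n_edge; ++e) samp_rel(si, e) = m.rel[e];
      std::string srep;
      for (const Shift& s : m.shifts) {
        char buf[64];
        snprintf(buf, sizeof(buf), "%d:%s:%.8g;", s.slot % m.n_edge + 1,
                 (s.slot / m.n_edge == 0) ? "branch" : "clade", s.scalar);
        srep += buf;
      }
      samp_shifts[si] = srep;
      ++si;
    }
    if (iter % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector prop_out(5), acc_out(5);
  for (int i = 0; i < 5; ++i) {
    prop_out[i] = (double)prop[i];
    acc_out[i] = (double)accn[i];
  }
  return List::create(
    _["iteration"] = samp_iter,
    _["params"] = samp_par,
    _["rel_rates"] = samp_rel,
    _["shifts"] = samp_shifts,
    _["proposed"] = prop_out,
    _["accepted"] = acc_out);
}

// [[Rcpp::export(name = ".vr_loglik_cpp")]]
double vr_loglik_cpp(IntegerMatrix schedule, NumericVector edge_len,
                     NumericMatrix traits, NumericVector rel,
                     NumericVector alpha, NumericVector sigma2) {
  VRModel m;
  m.n_tip = traits.nrow();
  m.K = traits.ncol();
  m.n_edge = edge_len.size();
  m.n_internal = schedule.nrow();
  m.prior_only = false;
  m.edge_len.assign(edge_len.begin(), edge_len.end());
  m.nd_id.resize(m.n_internal); m.c1.resize(m.n_internal); m.c2.resize(m.n_internal);
  m.e1.resize(m.n_internal); m.e2.resize(m.n_internal);
  for (int i = 0; i < m.n_internal; ++i) {
    m.nd_id[i] = schedule(i, 0) - 1;
    m.c1[i] = schedule(i, 1) - 1;
    m.c2[i] = schedule(i, 2) - 1;
    m.e1[i] = schedule(i, 3) - 1;
    m.e2[i] = schedule(i, 4) - 1;
  }
  m.root = m.nd_id[m.n_internal - 1];
  m.tip_vals.resize((size_t)m.n_tip * m.K);
  for (int i = 0; i < m.n_tip; ++i)
    for (int k = 0; k < m.K; ++k) m.tip_vals[i * m.K + k] = traits(i, k);
  m.rel.assign(rel.begin(), rel.end());
  m.prune();
  std::vector<double> a(alpha.begin(), alpha.end()), s2(sigma2.begin(), sigma2.end());
  return m.loglik_all(a, s2);
}
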