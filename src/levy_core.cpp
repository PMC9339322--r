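// Pruning-algorithm Gaussian likelihood machinery for Brownian / Levy-jump
// trait models, plus the Metropolis-within-sweep sampler over per-branch
// jump counts. Conditional on jump counts n, the Levy model is Brownian
// motion with effective branch lengths t_i + alpha * n_i, so everything
// reduces to O(N) pruning passes; the MCMC updates one branch at a time and
// recomputes only the root-ward path.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct PruneTree {
  int ntip = 0;
  int nnode = 0;                          // total nodes (tips + internals)
  int root = 0;                           // 0-based node id
  int nedge = 0;
  std::vector<int> eparent, echild;       // per edge, 0-based node ids
  std::vector<std::vector<int>> child_edges;  // per node: incident edges below
  std::vector<int> parent_edge;           // per node: edge above, -1 at root
  std::vector<int> postorder;             // internal nodes, children-first
  std::vector<std::vector<int>> eneigh;   // per edge: adjacent edges
  std::vector<int> ndepth;                // per node: topological depth
};

PruneTree build_tree(const IntegerMatrix& edge, int ntip) {
  PruneTree tr;
  tr.ntip = ntip;
  tr.nedge = edge.nrow();
  int mx = 0;
  for (int i = 0; i < tr.nedge; ++i) {
    mx = std::max(mx, std::max(edge(i, 0), edge(i, 1)));
  }
  tr.nnode = mx;
  tr.root = ntip;  // ape convention: root is node ntip+1 (1-based)
  tr.eparent.resize(tr.nedge);
  tr.echild.resize(tr.nedge);
  tr.child_edges.assign(tr.nnode, {});
  tr.parent_edge.assign(tr.nnode, -1);
  for (int i = 0; i < tr.nedge; ++i) {
    int p = edge(i, 0) - 1, c = edge(i, 1) - 1;
    tr.eparent[i] = p;
    tr.echild[i] = c;
    tr.child_edges[p].push_back(i);
    tr.parent_edge[c] = i;
  }
  // iterative postorder over internal nodes
  std::vector<int> stack{tr.root};
  std::vector<int> out;
  out.reserve(tr.nnode - ntip);
  while (!stack.empty()) {
    int u = stack.back();
    stack.pop_back();
    out.push_back(u);
    for (int e : tr.child_edges[u]) {
      int c = tr.echild[e];
      if (c >= ntip) stack.push_back(c);
    }
  }
  tr.postorder.assign(out.rbegin(), out.rend());
  // topological node depths (preorder over the reversed postorder)
  tr.ndepth.assign(tr.nnode, 0);
  for (auto it = tr.postorder.rbegin(); it != tr.postorder.rend(); ++it) {
    for (int e : tr.child_edges[*it]) {
      tr.ndepth[tr.echild[e]] = tr.ndepth[*it] + 1;
    }
  }
  // edge adjacency: edges sharing either endpoint node
  tr.eneigh.assign(tr.nedge, {});
  for (int e = 0; e < tr.nedge; ++e) {
    int p = tr.eparent[e], c = tr.echild[e];
    if (tr.parent_edge[p] != -1) tr.eneigh[e].push_back(tr.parent_edge[p]);
    for (int f : tr.child_edges[p])
      if (f != e) tr.eneigh[e].push_back(f);
    for (int f : tr.child_edges[c]) tr.eneigh[e].push_back(f);
  }
  return tr;
}

// Per-node pruning state. xhat/v: conditional root-state estimate and its
// extra variance; clog/css: this node's contribution to the log-determinant
// and to the scaled quadratic form (sums of contrast terms).
struct PruneState {
  std::vector<double> xhat, v, clog, css;
  double tlog = 0.0, tss = 0.0;  // running totals over internal nodes
  bool ok = true;
  int bad_node = -1;
};

// Combine children of node u sequentially (valid for polytomies too).
inline void recompute_node(const PruneTree& tr, const std::vector<double>& eff,
                           PruneState& st, int u) {
  const std::vector<int>& ce = tr.child_edges[u];
  int e0 = ce[0];
  double X = st.xhat[tr.echild[e0]];
  double V = st.v[tr.echild[e0]] + eff[e0];
  double cl = 0.0, cs = 0.0;
  for (size_t k = 1; k < ce.size(); ++k) {
    int e = ce[k];
    int c = tr.echild[e];
    double Vc = st.v[c] + eff[e];
    double S = V + Vc;
    if (S <= 0.0) {
      st.ok = false;
      st.bad_node = u;
      S = 1e-300;
    }
    double d = X - st.xhat[c];
    cl += std::log(S);
    cs += d * d / S;
    X = (X * Vc + st.xhat[c] * V) / S;
    V = V * Vc / S;
  }
  st.xhat[u] = X;
  st.v[u] = V;
  st.clog[u] = cl;
  st.css[u] = cs;
}

void full_prune(const PruneTree& tr, const std::vector<double>& eff,
                const NumericVector& tipvals, PruneState& st) {
  st.xhat.assign(tr.nnode, 0.0);
  st.v.assign(tr.nnode, 0.0);
  st.clog.assign(tr.nnode, 0.0);
  st.css.assign(tr.nnode, 0.0);
  st.tlog = 0.0;
  st.tss = 0.0;
  st.ok = true;
  st.bad_node = -1;
  for (int i = 0; i < tr.ntip; ++i) st.xhat[i] = tipvals[i];
  for (int u : tr.postorder) {
    recompute_node(tr, eff, st, u);
    st.tlog += st.clog[u];
    st.tss += st.css[u];
  }
}

// Full ML log-likelihood of the tip values given root state x0 and rate
// sigma2, from the pruning totals.
inline double loglik_from_state(const PruneTree& tr, const PruneState& st,
                                double sigma2, double x0) {
  double vr = st.v[tr.root];
  double dx = st.xhat[tr.root] - x0;
  return -0.5 * (tr.ntip * std::log(2.0 * M_PI * sigma2) + st.tlog +
                 std::log(vr) + (st.tss + dx * dx / vr) / sigma2);
}

std::vector<double> as_std(const NumericVector& x) {
  return std::vector<double>(x.begin(), x.end());
}

}  // namespace

// [[Rcpp::export]]
List prune_stats_cpp(IntegerMatrix edge, int ntip, NumericVector eff,
                     NumericVector tipvals) {
  PruneTree tr = build_tree(edge, ntip);
  PruneState st;
  std::vector<double> ef = as_std(eff);
  full_prune(tr, ef, tipvals, st);
  return List::create(
      _["xhat_root"] = st.xhat[tr.root], _["v_root"] = st.v[tr.root],
      _["ss"] = st.tss, _["sumlog"] = st.tlog, _["ok"] = st.ok,
      _["bad_node"] = st.bad_node + 1);
}

// Log-likelihoods for a batch of jump-count configurations (columns).
// [[Rcpp::export]]
NumericVector prune_loglik_batch_cpp(IntegerMatrix edge, int ntip,
                                     NumericVector elen, IntegerMatrix counts,
                                     double alpha, NumericVector tipvals,
                                     double sigma2, double x0) {
  PruneTree tr = build_tree(edge, ntip);
  PruneState st;
  int S = counts.ncol();
  NumericVector out(S);
  std::vector<double> eff(tr.nedge);
  for (int s = 0; s < S; ++s) {
    for (int e = 0; e < tr.nedge; ++e) eff[e] = elen[e] + alpha * counts(e, s);
    full_prune(tr, eff, tipvals, st);
    out[s] = st.ok ? loglik_from_state(tr, st, sigma2, x0) : R_NegInf;
  }
  return out;
}

namespace {

// One Metropolis sweep over all branches at inverse temperature beta on the
// likelihood (beta = 1: the posterior). Proposal: +/-1 with reflection at
// zero (q(0->1)=1, Hastings-corrected). Updates counts, eff and the pruning
// state in place; returns the number of accepted moves.
int mh_sweep(const PruneTree& tr, const std::vector<double>& t,
             const std::vector<double>& logmu, PruneState& st,
             std::vector<int>& n, std::vector<double>& eff, double sigma2,
             double alpha, double x0, double beta, std::vector<int>& path,
             std::vector<double>& sx, std::vector<double>& sv,
             std::vector<double>& scl, std::vector<double>& scs) {
  int ne = tr.nedge;
  int accepted = 0;
  for (int e = 0; e < ne; ++e) {
    if (!std::isfinite(logmu[e])) continue;  // prior forbids jumps here
    int cur = n[e];
    int prop;
    double log_hastings = 0.0;
    if (cur == 0) {
      prop = 1;
      log_hastings = std::log(0.5);  // q(1->0)=1/2 vs q(0->1)=1
    } else {
      prop = (unif_rand() < 0.5) ? cur - 1 : cur + 1;
      if (prop == 0) log_hastings = std::log(2.0);
    }
    // Poisson pmf ratio: P(n+1)/P(n) = mu/(n+1)
    double log_prior = (prop > cur) ? logmu[e] - std::log(double(prop))
                                    : std::log(double(cur)) - logmu[e];
    path.clear();
    sx.clear();
    sv.clear();
    scl.clear();
    scs.clear();
    for (int u = tr.eparent[e]; u != -1;
         u = (tr.parent_edge[u] == -1) ? -1 : tr.eparent[tr.parent_edge[u]]) {
      path.push_back(u);
      sx.push_back(st.xhat[u]);
      sv.push_back(st.v[u]);
      scl.push_back(st.clog[u]);
      scs.push_back(st.css[u]);
    }
    double tlog0 = st.tlog, tss0 = st.tss;
    double ll_cur = loglik_from_state(tr, st, sigma2, x0);
    double eff0 = eff[e];
    eff[e] = t[e] + alpha * prop;
    for (int u : path) {
      st.tlog -= st.clog[u];
      st.tss -= st.css[u];
      recompute_node(tr, eff, st, u);
      st.tlog += st.clog[u];
      st.tss += st.css[u];
    }
    double ll_prop = loglik_from_state(tr, st, sigma2, x0);
    double log_acc = log_prior + beta * (ll_prop - ll_cur) + log_hastings;
    if (std::log(unif_rand()) < log_acc) {
      n[e] = prop;
      ++accepted;
    } else {
      eff[e] = eff0;
      for (size_t k = 0; k < path.size(); ++k) {
        int u = path[k];
        st.xhat[u] = sx[k];
        st.v[u] = sv[k];
        st.clog[u] = scl[k];
        st.css[u] = scs[k];
      }
      st.tlog = tlog0;
      st.tss = tss0;
    }
  }
  return accepted;
}

// Relocation moves: pick an edge uniformly; if it carries a jump, propose
// moving one jump to a uniformly chosen adjacent edge. This lets a jump
// slide between neighbouring branches in one step, which the +/-1 kernel
// can only do through a low-probability intermediate state.
int relocate_attempts(const PruneTree& tr, const std::vector<double>& t,
                      const std::vector<double>& logmu, PruneState& st,
                      std::vector<int>& n, std::vector<double>& eff,
                      double sigma2, double alpha, double x0, double beta,
                      int n_attempts, std::vector<int>& path,
                      std::vector<double>& sx, std::vector<double>& sv,
                      std::vector<double>& scl, std::vector<double>& scs) {
  int ne = tr.nedge;
  int accepted = 0;
  for (int a = 0; a < n_attempts; ++a) {
    int e = int(unif_rand() * ne);
    if (e >= ne) e = ne - 1;
    if (n[e] == 0) continue;
    const std::vector<int>& nb = tr.eneigh[e];
    if (nb.empty()) continue;
    int f = nb[int(unif_rand() * nb.size())];
    if (f == e || !std::isfinite(logmu[f])) continue;
    double log_prior = logmu[f] - std::log(double(n[f] + 1)) +
                       std::log(double(n[e])) - logmu[e];
    double log_hastings = std::log(double(nb.size())) -
                          std::log(double(tr.eneigh[f].size()));
    // union of the two root-ward paths = path from the deeper parent node
    int pe = tr.eparent[e], pf = tr.eparent[f];
    int start = (tr.ndepth[pe] >= tr.ndepth[pf]) ? pe : pf;
    path.clear();
    sx.clear();
    sv.clear();
    scl.clear();
    scs.clear();
    for (int u = start; u != -1;
         u = (tr.parent_edge[u] == -1) ? -1 : tr.eparent[tr.parent_edge[u]]) {
      path.push_back(u);
      sx.push_back(st.xhat[u]);
      sv.push_back(st.v[u]);
      scl.push_back(st.clog[u]);
      scs.push_back(st.css[u]);
    }
    double tlog0 = st.tlog, tss0 = st.tss;
    double ll_cur = loglik_from_state(tr, st, sigma2, x0);
    double eff_e0 = eff[e], eff_f0 = eff[f];
    eff[e] = t[e] + alpha * (n[e] - 1);
    eff[f] = t[f] + alpha * (n[f] + 1);
    for (int u : path) {
      st.tlog -= st.clog[u];
      st.tss -= st.css[u];
      recompute_node(tr, eff, st, u);
      st.tlog += st.clog[u];
      st.tss += st.css[u];
    }
    double ll_prop = loglik_from_state(tr, st, sigma2, x0);
    double log_acc = log_prior + beta * (ll_prop - ll_cur) + log_hastings;
    if (std::log(unif_rand()) < log_acc) {
      n[e] -= 1;
      n[f] += 1;
      ++accepted;
    } else {
      eff[e] = eff_e0;
      eff[f] = eff_f0;
      for (size_t k = 0; k < path.size(); ++k) {
        int u = path[k];
        st.xhat[u] = sx[k];
        st.v[u] = sv[k];
        st.clog[u] = scl[k];
        st.css[u] = scs[k];
      }
      st.tlog = tlog0;
      st.tss = tss0;
    }
  }
  return accepted;
}

std::vector<double> log_poisson_means(const std::vector<double>& t,
                                      double lam) {
  std::vector<double> logmu(t.size());
  for (size_t e = 0; e < t.size(); ++e) {
    double mu = lam * t[e];
    logmu[e] = mu > 0.0 ? std::log(mu) : R_NegInf;
  }
  return logmu;
}

}  // namespace

// Metropolis sampler over per-branch jump counts, parameters fixed
// (empirical Bayes). Returns per-branch posterior probabilities of >=1
// jump and per-sample pruning summaries used by the EM M-step.
// [[Rcpp::export]]
List levy_mcmc_cpp(IntegerMatrix edge, int ntip, NumericVector elen,
                   NumericVector tipvals, double sigma2, double lam,
                   double alpha, double x0, IntegerVector counts_init,
                   int n_sweeps, int burnin, int thin, bool store_samples) {
  PruneTree tr = build_tree(edge, ntip);
  int ne = tr.nedge;
  std::vector<double> t = as_std(elen);
  std::vector<int> n(counts_init.begin(), counts_init.end());
  std::vector<double> eff(ne);
  for (int e = 0; e < ne; ++e) eff[e] = t[e] + alpha * n[e];
  PruneState st;
  full_prune(tr, eff, tipvals, st);
  if (!st.ok)
    stop("singular pruning state at node %d: zero-variance contrast",
         st.bad_node + 1);
  std::vector<double> logmu = log_poisson_means(t, lam);

  int n_keep = (n_sweeps - burnin + thin - 1) / thin;
  if (n_keep < 1) stop("n_sweeps must exceed burnin");
  NumericMatrix samples(store_samples ? 5 : 0, store_samples ? n_keep : 0);
  std::vector<double> pp(ne, 0.0), pp1(ne, 0.0), pp2(ne, 0.0);
  int kept = 0, half = n_keep / 2;
  long accepted = 0, proposed = 0;
  std::vector<int> path;
  std::vector<double> sx, sv, scl, scs;

  int n_reloc = std::max(1, ne / 2);
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    accepted += mh_sweep(tr, t, logmu, st, n, eff, sigma2, alpha, x0, 1.0,
                         path, sx, sv, scl, scs);
    relocate_attempts(tr, t, logmu, st, n, eff, sigma2, alpha, x0, 1.0,
                      n_reloc, path, sx, sv, scl, scs);
    proposed += ne;
    if ((sweep + 1) % 128 == 0) full_prune(tr, eff, tipvals, st);  // kill drift
    if (sweep >= burnin && (sweep - burnin) % thin == 0) {
      int tot = 0;
      for (int e = 0; e < ne; ++e) {
        if (n[e] >= 1) {
          pp[e] += 1.0;
          if (kept < half) pp1[e] += 1.0; else pp2[e] += 1.0;
        }
        tot += n[e];
      }
      if (store_samples) {
        samples(0, kept) = tot;
        samples(1, kept) = st.xhat[tr.root];
        samples(2, kept) = st.v[tr.root];
        samples(3, kept) = st.tss;
        samples(4, kept) = st.tlog;
      }
      ++kept;
    }
  }
  NumericVector ppv(ne), ppv1(ne), ppv2(ne);
  for (int e = 0; e < ne; ++e) {
    ppv[e] = pp[e] / kept;
    ppv1[e] = half > 0 ? pp1[e] / half : NA_REAL;
    ppv2[e] = (kept - half) > 0 ? pp2[e] / (kept - half) : NA_REAL;
  }
  return List::create(
      _["pp"] = ppv, _["pp_first"] = ppv1, _["pp_second"] = ppv2,
      _["samples"] = samples, _["counts"] = IntegerVector(n.begin(), n.end()),
      _["accept_rate"] = proposed ? double(accepted) / proposed : NA_REAL,
      _["n_kept"] = kept);
}

// Annealed importance sampling for the marginal log-likelihood: each
// particle starts from the Poisson prior and is moved through a geometric
// ladder of likelihood-tempered distributions (beta_k = (k/K)^2, finer
// near the prior) with `sweeps_per_temp` Metropolis sweeps at each rung.
// Returns the per-particle log-weights log w_s; log Z = log mean exp(w).
// [[Rcpp::export]]
NumericVector levy_ais_cpp(IntegerMatrix edge, int ntip, NumericVector elen,
                           NumericVector tipvals, double sigma2, double lam,
                           double alpha, double x0, int n_particles,
                           int n_temps, int sweeps_per_temp) {
  PruneTree tr = build_tree(edge, ntip);
  int ne = tr.nedge;
  std::vector<double> t = as_std(elen);
  std::vector<double> logmu = log_poisson_means(t, lam);
  NumericVector logw(n_particles);
  std::vector<int> n(ne), path;
  std::vector<double> eff(ne), sx, sv, scl, scs;
  PruneState st;
  for (int s = 0; s < n_particles; ++s) {
    for (int e = 0; e < ne; ++e) {
      double mu = lam * t[e];
      n[e] = mu > 0.0 ? int(R::rpois(mu)) : 0;
      eff[e] = t[e] + alpha * n[e];
    }
    full_prune(tr, eff, tipvals, st);
    if (!st.ok)
      stop("singular pruning state at node %d", st.bad_node + 1);
    double w = 0.0, beta_prev = 0.0;
    for (int k = 1; k <= n_temps; ++k) {
      double beta = std::pow(double(k) / n_temps, 2.0);
      w += (beta - beta_prev) * loglik_from_state(tr, st, sigma2, x0);
      for (int r = 0; r < sweeps_per_temp; ++r) {
        mh_sweep(tr, t, logmu, st, n, eff, sigma2, alpha, x0, beta, path, sx,
                 sv, scl, scs);
        relocate_attempts(tr, t, logmu, st, n, eff, sigma2, alpha, x0, beta,
                          std::max(1, ne / 2), path, sx, sv, scl, scs);
      }
      full_prune(tr, eff, tipvals, st);  // keep totals drift-free per rung
      beta_prev = beta;
    }
    logw[s] = w;
  }
  return logw;
}
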