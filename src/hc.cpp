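// Gaussian Bayesian network structure learning by greedy hill climbing on
// the decomposable BIC score. The scorer works from the column-centred
// scatter matrix S = Xc' Xc of the n x p data matrix, so a family score is
// one small symmetric solve; add/delete move deltas are cached per child and
// invalidated only when that child's parent set changes. Ties between moves
// are broken by scan order: (parent, child) lexicographic, move type
// add < delete < reverse.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double EPS_IMPROVE = 1e-9;

// BIC family score: OLS of child on parents with intercept; Gaussian
// log-likelihood at the MLE residual variance minus ((k+2)/2) log n
// (k coefficients + intercept + variance). Singular or exactly-fitting
// designs are disallowed (-Inf).
static double family_score(const arma::mat& S, int n, int child,
                           const std::vector<int>& parents) {
  const double scc = S(child, child);
  double rss;
  const int k = (int)parents.size();
  if (n < k + 2) return NEG_INF;
  if (k == 0) {
    rss = scc;
  } else {
    arma::uvec P(k);
    for (int i = 0; i < k; ++i) P[i] = (arma::uword)parents[i];
    arma::uvec C(1);
    C[0] = (arma::uword)child;
    arma::mat Spp = S.submat(P, P);
    arma::vec spc = arma::vectorise(S.submat(P, C));
    arma::vec beta;
    bool ok = arma::solve(beta, Spp, spc,
                          arma::solve_opts::no_approx + arma::solve_opts::likely_sympd);
    if (!ok) return NEG_INF;
    rss = scc - arma::dot(spc, beta);
  }
  if (!(rss > std::max(1e-12, 1e-9 * std::abs(scc)))) return NEG_INF;
  const double loglik = -0.5 * n * (std::log(2.0 * M_PI * rss / n) + 1.0);
  return loglik - 0.5 * (k + 2) * std::log((double)n);
}

// path existence (length >= 1) from every node, by DFS over the adjacency
static void reachability(const std::vector<std::vector<int>>& adj, int p,
                         std::vector<std::vector<bool>>& R) {
  std::vector<int> stack;
  for (int s = 0; s < p; ++s) {
    std::fill(R[s].begin(), R[s].end(), false);
    stack.clear();
    for (int w : adj[s]) stack.push_back(w);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      if (R[s][v]) continue;
      R[s][v] = true;
      for (int w : adj[v]) if (!R[s][w]) stack.push_back(w);
    }
  }
}

// Greedy hill climbing, optionally followed through flat/degrading stretches
// by a tabu phase: when no move improves, the best non-tabu move is applied
// anyway (its inverse joining a fixed-length tabu ring so the walk cannot
// immediately undo itself), the best structure ever visited is kept, and the
// walk stops after max_stall consecutive moves without a new best. tabu_len
// = 0 gives plain greedy ascent.
// [[Rcpp::export]]
IntegerMatrix hc_gaussian_cpp(const arma::mat& S, int n, int max_parents,
                              int tabu_len = 10, int max_stall = 10) {
  const int p = (int)S.n_rows;
  IntegerMatrix A(p, p);
  if (p < 2) return A;

  std::vector<std::vector<int>> pa(p), adj(p);
  std::vector<double> fs(p);
  std::vector<int> none;
  for (int j = 0; j < p; ++j) fs[j] = family_score(S, n, j, none);

  arma::mat Dadd(p, p), Ddel(p, p);
  Dadd.fill(NEG_INF);
  Ddel.fill(NEG_INF);
  std::vector<bool> dirty(p, true);
  std::vector<std::vector<bool>> R(p, std::vector<bool>(p, false));

  auto refresh_child = [&](int j) {
    std::vector<int> cand;
    for (int i = 0; i < p; ++i) {
      Dadd(i, j) = NEG_INF;
      Ddel(i, j) = NEG_INF;
    }
    if ((int)pa[j].size() < max_parents) {
      for (int i = 0; i < p; ++i) {
        if (i == j || A(i, j)) continue;
        cand = pa[j];
        cand.push_back(i);
        Dadd(i, j) = family_score(S, n, j, cand) - fs[j];
      }
    }
    for (int i : pa[j]) {
      cand.clear();
      for (int q : pa[j]) if (q != i) cand.push_back(q);
      Ddel(i, j) = family_score(S, n, j, cand) - fs[j];
    }
  };

  double cur = 0.0, best_score;
  for (int j = 0; j < p; ++j) cur += fs[j];
  best_score = cur;
  std::vector<int> bestA(p * p, 0);

  // tabu ring of inverse-move codes; code = (type * p + i) * p + j
  std::vector<long long> ring(std::max(tabu_len, 1), -1);
  int ring_pos = 0;
  auto code_of = [&](int type, int i, int j) {
    return ((long long)type * p + i) * p + j;
  };
  auto is_tabu = [&](int type, int i, int j) {
    if (tabu_len == 0) return false;
    long long c = code_of(type, i, j);
    for (int k = 0; k < tabu_len; ++k) if (ring[k] == c) return true;
    return false;
  };
  auto push_inverse = [&](int type, int i, int j) {
    if (tabu_len == 0) return;
    long long inv = type == 0 ? code_of(1, i, j)
                  : type == 1 ? code_of(0, i, j)
                              : code_of(2, j, i);
    ring[ring_pos] = inv;
    ring_pos = (ring_pos + 1) % tabu_len;
  };

  int stall = 0;
  for (;;) {
    for (int j = 0; j < p; ++j)
      if (dirty[j]) { refresh_child(j); dirty[j] = false; }
    reachability(adj, p, R);

    double best = -std::numeric_limits<double>::infinity();
    int bi = -1, bj = -1, btype = -1; // 0 add, 1 delete, 2 reverse
    for (int i = 0; i < p; ++i) {
      for (int j = 0; j < p; ++j) {
        if (i == j) continue;
        if (!A(i, j)) {
          // add i -> j: needs no path j ~> i
          double d = Dadd(i, j);
          if (std::isfinite(d) && d > best && !R[j][i] && !is_tabu(0, i, j)) {
            best = d; bi = i; bj = j; btype = 0;
          }
        } else {
          // delete i -> j
          double d = Ddel(i, j);
          if (std::isfinite(d) && d > best && !is_tabu(1, i, j)) {
            best = d; bi = i; bj = j; btype = 1;
          }
          // reverse i -> j: cycle iff a path i ~> j survives removing the
          // direct arc, i.e. some other out-neighbour k of i reaches j
          // (k, a descendant of i, cannot reach i in a DAG, so R[k][j]
          // never relies on the arc being removed)
          if ((int)pa[i].size() < max_parents) {
            double dr = Ddel(i, j) + Dadd(j, i);
            if (std::isfinite(dr) && dr > best && !is_tabu(2, i, j)) {
              bool cycle = false;
              for (int k = 0; k < p; ++k) {
                if (k == j || !A(i, k)) continue;
                if (R[k][j]) { cycle = true; break; }
              }
              if (!cycle) { best = dr; bi = i; bj = j; btype = 2; }
            }
          }
        }
      }
    }
    // stop at a local optimum when the tabu phase is disabled
    if (bi < 0 || (tabu_len == 0 && best <= EPS_IMPROVE)) break;

    if (btype == 0) {
      fs[bj] += Dadd(bi, bj);
      A(bi, bj) = 1;
      pa[bj].push_back(bi);
      adj[bi].push_back(bj);
      dirty[bj] = true;
    } else if (btype == 1) {
      fs[bj] += Ddel(bi, bj);
      A(bi, bj) = 0;
      pa[bj].erase(std::find(pa[bj].begin(), pa[bj].end(), bi));
      adj[bi].erase(std::find(adj[bi].begin(), adj[bi].end(), bj));
      dirty[bj] = true;
    } else {
      fs[bj] += Ddel(bi, bj);
      fs[bi] += Dadd(bj, bi);
      A(bi, bj) = 0;
      A(bj, bi) = 1;
      pa[bj].erase(std::find(pa[bj].begin(), pa[bj].end(), bi));
      adj[bi].erase(std::find(adj[bi].begin(), adj[bi].end(), bj));
      pa[bi].push_back(bj);
      adj[bj].push_back(bi);
      dirty[bi] = true;
      dirty[bj] = true;
    }
    push_inverse(btype, bi, bj);
    cur += best;

    if (cur > best_score + EPS_IMPROVE) {
      best_score = cur;
      for (int i = 0; i < p; ++i)
        for (int j = 0; j < p; ++j) bestA[i * p + j] = A(i, j);
      stall = 0;
    } else {
      if (++stall >= max_stall) break;
    }
  }

  if (best_score > cur + EPS_IMPROVE || stall > 0) {
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j) A(i, j) = bestA[i * p + j];
  }
  return A;
}
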