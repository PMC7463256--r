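// Felsenstein pruning for HKY+G on time-trees, with per-node partial caching.
//
// The MCMC driver in R owns proposal logic; this engine only recomputes the
// conditional likelihood vectors of internal nodes named in `dirty` (which
// must include every ancestor of any changed branch). Rejected proposals are
// rolled back from a backup of the overwritten blocks, so the cached state
// always matches the last accepted tree.
//
// Partials are stored pattern-major ([node][category][state][pattern]) so
// the per-pattern inner loops are unit-stride and vectorise.
//
// Node numbering follows ape: tips 1..n, internal n+1..2n-1, root n+1.
// Tip states: 0..3 = A,C,G,T; 4 = missing (N or gap).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct PlikState {
  int ntip, nint, npat, ncat;
  std::vector<int> tip_codes;      // ntip x npat, row-major [tip][pat]
  std::vector<double> weights;     // npat
  std::vector<double> partials;    // nint x ncat x 4 x npat
  std::vector<double> backup;      // same layout, blocks for dirty nodes
  std::vector<int> backup_nodes;   // internal node ids saved in `backup`
  // cached topology (rebuilt on demand)
  bool topo_built;
  std::vector<int> child1, child2, edge_of, postorder;
  double loglik_cur, loglik_prop;
  bool pending;

  inline double* block(int node) {  // node in n+1..2n-1
    return partials.data() + (size_t)(node - ntip - 1) * ncat * 4 * npat;
  }
  inline double* backup_block(int slot) {
    return backup.data() + (size_t)slot * ncat * 4 * npat;
  }
  size_t block_size() const { return (size_t)ncat * 4 * npat; }
};

// [[Rcpp::export]]
SEXP plik_init(IntegerMatrix tip_codes, NumericVector weights, int ncat) {
  PlikState* st = new PlikState();
  st->ntip = tip_codes.nrow();
  st->nint = st->ntip - 1;
  st->npat = tip_codes.ncol();
  st->ncat = ncat;
  st->tip_codes.resize((size_t)st->ntip * st->npat);
  for (int i = 0; i < st->ntip; ++i)
    for (int p = 0; p < st->npat; ++p)
      st->tip_codes[(size_t)i * st->npat + p] = tip_codes(i, p);
  st->weights.assign(weights.begin(), weights.end());
  st->partials.assign((size_t)st->nint * st->ncat * 4 * st->npat, 0.0);
  st->backup.assign((size_t)st->nint * st->ncat * 4 * st->npat, 0.0);
  st->topo_built = false;
  st->loglik_cur = R_NegInf;
  st->loglik_prop = R_NegInf;
  st->pending = false;
  XPtr<PlikState> ptr(st, true);
  return ptr;
}

static void hky_pmat(const double* U, const double* Uinv, const double* evals,
                     double d, double* P) {
  // P = U diag(exp(evals * d)) Uinv; U/Uinv column-major from R
  double e[4];
  for (int k = 0; k < 4; ++k) e[k] = std::exp(evals[k] * d);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      double s = 0.0;
      for (int k = 0; k < 4; ++k)
        s += U[i + 4 * k] * e[k] * Uinv[k + 4 * j];
      P[4 * i + j] = s > 0.0 ? s : 0.0;  // row-major, clipped
    }
}

static void build_topology(PlikState* st, const IntegerMatrix& edge) {
  const int n = st->ntip, nnode = 2 * n - 1, nedge = edge.nrow();
  st->child1.assign(nnode + 1, 0);
  st->child2.assign(nnode + 1, 0);
  st->edge_of.assign(nnode + 1, -1);
  for (int e = 0; e < nedge; ++e) {
    int p = edge(e, 0), c = edge(e, 1);
    st->edge_of[c] = e;
    if (st->child1[p] == 0) st->child1[p] = c; else st->child2[p] = c;
  }
  st->postorder.clear();
  std::vector<int> stack, order;
  stack.push_back(n + 1);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    order.push_back(v);
    if (v > n) { stack.push_back(st->child1[v]); stack.push_back(st->child2[v]); }
  }
  for (int i = (int)order.size() - 1; i >= 0; --i)
    if (order[i] > n) st->postorder.push_back(order[i]);
  st->topo_built = true;
}

// multiply child contribution into m[4][npat]; first child initialises
template <bool FIRST>
static void child_contrib(const PlikState* st, int child, int cat,
                          const double* P, double* m, int npat,
                          const double* child_block, const int* tipc) {
  if (tipc) {
    double tab[4][5];
    for (int i = 0; i < 4; ++i) {
      for (int b = 0; b < 4; ++b) tab[i][b] = P[4 * i + b];
      tab[i][4] = 1.0;
    }
    for (int i = 0; i < 4; ++i) {
      double* mi = m + (size_t)i * npat;
      const double* ti = tab[i];
      if (FIRST) for (int p = 0; p < npat; ++p) mi[p] = ti[tipc[p]];
      else       for (int p = 0; p < npat; ++p) mi[p] *= ti[tipc[p]];
    }
  } else {
    const double* L0 = child_block + (size_t)cat * 4 * npat;
    const double* L1 = L0 + npat;
    const double* L2 = L0 + 2 * npat;
    const double* L3 = L0 + 3 * npat;
    for (int i = 0; i < 4; ++i) {
      double* mi = m + (size_t)i * npat;
      const double a = P[4 * i], b = P[4 * i + 1], c = P[4 * i + 2],
                   d = P[4 * i + 3];
      if (FIRST)
        for (int p = 0; p < npat; ++p)
          mi[p] = a * L0[p] + b * L1[p] + c * L2[p] + d * L3[p];
      else
        for (int p = 0; p < npat; ++p)
          mi[p] *= a * L0[p] + b * L1[p] + c * L2[p] + d * L3[p];
    }
  }
}

// [[Rcpp::export]]
double plik_eval(SEXP ptr_, IntegerMatrix edge, NumericMatrix subs,
                 NumericMatrix U, NumericMatrix Uinv, NumericVector evals,
                 NumericVector pi, IntegerVector dirty, bool rebuild = false) {
  XPtr<PlikState> ptr(ptr_);
  PlikState* st = ptr.get();
  if (st->pending) stop("plik_eval called with a pending proposal");
  const int n = st->ntip, npat = st->npat, ncat = st->ncat;
  const int nnode = 2 * n - 1;

  if (npat == 0) {  // empty alignment: likelihood 1
    st->loglik_prop = 0.0;
    st->pending = true;
    st->backup_nodes.clear();
    return 0.0;
  }
  if (rebuild || !st->topo_built) build_topology(st, edge);

  std::vector<char> is_dirty(nnode + 1, 0);
  for (int i = 0; i < dirty.size(); ++i) {
    int v = dirty[i];
    if (v <= n || v > nnode) stop("dirty must contain internal node ids");
    is_dirty[v] = 1;
  }

  // back up blocks that will be overwritten
  st->backup_nodes.clear();
  for (int v : st->postorder) {
    if (!is_dirty[v]) continue;
    int slot = (int)st->backup_nodes.size();
    std::copy(st->block(v), st->block(v) + st->block_size(),
              st->backup_block(slot));
    st->backup_nodes.push_back(v);
  }

  const double* Up = U.begin();
  const double* Uip = Uinv.begin();
  const double* ev = evals.begin();
  double P1[16], P2[16];

  for (int v : st->postorder) {
    if (!is_dirty[v]) continue;
    const int c1 = st->child1[v], c2 = st->child2[v];
    double* L = st->block(v);
    const double* b1 = (c1 > n) ? st->block(c1) : nullptr;
    const double* b2 = (c2 > n) ? st->block(c2) : nullptr;
    const int* t1 = (c1 <= n) ? &st->tip_codes[(size_t)(c1 - 1) * npat] : nullptr;
    const int* t2 = (c2 <= n) ? &st->tip_codes[(size_t)(c2 - 1) * npat] : nullptr;
    for (int cat = 0; cat < ncat; ++cat) {
      hky_pmat(Up, Uip, ev, subs(st->edge_of[c1], cat), P1);
      hky_pmat(Up, Uip, ev, subs(st->edge_of[c2], cat), P2);
      double* m = L + (size_t)cat * 4 * npat;
      child_contrib<true>(st, c1, cat, P1, m, npat, b1, t1);
      child_contrib<false>(st, c2, cat, P2, m, npat, b2, t2);
    }
  }

  // log-likelihood at the root, averaging gamma categories with equal weight
  const double* Lr = st->block(n + 1);
  std::vector<double> site(npat, 0.0);
  for (int cat = 0; cat < ncat; ++cat) {
    for (int i = 0; i < 4; ++i) {
      const double* l = Lr + (size_t)cat * 4 * npat + (size_t)i * npat;
      const double w = pi[i];
      for (int p = 0; p < npat; ++p) site[p] += w * l[p];
    }
  }
  double ll = 0.0;
  for (int p = 0; p < npat; ++p) {
    if (site[p] <= 0.0) { ll = R_NegInf; break; }
    ll += st->weights[p] * std::log(site[p] / ncat);
  }
  st->loglik_prop = ll;
  st->pending = true;
  return ll;
}

// [[Rcpp::export]]
void plik_accept(SEXP ptr_) {
  XPtr<PlikState> ptr(ptr_);
  PlikState* st = ptr.get();
  if (!st->pending) stop("no pending proposal to accept");
  st->loglik_cur = st->loglik_prop;
  st->backup_nodes.clear();
  st->pending = false;
}

// [[Rcpp::export]]
void plik_reject(SEXP ptr_) {
  XPtr<PlikState> ptr(ptr_);
  PlikState* st = ptr.get();
  if (!st->pending) stop("no pending proposal to reject");
  for (int slot = 0; slot < (int)st->backup_nodes.size(); ++slot) {
    int v = st->backup_nodes[slot];
    std::copy(st->backup_block(slot), st->backup_block(slot) + st->block_size(),
              st->block(v));
  }
  st->backup_nodes.clear();
  st->pending = false;
}

// [[Rcpp::export]]
double plik_current(SEXP ptr_) {
  XPtr<PlikState> ptr(ptr_);
  return ptr.get()->loglik_cur;
}
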