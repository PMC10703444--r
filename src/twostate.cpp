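#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Closed-form transition kernel of the two-state CTMC with generator
// Q = [[-q01, q01], [q10, -q10]]:  P(t) = exp(Qt).
static inline void pmat(double q01, double q10, double t, double P[2][2]) {
  double q = q01 + q10;
  if (t <= 0.0 || q <= 0.0) {
    P[0][0] = 1.0; P[0][1] = 0.0; P[1][0] = 0.0; P[1][1] = 1.0;
    return;
  }
  double pi1 = q01 / q, pi0 = q10 / q;
  double e = std::exp(-q * t);
  P[0][0] = pi0 + pi1 * e;
  P[0][1] = pi1 * (1.0 - e);
  P[1][0] = pi0 * (1.0 - e);
  P[1][1] = pi1 + pi0 * e;
}

// Post-order conditional (subtree) likelihoods at every node, with
// per-node rescaling.  Edges must be in postorder (children before parents).
// Returns the accumulated log scale factor.
static double backward_partials(const IntegerVector& parent,
                                const IntegerVector& child,
                                const NumericVector& elen,
                                int ntip, int nnodes,
                                const IntegerVector& tip_state,
                                double q01, double q10,
                                std::vector<double>& L) {
  L.assign(2 * (size_t)nnodes, 1.0);
  for (int i = 0; i < ntip; ++i) {
    int s = tip_state[i];
    if (s != 0 && s != 1) stop("tip states must be 0 or 1");
    L[2 * i]     = (s == 0) ? 1.0 : 0.0;
    L[2 * i + 1] = (s == 1) ? 1.0 : 0.0;
  }
  double logscale = 0.0;
  int ne = parent.size();
  double P[2][2];
  for (int e = 0; e < ne; ++e) {
    int p = parent[e] - 1, c = child[e] - 1;
    pmat(q01, q10, elen[e], P);
    double m0 = P[0][0] * L[2 * c] + P[0][1] * L[2 * c + 1];
    double m1 = P[1][0] * L[2 * c] + P[1][1] * L[2 * c + 1];
    L[2 * p]     *= m0;
    L[2 * p + 1] *= m1;
    double mx = std::max(L[2 * p], L[2 * p + 1]);
    if (mx > 0.0 && mx < 1e-280) {
      L[2 * p] /= mx; L[2 * p + 1] /= mx;
      logscale += std::log(mx);
    }
  }
  return logscale;
}

// [[Rcpp::export]]
double cpp_pruning_loglik(IntegerVector parent, IntegerVector child,
                          NumericVector elen, int ntip, int nnodes, int root,
                          IntegerVector tip_state, double q01, double q10,
                          NumericVector prior) {
  std::vector<double> L;
  double logscale = backward_partials(parent, child, elen, ntip, nnodes,
                                      tip_state, q01, q10, L);
  int r = root - 1;
  double lik = prior[0] * L[2 * r] + prior[1] * L[2 * r + 1];
  if (!(lik > 0.0)) return R_NegInf;
  return std::log(lik) + logscale;
}

static inline int sample2(double w0, double w1) {
  double s = w0 + w1;
  if (!(s > 0.0)) stop("degenerate sampling weights (structural zero)");
  return (unif_rand() * s < w0) ? 0 : 1;
}

// Node states from the joint conditional distribution given the tips:
// backward pruning partials, then pre-order forward sampling.
static void sample_states_conditional(const IntegerVector& parent,
                                      const IntegerVector& child,
                                      const NumericVector& elen,
                                      int root,
                                      const NumericVector& prior,
                                      double q01, double q10,
                                      const std::vector<double>& L,
                                      std::vector<int>& st) {
  int ne = parent.size();
  int r = root - 1;
  st[r] = sample2(prior[0] * L[2 * r], prior[1] * L[2 * r + 1]);
  double P[2][2];
  for (int e = ne - 1; e >= 0; --e) {   // reverse postorder = preorder
    int p = parent[e] - 1, c = child[e] - 1;
    pmat(q01, q10, elen[e], P);
    int a = st[p];
    st[c] = sample2(P[a][0] * L[2 * c], P[a][1] * L[2 * c + 1]);
  }
}

// Node states under the unconditional (constant-rate null) process.
static void sample_states_unconditional(const IntegerVector& parent,
                                        const IntegerVector& child,
                                        const NumericVector& elen,
                                        int root,
                                        const NumericVector& prior,
                                        double q01, double q10,
                                        std::vector<int>& st) {
  int ne = parent.size();
  int r = root - 1;
  st[r] = sample2(prior[0], prior[1]);
  double P[2][2];
  for (int e = ne - 1; e >= 0; --e) {
    int p = parent[e] - 1, c = child[e] - 1;
    pmat(q01, q10, elen[e], P);
    int a = st[p];
    st[c] = sample2(P[a][0], P[a][1]);
  }
}

// Endpoint-conditioned path on one branch by uniformization with
// dominating rate mu = max(q01, q10) * (1 + eps).  Fills offsets (from the
// parent end) and the state entered at each real transition; returns the
// number of real transitions.  Virtual (self) jumps are discarded.
static int sample_bridge(double q01, double q10, double t, int a, int b,
                         std::vector<double>& times, std::vector<int>& states) {
  times.clear(); states.clear();
  if (t <= 0.0) {
    if (a != b) stop("zero-length branch with differing endpoint states");
    return 0;
  }
  double q = q01 + q10;
  if (q <= 0.0) return 0;
  double mu = std::max(q01, q10) * (1.0 + 1e-6);
  double pi1 = q01 / q, pi0 = q10 / q;
  double lam = 1.0 - q / mu;       // second eigenvalue of R = I + Q/mu
  double P[2][2];
  pmat(q01, q10, t, P);
  double pab = P[a][b];

  // R^m entries in closed form (shares eigenvectors with P(t))
  struct RnFun {
    double pi0, pi1, lam;
    double operator()(int m, int i, int j) const {
      double lm = (m == 0) ? 1.0 : std::pow(lam, (double)m);
      if (i == 0) return (j == 0) ? pi0 + pi1 * lm : pi1 * (1.0 - lm);
      return (j == 0) ? pi0 * (1.0 - lm) : pi1 + pi0 * lm;
    }
  } Rn = {pi0, pi1, lam};

  // number of uniformized jumps: p(n) ∝ Pois(n; mu t) * R^n[a,b]
  double u = unif_rand() * pab;
  double mt = mu * t;
  double pois = std::exp(-mt);
  double cum = 0.0;
  int n = 0;
  const int NMAX = 1000000;
  for (;; ++n) {
    cum += pois * Rn(n, a, b);
    if (cum >= u || n >= NMAX) break;
    pois *= mt / (double)(n + 1);
  }
  if (n >= NMAX) stop("uniformization failed to terminate (numerical)");
  if (n == 0) return 0;

  std::vector<double> tt(n);
  for (int k = 0; k < n; ++k) tt[k] = unif_rand() * t;
  std::sort(tt.begin(), tt.end());

  double R1[2][2] = {{1.0 - q01 / mu, q01 / mu}, {q10 / mu, 1.0 - q10 / mu}};
  int cur = a;
  for (int k = 1; k <= n; ++k) {
    int rem = n - k;
    double w0 = R1[cur][0] * Rn(rem, 0, b);
    double w1 = R1[cur][1] * Rn(rem, 1, b);
    int s = sample2(w0, w1);
    if (s != cur) {
      times.push_back(tt[k - 1]);
      states.push_back(s);
    }
    cur = s;
  }
  return (int)times.size();
}

// Forward (Gillespie) simulation along one branch from state a; records
// real transitions and returns the end state.
static int sim_forward(double q01, double q10, double t, int a,
                       std::vector<double>& times, std::vector<int>& states) {
  times.clear(); states.clear();
  int s = a;
  double tau = 0.0;
  for (;;) {
    double rate = (s == 0) ? q01 : q10;
    if (rate <= 0.0) break;
    tau += exp_rand() / rate;
    if (tau >= t) break;
    s = 1 - s;
    times.push_back(tau);
    states.push_back(s);
  }
  return s;
}

// Full mapped history: node states plus ordered transition events per branch.
// conditional = true -> stochastic mapping given tip states (backward-forward
// + uniformization bridges); false -> forward simulation from the root prior.
// [[Rcpp::export]]
List cpp_sample_history(IntegerVector parent, IntegerVector child,
                        NumericVector elen, int ntip, int nnodes, int root,
                        IntegerVector tip_state, double q01, double q10,
                        NumericVector prior, bool conditional) {
  int ne = parent.size();
  std::vector<int> st(nnodes, -1);
  std::vector<int> ev_edge, ev_state;
  std::vector<double> ev_time;
  std::vector<double> tbuf; std::vector<int> sbuf;

  if (conditional) {
    std::vector<double> L;
    backward_partials(parent, child, elen, ntip, nnodes, tip_state, q01, q10, L);
    sample_states_conditional(parent, child, elen, root, prior, q01, q10, L, st);
    for (int i = 0; i < ntip; ++i)
      if (st[i] != tip_state[i]) stop("internal error: sampled history contradicts tip data");
    for (int e = 0; e < ne; ++e) {
      int a = st[parent[e] - 1], b = st[child[e] - 1];
      sample_bridge(q01, q10, elen[e], a, b, tbuf, sbuf);
      for (size_t k = 0; k < tbuf.size(); ++k) {
        ev_edge.push_back(e + 1);
        ev_time.push_back(tbuf[k]);
        ev_state.push_back(sbuf[k]);
      }
    }
  } else {
    int r = root - 1;
    st[r] = sample2(prior[0], prior[1]);
    for (int e = ne - 1; e >= 0; --e) {  // preorder walk down the tree
      int p = parent[e] - 1, c = child[e] - 1;
      st[c] = sim_forward(q01, q10, elen[e], st[p], tbuf, sbuf);
      for (size_t k = 0; k < tbuf.size(); ++k) {
        ev_edge.push_back(e + 1);
        ev_time.push_back(tbuf[k]);
        ev_state.push_back(sbuf[k]);
      }
    }
  }
  return List::create(_["node_state"] = wrap(st),
                      _["ev_edge"] = wrap(ev_edge),
                      _["ev_time"] = wrap(ev_time),
                      _["ev_state"] = wrap(ev_state));
}

// Batch crown-gain indicators over n replicate histories.
// mode 0: net gain across the stem branch (parent 0 -> crown 1), in {0,1};
// mode 1: count of 0->1 events on the stem branch (endpoint-conditioned
//         bridge on that branch).
// stem_edge is the 1-based index (into the supplied edge order) of the edge
// whose child is the crown node.
// [[Rcpp::export]]
IntegerVector cpp_sample_gains(IntegerVector parent, IntegerVector child,
                               NumericVector elen, int ntip, int nnodes,
                               int root, IntegerVector tip_state,
                               double q01, double q10, NumericVector prior,
                               bool conditional, int n, int stem_edge,
                               int mode) {
  int se = stem_edge - 1;
  if (se < 0 || se >= parent.size()) stop("invalid stem edge index");
  int pnode = parent[se] - 1, cnode = child[se] - 1;
  std::vector<int> st(nnodes, -1);
  std::vector<double> L;
  if (conditional)
    backward_partials(parent, child, elen, ntip, nnodes, tip_state, q01, q10, L);
  IntegerVector out(n);
  std::vector<double> tbuf; std::vector<int> sbuf;
  for (int i = 0; i < n; ++i) {
    if (conditional)
      sample_states_conditional(parent, child, elen, root, prior, q01, q10, L, st);
    else
      sample_states_unconditional(parent, child, elen, root, prior, q01, q10, st);
    if (mode == 0) {
      out[i] = (st[pnode] == 0 && st[cnode] == 1) ? 1 : 0;
    } else {
      sample_bridge(q01, q10, elen[se], st[pnode], st[cnode], tbuf, sbuf);
      int g = 0;
      for (size_t k = 0; k < sbuf.size(); ++k) if (sbuf[k] == 1) ++g;
      out[i] = g;
    }
  }
  return out;
}
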