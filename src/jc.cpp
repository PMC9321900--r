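// JC69 sequence evolution along segment genealogies, and the Felsenstein
// pruning log-likelihood under JC69 with uniform root frequencies.
//
// States are coded 0..3 = T, C, A, G.  Along a branch of length t
// (expected substitutions per site) a site keeps its state with probability
// 1/4 + 3/4 exp(-4t/3) and changes to each other state with probability
// 1/4 - 1/4 exp(-4t/3).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double jc_same(double t) {
  return 0.25 + 0.75 * std::exp(-4.0 * t / 3.0);
}

// [[Rcpp::export(name = ".evolve_jc_cpp")]]
IntegerMatrix evolve_jc_cpp(int ns, int n_sites,
                            NumericVector r_age,
                            IntegerVector r_child1,
                            IntegerVector r_child2,
                            IntegerVector r_start,
                            IntegerVector r_end,
                            IntegerVector breakpoints) {
  const int K = r_age.size();
  const int nnode = ns + K;           // record i has node id ns + i
  IntegerMatrix aln(ns, n_sites);
  std::vector<std::vector<int> > st(nnode);

  const int nseg = breakpoints.size() - 1;
  for (int s = 0; s < nseg; s++) {
    int lo = breakpoints[s], hi = breakpoints[s + 1];
    int len = hi - lo;
    // covering records, indices sorted by age (records are time-ordered)
    std::vector<int> cov;
    for (int i = 0; i < K; i++)
      if (r_start[i] <= lo && r_end[i] >= hi) cov.push_back(i);
    if (cov.empty()) stop("segment without a genealogy");
    // root = oldest covering record; draw its states uniformly
    int root = ns + cov.back();
    st[root].resize(len);
    for (int j = 0; j < len; j++) {
      int x = (int)(unif_rand() * 4.0); if (x > 3) x = 3;
      st[root][j] = x;
    }
    // descend in decreasing age
    for (int c = (int)cov.size() - 1; c >= 0; c--) {
      int i = cov[c];
      int par = ns + i;
      double page = r_age[i];
      int kids[2] = { r_child1[i], r_child2[i] };
      for (int q = 0; q < 2; q++) {
        int ch = kids[q];
        double cage = ch < ns ? 0.0 : r_age[ch - ns];
        double t = page - cage;
        if (t < 0) stop("negative branch length in genealogy");
        double p0 = jc_same(t);
        st[ch].resize(len);
        for (int j = 0; j < len; j++) {
          double u = unif_rand();
          int x = st[par][j];
          if (u >= p0) {
            int y = (int)((u - p0) / (1.0 - p0) * 3.0); if (y > 2) y = 2;
            x = (x + y + 1) % 4;
          }
          st[ch][j] = x;
        }
      }
    }
    for (int i = 0; i < ns; i++)
      for (int j = 0; j < len; j++)
        aln(i, lo + j) = st[i][j];
  }
  return aln;
}

// Pruning log-likelihood.  Edges must be supplied in postorder (children
// before parents); node ids are 1-based ape ids: tips 1..ntip, internals
// ntip+1..  Tip pattern states: ntip x npat, values 0..3 or -1 for
// "unknown" (all-ones partial likelihood).
// [[Rcpp::export(name = ".jc_loglik_cpp")]]
double jc_loglik_cpp(IntegerVector edge_parent,
                     IntegerVector edge_child,
                     NumericVector edge_length,
                     int ntip, int nnode_total,
                     IntegerMatrix tip_pat,
                     NumericVector weights) {
  const int npat = tip_pat.ncol();
  const int E = edge_parent.size();
  std::vector<double> clv((size_t)nnode_total * npat * 4);
  std::vector<bool> init(nnode_total, false);

  // tips
  for (int i = 0; i < ntip; i++) {
    double *c = &clv[(size_t)i * npat * 4];
    for (int p = 0; p < npat; p++) {
      int sstate = tip_pat(i, p);
      for (int x = 0; x < 4; x++)
        c[p * 4 + x] = (sstate < 0 || sstate == x) ? 1.0 : 0.0;
    }
    init[i] = true;
  }
  int root = -1;
  for (int e = 0; e < E; e++) {
    int par = edge_parent[e] - 1, ch = edge_child[e] - 1;
    root = par;
    if (edge_length[e] < -1e-12) stop("negative branch length");
    double t = edge_length[e] < 0 ? 0 : edge_length[e];
    double p0 = jc_same(t), p1 = (1.0 - p0) / 3.0;
    double *cp = &clv[(size_t)par * npat * 4];
    double *cc = &clv[(size_t)ch * npat * 4];
    if (!init[par]) {
      for (int j = 0; j < npat * 4; j++) cp[j] = 1.0;
      init[par] = true;
    }
    if (!init[ch]) stop("edges are not in postorder");
    for (int p = 0; p < npat; p++) {
      double s = cc[p * 4] + cc[p * 4 + 1] + cc[p * 4 + 2] + cc[p * 4 + 3];
      for (int x = 0; x < 4; x++) {
        double v = p1 * (s - cc[p * 4 + x]) + p0 * cc[p * 4 + x];
        cp[p * 4 + x] *= v;
      }
    }
  }
  if (root < 0) stop("no edges");
  double ll = 0.0;
  double *cr = &clv[(size_t)root * npat * 4];
  for (int p = 0; p < npat; p++) {
    double site = 0.25 * (cr[p * 4] + cr[p * 4 + 1] + cr[p * 4 + 2] +
                          cr[p * 4 + 3]);
    if (site <= 0) return R_NegInf;
    ll += weights[p] * std::log(site);
  }
  return ll;
}
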