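// Bayesian MCMC under the multispecies coalescent (MSC) and MSC-with-
// introgression (MSci) models, assuming no intralocus recombination.
//
// The sampler treats the per-locus gene trees (topology, coalescent ages,
// and — on networks — the parent-path indicator of each lineage at each
// hybridization node) as latent variables, alongside the species divergence
// times tau, the per-branch population sizes theta and the introgression
// probabilities phi.  Moves:
//   * per-node gene-tree age moves (sliding window, reflected at the valid
//     interval; populations reassigned by retracing lineage paths, newly
//     crossed hybrid nodes resolved by indicators proposed from
//     Bernoulli(phi), which enter the Hastings ratio explicitly),
//   * same-age subtree-pruning-regrafting of gene-tree nodes (target edge
//     uniform among edges in the same population at that age; symmetric),
//   * hybrid-path indicator flips,
//   * tau sliding windows with the rubber-band deformation of gene-node
//     ages in adjacent populations (Jacobian-corrected),
//   * conjugate Gibbs draws for each theta (inverse-gamma) and each phi
//     (Beta), or analytic integration of the thetas across loci,
//   * a whole-model rescale ("mixing") move over all taus, all coalescent
//     ages and (when sampled) all thetas,
//   * rooted NNI on the species tree holding gene trees fixed (population
//     assignments re-derived; proposals that orphan a coalescence are
//     rejected).
// Priors: tau0 ~ invgamma(a,b) on the root age, remaining taus uniform
// given the order constraints (joint density 1/tau0^{ntau-1} on the valid
// region), theta ~ invgamma(a,b) i.i.d. per branch, phi ~ U(0,1).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Net {
  int np;
  std::vector<double> age;
  std::vector<int> parent;     // main parent, -1 root
  std::vector<int> parent2;    // second parent of hybrids, -1 otherwise
  std::vector<int> hyb_id;     // node -> hybrid index or -1
  std::vector<int> hyb_node;   // hybrid index -> node
  std::vector<double> phi;     // per hybrid: P(route to parent2)
  std::vector<int> age_class;  // node -> tau parameter index, -1 tips
  std::vector<std::vector<int> > class_nodes;
  int root;
  int ntau() const { return (int)class_nodes.size(); }
  double top(int p) const {
    return parent[p] < 0 ? R_PosInf : age[parent[p]];
  }
};

struct Locus {
  int m, M;
  std::vector<int> par, ch1, ch2;
  std::vector<double> age;
  std::vector<int> pop;
  std::vector<signed char> ind;   // M x H
  std::vector<int> pk;            // per pop coalescences
  std::vector<double> pc;         // per pop sum C(n,2) dt
  std::vector<int> nalt, nmain;   // per hybrid
  double loglik;
  int npat;
  std::vector<int> tip_pat;       // m x npat
  std::vector<double> wt;
  std::vector<double> clv;        // M x npat x 4
};

static inline double jc_same(double t) {
  return 0.25 + 0.75 * std::exp(-4.0 * t / 3.0);
}

struct Chain {
  Net net;
  std::vector<Locus> loci;
  int H;
  bool data_free, integrate_theta, do_nni;
  double a_tau, b_tau, a_th, b_th;
  std::vector<double> theta;
  std::vector<double> Ctot;
  std::vector<int> Ktot, AltTot, MainTot;
  double w_age, eps_mix;
  std::vector<double> w_tau;
  double acc[6][2];               // [move][0]=accepted, [1]=tried

  // ---------- scratch ----------
  std::vector<signed char> tmp_ind, used_slot;
  std::vector<double> evt_t;
  std::vector<int> evt_p, evt_d, idx, nact;
  std::vector<int> nk, nna, nnm;
  std::vector<double> nc;
  std::vector<double> sclv;
  std::vector<signed char> sdirty;
  std::vector<int> up;
  std::vector<int> cand;

  void reset_tmp(Locus &L) {
    tmp_ind.assign((size_t)L.M * std::max(H, 1), -2);
    used_slot.assign((size_t)L.M * std::max(H, 1), 0);
  }

  // ---------- path tracing ----------
  // Walk the edge above gene node i from (p0, t0) up to time t1.
  // mode 0: stored indicators only (fail if unset);
  // mode 1: overlay tmp_ind, draw unset from Bernoulli(phi) into tmp_ind,
  //         accumulate proposal log density, mark used slots.
  int trace(Locus &L, int i, int p0, double t0, double t1, int mode,
            double *logq, bool *ok) {
    int cur = p0;
    *ok = true;
    for (int guard = 0; guard < 1000; guard++) {
      double tp = net.top(cur);
      if (tp >= t1) return cur;
      int par = net.parent[cur];
      int h = net.hyb_id[par];
      if (h < 0) { cur = par; continue; }
      size_t slot = (size_t)i * H + h;
      signed char v = L.ind[slot];
      if (mode == 1 && tmp_ind[slot] != -2) v = tmp_ind[slot];
      if (v < 0) {
        if (mode == 0) { *ok = false; return -1; }
        double ph = net.phi[h];
        v = (unif_rand() < ph) ? 1 : 0;
        if (logq) *logq += std::log(v ? ph : 1.0 - ph);
      }
      if (mode == 1) { tmp_ind[slot] = v; used_slot[slot] = 1; }
      cur = v ? net.parent2[par] : par;
    }
    *ok = false;
    return -1;
  }

  // ---------- sufficient statistics ----------
  bool locus_stats(Locus &L, int mode, std::vector<int> &k,
                   std::vector<double> &c, std::vector<int> &na,
                   std::vector<int> &nm) {
    const int np = net.np;
    k.assign(np, 0); c.assign(np, 0.0);
    na.assign(std::max(H, 1), 0); nm.assign(std::max(H, 1), 0);
    evt_t.clear(); evt_p.clear(); evt_d.clear();
    for (int i = 0; i < L.M; i++) {
      if (i >= L.m) {
        if (L.pop[i] < 0) return false;
        k[L.pop[i]]++;
      }
      if (L.par[i] < 0) continue;
      int cur = L.pop[i];
      double t = L.age[i], t1 = L.age[L.par[i]];
      bool done = false;
      for (int guard = 0; guard < 1000 && !done; guard++) {
        double tp = net.top(cur);
        if (tp >= t1) {
          if (cur != L.pop[L.par[i]]) return false;
          evt_t.push_back(t); evt_p.push_back(cur); evt_d.push_back(+1);
          evt_t.push_back(t1); evt_p.push_back(cur); evt_d.push_back(-1);
          done = true;
          break;
        }
        int par = net.parent[cur];
        int h = net.hyb_id[par];
        int nxt;
        if (h < 0) nxt = par;
        else {
          size_t slot = (size_t)i * H + h;
          signed char v = L.ind[slot];
          if (mode == 1 && tmp_ind[slot] != -2) v = tmp_ind[slot];
          if (v < 0) return false;
          if (v) { nxt = net.parent2[par]; na[h]++; }
          else { nxt = par; nm[h]++; }
        }
        evt_t.push_back(t); evt_p.push_back(cur); evt_d.push_back(+1);
        evt_t.push_back(tp); evt_p.push_back(cur); evt_d.push_back(-1);
        cur = nxt; t = tp;
      }
      if (!done) return false;
    }
    idx.resize(evt_t.size());
    for (size_t i2 = 0; i2 < idx.size(); i2++) idx[i2] = (int)i2;
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      if (evt_t[a] != evt_t[b]) return evt_t[a] < evt_t[b];
      return evt_d[a] < evt_d[b];
    });
    nact.assign(np, 0);
    double tprev = 0.0;
    for (size_t q = 0; q < idx.size(); q++) {
      int e = idx[q];
      double tt = evt_t[e];
      if (tt > tprev) {
        for (int p = 0; p < np; p++)
          if (nact[p] >= 2)
            c[p] += 0.5 * nact[p] * (nact[p] - 1.0) * (tt - tprev);
        tprev = tt;
      }
      nact[evt_p[e]] += evt_d[e];
    }
    return true;
  }

  double pop_factor(double K, double C) {
    return K * M_LN2 + a_th * std::log(b_th) + std::lgamma(a_th + K) -
           std::lgamma(a_th) - (a_th + K) * std::log(b_th + 2.0 * C);
  }
  double global_pop_logdens() {
    double s = 0.0;
    for (int p = 0; p < net.np; p++)
      s += integrate_theta
         ? pop_factor(Ktot[p], Ctot[p])
         : Ktot[p] * std::log(2.0 / theta[p]) - 2.0 * Ctot[p] / theta[p];
    return s;
  }

  // ---------- likelihood ----------
  void clv_node(Locus &L, const double *c1, const double *c2,
                double t1, double t2, double *out) {
    double p0a = jc_same(t1), p1a = (1.0 - p0a) / 3.0;
    double p0b = jc_same(t2), p1b = (1.0 - p0b) / 3.0;
    for (int p = 0; p < L.npat; p++) {
      const double *a = c1 + p * 4, *b = c2 + p * 4;
      double sa = a[0] + a[1] + a[2] + a[3];
      double sb = b[0] + b[1] + b[2] + b[3];
      double *o = out + p * 4;
      for (int x = 0; x < 4; x++)
        o[x] = (p1a * (sa - a[x]) + p0a * a[x]) *
               (p1b * (sb - b[x]) + p0b * b[x]);
    }
  }
  double root_loglik(Locus &L, const double *cr) {
    double ll = 0.0;
    for (int p = 0; p < L.npat; p++) {
      double s = 0.25 * (cr[p * 4] + cr[p * 4 + 1] + cr[p * 4 + 2] +
                         cr[p * 4 + 3]);
      if (s <= 0) return R_NegInf;
      ll += L.wt[p] * std::log(s);
    }
    return ll;
  }
  // recompute CLVs of dirty nodes + ancestors into scratch; new loglik
  double partial_loglik(Locus &L, std::vector<int> &dirty) {
    up.clear();
    if (data_free) return 0.0;
    size_t B = (size_t)L.npat * 4;
    if (sclv.size() < (size_t)L.M * B) sclv.resize((size_t)L.M * B);
    sdirty.assign(L.M, 0);
    for (size_t q = 0; q < dirty.size(); q++) {
      int u = dirty[q];
      while (u >= 0 && !sdirty[u]) {
        sdirty[u] = 1; up.push_back(u); u = L.par[u];
      }
    }
    std::sort(up.begin(), up.end(), [&](int a, int b) {
      return L.age[a] < L.age[b];
    });
    int root = -1;
    for (int u2 = L.m; u2 < L.M; u2++) if (L.par[u2] < 0) root = u2;
    for (size_t q = 0; q < up.size(); q++) {
      int u = up[q];
      if (u < L.m) continue;
      int c1 = L.ch1[u], c2 = L.ch2[u];
      const double *b1 = (c1 >= L.m && sdirty[c1]) ? &sclv[c1 * B]
                                                   : &L.clv[c1 * B];
      const double *b2 = (c2 >= L.m && sdirty[c2]) ? &sclv[c2 * B]
                                                   : &L.clv[c2 * B];
      clv_node(L, b1, b2, L.age[u] - L.age[c1], L.age[u] - L.age[c2],
               &sclv[u * B]);
    }
    return root_loglik(L, (root >= 0 && sdirty[root]) ? &sclv[root * B]
                                                      : &L.clv[root * B]);
  }
  void commit_clv(Locus &L) {
    if (data_free) return;
    size_t B = (size_t)L.npat * 4;
    for (size_t q = 0; q < up.size(); q++) {
      int u = up[q];
      if (u >= L.m)
        std::copy(&sclv[u * B], &sclv[u * B] + B, &L.clv[u * B]);
    }
  }
  void full_clv(Locus &L) {
    if (data_free) { L.loglik = 0.0; return; }
    std::vector<int> dirty;
    for (int u = L.m; u < L.M; u++) dirty.push_back(u);
    L.loglik = partial_loglik(L, dirty);
    commit_clv(L);
  }

  // ---------- cache swap helpers ----------
  void swap_stats(Locus &L) {
    for (int p = 0; p < net.np; p++) {
      Ktot[p] += nk[p] - L.pk[p];
      Ctot[p] += nc[p] - L.pc[p];
    }
    for (int h = 0; h < H; h++) {
      AltTot[h] += nna[h] - L.nalt[h];
      MainTot[h] += nnm[h] - L.nmain[h];
    }
    L.pk = nk; L.pc = nc; L.nalt = nna; L.nmain = nnm;
  }
  double delta_logdens(Locus &L) {
    double d = 0.0;
    for (int p = 0; p < net.np; p++) {
      if (nk[p] == L.pk[p] && nc[p] == L.pc[p]) continue;
      if (integrate_theta)
        d += pop_factor(Ktot[p] + nk[p] - L.pk[p],
                        Ctot[p] + nc[p] - L.pc[p]) -
             pop_factor(Ktot[p], Ctot[p]);
      else
        d += (nk[p] - L.pk[p]) * std::log(2.0 / theta[p]) -
             2.0 * (nc[p] - L.pc[p]) / theta[p];
    }
    for (int h = 0; h < H; h++)
      d += (nna[h] - L.nalt[h]) * std::log(net.phi[h]) +
           (nnm[h] - L.nmain[h]) * std::log(1.0 - net.phi[h]);
    return d;
  }
  double drop_logq(Locus &L, const int *edges, int ne) {
    double lq = 0.0;
    for (int q = 0; q < ne; q++) {
      int i = edges[q];
      for (int h = 0; h < H; h++) {
        size_t s = (size_t)i * H + h;
        if (L.ind[s] >= 0 && !used_slot[s]) {
          double ph = net.phi[h];
          lq += std::log(L.ind[s] ? ph : 1.0 - ph);
        }
      }
    }
    return lq;
  }
  void commit_ind(Locus &L, const int *edges, int ne) {
    for (int q = 0; q < ne; q++) {
      int i = edges[q];
      for (int h = 0; h < H; h++) {
        size_t s = (size_t)i * H + h;
        L.ind[s] = used_slot[s] ? tmp_ind[s] : (signed char)-1;
      }
    }
  }
  int count_applicable(Locus &L) {
    int n = 0;
    for (int i = 0; i < L.M; i++)
      if (L.par[i] >= 0)
        for (int h = 0; h < H; h++)
          if (L.ind[(size_t)i * H + h] >= 0) n++;
    return n;
  }

  // ---------- moves ----------
  void age_move(int l, int u) {
    Locus &L = loci[l];
    double lo = std::max(L.age[L.ch1[u]], L.age[L.ch2[u]]);
    double hi = L.par[u] >= 0 ? L.age[L.par[u]] : R_PosInf;
    double t = L.age[u];
    double tstar = t + w_age * (unif_rand() - 0.5) * 2.0;
    for (int it = 0; it < 500; it++) {
      if (tstar < lo) tstar = 2 * lo - tstar;
      else if (R_FINITE(hi) && tstar > hi) tstar = 2 * hi - tstar;
      else break;
    }
    if (tstar <= lo || (R_FINITE(hi) && tstar >= hi)) return;
    acc[0][1] += 1;
    reset_tmp(L);
    double logq_fwd = 0.0;
    bool ok = true;
    int p1 = trace(L, L.ch1[u], L.pop[L.ch1[u]], L.age[L.ch1[u]], tstar, 1,
                   &logq_fwd, &ok);
    if (!ok) return;
    int p2 = trace(L, L.ch2[u], L.pop[L.ch2[u]], L.age[L.ch2[u]], tstar, 1,
                   &logq_fwd, &ok);
    if (!ok || p1 != p2) return;
    if (L.par[u] >= 0) {
      int pu = trace(L, u, p1, tstar, L.age[L.par[u]], 1, &logq_fwd, &ok);
      if (!ok || pu != L.pop[L.par[u]]) return;
    }
    double t_old = t;
    int pop_old = L.pop[u];
    L.age[u] = tstar; L.pop[u] = p1;
    if (!locus_stats(L, 1, nk, nc, nna, nnm)) {
      L.age[u] = t_old; L.pop[u] = pop_old;
      return;
    }
    double dd = delta_logdens(L);
    int ed[3] = { L.ch1[u], L.ch2[u], u };
    double logq_rev = drop_logq(L, ed, 3);
    std::vector<int> dirty(1, u);
    double newll = partial_loglik(L, dirty);
    double lr = (newll - L.loglik) + dd + (logq_rev - logq_fwd);
    if (std::log(unif_rand()) < lr) {
      swap_stats(L);
      commit_ind(L, ed, 3);
      commit_clv(L);
      L.loglik = newll;
      acc[0][0] += 1;
    } else {
      L.age[u] = t_old; L.pop[u] = pop_old;
    }
  }

  void spr_move(int l) {
    Locus &L = loci[l];
    int a = (int)(unif_rand() * L.M);
    if (a >= L.M || L.par[a] < 0) return;
    int u = L.par[a];
    if (L.par[u] < 0) return;          // regrafting above the root: no-op
    int g = L.par[u];
    int b = (L.ch1[u] == a) ? L.ch2[u] : L.ch1[u];
    double tu = L.age[u];
    acc[1][1] += 1;
    bool ok = true;
    int Pstar = trace(L, a, L.pop[a], L.age[a], tu, 0, 0, &ok);
    if (!ok) return;
    cand.clear();
    for (int c = 0; c < L.M; c++) {
      if (c == u || c == a) continue;
      int pc = (c == b) ? g : L.par[c];   // parent in detached configuration
      if (pc < 0) continue;
      if (!(L.age[c] < tu && tu < L.age[pc])) continue;
      bool ok2 = true;
      int pat = trace(L, c, L.pop[c], L.age[c], tu, 0, 0, &ok2);
      if (ok2 && pat == Pstar) cand.push_back(c);
    }
    if (cand.empty()) return;
    int cstar = cand[(int)(unif_rand() * cand.size())];
    if (cstar == b) { acc[1][0] += 1; return; }
    int save_par_u = L.par[u], save_par_b = L.par[b],
        save_par_c = L.par[cstar];
    int gc = L.par[cstar];
    // indicator juggling on edges u, b, cstar
    static std::vector<std::pair<size_t, signed char> > sv;
    sv.clear();
    for (int h = 0; h < H; h++) {
      int ids[3] = { u, b, cstar };
      for (int q = 0; q < 3; q++) {
        size_t s = (size_t)ids[q] * H + h;
        sv.push_back(std::make_pair(s, L.ind[s]));
      }
    }
    for (int h = 0; h < H; h++) {
      double hage = net.age[net.hyb_node[h]];
      size_t su = (size_t)u * H + h, sb = (size_t)b * H + h,
             sc = (size_t)cstar * H + h;
      signed char iu = L.ind[su], ic = L.ind[sc];
      if (iu >= 0 && hage > tu) L.ind[sb] = iu;
      L.ind[su] = (ic >= 0 && hage > tu) ? ic : (signed char)-1;
      if (ic >= 0 && hage > tu) L.ind[sc] = -1;
    }
    if (L.ch1[g] == u) L.ch1[g] = b; else L.ch2[g] = b;
    L.par[b] = g;
    if (L.ch1[u] == a) L.ch2[u] = cstar; else L.ch1[u] = cstar;
    L.par[cstar] = u;
    L.par[u] = gc;
    if (gc >= 0) {
      if (L.ch1[gc] == cstar) L.ch1[gc] = u; else L.ch2[gc] = u;
    }
    int pop_old = L.pop[u];
    L.pop[u] = Pstar;
    reset_tmp(L);
    double lr = R_NegInf, newll = 0;
    bool st_ok = locus_stats(L, 0, nk, nc, nna, nnm);
    if (st_ok) {
      double dd = delta_logdens(L);
      std::vector<int> dirty;
      dirty.push_back(u); dirty.push_back(g);
      newll = partial_loglik(L, dirty);
      lr = (newll - L.loglik) + dd;
    }
    if (st_ok && std::log(unif_rand()) < lr) {
      swap_stats(L);
      commit_clv(L);
      L.loglik = newll;
      acc[1][0] += 1;
    } else {
      L.par[u] = save_par_u;
      L.par[cstar] = save_par_c;
      L.par[b] = save_par_b;
      if (L.ch1[u] == cstar) L.ch1[u] = b; else L.ch2[u] = b;
      if (gc >= 0) {
        if (L.ch1[gc] == u) L.ch1[gc] = cstar; else L.ch2[gc] = cstar;
      }
      if (L.ch1[g] == b) L.ch1[g] = u; else L.ch2[g] = u;
      L.pop[u] = pop_old;
      for (size_t q = 0; q < sv.size(); q++) L.ind[sv[q].first] = sv[q].second;
    }
  }

  void flip_move(int l) {
    if (H == 0) return;
    Locus &L = loci[l];
    cand.clear();
    for (int i = 0; i < L.M; i++)
      if (L.par[i] >= 0)
        for (int h = 0; h < H; h++)
          if (L.ind[(size_t)i * H + h] >= 0) cand.push_back(i * H + h);
    if (cand.empty()) return;
    int n_old = (int)cand.size();
    int pick = cand[(int)(unif_rand() * n_old)];
    int i = pick / H, h = pick % H;
    acc[2][1] += 1;
    reset_tmp(L);
    size_t s = (size_t)i * H + h;
    tmp_ind[s] = 1 - L.ind[s];
    used_slot[s] = 1;
    double logq_fwd = 0.0;
    bool ok = true;
    int pend = trace(L, i, L.pop[i], L.age[i], L.age[L.par[i]], 1,
                     &logq_fwd, &ok);
    if (!ok || pend != L.pop[L.par[i]]) return;
    if (!locus_stats(L, 1, nk, nc, nna, nnm)) return;
    double dd = delta_logdens(L);
    int ed[1] = { i };
    double logq_rev = drop_logq(L, ed, 1);
    // slot-count change: edge i's applicable slots after the move
    int row_old = 0, row_new = 0;
    for (int h2 = 0; h2 < H; h2++) {
      size_t s2 = (size_t)i * H + h2;
      if (L.ind[s2] >= 0) row_old++;
      if (used_slot[s2]) row_new++;
    }
    int n_new = n_old - row_old + row_new;
    double lr = dd + (logq_rev - logq_fwd) +
                std::log((double)n_old) - std::log((double)n_new);
    if (std::log(unif_rand()) < lr) {
      swap_stats(L);
      commit_ind(L, ed, 1);
      acc[2][0] += 1;
    }
  }

  // ----- tau move with rubber-band remap -----
  struct SavedAge { int l, u; double t; };
  std::vector<SavedAge> saved_ages;
  std::vector<signed char> in_class;
  // CLV undo storage
  std::vector<double> clv_bak;
  std::vector<std::pair<int, int> > clv_bak_ids;
  void backup_clv(int l) {
    if (data_free) return;
    Locus &L = loci[l];
    size_t B = (size_t)L.npat * 4;
    for (size_t q = 0; q < up.size(); q++) {
      int u = up[q];
      if (u < L.m) continue;
      clv_bak_ids.push_back(std::make_pair(l, u));
      size_t at = clv_bak.size();
      clv_bak.resize(at + B);
      std::copy(&L.clv[u * B], &L.clv[u * B] + B, &clv_bak[at]);
    }
  }
  void restore_clv() {
    size_t at = 0;
    for (size_t q = 0; q < clv_bak_ids.size(); q++) {
      Locus &L = loci[clv_bak_ids[q].first];
      size_t B = (size_t)L.npat * 4;
      int u = clv_bak_ids[q].second;
      std::copy(&clv_bak[at], &clv_bak[at] + B, &L.clv[u * B]);
      at += B;
    }
  }

  void tau_move(int kcls) {
    std::vector<int> &nodes = net.class_nodes[kcls];
    bool is_root_class = false;
    double lo = 0.0, hi = R_PosInf;
    for (size_t q = 0; q < nodes.size(); q++) {
      int nd = nodes[q];
      if (nd == net.root) is_root_class = true;
      for (int c = 0; c < net.np; c++)
        if ((net.parent[c] == nd || net.parent2[c] == nd) &&
            net.age_class[c] != kcls)
          lo = std::max(lo, net.age[c]);
      if (net.parent[nd] >= 0 && net.age_class[net.parent[nd]] != kcls)
        hi = std::min(hi, net.age[net.parent[nd]]);
      if (net.parent2[nd] >= 0 && net.age_class[net.parent2[nd]] != kcls)
        hi = std::min(hi, net.age[net.parent2[nd]]);
    }
    double t = net.age[nodes[0]];
    double tstar = t + w_tau[kcls] * (unif_rand() - 0.5) * 2.0;
    for (int it = 0; it < 500; it++) {
      if (tstar < lo) tstar = 2 * lo - tstar;
      else if (R_FINITE(hi) && tstar > hi) tstar = 2 * hi - tstar;
      else break;
    }
    if (tstar <= lo || (R_FINITE(hi) && tstar >= hi) || tstar <= 0) return;
    acc[3][1] += 1;
    in_class.assign(net.np, 0);
    for (size_t q = 0; q < nodes.size(); q++) in_class[nodes[q]] = 1;
    std::vector<double> s0(net.np), e0(net.np), s1(net.np), e1(net.np);
    std::vector<signed char> affected(net.np, 0);
    std::vector<double> gam(net.np, 1.0);
    for (int p = 0; p < net.np; p++) {
      double s = net.age[p], e = net.top(p);
      double sn = in_class[p] ? tstar : s;
      double en = e;
      int par = net.parent[p];
      if (par >= 0 && in_class[par]) en = tstar;
      if (sn != s || en != e) {
        if (R_FINITE(e) && (e - s <= 0 || en - sn <= 0)) return;
        affected[p] = 1;
        s0[p] = s; e0[p] = e; s1[p] = sn; e1[p] = en;
        gam[p] = R_FINITE(e) ? (en - sn) / (e - s) : 1.0;
      }
    }
    double dlp = 0.0;
    int ntau = net.ntau();
    if (is_root_class) {
      dlp += (-(a_tau + 1.0) * std::log(tstar) - b_tau / tstar) -
             (-(a_tau + 1.0) * std::log(t) - b_tau / t);
      dlp += (ntau - 1) * (std::log(t) - std::log(tstar));
    }
    double logJ = 0.0;
    saved_ages.clear();
    clv_bak.clear(); clv_bak_ids.clear();
    std::vector<std::vector<int> > dirties(loci.size());
    for (size_t l = 0; l < loci.size(); l++) {
      Locus &L = loci[l];
      for (int u = L.m; u < L.M; u++) {
        int p = L.pop[u];
        if (!affected[p]) continue;
        double tnew;
        if (!R_FINITE(e0[p])) tnew = L.age[u] + (s1[p] - s0[p]);
        else {
          tnew = s1[p] + (L.age[u] - s0[p]) * gam[p];
          logJ += std::log(gam[p]);
        }
        saved_ages.push_back(SavedAge{(int)l, u, L.age[u]});
        L.age[u] = tnew;
        dirties[l].push_back(u);
      }
    }
    double dlogdens = 0.0;
    for (int p = 0; p < net.np; p++) {
      if (gam[p] == 1.0) continue;
      double Cn = Ctot[p] * gam[p];
      dlogdens += integrate_theta
        ? pop_factor(Ktot[p], Cn) - pop_factor(Ktot[p], Ctot[p])
        : -2.0 * (Cn - Ctot[p]) / theta[p];
    }
    for (size_t q = 0; q < nodes.size(); q++) net.age[nodes[q]] = tstar;
    double dll = 0.0;
    std::vector<double> newll(loci.size());
    bool bad = false;
    for (size_t l = 0; l < loci.size(); l++) {
      Locus &L = loci[l];
      if (dirties[l].empty()) { newll[l] = L.loglik; continue; }
      std::vector<int> d = dirties[l];
      size_t nd0 = d.size();
      for (size_t q = 0; q < nd0; q++)
        if (L.par[d[q]] >= 0) d.push_back(L.par[d[q]]);
      newll[l] = partial_loglik(L, d);
      backup_clv((int)l);
      commit_clv(L);
      if (!R_FINITE(newll[l])) bad = true;
      dll += newll[l] - L.loglik;
    }
    double lr = bad ? R_NegInf : dll + dlogdens + dlp + logJ;
    if (std::log(unif_rand()) < lr) {
      for (size_t l = 0; l < loci.size(); l++) {
        Locus &L = loci[l];
        for (int p = 0; p < net.np; p++)
          if (gam[p] != 1.0) L.pc[p] *= gam[p];
        L.loglik = newll[l];
      }
      for (int p = 0; p < net.np; p++) Ctot[p] *= gam[p];
      acc[3][0] += 1;
    } else {
      for (size_t q = 0; q < nodes.size(); q++) net.age[nodes[q]] = t;
      for (size_t q = 0; q < saved_ages.size(); q++)
        loci[saved_ages[q].l].age[saved_ages[q].u] = saved_ages[q].t;
      restore_clv();
    }
  }

  void gibbs_theta() {
    for (int p = 0; p < net.np; p++)
      theta[p] = (b_th + 2.0 * Ctot[p]) / R::rgamma(a_th + Ktot[p], 1.0);
  }
  void gibbs_phi() {
    for (int h = 0; h < H; h++)
      net.phi[h] = R::rbeta(1.0 + AltTot[h], 1.0 + MainTot[h]);
  }

  double tau_theta_logprior() {
    double t0 = net.age[net.root];
    double lp = -(a_tau + 1.0) * std::log(t0) - b_tau / t0 -
                (net.ntau() - 1) * std::log(t0);
    if (!integrate_theta)
      for (int p = 0; p < net.np; p++)
        lp += -(a_th + 1.0) * std::log(theta[p]) - b_th / theta[p];
    return lp;
  }

  void mix_move() {
    acc[4][1] += 1;
    double x = std::exp(eps_mix * (unif_rand() - 0.5));
    int nscaled = net.ntau();
    for (size_t l = 0; l < loci.size(); l++) nscaled += loci[l].m - 1;
    double old_pop_dens = global_pop_logdens();
    double old_prior = tau_theta_logprior();
    std::vector<double> th_old = theta;
    for (int p = 0; p < net.np; p++)
      if (net.age_class[p] >= 0) net.age[p] *= x;
    for (size_t l = 0; l < loci.size(); l++)
      for (int u = loci[l].m; u < loci[l].M; u++) loci[l].age[u] *= x;
    for (int p = 0; p < net.np; p++) Ctot[p] *= x;
    if (!integrate_theta) {
      for (int p = 0; p < net.np; p++) theta[p] *= x;
      nscaled += net.np;
    }
    clv_bak.clear(); clv_bak_ids.clear();
    double dll = 0.0;
    std::vector<double> newll(loci.size());
    for (size_t l = 0; l < loci.size(); l++) {
      std::vector<int> dirty;
      for (int u = loci[l].m; u < loci[l].M; u++) dirty.push_back(u);
      newll[l] = partial_loglik(loci[l], dirty);
      backup_clv((int)l);
      commit_clv(loci[l]);
      dll += newll[l] - loci[l].loglik;
    }
    double lr = dll + (global_pop_logdens() - old_pop_dens) +
                (tau_theta_logprior() - old_prior) + nscaled * std::log(x);
    if (std::log(unif_rand()) < lr) {
      for (size_t l = 0; l < loci.size(); l++) {
        for (int p = 0; p < net.np; p++) loci[l].pc[p] *= x;
        loci[l].loglik = newll[l];
      }
      acc[4][0] += 1;
    } else {
      for (int p = 0; p < net.np; p++)
        if (net.age_class[p] >= 0) net.age[p] /= x;
      for (size_t l = 0; l < loci.size(); l++)
        for (int u = loci[l].m; u < loci[l].M; u++) loci[l].age[u] /= x;
      for (int p = 0; p < net.np; p++) Ctot[p] /= x;
      theta = th_old;
      restore_clv();
    }
  }

  // ----- species-tree NNI (trees only) -----
  struct SavedPop { int l, u, p; };
  std::vector<SavedPop> saved_pops;
  void nni_move() {
    acc[5][1] += 1;
    std::vector<int> internals;
    std::vector<int> nch(net.np, 0);
    for (int i = 0; i < net.np; i++)
      if (net.parent[i] >= 0) nch[net.parent[i]]++;
    for (int i = 0; i < net.np; i++)
      if (net.parent[i] >= 0 && nch[i] == 2) internals.push_back(i);
    if (internals.empty()) return;
    int s = internals[(int)(unif_rand() * internals.size())];
    int p = net.parent[s];
    int b = -1;
    for (int j = 0; j < net.np; j++)
      if (net.parent[j] == p && j != s) b = j;
    std::vector<int> kids;
    for (int j = 0; j < net.np; j++)
      if (net.parent[j] == s) kids.push_back(j);
    if (b < 0 || kids.size() != 2) return;
    int c = kids[unif_rand() < 0.5 ? 0 : 1];
    if (net.age[b] >= net.age[s]) return;
    net.parent[b] = s; net.parent[c] = p;
    // re-derive population of every coalescence, youngest first
    saved_pops.clear();
    bool ok = true;
    double old_pop_dens = global_pop_logdens();
    std::vector<std::vector<int> > old_pk(loci.size());
    std::vector<std::vector<double> > old_pc(loci.size());
    size_t ldone = 0;
    for (size_t l = 0; l < loci.size() && ok; l++) {
      Locus &L = loci[l];
      ordbuf.resize(L.M - L.m);
      for (int u = L.m; u < L.M; u++) ordbuf[u - L.m] = u;
      std::sort(ordbuf.begin(), ordbuf.end(), [&](int x, int y) {
        return L.age[x] < L.age[y];
      });
      for (size_t q = 0; q < ordbuf.size() && ok; q++) {
        int u = ordbuf[q];
        int p1 = walk_up(L.pop[L.ch1[u]], L.age[u]);
        int p2 = walk_up(L.pop[L.ch2[u]], L.age[u]);
        if (p1 < 0 || p1 != p2) { ok = false; break; }
        if (p1 != L.pop[u]) {
          saved_pops.push_back(SavedPop{(int)l, u, L.pop[u]});
          L.pop[u] = p1;
        }
      }
      if (!ok) break;
      if (!locus_stats(L, 0, nk, nc, nna, nnm)) { ok = false; break; }
      old_pk[l] = L.pk; old_pc[l] = L.pc;
      for (int q = 0; q < net.np; q++) {
        Ktot[q] += nk[q] - L.pk[q];
        Ctot[q] += nc[q] - L.pc[q];
      }
      L.pk = nk; L.pc = nc;
      ldone = l + 1;
    }
    bool accept = false;
    if (ok) {
      double lr = global_pop_logdens() - old_pop_dens;
      accept = std::log(unif_rand()) < lr;
    }
    if (accept) {
      acc[5][0] += 1;
    } else {
      net.parent[b] = p; net.parent[c] = s;
      for (size_t q = 0; q < saved_pops.size(); q++)
        loci[saved_pops[q].l].pop[saved_pops[q].u] = saved_pops[q].p;
      for (size_t l = 0; l < ldone; l++) {
        Locus &L = loci[l];
        for (int q = 0; q < net.np; q++) {
          Ktot[q] += old_pk[l][q] - L.pk[q];
          Ctot[q] += old_pc[l][q] - L.pc[q];
        }
        L.pk = old_pk[l]; L.pc = old_pc[l];
      }
    }
  }
  std::vector<int> ordbuf;
  int walk_up(int start_pop, double t) {
    int cur = start_pop;
    for (int guard = 0; guard < 1000; guard++) {
      if (net.top(cur) > t) return cur;
      cur = net.parent[cur];
      if (cur < 0) return -1;
    }
    return -1;
  }

  // ---------- initial gene trees from the MSC prior ----------
  void init_locus(Locus &L, const std::vector<int> &tip_pop) {
    int m = L.m;
    L.M = 2 * m - 1;
    L.par.assign(L.M, -1);
    L.ch1.assign(L.M, -1);
    L.ch2.assign(L.M, -1);
    L.age.assign(L.M, 0.0);
    L.pop.assign(L.M, -1);
    L.ind.assign((size_t)L.M * std::max(H, 1), -1);
    // event times: all distinct internal-node ages
    std::vector<double> ev;
    for (int p = 0; p < net.np; p++)
      if (net.age_class[p] >= 0) ev.push_back(net.age[p]);
    std::sort(ev.begin(), ev.end());
    ev.erase(std::unique(ev.begin(), ev.end()), ev.end());
    std::vector<std::vector<int> > mem(net.np);
    for (int i = 0; i < m; i++) {
      L.pop[i] = tip_pop[i];
      mem[tip_pop[i]].push_back(i);
    }
    int nlin = m, next = m;
    double t = 0.0;
    size_t ei = 0;
    for (int guard = 0; guard < 100000 && nlin > 1; guard++) {
      double rate = 0.0;
      for (int p = 0; p < net.np; p++) {
        double k = (double)mem[p].size();
        if (k >= 2) rate += k * (k - 1.0) / theta[p];
      }
      double tnext = rate > 0 ? t + exp_rand() / rate : R_PosInf;
      if (ei < ev.size() && ev[ei] <= tnext) {
        t = ev[ei++];
        // transfer lineages whose population tops out at t
        for (int p = 0; p < net.np; p++) {
          if (mem[p].empty()) continue;
          if (net.top(p) != t) continue;
          int par = net.parent[p];
          int h = net.hyb_id[par];
          for (size_t q = 0; q < mem[p].size(); q++) {
            int i = mem[p][q];
            if (h < 0) mem[par].push_back(i);
            else {
              signed char v = (unif_rand() < net.phi[h]) ? 1 : 0;
              L.ind[(size_t)i * H + h] = v;
              mem[v ? net.parent2[par] : par].push_back(i);
            }
          }
          mem[p].clear();
        }
        continue;
      }
      if (!R_FINITE(tnext)) break;   // should not happen on a valid model
      t = tnext;
      double u = unif_rand() * rate;
      int cp = -1;
      for (int p = 0; p < net.np; p++) {
        double k = (double)mem[p].size();
        if (k >= 2) {
          u -= k * (k - 1.0) / theta[p];
          if (u <= 0) { cp = p; break; }
        }
      }
      if (cp < 0) continue;
      int k = (int)mem[cp].size();
      int i1 = (int)(unif_rand() * k); if (i1 >= k) i1 = k - 1;
      int i2 = (int)(unif_rand() * (k - 1)); if (i2 >= k - 1) i2 = k - 2;
      if (i2 >= i1) i2++;
      int A = mem[cp][i1], B = mem[cp][i2];
      int nd = next++;
      L.ch1[nd] = A; L.ch2[nd] = B;
      L.par[A] = nd; L.par[B] = nd;
      L.age[nd] = t; L.pop[nd] = cp;
      int hi2 = std::max(i1, i2), lo2 = std::min(i1, i2);
      mem[cp][hi2] = mem[cp].back(); mem[cp].pop_back();
      mem[cp][lo2] = mem[cp].back(); mem[cp].pop_back();
      mem[cp].push_back(nd);
      nlin--;
    }
  }

  // invariant checks for development/tests: recompute every cache from
  // scratch and compare
  void validate_state() {
    std::vector<int> K2(net.np, 0), A2(std::max(H,1), 0), M2(std::max(H,1), 0);
    std::vector<double> C2(net.np, 0.0);
    for (size_t l = 0; l < loci.size(); l++) {
      Locus &L = loci[l];
      if (!locus_stats(L, 0, nk, nc, nna, nnm))
        stop("state validation: inconsistent gene tree at locus %d", (int)l + 1);
      for (int p = 0; p < net.np; p++) {
        if (nk[p] != L.pk[p] ||
            std::fabs(nc[p] - L.pc[p]) > 1e-6 * (1.0 + std::fabs(nc[p])))
          stop("state validation: stale stats at locus %d pop %d (k %d vs %d, c %g vs %g)",
               (int)l + 1, p, nk[p], L.pk[p], nc[p], L.pc[p]);
        K2[p] += nk[p]; C2[p] += nc[p];
      }
      for (int h = 0; h < H; h++) { A2[h] += nna[h]; M2[h] += nnm[h]; }
      if (!data_free) {
        double ll0 = L.loglik;
        full_clv(L);
        if (std::fabs(ll0 - L.loglik) > 1e-5 * (1.0 + std::fabs(L.loglik)))
          stop("state validation: stale likelihood at locus %d (%g vs %g)",
               (int)l + 1, ll0, L.loglik);
      }
    }
    for (int p = 0; p < net.np; p++)
      if (K2[p] != Ktot[p] ||
          std::fabs(C2[p] - Ctot[p]) > 1e-6 * (1.0 + std::fabs(C2[p])))
        stop("state validation: stale totals at pop %d", p);
    for (int h = 0; h < H; h++)
      if (A2[h] != AltTot[h] || M2[h] != MainTot[h])
        stop("state validation: stale routing totals at hybrid %d", h);
  }

  // canonical topology-only newick of the species tree
  std::string topo_newick(const std::vector<std::string> &labels) {
    std::vector<std::vector<int> > kids(net.np);
    int root = -1;
    for (int i = 0; i < net.np; i++) {
      if (net.parent[i] < 0) root = i;
      else kids[net.parent[i]].push_back(i);
    }
    return topo_rec(root, kids, labels);
  }
  std::string topo_rec(int i, const std::vector<std::vector<int> > &kids,
                       const std::vector<std::string> &labels) {
    if (kids[i].empty()) return labels[i];
    std::vector<std::string> parts;
    for (size_t q = 0; q < kids[i].size(); q++)
      parts.push_back(topo_rec(kids[i][q], kids, labels));
    std::sort(parts.begin(), parts.end());
    std::string s = "(";
    for (size_t q = 0; q < parts.size(); q++) {
      if (q) s += ",";
      s += parts[q];
    }
    s += ")";
    return s;
  }
};

}  // namespace

// [[Rcpp::export(name = ".run_mcmc_cpp")]]
List run_mcmc_cpp(List net_in, List loci_in, List prior_in, List set_in) {
  Chain ch;
  Net &net = ch.net;
  net.age = as<std::vector<double> >(net_in["age"]);
  net.parent = as<std::vector<int> >(net_in["parent"]);
  net.parent2 = as<std::vector<int> >(net_in["parent2"]);
  net.age_class = as<std::vector<int> >(net_in["age_class"]);
  std::vector<double> phi_init = as<std::vector<double> >(net_in["phi"]);
  std::vector<std::string> labels =
    as<std::vector<std::string> >(net_in["label"]);
  net.np = (int)net.age.size();
  net.root = -1;
  net.hyb_id.assign(net.np, -1);
  for (int i = 0; i < net.np; i++) {
    if (net.parent[i] < 0) net.root = i;
    if (net.parent2[i] >= 0) {
      net.hyb_id[i] = (int)net.hyb_node.size();
      net.hyb_node.push_back(i);
      net.phi.push_back(phi_init[i]);
    }
  }
  ch.H = (int)net.hyb_node.size();
  int ntau = 0;
  for (int i = 0; i < net.np; i++)
    ntau = std::max(ntau, net.age_class[i] + 1);
  net.class_nodes.assign(ntau, std::vector<int>());
  for (int i = 0; i < net.np; i++)
    if (net.age_class[i] >= 0) net.class_nodes[net.age_class[i]].push_back(i);

  ch.a_tau = as<double>(prior_in["tau_alpha"]);
  ch.b_tau = as<double>(prior_in["tau_beta"]);
  ch.a_th = as<double>(prior_in["theta_alpha"]);
  ch.b_th = as<double>(prior_in["theta_beta"]);
  ch.integrate_theta = as<bool>(prior_in["integrate_theta"]);

  ch.data_free = as<bool>(set_in["data_free"]);
  ch.do_nni = as<bool>(set_in["species_tree_move"]);
  int burnin = as<int>(set_in["burnin"]);
  int nsamples = as<int>(set_in["nsamples"]);
  int thin = as<int>(set_in["thin"]);
  bool autotune = as<bool>(set_in["autotune"]);
  bool validate = set_in.containsElementNamed("validate") &&
                  as<bool>(set_in["validate"]);
  ch.w_age = as<double>(set_in["w_age"]);
  ch.eps_mix = as<double>(set_in["eps_mix"]);
  double w_tau0 = as<double>(set_in["w_tau"]);
  int n_spr = as<int>(set_in["n_spr"]);
  ch.w_tau.assign(ntau, w_tau0);
  ch.theta = as<std::vector<double> >(net_in["theta"]);
  for (int i = 0; i < 6; i++) ch.acc[i][0] = ch.acc[i][1] = 0;

  // loci
  int nloci = loci_in.size();
  ch.loci.resize(nloci);
  for (int l = 0; l < nloci; l++) {
    List li = loci_in[l];
    Locus &L = ch.loci[l];
    std::vector<int> tip_pop = as<std::vector<int> >(li["tip_pop"]);
    L.m = (int)tip_pop.size();
    if (!ch.data_free) {
      IntegerMatrix tp = li["tip_pat"];
      L.npat = tp.ncol();
      L.wt = as<std::vector<double> >(li["weights"]);
      L.tip_pat.resize((size_t)L.m * L.npat);
      for (int i = 0; i < L.m; i++)
        for (int p = 0; p < L.npat; p++)
          L.tip_pat[(size_t)i * L.npat + p] = tp(i, p);
    } else L.npat = 0;
    ch.init_locus(L, tip_pop);
    // tip CLVs
    if (!ch.data_free) {
      size_t B = (size_t)L.npat * 4;
      L.clv.assign((size_t)L.M * B, 0.0);
      for (int i = 0; i < L.m; i++)
        for (int p = 0; p < L.npat; p++) {
          int st = L.tip_pat[(size_t)i * L.npat + p];
          for (int x = 0; x < 4; x++)
            L.clv[i * B + p * 4 + x] = (st < 0 || st == x) ? 1.0 : 0.0;
        }
    }
    ch.full_clv(L);
  }
  // stats caches
  ch.Ktot.assign(net.np, 0);
  ch.Ctot.assign(net.np, 0.0);
  ch.AltTot.assign(std::max(ch.H, 1), 0);
  ch.MainTot.assign(std::max(ch.H, 1), 0);
  for (int l = 0; l < nloci; l++) {
    Locus &L = ch.loci[l];
    if (!ch.locus_stats(L, 0, ch.nk, ch.nc, ch.nna, ch.nnm))
      stop("invalid initial gene tree state at locus %d", l + 1);
    L.pk = ch.nk; L.pc = ch.nc; L.nalt = ch.nna; L.nmain = ch.nnm;
    for (int p = 0; p < net.np; p++) {
      ch.Ktot[p] += L.pk[p]; ch.Ctot[p] += L.pc[p];
    }
    for (int h = 0; h < ch.H; h++) {
      ch.AltTot[h] += L.nalt[h]; ch.MainTot[h] += L.nmain[h];
    }
  }

  // output
  int npar = ntau + (ch.integrate_theta ? 0 : net.np) + ch.H + 1;
  NumericMatrix out(nsamples, npar);
  CharacterVector topo(ch.do_nni ? nsamples : 0);
  int rec = 0;
  int total_iter = burnin + nsamples * thin;
  double tune_acc[6][2];
  for (int i = 0; i < 6; i++) tune_acc[i][0] = tune_acc[i][1] = 0;

  for (int iter = 0; iter < total_iter; iter++) {
    for (int l = 0; l < nloci; l++) {
      Locus &L = ch.loci[l];
      for (int u = L.m; u < L.M; u++) ch.age_move(l, u);
      for (int q = 0; q < n_spr; q++) ch.spr_move(l);
      if (ch.H > 0) { ch.flip_move(l); ch.flip_move(l); }
    }
    for (int k = 0; k < ntau; k++) ch.tau_move(k);
    if (!ch.integrate_theta) ch.gibbs_theta();
    if (ch.H > 0) ch.gibbs_phi();
    if (ch.do_nni) { ch.nni_move(); ch.nni_move(); }
    ch.mix_move();

    if (autotune && iter < burnin && (iter + 1) % 50 == 0) {
      // steer acceptance toward ~0.3
      double dacc[6];
      for (int i = 0; i < 6; i++) {
        double tried = ch.acc[i][1] - tune_acc[i][1];
        double accd = ch.acc[i][0] - tune_acc[i][0];
        dacc[i] = tried > 0 ? accd / tried : 0.3;
        tune_acc[i][0] = ch.acc[i][0]; tune_acc[i][1] = ch.acc[i][1];
      }
      double f0 = std::exp(std::min(0.5, std::max(-0.5, dacc[0] - 0.3)));
      ch.w_age *= f0;
      double f3 = std::exp(std::min(0.5, std::max(-0.5, dacc[3] - 0.3)));
      for (int k = 0; k < ntau; k++) ch.w_tau[k] *= f3;
      double f4 = std::exp(std::min(0.5, std::max(-0.5, dacc[4] - 0.3)));
      ch.eps_mix *= f4;
    }
    if (iter == burnin - 1)   // freeze tallies at end of burn-in
      for (int i = 0; i < 6; i++) ch.acc[i][0] = ch.acc[i][1] = 0;

    if (iter >= burnin && ((iter - burnin + 1) % thin == 0)) {
      int col = 0;
      for (int k = 0; k < ntau; k++)
        out(rec, col++) = net.age[net.class_nodes[k][0]];
      if (!ch.integrate_theta)
        for (int p = 0; p < net.np; p++) out(rec, col++) = ch.theta[p];
      for (int h = 0; h < ch.H; h++) out(rec, col++) = net.phi[h];
      double ll = 0;
      for (int l = 0; l < nloci; l++) ll += ch.loci[l].loglik;
      out(rec, col++) = ll;
      if (ch.do_nni) topo[rec] = ch.topo_newick(labels);
      rec++;
      if (rec >= nsamples) { /* keep iterating only if thinning leftover */ }
    }
    if (rec >= nsamples) break;
    if (validate && (iter % 100) == 99) ch.validate_state();
    if ((iter & 63) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix accm(6, 2);
  for (int i = 0; i < 6; i++) {
    accm(i, 0) = ch.acc[i][0];
    accm(i, 1) = ch.acc[i][1];
  }
  return List::create(
    _["samples"] = out,
    _["topology"] = topo,
    _["acceptance"] = accm,
    _["w_age"] = ch.w_age,
    _["w_tau"] = NumericVector(ch.w_tau.begin(), ch.w_tau.end()),
    _["eps_mix"] = ch.eps_mix);
}
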