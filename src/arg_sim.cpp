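// Hudson-style ancestral recombination graph simulation constrained by a
// species tree / MSci network, in mutation-scaled time (expected
// substitutions per site).
//
// Populations are the branches of the network; a backward-time schedule of
// MERGE (children -> ancestral population) and ROUTE (hybrid node: move to
// the second parent's population with probability phi) events is compiled in
// R.  Within a population of size theta each lineage pair coalesces at rate
// 2/theta; each lineage recombines at rate rec_per_link per link spanned by
// its ancestral breadth (Hudson's convention: links strictly between its
// leftmost and rightmost ancestral material; events in trapped gaps count).
// Breakpoints are discrete links 1..n-1.  Simulation ends when every site
// has reached its marginal most recent common ancestor; material that has
// reached its MRCA is stripped so it no longer contributes breadth.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Seg {
  int start, end;   // sites [start, end)
  int node;         // marginal-forest node id carried for these sites
};

struct Lineage {
  std::vector<Seg> segs;  // sorted, disjoint, non-empty when active
  int first() const { return segs.front().start; }
  int last() const { return segs.back().end - 1; }
  int breadth() const { return segs.empty() ? 0 : last() - first(); }
};

struct Record {     // one marginal coalescence over a site interval
  double age;
  int child1, child2;
  int start, end;
};

}  // namespace

// [[Rcpp::export(name = ".arg_simulate_cpp")]]
List arg_simulate_cpp(NumericVector pop_theta,
                      IntegerVector sample_pop,    // 0-based population ids
                      int n_sites,
                      double rec_per_link,
                      NumericVector ev_time,
                      IntegerVector ev_type,       // 1 MERGE, 2 ROUTE
                      IntegerVector ev_src,        // 0-based
                      IntegerVector ev_dest,
                      IntegerVector ev_alt,
                      NumericVector ev_prob,
                      bool build_trees) {
  const int P = pop_theta.size();
  const int ns = sample_pop.size();
  if (ns < 2) stop("need at least 2 sampled sequences");
  if (n_sites < 2) stop("need at least 2 sites");
  for (int p = 0; p < P; p++)
    if (!(pop_theta[p] > 0)) stop("nonpositive theta on a population");

  std::vector<Lineage> pool;
  pool.reserve(4 * ns);
  std::vector<std::vector<int> > members(P);  // lineage ids per population

  std::vector<int> cnt(n_sites, ns);  // active lineages carrying each site
  int remaining = n_sites;            // sites not yet at their MRCA

  for (int i = 0; i < ns; i++) {
    Lineage l;
    l.segs.push_back(Seg{0, n_sites, i});
    pool.push_back(l);
    members[sample_pop[i]].push_back((int)pool.size() - 1);
  }

  std::vector<Record> records;
  int next_node = ns;
  std::vector<double> rec_times;
  std::vector<int> rec_links;
  // links where an event split ancestral material proper (not a trapped
  // gap): these are the segment boundaries ms-style tree output shows
  std::vector<char> link_mark(n_sites, 0);
  const int nev = ev_time.size();
  std::vector<int> route_alt(nev, 0), route_tot(nev, 0);

  double t = 0.0;
  int eidx = 0;
  long guard = 0;

  while (remaining > 0) {
    if (++guard > 100000000L) stop("simulation failed to terminate");
    // rates
    double coal_rate = 0.0;
    std::vector<double> pop_rate(P, 0.0);
    for (int p = 0; p < P; p++) {
      double k = (double)members[p].size();
      if (k >= 2) {
        pop_rate[p] = k * (k - 1.0) / pop_theta[p];
        coal_rate += pop_rate[p];
      }
    }
    double tot_breadth = 0.0;
    for (int p = 0; p < P; p++)
      for (size_t j = 0; j < members[p].size(); j++)
        tot_breadth += pool[members[p][j]].breadth();
    double rec_rate = rec_per_link * tot_breadth;
    double total = coal_rate + rec_rate;

    double t_next = R_PosInf;
    if (total > 0) t_next = t + exp_rand() / total;

    if (eidx < nev && ev_time[eidx] <= t_next) {
      // process all demographic events at this time point
      t = ev_time[eidx];
      double tcur = ev_time[eidx];
      while (eidx < nev && ev_time[eidx] == tcur) {
        int src = ev_src[eidx], dest = ev_dest[eidx];
        if (ev_type[eidx] == 1) {  // MERGE: move all lineages src -> dest
          for (size_t j = 0; j < members[src].size(); j++)
            members[dest].push_back(members[src][j]);
          members[src].clear();
        } else {                   // ROUTE
          int alt = ev_alt[eidx];
          double phi = ev_prob[eidx];
          for (size_t j = 0; j < members[src].size(); j++) {
            route_tot[eidx]++;
            if (unif_rand() < phi) {
              members[alt].push_back(members[src][j]);
              route_alt[eidx]++;
            } else {
              members[dest].push_back(members[src][j]);
            }
          }
          members[src].clear();
        }
        eidx++;
      }
      continue;
    }
    if (!R_FINITE(t_next)) {
      stop("no further events possible but %d site(s) have not coalesced",
           remaining);
    }
    t = t_next;

    if (unif_rand() * total < rec_rate) {
      // ---- recombination: pick lineage proportional to breadth ----
      double u = unif_rand() * tot_breadth;
      int lp = -1, li = -1;
      for (int p = 0; p < P && lp < 0; p++)
        for (size_t j = 0; j < members[p].size(); j++) {
          u -= pool[members[p][j]].breadth();
          if (u <= 0) { lp = p; li = (int)j; break; }
        }
      if (lp < 0) continue;  // numerical corner: no breadth anywhere
      int id = members[lp][li];
      Lineage &L = pool[id];
      // link l in [first+1, last]: left keeps sites < l, right keeps >= l
      int span = L.breadth();
      int link = L.first() + 1 + (int)(unif_rand() * span);
      if (link > L.last()) link = L.last();
      Lineage right;
      std::vector<Seg> left;
      for (size_t s = 0; s < L.segs.size(); s++) {
        Seg sg = L.segs[s];
        if (sg.end <= link) left.push_back(sg);
        else if (sg.start >= link) right.segs.push_back(sg);
        else {
          left.push_back(Seg{sg.start, link, sg.node});
          right.segs.push_back(Seg{link, sg.end, sg.node});
          link_mark[link] = 1;
        }
      }
      L.segs = left;
      pool.push_back(right);
      members[lp].push_back((int)pool.size() - 1);
      rec_times.push_back(t);
      rec_links.push_back(link);
    } else {
      // ---- coalescence: pick population, then a uniform pair ----
      double u = unif_rand() * coal_rate;
      int cp = P - 1;
      for (int p = 0; p < P; p++) { u -= pop_rate[p]; if (u <= 0) { cp = p; break; } }
      int k = (int)members[cp].size();
      int i1 = (int)(unif_rand() * k); if (i1 >= k) i1 = k - 1;
      int i2 = (int)(unif_rand() * (k - 1)); if (i2 >= k - 1) i2 = k - 2;
      if (i2 >= i1) i2++;
      int idA = members[cp][i1], idB = members[cp][i2];
      // remove both from population (swap-remove, larger index first)
      int hi = std::max(i1, i2), lo = std::min(i1, i2);
      members[cp][hi] = members[cp].back(); members[cp].pop_back();
      members[cp][lo] = members[cp].back(); members[cp].pop_back();

      // sweep-merge the two segment lists
      const std::vector<Seg> &A = pool[idA].segs, &B = pool[idB].segs;
      Lineage M;
      size_t ia = 0, ib = 0;
      int pos = std::min(A.empty() ? n_sites : A[0].start,
                         B.empty() ? n_sites : B[0].start);
      while (ia < A.size() || ib < B.size()) {
        // advance past segments that end at or before pos
        while (ia < A.size() && A[ia].end <= pos) ia++;
        while (ib < B.size() && B[ib].end <= pos) ib++;
        if (ia >= A.size() && ib >= B.size()) break;
        bool inA = ia < A.size() && A[ia].start <= pos;
        bool inB = ib < B.size() && B[ib].start <= pos;
        if (!inA && !inB) {
          int nxt = n_sites;
          if (ia < A.size()) nxt = std::min(nxt, A[ia].start);
          if (ib < B.size()) nxt = std::min(nxt, B[ib].start);
          pos = nxt;
          continue;
        }
        // next boundary
        int stop_at = n_sites;
        if (ia < A.size()) {
          if (A[ia].start > pos) stop_at = std::min(stop_at, A[ia].start);
          else stop_at = std::min(stop_at, A[ia].end);
        }
        if (ib < B.size()) {
          if (B[ib].start > pos) stop_at = std::min(stop_at, B[ib].start);
          else stop_at = std::min(stop_at, B[ib].end);
        }
        if (inA && inB) {
          // coalescence of this interval: new marginal node
          int nd = next_node++;
          if (build_trees)
            records.push_back(Record{t, A[ia].node, B[ib].node, pos, stop_at});
          // update per-site active counts; completed sites are stripped
          int run_start = pos;
          for (int s2 = pos; s2 < stop_at; s2++) {
            cnt[s2]--;
            if (cnt[s2] == 1) {
              remaining--;
              if (run_start < s2)
                M.segs.push_back(Seg{run_start, s2, nd});
              run_start = s2 + 1;
            }
          }
          if (run_start < stop_at)
            M.segs.push_back(Seg{run_start, stop_at, nd});
        } else if (inA) {
          M.segs.push_back(Seg{pos, stop_at, A[ia].node});
        } else {
          M.segs.push_back(Seg{pos, stop_at, B[ib].node});
        }
        pos = stop_at;
      }
      // merge adjacent segments with identical node ids
      std::vector<Seg> squashed;
      for (size_t s = 0; s < M.segs.size(); s++) {
        if (!squashed.empty() && squashed.back().node == M.segs[s].node &&
            squashed.back().end == M.segs[s].start)
          squashed.back().end = M.segs[s].end;
        else squashed.push_back(M.segs[s]);
      }
      M.segs = squashed;
      pool[idA].segs.clear();
      pool[idB].segs.clear();
      if (!M.segs.empty()) {
        pool.push_back(M);
        members[cp].push_back((int)pool.size() - 1);
      }
    }
  }

  // assemble output
  List out;
  out["n_events"] = (int)rec_times.size();
  {
    int nb = 0;
    for (int i = 0; i < n_sites; i++) nb += link_mark[i];
    out["n_breakpoints"] = nb;
  }
  out["event_time"] = NumericVector(rec_times.begin(), rec_times.end());
  out["event_link"] = IntegerVector(rec_links.begin(), rec_links.end());
  out["route_alt"] = IntegerVector(route_alt.begin(), route_alt.end());
  out["route_tot"] = IntegerVector(route_tot.begin(), route_tot.end());
  if (build_trees) {
    int K = (int)records.size();
    NumericVector rage(K);
    IntegerVector rc1(K), rc2(K), rstart(K), rend(K);
    for (int i = 0; i < K; i++) {
      rage[i] = records[i].age;
      rc1[i] = records[i].child1;
      rc2[i] = records[i].child2;
      rstart[i] = records[i].start;
      rend[i] = records[i].end;
    }
    // segment partition from record boundaries
    std::vector<int> bp;
    bp.push_back(0); bp.push_back(n_sites);
    for (int i = 0; i < K; i++) {
      if (rstart[i] > 0) bp.push_back(rstart[i]);
      if (rend[i] < n_sites) bp.push_back(rend[i]);
    }
    std::sort(bp.begin(), bp.end());
    bp.erase(std::unique(bp.begin(), bp.end()), bp.end());
    out["records"] = DataFrame::create(
      _["age"] = rage, _["child1"] = rc1, _["child2"] = rc2,
      _["start"] = rstart, _["end"] = rend);
    out["breakpoints"] = IntegerVector(bp.begin(), bp.end());
  }
  return out;
}
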