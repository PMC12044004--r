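// Structured n-coalescent without migration, piecewise-constant population
// sizes. Time runs backwards in generations; sizes are diploid N so a pair of
// lineages in a population of size N coalesces at rate 1/(2N) per generation.
// Events (pre-sorted by time on the R side):
//   type 0: split  -- lineages of pop p1 move into pop p2
//   type 1: resize -- pop p1 takes diploid size `size`
// The R RNG is used throughout so results are reproducible via set.seed().
#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdio>
using namespace Rcpp;

struct SimTree {
  int n;                      // number of tips
  std::vector<double> time;   // node times (tips first, time 0)
  std::vector<int> parent;    // -1 for root
  std::vector<int> lchild, rchild; // -1 for tips
};

static void sim_genealogy(const std::vector<int> &nhap,
                          std::vector<double> sizes,
                          const std::vector<double> &ev_time,
                          const std::vector<int> &ev_type,
                          const std::vector<int> &ev_p1,
                          const std::vector<int> &ev_p2,
                          const std::vector<double> &ev_size,
                          SimTree &tr) {
  const int P = (int)nhap.size();
  int n = 0;
  for (int p = 0; p < P; ++p) n += nhap[p];
  if (n < 2) stop("need at least two sampled haplotypes in total");
  tr.n = n;
  const int nnode = 2 * n - 1;
  tr.time.assign(nnode, 0.0);
  tr.parent.assign(nnode, -1);
  tr.lchild.assign(nnode, -1);
  tr.rchild.assign(nnode, -1);

  std::vector<std::vector<int> > active(P);
  int id = 0;
  for (int p = 0; p < P; ++p)
    for (int i = 0; i < nhap[p]; ++i) active[p].push_back(id++);

  int next_node = n, total = n, ei = 0;
  const int nev = (int)ev_time.size();
  double t = 0.0;

  while (total > 1) {
    double R = 0.0;
    for (int p = 0; p < P; ++p) {
      double k = (double)active[p].size();
      if (k >= 2.0) R += k * (k - 1.0) / (4.0 * sizes[p]);
    }
    double t_ev = (ei < nev) ? ev_time[ei] : R_PosInf;
    bool coalesced = false;
    if (R <= 0.0) {
      if (!R_FINITE(t_ev))
        stop("malformed demographic model: remaining lineages can never coalesce");
      t = t_ev;
    } else {
      double dt = exp_rand() / R;
      if (t + dt >= t_ev) {
        t = t_ev;
      } else {
        t += dt;
        double u = unif_rand() * R, acc = 0.0;
        int pc = -1;
        for (int p = 0; p < P; ++p) {
          double k = (double)active[p].size();
          if (k >= 2.0) {
            acc += k * (k - 1.0) / (4.0 * sizes[p]);
            pc = p;
            if (u <= acc) break;
          }
        }
        int k = (int)active[pc].size();
        int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
        int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
        if (j >= i) ++j;
        int a = active[pc][i], b = active[pc][j];
        int v = next_node++;
        tr.time[v] = t;
        tr.parent[a] = v; tr.parent[b] = v;
        tr.lchild[v] = a; tr.rchild[v] = b;
        if (i > j) std::swap(i, j);
        active[pc][i] = v;
        active[pc].erase(active[pc].begin() + j);
        --total;
        coalesced = true;
      }
    }
    if (!coalesced) {
      while (ei < nev && ev_time[ei] <= t) {
        if (ev_type[ei] == 0) {
          int p1 = ev_p1[ei], p2 = ev_p2[ei];
          for (size_t q = 0; q < active[p1].size(); ++q)
            active[p2].push_back(active[p1][q]);
          active[p1].clear();
        } else {
          sizes[ev_p1[ei]] = ev_size[ei];
        }
        ++ei;
      }
    }
  }
}

// tips below each node, creation order guarantees children precede parents
static void descendant_tips(const SimTree &tr, int v, std::vector<int> &out) {
  out.clear();
  std::vector<int> stack;
  stack.push_back(v);
  while (!stack.empty()) {
    int w = stack.back(); stack.pop_back();
    if (w < tr.n) out.push_back(w);
    else { stack.push_back(tr.lchild[w]); stack.push_back(tr.rchild[w]); }
  }
}

static std::string newick_node(const SimTree &tr, int v,
                               const std::vector<std::string> &labels,
                               double parent_time) {
  char buf[64];
  if (v < tr.n) {
    std::snprintf(buf, sizeof(buf), ":%.8g", parent_time - tr.time[v]);
    return labels[v] + buf;
  }
  std::string s = "(" + newick_node(tr, tr.lchild[v], labels, tr.time[v]) + "," +
                  newick_node(tr, tr.rchild[v], labels, tr.time[v]) + ")";
  if (R_FINITE(parent_time)) {
    std::snprintf(buf, sizeof(buf), ":%.8g", parent_time - tr.time[v]);
    s += buf;
  }
  return s;
}

// [[Rcpp::export]]
List cpp_simulate(IntegerVector nhap, NumericVector sizes,
                  NumericVector ev_time, IntegerVector ev_type,
                  IntegerVector ev_p1, IntegerVector ev_p2,
                  NumericVector ev_size,
                  int n_loci, double locus_len, double mu,
                  bool want_sites, bool one_snp_per_locus,
                  bool want_trees,
                  bool want_sfs, int focalA, int focalB) {
  const int P = nhap.size();
  std::vector<int> vn(nhap.begin(), nhap.end());
  std::vector<double> vsz(sizes.begin(), sizes.end());
  std::vector<double> vet(ev_time.begin(), ev_time.end());
  std::vector<int> vety(ev_type.begin(), ev_type.end());
  std::vector<int> vp1(ev_p1.begin(), ev_p1.end());
  std::vector<int> vp2(ev_p2.begin(), ev_p2.end());
  std::vector<double> ves(ev_size.begin(), ev_size.end());
  for (int p = 0; p < P; ++p)
    if (vsz[p] <= 0.0) stop("population sizes must be positive");

  int n = 0;
  for (int p = 0; p < P; ++p) n += vn[p];

  // pop of each tip, and per-tip focal membership
  std::vector<int> tip_pop(n);
  {
    int id = 0;
    for (int p = 0; p < P; ++p)
      for (int i = 0; i < vn[p]; ++i) tip_pop[id++] = p;
  }

  std::vector<std::string> labels(n);
  for (int i = 0; i < n; ++i) {
    char b[16];
    std::snprintf(b, sizeof(b), "h%d", i + 1);
    labels[i] = b;
  }

  NumericVector tmrca(n_loci);
  CharacterVector newicks(want_trees ? n_loci : 0);

  int nA = (want_sfs && focalA >= 0) ? vn[focalA] : 0;
  int nB = (want_sfs && focalB >= 0) ? vn[focalB] : 0;
  NumericMatrix sfs_w(want_sfs ? nA + 1 : 0, want_sfs ? nB + 1 : 0);

  std::vector<unsigned char> site_data; // site-major, n bytes per site
  std::vector<int> site_locus;

  SimTree tr;
  std::vector<int> tips;
  std::vector<int> cntA, cntB;

  for (int l = 0; l < n_loci; ++l) {
    sim_genealogy(vn, vsz, vet, vety, vp1, vp2, ves, tr);
    const int nnode = 2 * n - 1;
    tmrca[l] = tr.time[nnode - 1];
    if (want_trees)
      newicks[l] = newick_node(tr, nnode - 1, labels, R_PosInf) + ";";

    if (want_sfs) {
      cntA.assign(nnode, 0);
      cntB.assign(nnode, 0);
      for (int i = 0; i < n; ++i) {
        if (tip_pop[i] == focalA) cntA[i] = 1;
        if (tip_pop[i] == focalB) cntB[i] = 1;
      }
      for (int v = n; v < nnode; ++v) {
        cntA[v] = cntA[tr.lchild[v]] + cntA[tr.rchild[v]];
        cntB[v] = cntB[tr.lchild[v]] + cntB[tr.rchild[v]];
      }
      for (int v = 0; v < nnode - 1; ++v) {
        double len = tr.time[tr.parent[v]] - tr.time[v];
        sfs_w(cntA[v], cntB[v]) += len;
      }
    }

    if (want_sites) {
      if (one_snp_per_locus) {
        double tot = 0.0;
        for (int v = 0; v < nnode - 1; ++v)
          tot += tr.time[tr.parent[v]] - tr.time[v];
        double u = unif_rand() * tot, acc = 0.0;
        int chosen = nnode - 2;
        for (int v = 0; v < nnode - 1; ++v) {
          acc += tr.time[tr.parent[v]] - tr.time[v];
          if (u <= acc) { chosen = v; break; }
        }
        descendant_tips(tr, chosen, tips);
        size_t off = site_data.size();
        site_data.resize(off + n, 0);
        for (size_t q = 0; q < tips.size(); ++q) site_data[off + tips[q]] = 1;
        site_locus.push_back(l + 1);
      } else {
        for (int v = 0; v < nnode - 1; ++v) {
          double len = tr.time[tr.parent[v]] - tr.time[v];
          int nm = (int)R::rpois(mu * locus_len * len);
          if (nm > 0) {
            descendant_tips(tr, v, tips);
            for (int m = 0; m < nm; ++m) {
              size_t off = site_data.size();
              site_data.resize(off + n, 0);
              for (size_t q = 0; q < tips.size(); ++q)
                site_data[off + tips[q]] = 1;
              site_locus.push_back(l + 1);
            }
          }
        }
      }
    }
  }

  List out = List::create(_["tmrca"] = tmrca);
  if (want_trees) out["newick"] = newicks;
  if (want_sfs) out["sfs_weights"] = sfs_w;
  if (want_sites) {
    int nsites = (int)site_locus.size();
    RawMatrix H(n, nsites); // haplotypes x sites
    for (int s = 0; s < nsites; ++s)
      for (int i = 0; i < n; ++i)
        H(i, s) = site_data[(size_t)s * n + i];
    out["haplotypes"] = H;
    out["site_locus"] = wrap(site_locus);
  }
  return out;
}
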