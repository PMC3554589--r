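// Coalescent simulator with recombination (ancestral recombination graph)
// under a piecewise-constant population-size history, conditioned on a
// fixed number of segregating sites placed uniformly on the unit
// interval (ms "-s" semantics: one mutation per site, dropped on the
// site's marginal genealogy proportional to branch length).
//
// Time is measured in units of 4N0 generations; with k lineages and
// relative size x the total coalescence rate is k(k-1)/x and each
// lineage recombines at rate (rho/2) * (span of its ancestral material).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Lineage {
  std::vector<int> node;  // node id per site, -1 = not ancestral here
  int nsites;
  double left, right;     // positions of outermost ancestral sites
};

void refresh_bounds(Lineage &lin, const std::vector<double> &pos) {
  lin.nsites = 0;
  lin.left = 1.0;
  lin.right = 0.0;
  for (size_t s = 0; s < lin.node.size(); ++s) {
    if (lin.node[s] >= 0) {
      ++lin.nsites;
      if (pos[s] < lin.left) lin.left = pos[s];
      if (pos[s] > lin.right) lin.right = pos[s];
    }
  }
  if (lin.nsites == 0) { lin.left = 0.0; lin.right = 0.0; }
}

// population size at time t for ms-style -eN events (times ascending);
// size 1 before the first event time (looking backward from 0)
double size_at(double t, const NumericVector &etimes,
               const NumericVector &esizes) {
  double x = 1.0;
  for (int i = 0; i < etimes.size(); ++i)
    if (t >= etimes[i]) x = esizes[i];
  return x;
}

double next_boundary(double t, const NumericVector &etimes) {
  for (int i = 0; i < etimes.size(); ++i)
    if (etimes[i] > t) return etimes[i];
  return R_PosInf;
}

}  // namespace

// [[Rcpp::export(name = ".coalescent_sim_cpp")]]
List coalescent_sim_cpp(int n, int S, double rho,
                        NumericVector etimes, NumericVector esizes) {
  if (n < 2) stop("need n >= 2 chromosomes");
  if (S < 1) stop("need S >= 1 sites");
  std::vector<double> pos(S);
  for (int s = 0; s < S; ++s) pos[s] = unif_rand();
  std::sort(pos.begin(), pos.end());

  std::vector<Lineage> lin;
  lin.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    Lineage L;
    L.node.assign(S, 0);
    for (int s = 0; s < S; ++s) L.node[s] = i;
    refresh_bounds(L, pos);
    lin.push_back(L);
  }
  std::vector<int> kper(S, n);          // active lineages per site
  int sites_open = S;
  int next_node = n;
  std::vector<double> node_time(n, 0.0);
  // per-site marginal-tree events: child1, child2, parent
  std::vector<std::vector<int> > ev_c1(S), ev_c2(S), ev_par(S);
  for (int s = 0; s < S; ++s) {
    ev_c1[s].reserve(n - 1);
    ev_c2[s].reserve(n - 1);
    ev_par[s].reserve(n - 1);
  }

  double t = 0.0;
  long guard = 0;
  while (sites_open > 0) {
    if (++guard > 100000000L) stop("coalescent failed to terminate");
    int k = (int)lin.size();
    double x = size_at(t, etimes, esizes);
    double coal = (double)k * (k - 1) / x;
    double span_sum = 0.0;
    for (int i = 0; i < k; ++i)
      if (lin[i].nsites > 1) span_sum += lin[i].right - lin[i].left;
    double rec = 0.5 * rho * span_sum;
    double total = coal + rec;
    if (total <= 0.0) stop("rate underflow in coalescent");
    double dt = exp_rand() / total;
    double bound = next_boundary(t, etimes);
    if (t + dt > bound) { t = bound; continue; }
    t += dt;
    if (unif_rand() * total < rec) {
      // recombination: pick lineage by span, break uniformly within it
      double u = unif_rand() * span_sum;
      int pick = -1;
      for (int i = 0; i < k; ++i) {
        if (lin[i].nsites <= 1) continue;
        u -= lin[i].right - lin[i].left;
        if (u <= 0) { pick = i; break; }
      }
      if (pick < 0) continue;
      double brk = lin[pick].left +
        unif_rand() * (lin[pick].right - lin[pick].left);
      Lineage right;
      right.node.assign(S, -1);
      for (int s = 0; s < S; ++s) {
        if (lin[pick].node[s] >= 0 && pos[s] > brk) {
          right.node[s] = lin[pick].node[s];
          lin[pick].node[s] = -1;
        }
      }
      refresh_bounds(right, pos);
      refresh_bounds(lin[pick], pos);
      if (right.nsites > 0 && lin[pick].nsites > 0) {
        lin.push_back(right);
      } else if (right.nsites > 0) {
        lin[pick] = right;  // breakpoint left of all material
      }
    } else {
      // coalescence of a uniformly chosen pair
      int i = (int)(unif_rand() * k);
      int j = (int)(unif_rand() * (k - 1));
      if (j >= i) ++j;
      if (i > j) std::swap(i, j);
      Lineage &A = lin[i];
      Lineage &B = lin[j];
      int v = next_node++;
      node_time.push_back(t);
      Lineage merged;
      merged.node.assign(S, -1);
      for (int s = 0; s < S; ++s) {
        int a = A.node[s], b = B.node[s];
        if (a >= 0 && b >= 0) {
          ev_c1[s].push_back(a);
          ev_c2[s].push_back(b);
          ev_par[s].push_back(v);
          if (--kper[s] == 1) {
            merged.node[s] = -1;  // site has reached its MRCA
            --sites_open;
          } else {
            merged.node[s] = v;
          }
        } else if (a >= 0) {
          merged.node[s] = a;
        } else if (b >= 0) {
          merged.node[s] = b;
        }
      }
      refresh_bounds(merged, pos);
      lin.erase(lin.begin() + j);
      lin.erase(lin.begin() + i);
      if (merged.nsites > 0) lin.push_back(merged);
      if (lin.empty() && sites_open > 0)
        stop("internal error: lost ancestral material");
    }
  }

  // drop one mutation per site, branch chosen proportional to length
  IntegerMatrix mat(n, S);
  std::vector<int> kids;
  for (int s = 0; s < S; ++s) {
    int ne = (int)ev_par[s].size();
    // branch lengths: every child edge of every event
    double tot = 0.0;
    std::vector<double> blen(2 * ne);
    for (int e = 0; e < ne; ++e) {
      blen[2 * e] = node_time[ev_par[s][e]] - node_time[ev_c1[s][e]];
      blen[2 * e + 1] = node_time[ev_par[s][e]] - node_time[ev_c2[s][e]];
      tot += blen[2 * e] + blen[2 * e + 1];
    }
    double u = unif_rand() * tot;
    int chosen = -1;
    for (int b = 0; b < 2 * ne; ++b) {
      u -= blen[b];
      if (u <= 0) { chosen = b; break; }
    }
    if (chosen < 0) chosen = 2 * ne - 1;
    int top = (chosen % 2 == 0) ? ev_c1[s][chosen / 2]
                                : ev_c2[s][chosen / 2];
    // leaves below `top` in this site's marginal tree
    kids.clear();
    kids.push_back(top);
    while (!kids.empty()) {
      int v = kids.back();
      kids.pop_back();
      if (v < n) {
        mat(v, s) = 1;
        continue;
      }
      for (int e = 0; e < ne; ++e) {
        if (ev_par[s][e] == v) {
          kids.push_back(ev_c1[s][e]);
          kids.push_back(ev_c2[s][e]);
          break;
        }
      }
    }
  }
  return List::create(Named("mat") = mat,
                      Named("positions") = NumericVector(pos.begin(),
                                                         pos.end()));
}
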