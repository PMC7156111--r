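#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic gene-for-gene recursion, one host generation (two parasite
// infection cycles, auto-infection). State is (R, a1); a2 is the within-
// generation infective frequency after the second cycle.
// ---------------------------------------------------------------------------
static inline void gfg_step_c(double R, double a1, double s, double cH, double cP,
                              double &Rn, double &a1n, double &a2) {
  const double s1 = s, s2 = s / 2.0;
  const double r = 1.0 - R, A1 = 1.0 - a1;

  const double den_a = a1 * (1.0 - cP) + A1 * r;
  if (den_a < 1e-300)
    stop("degenerate denominator in second-cycle parasite recursion (R = 1, a = 0)");
  a2 = a1 * (1.0 - cP) / den_a;
  const double A2 = 1.0 - a2;

  const double num_b = (1.0 - cP) * (R * (A1 * a2 + a1) + r * a1);
  const double den_b = num_b + r * A1;
  if (den_b < 1e-300)
    stop("degenerate denominator in parasite recursion");
  a1n = num_b / den_b;

  const double num_c = R * (1.0 - cH) *
    (A1 * A2 + A1 * a2 * (1.0 - s2) + a1 * (1.0 - s1));
  const double den_c = num_c + r * (1.0 - s1);
  if (den_c < 1e-300)
    stop("degenerate denominator in host recursion");
  Rn = num_c / den_c;
}

// [[Rcpp::export]]
NumericVector cpp_gfg_step(double R, double a1, double s, double cH, double cP) {
  double Rn, a1n, a2;
  gfg_step_c(R, a1, s, cH, cP, Rn, a1n, a2);
  return NumericVector::create(_["R"] = Rn, _["a1"] = a1n, _["a2"] = a2);
}

// Deterministic trajectory: rows 0..g_max; a2[i] is the within-generation
// value of the step leaving state i (NA for the final row).
// [[Rcpp::export]]
NumericMatrix cpp_gfg_iterate(double R0, double a0, int g_max,
                              double s, double cH, double cP) {
  NumericMatrix out(g_max + 1, 3);
  double R = R0, a1 = a0;
  out(0, 0) = R; out(0, 1) = a1;
  for (int g = 0; g < g_max; ++g) {
    double Rn, a1n, a2;
    gfg_step_c(R, a1, s, cH, cP, Rn, a1n, a2);
    out(g, 2) = a2;
    R = Rn; a1 = a1n;
    out(g + 1, 0) = R; out(g + 1, 1) = a1;
  }
  out(g_max, 2) = NA_REAL;
  return out;
}

// ---------------------------------------------------------------------------
// Stochastic frequency path: deterministic step, binomial drift, recurrent
// functional mutation (binomial counts of switching individuals), recorded
// as integer allele counts at the start of each host generation.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_forward_path(int NH, int NP, double R0, double a0, int g_max,
                      double s, double cH, double cP,
                      double mu_Rtor, double mu_rtoR,
                      double mu_ntoI, double mu_Iton) {
  IntegerVector host(g_max + 1), para(g_max + 1);
  int H = (int) std::lround(R0 * NH);
  int P = (int) std::lround(a0 * NP);
  host[0] = H; para[0] = P;
  for (int g = 1; g <= g_max; ++g) {
    double Rn, a1n, a2;
    if (H == NH && P == 0) {
      // corner state: resistant hosts fixed, infective parasites absent.
      // Non-infective parasites cannot reproduce on resistant hosts, but
      // population sizes are constant by assumption, so the allele
      // frequencies carry over unchanged (R' = 1 is also the r -> 0 limit of
      // the host recursion); recurrent mutation can re-seed both alleles.
      Rn = 1.0; a1n = 0.0;
    } else {
      gfg_step_c((double) H / NH, (double) P / NP, s, cH, cP, Rn, a1n, a2);
    }
    H = (int) R::rbinom(NH, Rn);
    P = (int) R::rbinom(NP, a1n);
    H += (int) R::rbinom(NH - H, mu_rtoR) - (int) R::rbinom(H, mu_Rtor);
    P += (int) R::rbinom(NP - P, mu_ntoI) - (int) R::rbinom(P, mu_Iton);
    if (H < 0) H = 0; else if (H > NH) H = NH;
    if (P < 0) P = 0; else if (P > NP) P = NP;
    host[g] = H; para[g] = P;
  }
  return List::create(_["host"] = host, _["parasite"] = para);
}

// ---------------------------------------------------------------------------
// Genealogy containers: nodes are numbered from 0; leaves are 0..n-1 at time
// 0 (generations before present). parent = -1 marks the root.
// ---------------------------------------------------------------------------
struct TreeBuild {
  std::vector<int> parent;
  std::vector<double> time;
  int new_node(double t) {
    parent.push_back(-1);
    time.push_back(t);
    return (int) parent.size() - 1;
  }
};

static List tree_to_list(const TreeBuild &tb, int n_leaves) {
  return List::create(_["parent"] = IntegerVector(tb.parent.begin(), tb.parent.end()),
                      _["time"] = NumericVector(tb.time.begin(), tb.time.end()),
                      _["n_leaves"] = n_leaves);
}

// Discrete-generation Kingman coalescent in a panmictic population of size N,
// starting from k lineages at time t0. Waiting times are geometric with
// per-generation success probability 1 - prod(1 - i/N); a uniformly chosen
// pair merges. Operates in place on the active lineage list.
static void kingman_tail(TreeBuild &tb, std::vector<int> &active, int N, double t0) {
  double t = t0;
  while (active.size() > 1) {
    int k = (int) active.size();
    double q = 1.0;
    for (int i = 1; i < k; ++i) q *= 1.0 - (double) i / N;
    q = 1.0 - q;
    t += 1.0 + R::rgeom(q);
    int i = (int) (unif_rand() * k); if (i >= k) i = k - 1;
    int j = (int) (unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
    if (j >= i) ++j;
    int node = tb.new_node(t);
    tb.parent[active[i]] = node;
    tb.parent[active[j]] = node;
    if (i > j) std::swap(i, j);
    active[i] = node;
    active.erase(active.begin() + j);
  }
}

// [[Rcpp::export]]
List cpp_kingman_genealogy(int N, int n) {
  TreeBuild tb;
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) { tb.new_node(0.0); active[i] = i; }
  kingman_tail(tb, active, N, 0.0);
  return tree_to_list(tb, n);
}

// ---------------------------------------------------------------------------
// Structured coalescent conditioned on a frequency path of the derived
// functional allele. derived_counts has g_max+1 entries; entry g_max is the
// present. Backward in time, lineages live in two classes whose sizes follow
// the path; within a class each lineage picks a parent uniformly among the
// class members of the previous generation (identical picks merge,
// Wright-Fisher style). A lineage's parent sits in the other class with
// probability min(1, mu_fwd * X_other(g-1) / X_own(g)) -- the backward shadow
// of forward functional mutation -- and with probability one when its own
// class is empty in the previous generation (allele origin). Older than the
// path, surviving lineages coalesce as a discrete Kingman process of size N.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_conditioned_genealogy(IntegerVector derived_counts, int N, int n,
                               int k_derived, double mu_gain, double mu_loss) {
  const int g_max = derived_counts.size() - 1;
  TreeBuild tb;
  std::vector<int> active;   // node ids of live lineages
  std::vector<int> cls;      // 0 = ancestral class, 1 = derived class
  active.reserve(2 * n); cls.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    tb.new_node(0.0);
    active.push_back(i);
    cls.push_back(i < k_derived ? 1 : 0);
  }

  std::vector<int> pcls(n), pidx(n);
  for (int g = g_max; g >= 1 && active.size() > 1; --g) {
    const int Xd_now = derived_counts[g];
    const int Xd_prev = derived_counts[g - 1];
    const int Xa_now = N - Xd_now, Xa_prev = N - Xd_prev;
    const double t_parent = (double) (g_max - g + 1);
    const int k = (int) active.size();
    pcls.resize(k); pidx.resize(k);

    // parent class of every lineage
    int n_to_d = 0, n_to_a = 0;
    for (int i = 0; i < k; ++i) {
      const int c = cls[i];
      const int X_own_prev = c ? Xd_prev : Xa_prev;
      const int X_other_prev = c ? Xa_prev : Xd_prev;
      const int X_own_now = c ? Xd_now : Xa_now;
      if (X_own_now <= 0)
        stop("inconsistent frequency path: lineage in an empty class at generation %d", g);
      int pc = c;
      if (X_own_prev == 0) {
        pc = 1 - c;                       // allele origin: forced relocation
      } else if (X_other_prev > 0) {
        const double mu = c ? mu_gain : mu_loss;
        double pmig = mu * (double) X_other_prev / (double) X_own_now;
        if (pmig >= 1.0 || (pmig > 0.0 && unif_rand() < pmig)) pc = 1 - c;
      }
      pcls[i] = pc;
      if (pc) ++n_to_d; else ++n_to_a;
    }

    // parent index within the class (collision = coalescence); lineages that
    // are alone in their parent class cannot collide, so no draw is needed
    for (int i = 0; i < k; ++i) {
      const int pool = pcls[i] ? Xd_prev : Xa_prev;
      const int crowd = pcls[i] ? n_to_d : n_to_a;
      if (crowd > 1) {
        int j = (int) (unif_rand() * pool);
        if (j >= pool) j = pool - 1;
        pidx[i] = j;
      } else {
        pidx[i] = -1 - i;                 // unique sentinel, never collides
      }
    }

    // merge lineages sharing (parent class, parent index)
    std::vector<int> new_active, new_cls;
    std::vector<bool> done(k, false);
    for (int i = 0; i < k; ++i) {
      if (done[i]) continue;
      std::vector<int> grp(1, i);
      for (int j = i + 1; j < k; ++j)
        if (!done[j] && pcls[j] == pcls[i] && pidx[j] == pidx[i] && pidx[i] >= 0)
          grp.push_back(j);
      if (grp.size() > 1) {
        int node = tb.new_node(t_parent);
        for (size_t m = 0; m < grp.size(); ++m) {
          tb.parent[active[grp[m]]] = node;
          done[grp[m]] = true;
        }
        new_active.push_back(node);
      } else {
        done[i] = true;
        new_active.push_back(active[i]);
      }
      new_cls.push_back(pcls[i]);
    }
    active.swap(new_active);
    cls.swap(new_cls);
  }

  if (active.size() > 1)
    kingman_tail(tb, active, N, (double) g_max);
  return tree_to_list(tb, n);
}

// ---------------------------------------------------------------------------
// Infinite-sites neutral mutations: Poisson(branch length * locus_rate) per
// branch, uniform positions on [0,1) (collisions redrawn), derived state for
// all leaves below the branch. Columns are returned sorted by position.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_drop_mutations(IntegerVector parent, NumericVector time, int n_leaves,
                        double locus_rate) {
  const int n_nodes = parent.size();

  // children lists for leaf collection
  std::vector< std::vector<int> > children(n_nodes);
  for (int i = 0; i < n_nodes; ++i)
    if (parent[i] >= 0) children[parent[i]].push_back(i);

  std::vector<int> mut_node;
  for (int i = 0; i < n_nodes; ++i) {
    if (parent[i] < 0) continue;
    const double b = time[parent[i]] - time[i];
    const int m = (int) R::rpois(b * locus_rate);
    for (int j = 0; j < m; ++j) mut_node.push_back(i);
  }
  const int S = (int) mut_node.size();

  NumericVector pos(S);
  for (int j = 0; j < S; ++j) {
    bool fresh = false;
    double u = 0.0;
    while (!fresh) {
      u = unif_rand();
      fresh = true;
      for (int m = 0; m < j; ++m) if (pos[m] == u) { fresh = false; break; }
    }
    pos[j] = u;
  }

  IntegerMatrix geno(n_leaves, S);
  std::vector<int> stack;
  for (int j = 0; j < S; ++j) {
    stack.clear();
    stack.push_back(mut_node[j]);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (v < n_leaves) geno(v, j) = 1;
      for (size_t c = 0; c < children[v].size(); ++c) stack.push_back(children[v][c]);
    }
  }

  // sort columns by position
  IntegerVector ord(S);
  std::vector<int> idx(S);
  for (int j = 0; j < S; ++j) idx[j] = j;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return pos[a] < pos[b]; });
  IntegerMatrix geno_s(n_leaves, S);
  NumericVector pos_s(S);
  for (int j = 0; j < S; ++j) {
    pos_s[j] = pos[idx[j]];
    for (int i = 0; i < n_leaves; ++i) geno_s(i, j) = geno(i, idx[j]);
  }
  return List::create(_["genotypes"] = geno_s, _["positions"] = pos_s);
}
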