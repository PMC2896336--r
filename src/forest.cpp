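// Genotype-specialized random forest engine: bagged unpruned CART trees over
// 0/1/2 minor-allele dosages, random per-node candidate subsets, weighted
// Gini splits over the three binary partitions of {0,1,2}, out-of-bag error
// and permutation variable importance.
//
// All randomness comes from a self-contained splitmix64-based generator with
// per-tree streams derived from the master seed by tree index, so results
// are bit-reproducible and independent of evaluation order and platform.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG

static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed) {}
  uint64_t next() {
    state += 0x9E3779B97F4A7C15ULL;
    uint64_t z = state;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n), Lemire multiply-shift
  int below(int n) {
    uint64_t x = next();
    __uint128_t m = ( (__uint128_t) x ) * ( (__uint128_t) (uint64_t) n );
    return (int) (uint64_t) (m >> 64);
  }
};

static inline uint64_t tree_stream_seed(double seed_d, int tree) {
  uint64_t s = (uint64_t) (int64_t) seed_d;
  return mix64(mix64(s) + 0x9E3779B97F4A7C15ULL * (uint64_t) (tree + 1));
}

// Fisher-Yates shuffle of idx[0..n) using rng (backward convention)
static void shuffle_vec(std::vector<int> &idx, Rng &rng) {
  for (int k = (int) idx.size() - 1; k >= 1; --k) {
    int j = rng.below(k + 1);
    std::swap(idx[k], idx[j]);
  }
}

// ---------------------------------------------------------------------------
// Split search

// Left-branch genotype sets, in fixed tie-break order:
//   part 1: {0} | {1,2};  part 2: {0,1} | {2};  part 3: {0,2} | {1}
static inline bool in_left(int part, int g) {
  switch (part) {
  case 1: return g == 0;
  case 2: return g <= 1;
  default: return g != 1;
  }
}

struct SplitRes {
  bool found;
  int snp;      // 0-based column
  int part;     // 1..3
  double dec;   // weighted Gini impurity decrease
};

// counts[g][c]: weighted class counts for genotype g, class c at this node
static SplitRes best_split_core(const int *geno, int n, int /*p*/,
                                const int *y, const double w[2],
                                const std::vector<int> &smp, int start, int end,
                                const std::vector<int> &cands) {
  SplitRes best = {false, -1, 0, 0.0};
  double W0 = 0.0, W1 = 0.0;
  for (int k = start; k < end; ++k) {
    if (y[smp[k]] == 0) W0 += w[0]; else W1 += w[1];
  }
  double W = W0 + W1;
  if (W0 == 0.0 || W1 == 0.0) return best;  // pure node
  double gini_parent = 1.0 - (W0 * W0 + W1 * W1) / (W * W);

  for (size_t ci = 0; ci < cands.size(); ++ci) {
    int s = cands[ci];
    const int *col = geno + (size_t) n * (size_t) s;
    double cnt[3][2] = {{0, 0}, {0, 0}, {0, 0}};
    for (int k = start; k < end; ++k) {
      int i = smp[k];
      cnt[col[i]][y[i]] += w[y[i]];
    }
    for (int part = 1; part <= 3; ++part) {
      double L0 = 0.0, L1 = 0.0;
      for (int g = 0; g < 3; ++g) {
        if (in_left(part, g)) { L0 += cnt[g][0]; L1 += cnt[g][1]; }
      }
      double R0 = W0 - L0, R1 = W1 - L1;
      double WL = L0 + L1, WR = R0 + R1;
      if (WL == 0.0 || WR == 0.0) continue;  // empty side: invalid here
      double gini_l = 1.0 - (L0 * L0 + L1 * L1) / (WL * WL);
      double gini_r = 1.0 - (R0 * R0 + R1 * R1) / (WR * WR);
      double dec = gini_parent - (WL * gini_l + WR * gini_r) / W;
      if (!best.found || dec > best.dec) {
        best.found = true; best.snp = s; best.part = part; best.dec = dec;
      }
    }
  }
  return best;
}

// ---------------------------------------------------------------------------
// Tree growth

struct Tree {
  std::vector<int> split_snp;  // -1 terminal
  std::vector<int> part;       // 0 terminal
  std::vector<int> left, right;
  std::vector<double> v0, v1;  // weighted class counts at node

  int new_node() {
    split_snp.push_back(-1); part.push_back(0);
    left.push_back(-1); right.push_back(-1);
    v0.push_back(0.0); v1.push_back(0.0);
    return (int) split_snp.size() - 1;
  }
  int size() const { return (int) split_snp.size(); }
};

struct NodeRange { int node, start, end; };

// grow one unpruned tree on the bootstrap sample `smp` (sample indices with
// multiplicity); perm is a reusable 0..p-1 workspace for mtry draws
static Tree grow_tree_core(const int *geno, int n, int p, const int *y,
                           const double w[2], std::vector<int> smp,
                           int mtry, Rng &rng, std::vector<int> &perm) {
  Tree tr;
  std::vector<int> cands(mtry);
  std::vector<NodeRange> stack;
  int root = tr.new_node();
  stack.push_back({root, 0, (int) smp.size()});

  while (!stack.empty()) {
    NodeRange nr = stack.back(); stack.pop_back();
    double W0 = 0.0, W1 = 0.0;
    for (int k = nr.start; k < nr.end; ++k) {
      if (y[smp[k]] == 0) W0 += w[0]; else W1 += w[1];
    }
    tr.v0[nr.node] = W0; tr.v1[nr.node] = W1;
    if (W0 == 0.0 || W1 == 0.0) continue;  // pure -> terminal

    // fresh uniform subset of mtry distinct SNPs
    for (int i = 0; i < mtry; ++i) {
      int j = i + rng.below(p - i);
      std::swap(perm[i], perm[j]);
    }
    for (int i = 0; i < mtry; ++i) cands[i] = perm[i];
    std::sort(cands.begin(), cands.end());

    SplitRes sp = best_split_core(geno, n, p, y, w, smp, nr.start, nr.end, cands);
    if (!sp.found) continue;  // no candidate varies here -> terminal

    tr.split_snp[nr.node] = sp.snp;
    tr.part[nr.node] = sp.part;
    const int *col = geno + (size_t) n * (size_t) sp.snp;
    int partc = sp.part;
    std::vector<int>::iterator mid = std::stable_partition(
        smp.begin() + nr.start, smp.begin() + nr.end,
        [col, partc](int i) { return in_left(partc, col[i]); });
    int m = (int) (mid - smp.begin());
    int L = tr.new_node(), R = tr.new_node();
    tr.left[nr.node] = L; tr.right[nr.node] = R;
    stack.push_back({R, m, nr.end});
    stack.push_back({L, nr.start, m});
  }
  return tr;
}

// pass sample i down the tree; returns terminal node index
static inline int drop_down(const Tree &tr, const int *geno, int n, int i) {
  int node = 0;
  while (tr.split_snp[node] >= 0) {
    int g = geno[(size_t) n * (size_t) tr.split_snp[node] + i];
    node = in_left(tr.part[node], g) ? tr.left[node] : tr.right[node];
  }
  return node;
}

// tree-level class vote at terminal: weighted argmax, tie -> control (0)
static inline int terminal_class(const Tree &tr, int node) {
  return (tr.v1[node] > tr.v0[node]) ? 1 : 0;
}

// ---------------------------------------------------------------------------
// R interface helpers

static List tree_to_list(const Tree &tr) {
  int m = tr.size();
  IntegerMatrix nodes(m, 4);
  NumericMatrix votes(m, 2);
  for (int i = 0; i < m; ++i) {
    nodes(i, 0) = tr.split_snp[i] >= 0 ? tr.split_snp[i] + 1 : NA_INTEGER;
    nodes(i, 1) = tr.part[i] > 0 ? tr.part[i] : NA_INTEGER;
    nodes(i, 2) = tr.left[i] >= 0 ? tr.left[i] + 1 : NA_INTEGER;
    nodes(i, 3) = tr.right[i] >= 0 ? tr.right[i] + 1 : NA_INTEGER;
    votes(i, 0) = tr.v0[i];
    votes(i, 1) = tr.v1[i];
  }
  colnames(nodes) = CharacterVector::create("split_snp", "partition",
                                            "left", "right");
  colnames(votes) = CharacterVector::create("control", "case");
  return List::create(_["nodes"] = nodes, _["votes"] = votes);
}

static Tree tree_from_list(const List &tl) {
  IntegerMatrix nodes = tl["nodes"];
  NumericMatrix votes = tl["votes"];
  Tree tr;
  int m = nodes.nrow();
  tr.split_snp.resize(m); tr.part.resize(m);
  tr.left.resize(m); tr.right.resize(m);
  tr.v0.resize(m); tr.v1.resize(m);
  for (int i = 0; i < m; ++i) {
    tr.split_snp[i] = nodes(i, 0) == NA_INTEGER ? -1 : nodes(i, 0) - 1;
    tr.part[i]  = nodes(i, 1) == NA_INTEGER ? 0 : nodes(i, 1);
    tr.left[i]  = nodes(i, 2) == NA_INTEGER ? -1 : nodes(i, 2) - 1;
    tr.right[i] = nodes(i, 3) == NA_INTEGER ? -1 : nodes(i, 3) - 1;
    tr.v0[i] = votes(i, 0); tr.v1[i] = votes(i, 1);
  }
  return tr;
}

// ---------------------------------------------------------------------------
// Exported: split search (for brute-force oracle comparison)

// [[Rcpp::export]]
SEXP cpp_best_split(IntegerMatrix geno, IntegerVector y, IntegerVector rows,
                    IntegerVector candidates, double w0, double w1) {
  int n = geno.nrow();
  double w[2] = {w0, w1};
  std::vector<int> smp(rows.size());
  for (int k = 0; k < rows.size(); ++k) smp[k] = rows[k] - 1;
  std::vector<int> cands(candidates.size());
  for (int k = 0; k < candidates.size(); ++k) cands[k] = candidates[k] - 1;
  std::sort(cands.begin(), cands.end());
  SplitRes sp = best_split_core(geno.begin(), n, geno.ncol(), y.begin(), w,
                                smp, 0, (int) smp.size(), cands);
  if (!sp.found) return R_NilValue;
  return List::create(_["snp"] = sp.snp + 1, _["partition"] = sp.part,
                      _["decrease"] = sp.dec);
}

// ---------------------------------------------------------------------------
// Exported: single tree (determinism replay, CART-oracle comparison)

// [[Rcpp::export]]
List cpp_grow_tree(IntegerMatrix geno, IntegerVector y, IntegerVector boot,
                   int mtry, double w0, double w1, double seed) {
  int n = geno.nrow(), p = geno.ncol();
  double w[2] = {w0, w1};
  std::vector<int> smp(boot.size());
  for (int k = 0; k < boot.size(); ++k) smp[k] = boot[k] - 1;
  Rng rng(mix64((uint64_t) (int64_t) seed));
  std::vector<int> perm(p);
  for (int i = 0; i < p; ++i) perm[i] = i;
  Tree tr = grow_tree_core(geno.begin(), n, p, y.begin(), w, smp, mtry,
                           rng, perm);
  return tree_to_list(tr);
}

// ---------------------------------------------------------------------------
// Exported: full forest

// [[Rcpp::export]]
List cpp_grow_forest(IntegerMatrix geno, IntegerVector y, int ntree, int mtry,
                     double w0, double w1, double seed) {
  int n = geno.nrow(), p = geno.ncol();
  double w[2] = {w0, w1};
  const int *gp = geno.begin();
  const int *yp = y.begin();

  List trees(ntree);
  IntegerMatrix boot_out(ntree, n);
  List oob_out(ntree);
  NumericVector traj_bal(ntree), traj_raw(ntree);
  NumericMatrix votes_acc(n, 2);  // accumulated tree votes per sample
  std::vector<int> perm(p);
  std::vector<char> inbag(n);

  for (int t = 0; t < ntree; ++t) {
    Rng rng(tree_stream_seed(seed, t));
    std::vector<int> smp(n);
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int k = 0; k < n; ++k) {
      int i = rng.below(n);
      smp[k] = i;
      inbag[i] = 1;
      boot_out(t, k) = i + 1;
    }
    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);

    for (int i = 0; i < p; ++i) perm[i] = i;
    Tree tr = grow_tree_core(gp, n, p, yp, w, smp, mtry, rng, perm);

    for (size_t k = 0; k < oob.size(); ++k) {
      int i = oob[k];
      int cls = terminal_class(tr, drop_down(tr, gp, n, i));
      votes_acc(i, cls) += 1.0;
    }

    // OOB error after t+1 trees: samples with >=1 OOB vote, class-weighted
    // aggregation (and the raw rate alongside)
    double nerr[2] = {0, 0}, ntot[2] = {0, 0};
    for (int i = 0; i < n; ++i) {
      double vc0 = votes_acc(i, 0), vc1 = votes_acc(i, 1);
      if (vc0 + vc1 == 0.0) continue;
      int pred = (w1 * vc1 > w0 * vc0) ? 1 : 0;
      ntot[yp[i]] += 1.0;
      if (pred != yp[i]) nerr[yp[i]] += 1.0;
    }
    double denom_raw = ntot[0] + ntot[1];
    traj_raw[t] = denom_raw > 0 ? (nerr[0] + nerr[1]) / denom_raw : NA_REAL;
    if (ntot[0] > 0 && ntot[1] > 0) {
      double e0 = nerr[0] / ntot[0], e1 = nerr[1] / ntot[1];
      traj_bal[t] = (w0 * e0 + w1 * e1) / (w0 + w1);
    } else {
      traj_bal[t] = NA_REAL;
    }

    IntegerVector oobv(oob.size());
    for (size_t k = 0; k < oob.size(); ++k) oobv[k] = oob[k] + 1;
    oob_out[t] = oobv;
    trees[t] = tree_to_list(tr);
  }

  return List::create(
      _["trees"] = trees, _["bootstrap"] = boot_out, _["oob"] = oob_out,
      _["oob_trajectory"] = traj_bal, _["oob_trajectory_raw"] = traj_raw,
      _["oob_votes"] = votes_acc);
}

// ---------------------------------------------------------------------------
// Exported: permutation variable importance

// sample i down the tree with SNP `snp` read through permuted OOB positions
static inline int drop_down_perm(const Tree &tr, const int *geno, int n,
                                 int i, int snp, int i_perm) {
  int node = 0;
  while (tr.split_snp[node] >= 0) {
    int s = tr.split_snp[node];
    int src = (s == snp) ? i_perm : i;
    int g = geno[(size_t) n * (size_t) s + src];
    node = in_left(tr.part[node], g) ? tr.left[node] : tr.right[node];
  }
  return node;
}

// [[Rcpp::export]]
NumericVector cpp_permutation_importance(List trees, List oob,
                                         IntegerMatrix geno, IntegerVector y,
                                         double w0, double w1, double vi_seed) {
  int n = geno.nrow(), p = geno.ncol();
  int ntree = trees.size();
  const int *gp = geno.begin();
  const int *yp = y.begin();
  double w[2] = {w0, w1};
  NumericVector score(p);

  for (int t = 0; t < ntree; ++t) {
    Tree tr = tree_from_list(trees[t]);
    IntegerVector oobv = oob[t];
    int m = oobv.size();
    if (m == 0) continue;
    std::vector<int> O(m);
    for (int k = 0; k < m; ++k) O[k] = oobv[k] - 1;

    double wsum = 0.0, base = 0.0;
    for (int k = 0; k < m; ++k) {
      int i = O[k];
      double wi = w[yp[i]];
      wsum += wi;
      if (terminal_class(tr, drop_down(tr, gp, n, i)) == yp[i]) base += wi;
    }
    base /= wsum;

    // sorted unique SNPs appearing in this tree
    std::vector<int> used;
    for (size_t j = 0; j < tr.split_snp.size(); ++j)
      if (tr.split_snp[j] >= 0) used.push_back(tr.split_snp[j]);
    std::sort(used.begin(), used.end());
    used.erase(std::unique(used.begin(), used.end()), used.end());

    Rng vr(tree_stream_seed(vi_seed, t));
    std::vector<int> pidx(m);
    for (size_t u = 0; u < used.size(); ++u) {
      int s = used[u];
      for (int k = 0; k < m; ++k) pidx[k] = k;
      shuffle_vec(pidx, vr);
      double acc = 0.0;
      for (int k = 0; k < m; ++k) {
        int i = O[k];
        int cls = terminal_class(tr, drop_down_perm(tr, gp, n, i, s,
                                                    O[pidx[k]]));
        if (cls == yp[i]) acc += w[yp[i]];
      }
      acc /= wsum;
      score[s] += base - acc;
    }
  }
  for (int s = 0; s < p; ++s) score[s] /= (double) ntree;
  return score;
}

// replay the first k OOB permutations the VI pass draws for a given tree
// (tree_index is 1-based); rows of the result are 1-based permutations
// [[Rcpp::export]]
IntegerMatrix cpp_vi_perms(double vi_seed, int tree_index, int n_oob, int k) {
  Rng vr(tree_stream_seed(vi_seed, tree_index - 1));
  IntegerMatrix out(k, n_oob);
  std::vector<int> pidx(n_oob);
  for (int r = 0; r < k; ++r) {
    for (int i = 0; i < n_oob; ++i) pidx[i] = i;
    shuffle_vec(pidx, vr);
    for (int i = 0; i < n_oob; ++i) out(r, i) = pidx[i] + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exported: prediction votes (count of trees voting each class per sample)

// [[Rcpp::export]]
NumericMatrix cpp_predict_votes(List trees, IntegerMatrix geno) {
  int n = geno.nrow();
  const int *gp = geno.begin();
  NumericMatrix votes(n, 2);
  for (int t = 0; t < trees.size(); ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) {
      votes(i, terminal_class(tr, drop_down(tr, gp, n, i))) += 1.0;
    }
  }
  colnames(votes) = CharacterVector::create("control", "case");
  return votes;
}
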