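#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <utility>
#include <vector>
using namespace Rcpp;

// Edge-list view of a directed graph, built once per call so that the cost of
// a node correspondence is evaluated in O(V + E) rather than O(V^2).
struct GraphView {
  int n;
  std::vector<std::pair<int, int>> edges;  // u -> v, u != v
  std::vector<char> self;                  // self-loop flags
  std::vector<char> adj;                   // n x n lookup, row-major

  explicit GraphView(const LogicalMatrix &A) : n(A.nrow()), self(n, 0), adj((size_t)n * n, 0) {
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) {
        if (A(i, j)) {
          adj[(size_t)i * n + j] = 1;
          if (i == j)
            self[i] = 1;
          else
            edges.emplace_back(i, j);
        }
      }
    }
  }
  inline bool has(int i, int j) const { return adj[(size_t)i * n + j] != 0; }
};

// Scratch space reused across evaluations of the same graph pair.
struct CostScratch {
  std::vector<int> inv;        // g2 node -> g1 preimage (-1 = inserted)
  std::vector<int> pair_seen;  // stamp per unordered mapped g1 pair
  std::vector<int> pairs;      // collected pair codes for this evaluation
  int stamp = 0;

  void init(int n1, int n2) {
    inv.assign(n2, -1);
    pair_seen.assign((size_t)n1 * n1, 0);
    pairs.reserve(256);
  }
};

// Cost of one correspondence. map is 1-based into g2, 0 = deleted g1 node.
// Node term: cnode per deleted/inserted node. Link term: clink per link
// incident to a deleted or inserted node (once per link, self-loops
// included); mapped unordered pairs compared by state (none/forward/
// backward/both): one-arc difference clink, none<->both 2*clink, pure
// reversal min(cflip, 2*clink); mapped self-loop mismatch clink.
static double cost_of_mapping(const GraphView &g1, const GraphView &g2,
                              const int *map, double cflip, double cnode,
                              double clink, CostScratch &sc) {
  const int n1 = g1.n, n2 = g2.n;
  ++sc.stamp;
  std::fill(sc.inv.begin(), sc.inv.end(), -1);
  int n_del = 0;
  for (int i = 0; i < n1; ++i) {
    if (map[i] > 0)
      sc.inv[map[i] - 1] = i;
    else
      ++n_del;
  }
  int n_ins = 0;
  for (int j = 0; j < n2; ++j)
    if (sc.inv[j] < 0) ++n_ins;

  double cost = cnode * (n_del + n_ins);

  // links lost with deleted nodes / gained with inserted nodes
  for (const auto &e : g1.edges)
    if (map[e.first] == 0 || map[e.second] == 0) cost += clink;
  for (int i = 0; i < n1; ++i)
    if (g1.self[i] && map[i] == 0) cost += clink;
  for (const auto &e : g2.edges)
    if (sc.inv[e.first] < 0 || sc.inv[e.second] < 0) cost += clink;
  for (int j = 0; j < n2; ++j)
    if (g2.self[j] && sc.inv[j] < 0) cost += clink;

  // mapped self-loop mismatches
  for (int i = 0; i < n1; ++i) {
    if (map[i] > 0 && g1.self[i] != g2.self[map[i] - 1]) cost += clink;
  }

  // mapped pairs with at least one arc in either graph; a pair with no arcs
  // anywhere costs 0 and never needs visiting, so only edge-touched pairs
  // are collected (deduplicated by stamp)
  sc.pairs.clear();
  auto visit = [&](int u, int v) {
    int a = u < v ? u : v, b = u < v ? v : u;
    size_t code = (size_t)a * n1 + b;
    if (sc.pair_seen[code] != sc.stamp) {
      sc.pair_seen[code] = sc.stamp;
      sc.pairs.push_back((int)code);
    }
  };
  for (const auto &e : g1.edges)
    if (map[e.first] > 0 && map[e.second] > 0) visit(e.first, e.second);
  for (const auto &e : g2.edges) {
    int pu = sc.inv[e.first], pv = sc.inv[e.second];
    if (pu >= 0 && pv >= 0) visit(pu, pv);
  }

  const double flip_price = std::min(cflip, 2.0 * clink);
  for (int code : sc.pairs) {
    const int u = code / n1, v = code % n1;
    const int mu = map[u] - 1, mv = map[v] - 1;
    const int s1 = (g1.has(u, v) ? 1 : 0) | (g1.has(v, u) ? 2 : 0);
    const int s2 = (g2.has(mu, mv) ? 1 : 0) | (g2.has(mv, mu) ? 2 : 0);
    if (s1 == s2) continue;
    if ((s1 | s2) == 3 && (s1 & s2) == 0 && s1 != 0 && s2 != 0)
      cost += flip_price;  // forward <-> backward
    else if ((s1 & s2) == 0 && (s1 | s2) == 3)
      cost += 2.0 * clink;  // none <-> both
    else
      cost += clink;  // differ by one arc
  }
  return cost;
}

// [[Rcpp::export]]
double ged_mapping_cost_cpp(LogicalMatrix A1, LogicalMatrix A2,
                            IntegerVector map, double cflip, double cnode,
                            double clink) {
  if (map.size() != A1.nrow()) stop("mapping length must equal |V1|");
  GraphView g1(A1), g2(A2);
  CostScratch sc;
  sc.init(g1.n, g2.n);
  return cost_of_mapping(g1, g2, INTEGER(map), cflip, cnode, clink, sc);
}

// [[Rcpp::export]]
NumericVector ged_mapping_costs_cpp(LogicalMatrix A1, LogicalMatrix A2,
                                    IntegerMatrix maps, double cflip,
                                    double cnode, double clink) {
  const int m = maps.nrow();
  if (maps.ncol() != A1.nrow()) stop("mapping width must equal |V1|");
  GraphView g1(A1), g2(A2);
  CostScratch sc;
  sc.init(g1.n, g2.n);
  NumericVector out(m);
  std::vector<int> row(maps.ncol());
  for (int r = 0; r < m; ++r) {
    for (int c = 0; c < (int)row.size(); ++c) row[c] = maps(r, c);
    out[r] = cost_of_mapping(g1, g2, row.data(), cflip, cnode, clink, sc);
  }
  return out;
}

// deterministic, platform-stable draws on top of std::mt19937
static inline int rnd_int(std::mt19937 &rng, int n) {
  return (int)(rng() % (uint32_t)n);
}
static inline double rnd_unif(std::mt19937 &rng) {
  return rng() * (1.0 / 4294967296.0);
}

struct Chrom {
  std::vector<int> perm;  // permutation of 1..(n1+n2); first n1 genes read
  double fit;
};

// genes > n2 encode the null partner (deleted g1 node)
static void decode(const Chrom &ch, int n1, int n2, std::vector<int> &map) {
  map.resize(n1);
  for (int i = 0; i < n1; ++i) map[i] = ch.perm[i] <= n2 ? ch.perm[i] : 0;
}

// Evolutionary search over complete correspondences (smaller web padded with
// null partners). Elitist generational EA: tournament selection, pairwise
// assignment crossover (uniform gene adoption with swap repair, preserving
// the permutation), per-gene swap mutation. The delete-all/insert-all
// chromosome and, when supplied, the taxon-identity chromosome are placed in
// the initial population of every restart.
// [[Rcpp::export]]
List ged_evolve_cpp(LogicalMatrix A1, LogicalMatrix A2, double cflip,
                    double cnode, double clink, int pop_size, double mut_rate,
                    double elite_frac, int stall_limit, int max_iter,
                    int restarts, int seed, IntegerVector identity_map) {
  GraphView g1(A1), g2(A2);
  const int n1 = g1.n, n2 = g2.n, L = n1 + n2;
  CostScratch sc;
  sc.init(n1, n2);

  long long evals = 0;
  double best_cost = R_PosInf;
  std::vector<int> best_map(n1, 0), buf;

  std::mt19937 rng((uint32_t)seed);
  if (pop_size < 2) pop_size = 2;
  const int n_elite = std::max(1, (int)std::lround(elite_frac * pop_size));

  auto eval_chrom = [&](Chrom &ch) {
    decode(ch, n1, n2, buf);
    ch.fit = cost_of_mapping(g1, g2, buf.data(), cflip, cnode, clink, sc);
    ++evals;
  };

  for (int rs = 0; rs < restarts; ++rs) {
    std::vector<Chrom> pop(pop_size);
    for (int p = 0; p < pop_size; ++p) {
      Chrom &ch = pop[p];
      ch.perm.resize(L);
      if (p == 0) {
        // delete-all/insert-all: raw cost equals C_max by construction
        for (int i = 0; i < n1; ++i) ch.perm[i] = n2 + 1 + i;
        for (int j = 0; j < n2; ++j) ch.perm[n1 + j] = j + 1;
      } else if (p == 1 && identity_map.size() == n1 && n1 > 0) {
        std::vector<char> used(n2, 0);
        int next_null = n2 + 1;
        for (int i = 0; i < n1; ++i) {
          int g = identity_map[i];
          if (g > 0) {
            ch.perm[i] = g;
            used[g - 1] = 1;
          } else {
            ch.perm[i] = next_null++;
          }
        }
        int pos = n1;
        for (int j = 0; j < n2; ++j)
          if (!used[j]) ch.perm[pos++] = j + 1;
        while (pos < L) ch.perm[pos++] = next_null++;
      } else {
        for (int i = 0; i < L; ++i) ch.perm[i] = i + 1;
        for (int i = L - 1; i > 0; --i)
          std::swap(ch.perm[i], ch.perm[rnd_int(rng, i + 1)]);
      }
      eval_chrom(ch);
    }

    double run_best = R_PosInf;
    int stall = 0;
    std::vector<int> idx(pop_size), posbuf(L + 1);
    std::vector<Chrom> next(pop_size);
    for (int gen = 0; gen < max_iter && stall < stall_limit; ++gen) {
      for (int i = 0; i < pop_size; ++i) idx[i] = i;
      std::sort(idx.begin(), idx.end(), [&](int a, int b) {
        return pop[a].fit < pop[b].fit || (pop[a].fit == pop[b].fit && a < b);
      });
      if (pop[idx[0]].fit < run_best - 1e-12) {
        run_best = pop[idx[0]].fit;
        stall = 0;
      } else {
        ++stall;
      }
      if (pop[idx[0]].fit < best_cost) {
        best_cost = pop[idx[0]].fit;
        decode(pop[idx[0]], n1, n2, best_map);
      }

      for (int e = 0; e < n_elite; ++e) next[e] = pop[idx[e]];
      for (int o = n_elite; o < pop_size; ++o) {
        int a1 = rnd_int(rng, pop_size), a2 = rnd_int(rng, pop_size);
        const Chrom &pa = pop[a1].fit <= pop[a2].fit ? pop[a1] : pop[a2];
        int b1 = rnd_int(rng, pop_size), b2 = rnd_int(rng, pop_size);
        const Chrom &pb = pop[b1].fit <= pop[b2].fit ? pop[b1] : pop[b2];
        Chrom &ch = next[o];
        ch.perm = pa.perm;
        for (int g = 0; g < L; ++g) posbuf[ch.perm[g]] = g;
        for (int i = 0; i < n1; ++i) {
          if (rnd_unif(rng) < 0.5) {
            int g = pb.perm[i], j = posbuf[g];
            if (j != i) {
              posbuf[ch.perm[i]] = j;
              posbuf[g] = i;
              std::swap(ch.perm[i], ch.perm[j]);
            }
          }
        }
        for (int i = 0; i < n1; ++i) {
          if (rnd_unif(rng) < mut_rate) {
            int j = rnd_int(rng, L);
            std::swap(ch.perm[i], ch.perm[j]);
          }
        }
        eval_chrom(ch);
      }
      pop.swap(next);
    }
    for (int p = 0; p < pop_size; ++p) {
      if (pop[p].fit < best_cost) {
        best_cost = pop[p].fit;
        decode(pop[p], n1, n2, best_map);
      }
    }
  }

  if (n1 == 0 && !R_finite(best_cost))
    best_cost = cost_of_mapping(g1, g2, nullptr, cflip, cnode, clink, sc);
  return List::create(_["cost"] = best_cost,
                      _["map"] = IntegerVector(best_map.begin(), best_map.end()),
                      _["evaluations"] = (double)evals);
}
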