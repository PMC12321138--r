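#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Monte Carlo engine for public goods games on hypergraphs under the five
// higher-order update mechanisms. The hypergraph is passed in CSR form:
//   edge_ptr (E+1), edge_nodes: members of hyperedge e are
//     edge_nodes[edge_ptr[e] .. edge_ptr[e+1]-1]   (0-based node ids)
//   node_ptr (N+1), node_edges: hyperedges adjacent to node i.
// Randomness comes from R's RNG (unif_rand), so set.seed() in R fixes the
// whole trajectory.

enum Mechanism { HDB = 1, HIM = 2, GMC = 3, GIC = 4, HPC = 5 };

struct HGraph {
  int N, E;
  std::vector<int> edge_ptr, edge_nodes, node_ptr, node_edges;
  std::vector<double> inv_k;
  int g(int e) const { return edge_ptr[e + 1] - edge_ptr[e]; }
  int k(int i) const { return node_ptr[i + 1] - node_ptr[i]; }
};

static HGraph build_graph(const IntegerVector& edge_ptr,
                          const IntegerVector& edge_nodes,
                          const IntegerVector& node_ptr,
                          const IntegerVector& node_edges) {
  HGraph H;
  H.E = edge_ptr.size() - 1;
  H.N = node_ptr.size() - 1;
  H.edge_ptr.assign(edge_ptr.begin(), edge_ptr.end());
  H.edge_nodes.assign(edge_nodes.begin(), edge_nodes.end());
  H.node_ptr.assign(node_ptr.begin(), node_ptr.end());
  H.node_edges.assign(node_edges.begin(), node_edges.end());
  H.inv_k.resize(H.N);
  for (int i = 0; i < H.N; ++i) H.inv_k[i] = 1.0 / H.k(i);
  return H;
}

static inline int sample_uniform(int n) {
  int x;
  do { x = (int)(unif_rand() * n); } while (x >= n);
  return x;
}

// fitness of node j given per-edge cooperator counts
static inline double node_fitness(const HGraph& H, const std::vector<int>& s,
                                  const std::vector<int>& coop,
                                  double r, double delta, int j) {
  double tot = 0.0;
  for (int a = H.node_ptr[j]; a < H.node_ptr[j + 1]; ++a)
    tot += coop[H.node_edges[a]];
  double u = r * tot * H.inv_k[j] - s[j];
  return std::exp(delta * u);
}

// One asynchronous update of a uniformly chosen focal node. Returns +1/-1
// if the cooperator count changed, 0 otherwise.
static int one_step(const HGraph& H, std::vector<int>& s,
                    std::vector<int>& coop, double r, double delta,
                    int mech, std::vector<double>& wbuf,
                    std::vector<double>& fbuf) {
  int i = sample_uniform(H.N);
  int ki = H.k(i);
  const int* my_edges = &H.node_edges[H.node_ptr[i]];
  double fi = 0.0;
  if (mech == HDB || mech == GIC || mech == HPC || mech == HIM || mech == GMC)
    fi = node_fitness(H, s, coop, r, delta, i);

  int j = -1;            // node whose strategy i may adopt
  bool adopt = true;

  if (mech == HPC) {
    int e = my_edges[sample_uniform(ki)];
    int ge = H.g(e);
    // uniform peer among the other g_e - 1 members
    int pick = sample_uniform(ge - 1);
    const int* mem = &H.edge_nodes[H.edge_ptr[e]];
    int seen = 0;
    for (int t = 0; t < ge; ++t) {
      if (mem[t] == i) continue;
      if (seen == pick) { j = mem[t]; break; }
      ++seen;
    }
    double fj = node_fitness(H, s, coop, r, delta, j);
    adopt = unif_rand() < fj / (fi + fj);
  } else {
    // stage 1: choose a hyperedge
    int e;
    if (mech == GIC) {
      e = my_edges[sample_uniform(ki)];
    } else {
      wbuf.resize(ki);
      double wsum = 0.0;
      for (int a = 0; a < ki; ++a) {
        int ea = my_edges[a];
        int ge = H.g(ea);
        double fs = 0.0;
        const int* mem = &H.edge_nodes[H.edge_ptr[ea]];
        for (int t = 0; t < ge; ++t)
          fs += node_fitness(H, s, coop, r, delta, mem[t]);
        double w;
        if (mech == HDB)      w = (fs - fi) / (ge - 1); // mean over others
        else                  w = fs / ge;              // HIM, GMC: full mean
        wbuf[a] = w;
        wsum += w;
      }
      double pick = unif_rand() * wsum, acc = 0.0;
      e = my_edges[ki - 1];
      for (int a = 0; a < ki; ++a) {
        acc += wbuf[a];
        if (pick <= acc) { e = my_edges[a]; break; }
      }
    }
    // stage 2: choose a member of e
    int ge = H.g(e);
    const int* mem = &H.edge_nodes[H.edge_ptr[e]];
    if (mech == GMC) {
      int pick = sample_uniform(ge - 1), seen = 0;
      for (int t = 0; t < ge; ++t) {
        if (mem[t] == i) continue;
        if (seen == pick) { j = mem[t]; break; }
        ++seen;
      }
    } else if (mech == HIM) {
      fbuf.resize(ge);
      double fs = 0.0;
      for (int t = 0; t < ge; ++t) {
        fbuf[t] = node_fitness(H, s, coop, r, delta, mem[t]);
        fs += fbuf[t];
      }
      double pick = unif_rand() * fs, acc = 0.0;
      j = mem[ge - 1];
      for (int t = 0; t < ge; ++t) {
        acc += fbuf[t];
        if (pick <= acc) { j = mem[t]; break; }
      }
    } else { // HDB, GIC: fitness-proportional among others
      fbuf.resize(ge);
      double fs = 0.0;
      for (int t = 0; t < ge; ++t) {
        if (mem[t] == i) { fbuf[t] = 0.0; continue; }
        fbuf[t] = node_fitness(H, s, coop, r, delta, mem[t]);
        fs += fbuf[t];
      }
      double pick = unif_rand() * fs, acc = 0.0;
      j = -1;
      for (int t = 0; t < ge; ++t) {
        acc += fbuf[t];
        if (fbuf[t] > 0.0 && pick <= acc) { j = mem[t]; break; }
      }
      if (j < 0) for (int t = ge - 1; t >= 0; --t)
        if (mem[t] != i) { j = mem[t]; break; }
    }
  }

  if (!adopt || s[j] == s[i]) return 0;
  int d = s[j] - s[i];
  s[i] = s[j];
  for (int a = H.node_ptr[i]; a < H.node_ptr[i + 1]; ++a)
    coop[H.node_edges[a]] += d;
  return d;
}

// [[Rcpp::export]]
List cpp_run_to_absorption(IntegerVector edge_ptr, IntegerVector edge_nodes,
                           IntegerVector node_ptr, IntegerVector node_edges,
                           IntegerVector state, int mech, double r,
                           double delta, double max_steps) {
  HGraph H = build_graph(edge_ptr, edge_nodes, node_ptr, node_edges);
  std::vector<int> s(state.begin(), state.end());
  std::vector<int> coop(H.E, 0);
  int nc = 0;
  for (int i = 0; i < H.N; ++i) nc += s[i];
  for (int e = 0; e < H.E; ++e)
    for (int t = H.edge_ptr[e]; t < H.edge_ptr[e + 1]; ++t)
      coop[e] += s[H.edge_nodes[t]];
  std::vector<double> wbuf, fbuf;
  double steps = 0.0;
  while (nc > 0 && nc < H.N) {
    if (steps >= max_steps)
      stop("no absorption within %.0f steps", max_steps);
    nc += one_step(H, s, coop, r, delta, mech, wbuf, fbuf);
    steps += 1.0;
    if (((long long)steps & 0xFFFFF) == 0) checkUserInterrupt();
  }
  return List::create(_["fixed_cooperation"] = (nc == H.N),
                      _["steps"] = steps,
                      _["state"] = IntegerVector(s.begin(), s.end()));
}

// [[Rcpp::export]]
List cpp_fixation_batch(IntegerVector edge_ptr, IntegerVector edge_nodes,
                        IntegerVector node_ptr, IntegerVector node_edges,
                        int mech, double r, double delta, int replicates,
                        bool mutant_cooperator, double max_steps) {
  HGraph H = build_graph(edge_ptr, edge_nodes, node_ptr, node_edges);
  std::vector<int> s(H.N), coop(H.E);
  std::vector<double> wbuf, fbuf;
  int fixed = 0;
  double total_steps = 0.0;
  for (int rep = 0; rep < replicates; ++rep) {
    int m = sample_uniform(H.N); // mutant position, uniform each replicate
    int base = mutant_cooperator ? 0 : 1;
    std::fill(s.begin(), s.end(), base);
    s[m] = 1 - base;
    for (int e = 0; e < H.E; ++e) {
      int c = 0;
      for (int t = H.edge_ptr[e]; t < H.edge_ptr[e + 1]; ++t)
        c += s[H.edge_nodes[t]];
      coop[e] = c;
    }
    int nc = mutant_cooperator ? 1 : H.N - 1;
    double steps = 0.0;
    while (nc > 0 && nc < H.N) {
      if (steps >= max_steps)
        stop("no absorption within %.0f steps (replicate %d)", max_steps, rep + 1);
      nc += one_step(H, s, coop, r, delta, mech, wbuf, fbuf);
      steps += 1.0;
      if (((long long)steps & 0xFFFFF) == 0) checkUserInterrupt();
    }
    bool mutant_fixed = mutant_cooperator ? (nc == H.N) : (nc == 0);
    if (mutant_fixed) ++fixed;
    total_steps += steps;
    if ((rep & 0x3FF) == 0) checkUserInterrupt();
  }
  return List::create(_["fixed"] = fixed,
                      _["replicates"] = replicates,
                      _["mean_steps"] = total_steps / replicates);
}
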