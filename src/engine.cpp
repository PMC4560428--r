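#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Synchronous Boolean network engine.
//
// A network with N nodes (N <= 24) is represented by, per node, an integer
// vector of 0-based input indices and a 0/1 truth table of length 2^k whose
// row index packs the input values with the FIRST input in the LOW bit.
// A global state is an integer code in [0, 2^N) with node i in bit i.

namespace {

// Build the full successor table: succ[s] = synchronous image of state s.
void build_succ(const std::vector<std::vector<int> > &inputs,
                const std::vector<std::vector<uint8_t> > &tables,
                int nNodes, std::vector<int> &succ) {
  const int M = 1 << nNodes;
  succ.assign(M, 0);
  for (int i = 0; i < nNodes; ++i) {
    const std::vector<int> &in = inputs[i];
    const std::vector<uint8_t> &tab = tables[i];
    const int k = (int)in.size();
    const int bit = 1 << i;
    for (int s = 0; s < M; ++s) {
      int row = 0;
      for (int j = 0; j < k; ++j) row |= ((s >> in[j]) & 1) << j;
      if (tab[row]) succ[s] |= bit;
    }
  }
}

// Decompose the functional graph succ into attractors.
// attr[s] receives the 0-based attractor index of every state; cycles
// receives each attractor's configuration cycle in successor order,
// rotated so that the minimal state code comes first (canonical form).
void decompose(const std::vector<int> &succ,
               std::vector<int> &attr,
               std::vector<std::vector<int> > &cycles,
               std::vector<int> &basin) {
  const int M = (int)succ.size();
  attr.assign(M, -1);
  cycles.clear();
  basin.clear();
  std::vector<int> stamp(M, -1);
  std::vector<int> path;
  path.reserve(256);
  for (int s0 = 0; s0 < M; ++s0) {
    if (attr[s0] >= 0) continue;
    path.clear();
    int cur = s0;
    while (attr[cur] < 0 && stamp[cur] != s0) {
      stamp[cur] = s0;
      path.push_back(cur);
      cur = succ[cur];
    }
    int id;
    if (attr[cur] >= 0) {
      id = attr[cur];
    } else {
      // new cycle: cur is the first repeated state on this path
      id = (int)cycles.size();
      size_t pos = 0;
      while (path[pos] != cur) ++pos;
      std::vector<int> cyc(path.begin() + pos, path.end());
      // canonical rotation: minimal code first
      size_t mi = 0;
      for (size_t j = 1; j < cyc.size(); ++j) if (cyc[j] < cyc[mi]) mi = j;
      std::rotate(cyc.begin(), cyc.begin() + mi, cyc.end());
      cycles.push_back(cyc);
      basin.push_back(0);
    }
    for (size_t j = 0; j < path.size(); ++j) attr[path[j]] = id;
  }
  for (int s = 0; s < M; ++s) basin[attr[s]] += 1;
}

std::vector<std::vector<int> > as_cycles(const List &ref) {
  std::vector<std::vector<int> > out;
  for (int i = 0; i < ref.size(); ++i) {
    IntegerVector v = ref[i];
    out.push_back(std::vector<int>(v.begin(), v.end()));
  }
  return out;
}

bool cycle_present(const std::vector<std::vector<int> > &cycles,
                   const std::vector<int> &target) {
  for (size_t i = 0; i < cycles.size(); ++i)
    if (cycles[i] == target) return true;
  return false;
}

// Three-way outcome against a reference attractor set:
// 0 = recovered_only, 1 = recovered_plus_new, 2 = altered.
int classify(const std::vector<std::vector<int> > &cycles,
             const std::vector<std::vector<int> > &ref) {
  for (size_t i = 0; i < ref.size(); ++i)
    if (!cycle_present(cycles, ref[i])) return 2;
  return cycles.size() == ref.size() ? 0 : 1;
}

void unpack_network(const List &inputs, const List &tables,
                    std::vector<std::vector<int> > &in,
                    std::vector<std::vector<uint8_t> > &tab) {
  const int n = inputs.size();
  in.resize(n);
  tab.resize(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = inputs[i];
    in[i] = std::vector<int>(v.begin(), v.end());
    IntegerVector t = tables[i];
    tab[i].assign(t.begin(), t.end());
  }
}

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_transition_table(List inputs, List tables, int nNodes) {
  std::vector<std::vector<int> > in;
  std::vector<std::vector<uint8_t> > tab;
  unpack_network(inputs, tables, in, tab);
  std::vector<int> succ;
  build_succ(in, tab, nNodes, succ);
  return IntegerVector(succ.begin(), succ.end());
}

// [[Rcpp::export]]
List cpp_attractors(IntegerVector succ) {
  std::vector<int> s(succ.begin(), succ.end());
  std::vector<int> attr, basin;
  std::vector<std::vector<int> > cycles;
  decompose(s, attr, cycles, basin);
  List cyc(cycles.size());
  for (size_t i = 0; i < cycles.size(); ++i)
    cyc[i] = IntegerVector(cycles[i].begin(), cycles[i].end());
  return List::create(_["cycles"] = cyc,
                      _["basin"] = IntegerVector(basin.begin(), basin.end()),
                      _["assignment"] = IntegerVector(attr.begin(), attr.end()));
}

// Exhaustive truth-table bit-flip scan: every output bit of every rule is
// flipped in turn and the perturbed network's attractor set classified
// against the reference cycles. Returns one outcome row per flip.
// [[Rcpp::export]]
IntegerMatrix cpp_function_flip_scan(List inputs, List tables, int nNodes,
                                     List refCycles) {
  std::vector<std::vector<int> > in;
  std::vector<std::vector<uint8_t> > tab;
  unpack_network(inputs, tables, in, tab);
  std::vector<std::vector<int> > ref = as_cycles(refCycles);
  int total = 0;
  for (size_t i = 0; i < tab.size(); ++i) total += (int)tab[i].size();
  IntegerMatrix out(total, 3); // node (0-based), row (0-based), category
  std::vector<int> succ, attr, basin;
  std::vector<std::vector<int> > cycles;
  int r = 0;
  for (int i = 0; i < nNodes; ++i) {
    for (size_t row = 0; row < tab[i].size(); ++row) {
      tab[i][row] ^= 1;
      build_succ(in, tab, nNodes, succ);
      decompose(succ, attr, cycles, basin);
      tab[i][row] ^= 1;
      out(r, 0) = i;
      out(r, 1) = (int)row;
      out(r, 2) = classify(cycles, ref);
      ++r;
    }
  }
  return out;
}

// Classify a batch of state-transition bit flips: trial t flips bit
// nodeIdx[t] of the successor of state stateIdx[t] in the global
// transition table, then re-derives the attractor landscape.
// [[Rcpp::export]]
IntegerVector cpp_transition_flip_trials(IntegerVector succ0, int nNodes,
                                         IntegerVector stateIdx,
                                         IntegerVector nodeIdx,
                                         List refCycles) {
  std::vector<int> succ(succ0.begin(), succ0.end());
  std::vector<std::vector<int> > ref = as_cycles(refCycles);
  const int n = stateIdx.size();
  IntegerVector out(n);
  std::vector<int> attr, basin;
  std::vector<std::vector<int> > cycles;
  for (int t = 0; t < n; ++t) {
    const int s = stateIdx[t], b = 1 << nodeIdx[t];
    succ[s] ^= b;
    decompose(succ, attr, cycles, basin);
    succ[s] ^= b;
    out[t] = classify(cycles, ref);
  }
  return out;
}

// Exhaustive scan over every (state, node) transition bit. Returns the
// count of outcomes in each category (recovered_only, recovered_plus_new,
// altered).
// [[Rcpp::export]]
IntegerVector cpp_transition_flip_exhaustive(IntegerVector succ0, int nNodes,
                                             List refCycles) {
  std::vector<int> succ(succ0.begin(), succ0.end());
  std::vector<std::vector<int> > ref = as_cycles(refCycles);
  const int M = (int)succ.size();
  std::vector<int> attr, basin;
  std::vector<std::vector<int> > cycles;
  IntegerVector counts(3);
  for (int s = 0; s < M; ++s) {
    for (int i = 0; i < nNodes; ++i) {
      const int b = 1 << i;
      succ[s] ^= b;
      decompose(succ, attr, cycles, basin);
      succ[s] ^= b;
      counts[classify(cycles, ref)] += 1;
    }
  }
  return counts;
}

// Classify perturbed copies in which several (state, node) successor
// bits are flipped at once: trial t flips entries
// [t*flipsPerTrial, (t+1)*flipsPerTrial) of stateIdx/nodeIdx.
// [[Rcpp::export]]
IntegerVector cpp_transition_multiflip_trials(IntegerVector succ0, int nNodes,
                                              IntegerVector stateIdx,
                                              IntegerVector nodeIdx,
                                              int flipsPerTrial,
                                              List refCycles) {
  std::vector<int> succ(succ0.begin(), succ0.end());
  std::vector<std::vector<int> > ref = as_cycles(refCycles);
  const int n = stateIdx.size() / flipsPerTrial;
  IntegerVector out(n);
  std::vector<int> attr, basin;
  std::vector<std::vector<int> > cycles;
  for (int t = 0; t < n; ++t) {
    const int off = t * flipsPerTrial;
    for (int j = 0; j < flipsPerTrial; ++j)
      succ[stateIdx[off + j]] ^= (1 << nodeIdx[off + j]);
    decompose(succ, attr, cycles, basin);
    for (int j = 0; j < flipsPerTrial; ++j)
      succ[stateIdx[off + j]] ^= (1 << nodeIdx[off + j]);
    out[t] = classify(cycles, ref);
  }
  return out;
}
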