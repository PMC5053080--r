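// Explicit-state engine for asynchronous Boolean dynamics.
//
// States are encoded as unsigned 32-bit integers: bit i carries the value of
// the i-th node in the network's (lexicographic) node order, so networks are
// limited to 30 nodes.  A perturbation is encoded by the set of free
// (non-forced) bit positions plus a base state holding the forced bits; the
// dynamics only ever flips free bits.  The update rule is sign-based:
// activators OR'd, inhibitors dominant, input nodes hold their value.
//
// Successor lists are recomputed on demand (O(#free) per state) instead of
// being stored, which keeps the exact engine's memory linear in the number of
// enumerated states even near the state-space cap.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Dyn {
  int nNodes;
  std::vector<uint32_t> act;   // per node: OR-mask of activator sources
  std::vector<uint32_t> inh;   // per node: OR-mask of inhibitor sources
  std::vector<int> regType;    // 0 = no regulators, 1 = has activators, 2 = inhibitors only
  std::vector<int> freeIdx;    // free (non-forced) node indices, ascending
  uint32_t forcedState;        // forced bits set to their clamped values, free bits 0
  uint32_t freeMask;           // OR of free bit positions
};

Dyn makeDyn(int nNodes, IntegerVector act, IntegerVector inh, IntegerVector regType,
            IntegerVector freeIdx, double forcedState) {
  Dyn d;
  d.nNodes = nNodes;
  d.act.assign(act.begin(), act.end());
  d.inh.assign(inh.begin(), inh.end());
  d.regType.assign(regType.begin(), regType.end());
  d.freeIdx.assign(freeIdx.begin(), freeIdx.end());
  d.forcedState = static_cast<uint32_t>(forcedState);
  d.freeMask = 0;
  for (int i : d.freeIdx) d.freeMask |= (1u << i);
  return d;
}

inline int targetBit(const Dyn& d, uint32_t s, int node) {
  bool a = (s & d.act[node]) != 0;
  bool i = (s & d.inh[node]) != 0;
  switch (d.regType[node]) {
  case 1:  return (a && !i) ? 1 : 0;   // >=1 activating in-edge
  case 2:  return i ? 0 : 1;           // inhibiting in-edges only
  default: return (s >> node) & 1u;    // no regulators: hold
  }
}

// Append asynchronous successors of s (one flipped free node each) to out.
inline void successors(const Dyn& d, uint32_t s, std::vector<uint32_t>& out) {
  out.clear();
  for (int node : d.freeIdx) {
    int cur = (s >> node) & 1u;
    if (targetBit(d, s, node) != cur) out.push_back(s ^ (1u << node));
  }
}

// Map between full states and compact indices over the free bits.
inline uint32_t fullFromFree(const Dyn& d, uint32_t j) {
  uint32_t s = d.forcedState;
  for (size_t k = 0; k < d.freeIdx.size(); ++k)
    if (j & (1u << k)) s |= (1u << d.freeIdx[k]);
  return s;
}
inline uint32_t freeFromFull(const Dyn& d, uint32_t s) {
  uint32_t j = 0;
  for (size_t k = 0; k < d.freeIdx.size(); ++k)
    if (s & (1u << d.freeIdx[k])) j |= (1u << k);
  return j;
}

// Canonical sort key: node 0 is the most significant bit, so comparing keys
// equals lexicographic comparison of the printed bit-strings.
inline uint32_t stateKey(const Dyn& d, uint32_t s) {
  uint32_t key = 0;
  for (int i = 0; i < d.nNodes; ++i)
    if (s & (1u << i)) key |= (1u << (d.nNodes - 1 - i));
  return key;
}

// Iterative Tarjan SCC over an implicitly represented graph.  `stateOf` maps a
// vertex id in [0, n) to its full state; `indexOf` maps a successor state back
// to a vertex id (or -1 if outside the vertex set, which is treated as an
// escape edge making the component non-terminal).
template <typename StateOf, typename IndexOf>
void terminalSCCs(const Dyn& d, uint32_t n, StateOf stateOf, IndexOf indexOf,
                  std::vector<std::vector<uint32_t> >& attractors) {
  const int UNDEF = -1;
  std::vector<int> index(n, UNDEF), lowlink(n, 0), comp(n, UNDEF);
  std::vector<uint8_t> onStack(n, 0);
  std::vector<uint32_t> stack;           // Tarjan stack of vertex ids
  std::vector<uint32_t> succBuf;
  int nextIndex = 0, nComp = 0;

  struct Frame { uint32_t v; size_t child; std::vector<uint32_t> succ; };
  std::vector<Frame> call;

  for (uint32_t root = 0; root < n; ++root) {
    if (index[root] != UNDEF) continue;
    call.push_back(Frame{root, 0, {}});
    while (!call.empty()) {
      Frame& f = call.back();
      uint32_t v = f.v;
      if (f.child == 0) {
        index[v] = lowlink[v] = nextIndex++;
        stack.push_back(v); onStack[v] = 1;
        successors(d, stateOf(v), succBuf);
        f.succ.reserve(succBuf.size());
        for (uint32_t s : succBuf) {
          int w = indexOf(s);
          if (w >= 0) f.succ.push_back(static_cast<uint32_t>(w));
        }
      }
      bool descended = false;
      while (f.child < f.succ.size()) {
        uint32_t w = f.succ[f.child];
        if (index[w] == UNDEF) {
          ++f.child;
          call.push_back(Frame{w, 0, {}});
          descended = true;
          break;
        }
        if (onStack[w] && lowlink[v] > index[w]) lowlink[v] = index[w];
        ++f.child;
      }
      if (descended) continue;
      if (lowlink[v] == index[v]) {
        uint32_t w;
        do {
          w = stack.back(); stack.pop_back(); onStack[w] = 0;
          comp[w] = nComp;
        } while (w != v);
        ++nComp;
      }
      uint32_t vDone = v;
      call.pop_back();
      if (!call.empty()) {
        uint32_t parent = call.back().v;
        if (lowlink[parent] > lowlink[vDone]) lowlink[parent] = lowlink[vDone];
      }
    }
  }

  // Terminal components: no successor leaves the component (an edge out of the
  // vertex set also disqualifies).
  std::vector<uint8_t> terminal(nComp, 1);
  for (uint32_t v = 0; v < n; ++v) {
    successors(d, stateOf(v), succBuf);
    for (uint32_t s : succBuf) {
      int w = indexOf(s);
      if (w < 0 || comp[w] != comp[v]) terminal[comp[v]] = 0;
    }
  }
  std::vector<std::vector<uint32_t> > byComp(nComp);
  for (uint32_t v = 0; v < n; ++v)
    if (terminal[comp[v]]) byComp[comp[v]].push_back(stateOf(v));
  for (int c = 0; c < nComp; ++c)
    if (terminal[c] && !byComp[c].empty()) attractors.push_back(std::move(byComp[c]));
}

List attractorsToList(const Dyn& d, std::vector<std::vector<uint32_t> >& attractors) {
  // Sort states within each attractor and attractors by their smallest state,
  // both under the bit-string key, for a deterministic canonical order.
  for (auto& a : attractors)
    std::sort(a.begin(), a.end(), [&](uint32_t x, uint32_t y) {
      return stateKey(d, x) < stateKey(d, y);
    });
  std::sort(attractors.begin(), attractors.end(),
            [&](const std::vector<uint32_t>& x, const std::vector<uint32_t>& y) {
              return stateKey(d, x[0]) < stateKey(d, y[0]);
            });
  List out(attractors.size());
  for (size_t i = 0; i < attractors.size(); ++i) {
    IntegerVector v(attractors[i].size());
    for (size_t j = 0; j < attractors[i].size(); ++j)
      v[j] = static_cast<int>(attractors[i][j]);
    out[i] = v;
  }
  return out;
}

} // namespace

// [[Rcpp::export(name = ".cpp_exact_attractors")]]
List cpp_exact_attractors(int nNodes, IntegerVector act, IntegerVector inh,
                          IntegerVector regType, IntegerVector freeIdx,
                          double forcedState) {
  Dyn d = makeDyn(nNodes, act, inh, regType, freeIdx, forcedState);
  uint32_t n = 1u << d.freeIdx.size();
  std::vector<std::vector<uint32_t> > attractors;
  terminalSCCs(d, n,
               [&](uint32_t v) { return fullFromFree(d, v); },
               [&](uint32_t s) { return static_cast<int>(freeFromFull(d, s)); },
               attractors);
  return attractorsToList(d, attractors);
}

// [[Rcpp::export(name = ".cpp_reachable_states")]]
IntegerVector cpp_reachable_states(int nNodes, IntegerVector act, IntegerVector inh,
                                   IntegerVector regType, IntegerVector freeIdx,
                                   double forcedState, IntegerVector starts) {
  Dyn d = makeDyn(nNodes, act, inh, regType, freeIdx, forcedState);
  uint32_t n = 1u << d.freeIdx.size();
  std::vector<uint8_t> visited(n, 0);
  std::vector<uint32_t> frontier, next, succBuf, out;
  for (int s0 : starts) {
    uint32_t s = (static_cast<uint32_t>(s0) & d.freeMask) | d.forcedState;
    uint32_t j = freeFromFull(d, s);
    if (!visited[j]) { visited[j] = 1; frontier.push_back(s); out.push_back(s); }
  }
  while (!frontier.empty()) {
    next.clear();
    for (uint32_t s : frontier) {
      successors(d, s, succBuf);
      for (uint32_t t : succBuf) {
        uint32_t j = freeFromFull(d, t);
        if (!visited[j]) { visited[j] = 1; next.push_back(t); out.push_back(t); }
      }
    }
    frontier.swap(next);
  }
  return IntegerVector(out.begin(), out.end());
}

// Batched helpers for the fitness hot path: attractor sets together with
// their average-state vectors, and the reachability matrix between two
// perturbations' attractor sets.

// [[Rcpp::export(name = ".cpp_attractors_avg")]]
List cpp_attractors_avg(int nNodes, IntegerVector act, IntegerVector inh,
                        IntegerVector regType, IntegerVector freeIdx,
                        double forcedState) {
  Dyn d = makeDyn(nNodes, act, inh, regType, freeIdx, forcedState);
  uint32_t n = 1u << d.freeIdx.size();
  std::vector<std::vector<uint32_t> > attractors;
  terminalSCCs(d, n,
               [&](uint32_t v) { return fullFromFree(d, v); },
               [&](uint32_t s) { return static_cast<int>(freeFromFull(d, s)); },
               attractors);
  List sets = attractorsToList(d, attractors);
  NumericMatrix avg(nNodes, sets.size());
  for (int a = 0; a < sets.size(); ++a) {
    IntegerVector st = sets[a];
    for (int i = 0; i < nNodes; ++i) {
      double m = 0;
      for (int j = 0; j < st.size(); ++j)
        m += (static_cast<uint32_t>(st[j]) >> i) & 1u;
      avg(i, a) = m / st.size();
    }
  }
  return List::create(Named("sets") = sets, Named("avg") = avg);
}

// reach(i, j) = TRUE iff some state of sourceSets[i] (clamps of the target
// perturbation overwritten) reaches some state of targetSets[j] under the
// target perturbation's dynamics
// [[Rcpp::export(name = ".cpp_reach_matrix")]]
LogicalMatrix cpp_reach_matrix(int nNodes, IntegerVector act, IntegerVector inh,
                               IntegerVector regType, IntegerVector freeIdx,
                               double forcedState, List sourceSets,
                               List targetSets) {
  Dyn d = makeDyn(nNodes, act, inh, regType, freeIdx, forcedState);
  uint32_t n = 1u << d.freeIdx.size();
  LogicalMatrix out(sourceSets.size(), targetSets.size());
  std::vector<uint8_t> visited(n);
  std::vector<uint32_t> frontier, next, succBuf;
  for (int i = 0; i < sourceSets.size(); ++i) {
    std::fill(visited.begin(), visited.end(), 0);
    frontier.clear();
    IntegerVector starts = sourceSets[i];
    for (int k = 0; k < starts.size(); ++k) {
      uint32_t s = (static_cast<uint32_t>(starts[k]) & d.freeMask) | d.forcedState;
      uint32_t j = freeFromFull(d, s);
      if (!visited[j]) { visited[j] = 1; frontier.push_back(s); }
    }
    while (!frontier.empty()) {
      next.clear();
      for (uint32_t s : frontier) {
        successors(d, s, succBuf);
        for (uint32_t t : succBuf) {
          uint32_t j = freeFromFull(d, t);
          if (!visited[j]) { visited[j] = 1; next.push_back(t); }
        }
      }
      frontier.swap(next);
    }
    for (int j = 0; j < targetSets.size(); ++j) {
      IntegerVector ts = targetSets[j];
      bool hit = false;
      for (int k = 0; k < ts.size() && !hit; ++k)
        hit = visited[freeFromFull(d, static_cast<uint32_t>(ts[k]))] != 0;
      out(i, j) = hit;
    }
  }
  return out;
}

// Random asynchronous walk of at most `len` steps using R's RNG; stops early
// at a steady state.  Returns the visited path (including start and final
// state).
// [[Rcpp::export(name = ".cpp_walk")]]
IntegerVector cpp_walk(int nNodes, IntegerVector act, IntegerVector inh,
                       IntegerVector regType, IntegerVector freeIdx,
                       double forcedState, double start, int len) {
  Dyn d = makeDyn(nNodes, act, inh, regType, freeIdx, forcedState);
  uint32_t s = (static_cast<uint32_t>(start) & d.freeMask) | d.forcedState;
  std::vector<uint32_t> path;
  path.push_back(s);
  std::vector<uint32_t> succBuf;
  for (int step = 0; step < len; ++step) {
    successors(d, s, succBuf);
    if (succBuf.empty()) break;           // steady state
    int k = static_cast<int>(unif_rand() * succBuf.size());
    if (k >= static_cast<int>(succBuf.size())) k = succBuf.size() - 1;
    s = succBuf[k];
    path.push_back(s);
  }
  return IntegerVector(path.begin(), path.end());
}

// Bounded forward closure from `start`; if it completes within `cap` states,
// its terminal SCCs are certified attractors of the full transition graph
// (the closure is forward-closed by construction).
// [[Rcpp::export(name = ".cpp_closure_attractors")]]
List cpp_closure_attractors(int nNodes, IntegerVector act, IntegerVector inh,
                            IntegerVector regType, IntegerVector freeIdx,
                            double forcedState, double start, int cap) {
  Dyn d = makeDyn(nNodes, act, inh, regType, freeIdx, forcedState);
  uint32_t s0 = (static_cast<uint32_t>(start) & d.freeMask) | d.forcedState;
  std::unordered_map<uint32_t, int> idx;
  std::vector<uint32_t> states;
  std::vector<uint32_t> queue, succBuf;
  bool complete = true;
  idx[s0] = 0; states.push_back(s0); queue.push_back(s0);
  size_t head = 0;
  while (head < queue.size()) {
    uint32_t s = queue[head++];
    successors(d, s, succBuf);
    for (uint32_t t : succBuf) {
      if (idx.find(t) == idx.end()) {
        if (states.size() >= static_cast<size_t>(cap)) { complete = false; break; }
        idx[t] = static_cast<int>(states.size());
        states.push_back(t);
        queue.push_back(t);
      }
    }
    if (!complete) break;
  }
  List out;
  IntegerVector visited(states.begin(), states.end());
  if (!complete) {
    out["complete"] = false;
    out["attractors"] = List(0);
    out["visited"] = visited;
    return out;
  }
  std::vector<std::vector<uint32_t> > attractors;
  terminalSCCs(d, static_cast<uint32_t>(states.size()),
               [&](uint32_t v) { return states[v]; },
               [&](uint32_t s) {
                 auto it = idx.find(s);
                 return it == idx.end() ? -1 : it->second;
               },
               attractors);
  out["complete"] = true;
  out["attractors"] = attractorsToList(d, attractors);
  out["visited"] = visited;
  return out;
}
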