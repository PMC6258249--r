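#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

// Bond-alternation pass over a pi-system.
//
// The pi-system is given in CSR form: for member atom a (0-based), its
// incident pi-edges are adj_edge[ptr[a] .. ptr[a+1]-1] with opposite
// endpoints adj_nbr[...].  d holds the per-atom pi-deficiency (1 or 2).
//
// The pass combines randomized bond selection with forced-move
// propagation, which is what lets a single sweep alternate bonds across
// a fused-ring system almost perfectly:
//
//   * an atom whose free capacity (sum over unassigned incident edges
//     of min(2, partner's remaining demand)) exactly equals its
//     remaining demand has a unique extension; such forced assignments
//     are propagated immediately through a worklist (this is how a
//     placed double bond "alternates" outward along rings and chains);
//   * when nothing is forced, the next atom in the shuffled visiting
//     order (atom_order) claims pi-order on an eligible incident edge,
//     ties among edges broken by edge_prio (smaller wins) -- the random
//     selection of a double bond in the node.  A deficiency-2 atom
//     prefers a single pi-order-2 edge (triple bond) when its partner
//     can accept two units, else two pi-order-1 edges (cumulene).
//
// Edges never claimed stay pi-order 0 (single).  Atoms whose demand
// cannot be met are returned as unmatched.  Deterministic given
// (atom_order, edge_prio).
// [[Rcpp::export]]
List cpp_alternate_pass(IntegerVector ptr, IntegerVector adj_edge,
                        IntegerVector adj_nbr, IntegerVector d,
                        IntegerVector atom_order, IntegerVector edge_prio) {
  const int m = d.size();
  const int ne = edge_prio.size();
  IntegerVector x(ne, 0);
  std::vector<bool> assigned(ne, false);
  std::vector<int> rem(d.begin(), d.end());
  std::vector<int> work;
  work.reserve(256);
  double ops = 0.0;

  // claim order v on edge e = (a, u) and queue both neighbourhoods for
  // forced-move checks
  auto assign = [&](int e, int a, int u, int v) {
    x[e] = v;
    assigned[e] = true;
    rem[a] -= v;
    rem[u] -= v;
    for (int k = ptr[a]; k < ptr[a + 1]; ++k) work.push_back(adj_nbr[k]);
    for (int k = ptr[u]; k < ptr[u + 1]; ++k) work.push_back(adj_nbr[k]);
  };

  // propagate all forced assignments
  auto process_forced = [&]() {
    while (!work.empty()) {
      const int a = work.back();
      work.pop_back();
      if (rem[a] <= 0) continue;
      int cap = 0;
      for (int k = ptr[a]; k < ptr[a + 1]; ++k) {
        ++ops;
        const int e = adj_edge[k];
        if (assigned[e]) continue;
        cap += std::min(2, rem[adj_nbr[k]]);
      }
      if (cap != rem[a]) continue;   // not forced (or already doomed)
      for (int k = ptr[a]; k < ptr[a + 1] && rem[a] > 0; ++k) {
        const int e = adj_edge[k];
        if (assigned[e]) continue;
        const int u = adj_nbr[k];
        const int v = std::min(2, std::min(rem[u], rem[a]));
        if (v <= 0) continue;
        assign(e, a, u, v);
      }
    }
  };

  // boundary atoms (terminal alkynes, exocyclic methylenes, ...) are
  // forced before any random choice is made
  for (int i = 0; i < m; ++i) work.push_back(i);
  process_forced();

  for (int oi = 0; oi < m; ++oi) {
    const int a = atom_order[oi];
    while (rem[a] > 0) {
      int se = -1, su = -1, sprio = INT_MAX;
      bool spair2 = false;
      const bool want2 = rem[a] == 2;
      for (int k = ptr[a]; k < ptr[a + 1]; ++k) {
        ++ops;
        const int e = adj_edge[k];
        if (assigned[e]) continue;
        const int u = adj_nbr[k];
        if (rem[u] <= 0) continue;
        const bool pair2 = want2 && rem[u] >= 2;
        if (se < 0 || (pair2 && !spair2) ||
            (pair2 == spair2 && edge_prio[e] < sprio)) {
          se = e; su = u; spair2 = pair2; sprio = edge_prio[e];
        }
      }
      if (se < 0) break;             // atom stays unmatched
      assign(se, a, su, spair2 ? 2 : 1);
      process_forced();
    }
  }

  std::vector<int> unmatched;
  for (int i = 0; i < m; ++i) if (rem[i] > 0) unmatched.push_back(i);
  return List::create(_["pi"] = x,
                      _["rem"] = wrap(rem),
                      _["unmatched"] = wrap(unmatched),
                      _["ops"] = ops);
}

// Alternating-path repair (the removal of unmatched atoms): starting
// from each atom with unmet demand, breadth-first search for a walk
// that alternates increasable edges (pi-order < 2) and decreasable
// edges (pi-order > 0) and ends at another demanding atom through an
// increasable edge; applying +1/-1 along the walk raises both
// endpoints' coverage by one and leaves every interior atom unchanged.
// This is capacitated b-matching augmentation; no blossom handling, so
// a missed augmenting walk simply leaves the atom unmatched and the
// caller reshuffles.  Each applied walk is verified (pi-orders within
// 0..2, no demand overshoot) and rolled back if a self-crossing walk
// would corrupt the assignment.
// [[Rcpp::export]]
List cpp_augment(IntegerVector ptr, IntegerVector adj_edge,
                 IntegerVector adj_nbr, IntegerVector x_in,
                 IntegerVector rem_in) {
  const int m = rem_in.size();
  std::vector<int> x(x_in.begin(), x_in.end());
  std::vector<int> rem(rem_in.begin(), rem_in.end());
  // per (atom, arrival-parity) BFS bookkeeping; parity 0 = must leave
  // via an increasable edge, 1 = via a decreasable edge
  std::vector<int> seen(2 * m, -1), prev_edge(2 * m, -1),
      prev_state(2 * m, -1);
  std::vector<int> queue;
  queue.reserve(256);
  int run = 0;

  for (int s = 0; s < m; ++s) {
    while (rem[s] > 0) {
      ++run;
      queue.clear();
      const int s0 = 2 * s;
      queue.push_back(s0);
      seen[s0] = run;
      int end_state = -1, end_e = -1, end_atom = -1;
      for (size_t qi = 0; qi < queue.size() && end_e < 0; ++qi) {
        const int st = queue[qi];
        const int a = st / 2, par = st % 2;
        for (int k = ptr[a]; k < ptr[a + 1]; ++k) {
          const int e = adj_edge[k], u = adj_nbr[k];
          if (par == 0) {
            if (x[e] >= 2) continue;          // need an increasable edge
            if (rem[u] > 0 && u != s) {       // demanding endpoint found
              end_state = st; end_e = e; end_atom = u;
              break;
            }
            const int nxt = 2 * u + 1;
            if (seen[nxt] == run) continue;
            seen[nxt] = run; prev_edge[nxt] = e; prev_state[nxt] = st;
            queue.push_back(nxt);
          } else {
            if (x[e] <= 0) continue;          // need a decreasable edge
            const int nxt = 2 * u;
            if (seen[nxt] == run) continue;
            seen[nxt] = run; prev_edge[nxt] = e; prev_state[nxt] = st;
            queue.push_back(nxt);
          }
        }
      }
      if (end_e < 0) break;                   // no augmenting walk from s
      // collect the walk, apply +1 / -1, verify, roll back on violation
      std::vector<int> es, dirs;
      es.push_back(end_e); dirs.push_back(+1);
      for (int st = end_state; st != s0; st = prev_state[st]) {
        es.push_back(prev_edge[st]);
        dirs.push_back(st % 2 == 1 ? +1 : -1);
      }
      bool ok = true;
      for (size_t i = 0; i < es.size(); ++i) {
        x[es[i]] += dirs[i];
        if (x[es[i]] < 0 || x[es[i]] > 2) ok = false;
      }
      if (!ok) {
        for (size_t i = 0; i < es.size(); ++i) x[es[i]] -= dirs[i];
        break;
      }
      rem[s] -= 1;
      rem[end_atom] -= 1;
    }
  }
  int n_un = 0;
  for (int i = 0; i < m; ++i) if (rem[i] > 0) ++n_un;
  return List::create(_["pi"] = wrap(x),
                      _["rem"] = wrap(rem),
                      _["n_unmatched"] = n_un);
}

namespace {

struct Pos { int e, u; };

struct Frame {
  int a;
  std::vector<Pos> ps;               // this atom's unassigned edges
  std::vector<std::vector<int> > combos;  // valid local assignments
  int ci;                            // current combo, -1 = none applied
};

// Exact search state: edges carry -1 (unassigned) or a fixed pi-order.
struct Bt {
  const IntegerVector &ptr, &adj_edge, &adj_nbr;
  std::vector<int> rem, x, free_cnt;
  std::vector<double> stamp;
  std::vector<int> comp_seen, comp_stack;   // scratch for parity sweep
  int comp_gen;
  double nodes, node_limit, clock;
  bool hit_limit;

  Bt(const IntegerVector &p, const IntegerVector &ae,
     const IntegerVector &an, const IntegerVector &d, int ne, double limit)
      : ptr(p), adj_edge(ae), adj_nbr(an), rem(d.begin(), d.end()),
        x(ne, -1), free_cnt(d.size()), stamp(d.size(), 0.0),
        comp_seen(d.size(), 0), comp_gen(0), nodes(0.0),
        node_limit(limit), clock(0.0), hit_limit(false) {
    for (int a = 0; a < (int)free_cnt.size(); ++a)
      free_cnt[a] = ptr[a + 1] - ptr[a];
  }

  // Any connected component of still-demanding atoms (joined by
  // unassigned edges between two such atoms) must have an even total
  // remaining demand: each edge unit satisfies two demand units.  An
  // odd component makes the current partial assignment a dead end.
  bool components_even() {
    ++comp_gen;
    const int m = (int)rem.size();
    for (int s = 0; s < m; ++s) {
      if (rem[s] <= 0 || comp_seen[s] == comp_gen) continue;
      int total = 0;
      comp_stack.clear();
      comp_stack.push_back(s);
      comp_seen[s] = comp_gen;
      while (!comp_stack.empty()) {
        const int a = comp_stack.back();
        comp_stack.pop_back();
        total += rem[a];
        for (int k = ptr[a]; k < ptr[a + 1]; ++k) {
          if (x[adj_edge[k]] >= 0) continue;
          const int u = adj_nbr[k];
          if (rem[u] <= 0 || comp_seen[u] == comp_gen) continue;
          comp_seen[u] = comp_gen;
          comp_stack.push_back(u);
        }
      }
      if (total % 2 != 0) return false;
    }
    return true;
  }

  bool capacity_ok(int u) const {
    if (rem[u] <= 0) return true;
    int cap = 0;
    for (int k = ptr[u]; k < ptr[u + 1]; ++k) {
      if (x[adj_edge[k]] >= 0) continue;
      cap += std::min(2, rem[adj_nbr[k]]);
      if (cap >= rem[u]) return true;
    }
    return false;
  }

  // Select the next atom to expand.  A full capacity sweep fails fast
  // (-2) when any unsatisfied atom can no longer meet its demand, and an
  // atom whose free capacity exactly equals its demand has a unique
  // extension and is taken immediately.  Otherwise:
  // most-constrained-first (fewest unassigned incident edges), ties
  // broken toward the most recently touched atom so the search stays
  // localized on lattice-like graphs.  -1 = all demands met.
  int select() {
    if (!components_even()) return -2;
    int a = -1, best = INT_MAX;
    double best_stamp = -1.0;
    for (int i = 0; i < (int)rem.size(); ++i) {
      if (rem[i] <= 0) continue;
      int cap = 0;
      for (int k = ptr[i]; k < ptr[i + 1]; ++k) {
        if (x[adj_edge[k]] >= 0) continue;
        cap += std::min(2, rem[adj_nbr[k]]);
      }
      if (cap < rem[i]) return -2;
      if (cap == rem[i]) return i;
      if (free_cnt[i] < best ||
          (free_cnt[i] == best && stamp[i] > best_stamp)) {
        best = free_cnt[i]; a = i; best_stamp = stamp[i];
      }
    }
    return a;
  }

  Frame make_frame(int a) {
    Frame f;
    f.a = a;
    f.ci = -1;
    for (int k = ptr[a]; k < ptr[a + 1]; ++k) {
      if (x[adj_edge[k]] < 0) {
        Pos p; p.e = adj_edge[k]; p.u = adj_nbr[k];
        f.ps.push_back(p);
      }
    }
    // enumerate local assignments summing exactly to rem[a], each value
    // capped by the partner's remaining demand (and 2); higher orders
    // first so triples are preferred over cumulated doubles
    std::vector<int> cur(f.ps.size(), 0);
    enumerate(f, cur, 0, rem[a]);
    return f;
  }

  void enumerate(Frame &f, std::vector<int> &cur, size_t i, int need) {
    if (i == f.ps.size()) {
      if (need == 0) f.combos.push_back(cur);
      return;
    }
    int rest = 0;
    for (size_t j = i + 1; j < f.ps.size(); ++j)
      rest += std::min(2, rem[f.ps[j].u]);
    const int hi = std::min(2, std::min(need, rem[f.ps[i].u]));
    for (int v = hi; v >= 0; --v) {
      if (need - v > rest) continue;
      cur[i] = v;
      enumerate(f, cur, i + 1, need - v);
    }
    cur[i] = 0;
  }

  void apply(Frame &f, const std::vector<int> &vals) {
    for (size_t i = 0; i < f.ps.size(); ++i) {
      x[f.ps[i].e] = vals[i];
      rem[f.ps[i].u] -= vals[i];
      rem[f.a] -= vals[i];
      free_cnt[f.ps[i].u]--;
      free_cnt[f.a]--;
      stamp[f.ps[i].u] = ++clock;
    }
  }

  void undo(Frame &f, const std::vector<int> &vals) {
    for (size_t i = 0; i < f.ps.size(); ++i) {
      x[f.ps[i].e] = -1;
      rem[f.ps[i].u] += vals[i];
      rem[f.a] += vals[i];
      free_cnt[f.ps[i].u]++;
      free_cnt[f.a]++;
    }
  }

  // move the frame to its next locally valid assignment
  bool advance(Frame &f) {
    if (f.ci >= 0) undo(f, f.combos[f.ci]);
    while (++f.ci < (int)f.combos.size()) {
      if (++nodes > node_limit) { hit_limit = true; return false; }
      apply(f, f.combos[f.ci]);
      bool ok = true;
      for (size_t i = 0; i < f.ps.size() && ok; ++i)
        ok = capacity_ok(f.ps[i].u);
      if (ok) return true;
      undo(f, f.combos[f.ci]);
    }
    return false;
  }

  // iterative depth-first search (explicit frame stack, so pi-systems of
  // any size cannot overflow the C stack)
  bool solve() {
    std::vector<Frame> st;
    bool descend = true;
    for (;;) {
      if (hit_limit) return false;
      if (descend) {
        const int sel = select();
        if (sel == -1) return true;
        if (sel >= 0) {
          st.push_back(make_frame(sel));
        }
        // sel == -2: dead end; advance the top frame instead
      }
      if (st.empty()) return false;
      if (advance(st.back())) {
        descend = true;
      } else {
        st.pop_back();
        descend = false;
      }
    }
  }
};

}  // namespace

// Exact feasibility decision for a pi-system by depth-first search over
// per-atom demand satisfaction with forward capacity pruning.  Returns a
// witness assignment when feasible.  node_limit bounds the number of
// search nodes (R_PosInf = unlimited).
// [[Rcpp::export]]
List cpp_backtrack(IntegerVector ptr, IntegerVector adj_edge,
                   IntegerVector adj_nbr, IntegerVector d, int ne,
                   double node_limit) {
  Bt st(ptr, adj_edge, adj_nbr, d, ne, node_limit);
  bool ok = st.solve();
  IntegerVector x(ne);
  for (int e = 0; e < ne; ++e) x[e] = st.x[e] < 0 ? 0 : st.x[e];
  return List::create(_["exists"] = ok,
                      _["pi"] = x,
                      _["nodes"] = st.nodes,
                      _["hit_limit"] = st.hit_limit);
}
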