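#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// One-dimensional annihilating-coalescing domain-wall engine on a ring.
//
// Walls live off-lattice at continuous angular positions in [0, 2*pi).
// Cyclic order is kept in a doubly linked list (nxt/prv), not by sorting, so
// positions may wrap freely.  labArc[w] is the strain occupying the arc
// running counter-clockwise from wall w to wall nxt[w]; the wall type of w is
// (labArc[prv[w]] | labArc[w]).
//
// Each step: pick a wall uniformly at random, hop it a distance a (angular
// step a/R with the pre-hop radius R) right with probability (1+r_ij)/2 else
// left.  A hop that reaches or crosses the nearest neighbour in the hop
// direction is truncated at that neighbour's position and the two walls react
// instantly: annihilation when the outer flanking strains match, coalescence
// otherwise (the new wall keeps the collision point).  After the hop the
// clock advances by dt = 1/N generations (N = wall count before the hop),
// the length expanded by dL = d/N, and for radial geometry the radius tracks
// the expansion, R = R0 + d*t (= R0 + L), reducing to R0 + a*t when d = a.

namespace {

struct Ring {
  std::vector<double> phi;
  std::vector<int> lab;   // arc label counter-clockwise of wall
  std::vector<int> nxt, prv;
  std::vector<int> act;      // active wall ids
  std::vector<int> pos;      // id -> index in act, -1 if dead
  int n;

  void init(const NumericVector& phi0, const IntegerVector& lab0) {
    n = phi0.size();
    phi.assign(phi0.begin(), phi0.end());
    lab.assign(lab0.begin(), lab0.end());
    nxt.resize(n); prv.resize(n); act.resize(n); pos.resize(n);
    for (int k = 0; k < n; ++k) {
      nxt[k] = (k + 1) % n;
      prv[k] = (k + n - 1) % n;
      act[k] = k;
      pos[k] = k;
    }
  }

  void remove(int id) {
    int k = pos[id], last = act.back();
    act[k] = last; pos[last] = k;
    act.pop_back(); pos[id] = -1;
    --n;
  }

  // unlink id from the cyclic list (neighbours rewired by caller)
};

List state_snapshot(const Ring& rg, double R0, double R, double L, double t) {
  int m = rg.n;
  NumericVector sphi(m);
  IntegerVector slab(m);
  if (m > 0) {
    // walk the linked list starting from the smallest position; cyclic list
    // order is authoritative (it always matches the circle order)
    int start = rg.act[0];
    for (int id : rg.act) if (rg.phi[id] < rg.phi[start]) start = id;
    int c = start;
    for (int k = 0; k < m; ++k) {
      sphi[k] = rg.phi[c];
      slab[k] = rg.lab[c];
      c = rg.nxt[c];
    }
  }
  return List::create(_["phi"] = sphi, _["lab"] = slab, _["R0"] = R0,
                      _["R"] = R, _["L"] = L, _["t"] = t, _["n_walls"] = m);
}

} // namespace

// [[Rcpp::export]]
List cpp_run_expansion(NumericVector phi0, IntegerVector lab0,
                       double R0, bool radial, double a, double d,
                       NumericMatrix bias, NumericVector snapshot_L,
                       double max_L, double max_steps) {
  const double TWO_PI = 2.0 * M_PI;
  Ring rg;
  rg.init(phi0, lab0);

  double t = 0.0, L = 0.0, R = R0;
  double steps = 0.0;

  int nsnap = snapshot_L.size(), snap_idx = 0;
  List snapshots(nsnap);

  // event log columns
  std::vector<double> ev_L;
  std::vector<int> ev_kind;              // 1 annihilation, 2 coalescence
  std::vector<int> ev_c1l, ev_c1r, ev_c2l, ev_c2r, ev_pl, ev_pr;

  while (rg.n > 0 && steps < max_steps && L <= max_L) {
    int N = rg.n;
    int u = rg.act[(int)(unif_rand() * N) % N];
    int i = rg.lab[rg.prv[u]], j = rg.lab[u];
    double r = bias(i, j);
    bool right = unif_rand() < 0.5 * (1.0 + r);
    double dphi = a / R;

    bool collided = false;
    int kind = 0, c1l = 0, c1r = 0, c2l = 0, c2r = 0, pl = NA_INTEGER, pr = NA_INTEGER;

    if (right) {
      int w = rg.nxt[u];
      // collision test uses the exact position that would be written, so a
      // wall can never cross or land on its neighbour without reacting
      double target = (rg.phi[w] <= rg.phi[u]) ? rg.phi[w] + TWO_PI : rg.phi[w];
      double newp = rg.phi[u] + dphi;
      double wrapped = newp >= TWO_PI ? newp - TWO_PI : newp;
      if (newp >= target || wrapped == rg.phi[w]) {
        collided = true;
        int A = rg.lab[rg.prv[u]], B = rg.lab[u], C = rg.lab[w];
        c1l = A; c1r = B; c2l = B; c2r = C;
        if (A == C) {
          kind = 1;
          int p = rg.prv[u], q = rg.nxt[w];
          rg.remove(u); rg.remove(w);
          if (rg.n > 0) { rg.nxt[p] = q; rg.prv[q] = p; }
        } else {
          kind = 2; pl = A; pr = C;
          int p = rg.prv[u];
          rg.remove(u);
          rg.nxt[p] = w; rg.prv[w] = p;
          // w keeps the collision point rg.phi[w]; its type is now A|C
        }
      } else {
        rg.phi[u] = wrapped;
      }
    } else {
      int w = rg.prv[u];
      double target = (rg.phi[w] >= rg.phi[u]) ? rg.phi[w] - TWO_PI : rg.phi[w];
      double newp = rg.phi[u] - dphi;
      double wrapped = newp < 0.0 ? newp + TWO_PI : newp;
      if (wrapped >= TWO_PI) wrapped = 0.0;  // -eps + 2*pi can round up to 2*pi
      if (newp <= target || wrapped == rg.phi[w]) {
        collided = true;
        int A = rg.lab[rg.prv[w]], B = rg.lab[w], C = rg.lab[u];
        c1l = A; c1r = B; c2l = B; c2r = C;
        if (A == C) {
          kind = 1;
          int p = rg.prv[w], q = rg.nxt[u];
          rg.remove(w); rg.remove(u);
          if (rg.n > 0) { rg.nxt[p] = q; rg.prv[q] = p; }
        } else {
          kind = 2; pl = A; pr = C;
          int q = rg.nxt[u];
          rg.remove(u);
          rg.nxt[w] = q; rg.prv[q] = w;
          rg.lab[w] = C;   // wall w now has type A|C at the collision point
        }
      } else {
        rg.phi[u] = wrapped;
      }
    }

    t += 1.0 / N;
    L += d / N;
    if (radial) R = R0 + L;   // the radius tracks the length expanded
    steps += 1.0;

    if (collided) {
      ev_L.push_back(L); ev_kind.push_back(kind);
      ev_c1l.push_back(c1l); ev_c1r.push_back(c1r);
      ev_c2l.push_back(c2l); ev_c2r.push_back(c2r);
      ev_pl.push_back(pl); ev_pr.push_back(pr);
    }

    while (snap_idx < nsnap && L >= snapshot_L[snap_idx]) {
      snapshots[snap_idx] = state_snapshot(rg, R0, R, L, t);
      ++snap_idx;
    }
  }

  // requested lengths never reached (fixation or step cap): record final state
  while (snap_idx < nsnap) {
    snapshots[snap_idx] = state_snapshot(rg, R0, R, L, t);
    ++snap_idx;
  }

  int ne = ev_L.size();
  List events = List::create(
    _["L_at"] = NumericVector(ev_L.begin(), ev_L.end()),
    _["kind"] = IntegerVector(ev_kind.begin(), ev_kind.end()),
    _["left_in1"] = IntegerVector(ev_c1l.begin(), ev_c1l.end()),
    _["right_in1"] = IntegerVector(ev_c1r.begin(), ev_c1r.end()),
    _["left_in2"] = IntegerVector(ev_c2l.begin(), ev_c2l.end()),
    _["right_in2"] = IntegerVector(ev_c2r.begin(), ev_c2r.end()),
    _["left_out"] = IntegerVector(ev_pl.begin(), ev_pl.end()),
    _["right_out"] = IntegerVector(ev_pr.begin(), ev_pr.end()));

  return List::create(
    _["snapshots"] = snapshots,
    _["events"] = events,
    _["n_events"] = ne,
    _["final"] = state_snapshot(rg, R0, R, L, t),
    _["steps"] = steps);
}

// Exact angular occupancy of each strain within uniform bins.
// Walls at sorted positions phi (arc lab[k] runs from phi[k] to phi[k+1]).
// Returns a q x n_bins matrix of fractions.
// [[Rcpp::export]]
NumericMatrix cpp_occupancy(NumericVector phi, IntegerVector lab, int q,
                            int n_bins) {
  const double TWO_PI = 2.0 * M_PI;
  NumericMatrix out(q, n_bins);
  int m = phi.size();
  double bw = TWO_PI / n_bins;
  if (m == 0) return out; // caller fills single-strain case
  // overlap of each (possibly wrapping) arc with every bin it spans
  for (int k = 0; k < m; ++k) {
    double lo = phi[k];
    double hi = (k + 1 < m) ? phi[k + 1] : phi[0] + TWO_PI;
    if (hi < lo) hi += TWO_PI; // guard (sorted input should not need it)
    int s = lab[k];
    long b_lo = (long)std::floor(lo / bw);
    long b_hi = (long)std::floor((hi - 1e-15) / bw);
    for (long b = b_lo; b <= b_hi; ++b) {
      double ov = std::min(hi, (b + 1) * bw) - std::max(lo, b * bw);
      if (ov > 0) out(s, (int)(b % n_bins)) += ov / bw;
    }
  }
  return out;
}
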