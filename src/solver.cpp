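// Direct-method SSA core over generic mass-action event channels.
//
// Every channel (volume reaction, inter-tet diffusion hop, surface
// reaction, surface-diffusion hop) is reduced on the R side to the same
// shape: propensity = cfac * prod over reactant slots of the falling
// factorial n * (n-1) * ... * (n-stoich+1), plus a list of count deltas to
// apply when the channel fires. Counts live in one flat entity array
// (entity = element x species).
//
// Channel selection is exact direct-method sampling (probability
// proportional to propensity) organized in two levels: a 4-ary sum-tree
// over per-element channel groups, then a linear scan inside the chosen
// group (a handful of channels). An event touches O(1) groups, so its cost
// is a couple of log-depth tree climbs instead of one per channel.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>

using namespace Rcpp;

class Solver {
public:
  int nent = 0, nch = 0, ngrp = 0;
  int M = 1;                           // leaf slots (power of 4)
  int base = 0;                        // index of first leaf in `tree`
  std::vector<double> cfac, counts, prop;
  std::vector<int> rptr, rent, rsto;   // reactant CSR per channel
  std::vector<int> dptr, dent, ddel;   // delta CSR per channel
  std::vector<int> depptr, depch;      // entity -> dependent channels CSR
  std::vector<int> grp;                // channel -> group
  std::vector<int> gptr, gch;          // group -> member channels CSR
  std::vector<double> tree;            // 4-ary heap; leaves = group sums
  double t = 0.0;
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};

  Solver(int n_entities,
         const NumericVector& cfac_,
         const IntegerVector& rptr_, const IntegerVector& rent_,
         const IntegerVector& rsto_,
         const IntegerVector& dptr_, const IntegerVector& dent_,
         const IntegerVector& ddel_,
         const IntegerVector& group_, double seed) {
    nent = n_entities;
    nch = cfac_.size();
    cfac.assign(cfac_.begin(), cfac_.end());
    rptr.assign(rptr_.begin(), rptr_.end());
    rent.assign(rent_.begin(), rent_.end());
    rsto.assign(rsto_.begin(), rsto_.end());
    dptr.assign(dptr_.begin(), dptr_.end());
    dent.assign(dent_.begin(), dent_.end());
    ddel.assign(ddel_.begin(), ddel_.end());
    grp.assign(group_.begin(), group_.end());
    ngrp = 0;
    for (int ch = 0; ch < nch; ++ch) ngrp = std::max(ngrp, grp[ch] + 1);
    counts.assign(nent, 0.0);
    prop.assign(nch, 0.0);
    M = 1;
    while (M < std::max(ngrp, 1)) M <<= 2;
    base = (M - 1) / 3;
    tree.assign(base + M, 0.0);
    build_groups();
    build_deps();
    reseed(seed);
  }

  void build_groups() {
    std::vector<int> cnt(ngrp + 1, 0);
    for (int ch = 0; ch < nch; ++ch) cnt[grp[ch] + 1]++;
    gptr.assign(ngrp + 1, 0);
    for (int g = 0; g < ngrp; ++g) gptr[g + 1] = gptr[g] + cnt[g + 1];
    gch.assign(nch, 0);
    std::vector<int> fill(gptr.begin(), gptr.end() - 1);
    for (int ch = 0; ch < nch; ++ch) gch[fill[grp[ch]]++] = ch;
  }

  void build_deps() {
    std::vector<int> cnt(nent + 1, 0);
    for (size_t q = 0; q < rent.size(); ++q) cnt[rent[q] + 1]++;
    depptr.assign(nent + 1, 0);
    for (int e = 0; e < nent; ++e) depptr[e + 1] = depptr[e] + cnt[e + 1];
    depch.assign(rent.size(), 0);
    std::vector<int> fill(depptr.begin(), depptr.end() - 1);
    for (int ch = 0; ch < nch; ++ch)
      for (int q = rptr[ch]; q < rptr[ch + 1]; ++q)
        depch[fill[rent[q]]++] = ch;
  }

  void reseed(double seed) { rng.seed((uint64_t)seed); }

  double channel_prop(int ch) const {
    double v = cfac[ch];
    for (int q = rptr[ch]; q < rptr[ch + 1]; ++q) {
      double n = counts[rent[q]];
      for (int s = 0; s < rsto[q]; ++s) v *= (n - s);
      if (v <= 0.0) return 0.0;
    }
    return v;
  }

  double group_sum(int g) const {
    double s = 0.0;
    for (int q = gptr[g]; q < gptr[g + 1]; ++q) s += prop[gch[q]];
    return s;
  }

  void set_group_leaf(int g) {
    int i = base + g;
    tree[i] = group_sum(g);
    while (i > 0) {
      i = (i - 1) >> 2;
      int c = 4 * i + 1;
      tree[i] = tree[c] + tree[c + 1] + tree[c + 2] + tree[c + 3];
    }
  }

  // recompute all channels depending on a changed entity, then refresh the
  // touched group sums (usually 1-2 groups)
  void refresh_entity(int e) {
    int touched[64];
    int nt = 0;
    for (int q = depptr[e]; q < depptr[e + 1]; ++q) {
      int ch = depch[q];
      prop[ch] = channel_prop(ch);
      int g = grp[ch];
      bool seen = false;
      for (int k = 0; k < nt; ++k) if (touched[k] == g) { seen = true; break; }
      if (!seen && nt < 64) touched[nt++] = g;
      if (nt == 64) set_group_leaf(g);   // overflow: update immediately
    }
    for (int k = 0; k < nt; ++k) set_group_leaf(touched[k]);
  }

  void rebuild_all() {
    for (int ch = 0; ch < nch; ++ch) prop[ch] = channel_prop(ch);
    for (int g = 0; g < ngrp; ++g) tree[base + g] = group_sum(g);
    for (int g = ngrp; g < M; ++g) tree[base + g] = 0.0;
    for (int i = base - 1; i >= 0; --i) {
      int c = 4 * i + 1;
      tree[i] = tree[c] + tree[c + 1] + tree[c + 2] + tree[c + 3];
    }
  }

  double a0() const { return tree[0]; }

  int select(double r) const {
    int i = 0;
    while (i < base) {
      int c = 4 * i + 1;
      for (int k = 0; k < 3; ++k) {   // the 4th child is the fall-through
        if (r < tree[c]) break;
        r -= tree[c];
        ++c;
      }
      i = c;
    }
    int g = i - base;
    if (g >= ngrp) g = ngrp - 1;
    // linear scan inside the group
    int last_active = -1;
    for (int q = gptr[g]; q < gptr[g + 1]; ++q) {
      int ch = gch[q];
      if (prop[ch] <= 0.0) continue;
      last_active = ch;
      if (r < prop[ch]) return ch;
      r -= prop[ch];
    }
    if (last_active >= 0) return last_active;  // numeric edge within group
    // group numerically empty: fall back to any active channel
    for (int ch = nch - 1; ch >= 0; --ch) if (prop[ch] > 0.0) return ch;
    stop("channel selection failed with a0 > 0");
    return -1;
  }

  void apply(int ch) {
    for (int q = dptr[ch]; q < dptr[ch + 1]; ++q) {
      counts[dent[q]] += ddel[q];
      if (counts[dent[q]] < 0)
        stop("negative molecule count after event (internal error)");
    }
    for (int q = dptr[ch]; q < dptr[ch + 1]; ++q)
      refresh_entity(dent[q]);
  }

  // advance one event; returns false if no channel is active
  bool step_once() {
    double a = a0();
    if (a <= 0.0) return false;
    double tau = -std::log(1.0 - unif(rng)) / a;
    t += tau;
    apply(select(unif(rng) * a));
    return true;
  }

  // advance to t_end; an event that would land past t_end is not executed
  long run_until(double t_end) {
    long n = 0;
    while (true) {
      double a = a0();
      if (a <= 0.0) { t = t_end; break; }
      double tau = -std::log(1.0 - unif(rng)) / a;
      if (t + tau > t_end) { t = t_end; break; }
      t += tau;
      apply(select(unif(rng) * a));
      ++n;
    }
    return n;
  }
};

// [[Rcpp::export]]
SEXP solver_new(int n_entities, NumericVector cfac,
                IntegerVector rptr, IntegerVector rent, IntegerVector rsto,
                IntegerVector dptr, IntegerVector dent, IntegerVector ddel,
                IntegerVector group, double seed) {
  XPtr<Solver> p(new Solver(n_entities, cfac, rptr, rent, rsto,
                            dptr, dent, ddel, group, seed), true);
  return p;
}

// [[Rcpp::export]]
void solver_reset(SEXP ptr, double seed) {
  XPtr<Solver> p(ptr);
  std::fill(p->counts.begin(), p->counts.end(), 0.0);
  p->t = 0.0;
  p->rebuild_all();
  p->reseed(seed);
}

// [[Rcpp::export]]
NumericVector solver_counts(SEXP ptr) {
  XPtr<Solver> p(ptr);
  return NumericVector(p->counts.begin(), p->counts.end());
}

// [[Rcpp::export]]
void solver_set_counts(SEXP ptr, IntegerVector entities0,
                       NumericVector values) {
  XPtr<Solver> p(ptr);
  for (int i = 0; i < entities0.size(); ++i) {
    if (values[i] < 0) stop("negative count");
    p->counts[entities0[i]] = values[i];
  }
  for (int i = 0; i < entities0.size(); ++i)
    p->refresh_entity(entities0[i]);
}

// [[Rcpp::export]]
void solver_inject_multinomial(SEXP ptr, IntegerVector entities0,
                               NumericVector weights, int n) {
  XPtr<Solver> p(ptr);
  double wsum = 0.0;
  for (int i = 0; i < weights.size(); ++i) wsum += weights[i];
  int left = n;
  for (int i = 0; i < entities0.size(); ++i) {
    if (left <= 0) break;
    int k;
    if (i == entities0.size() - 1) k = left;
    else {
      double pr = weights[i] / wsum;
      if (pr > 1.0) pr = 1.0;
      std::binomial_distribution<int> bin(left, pr);
      k = bin(p->rng);
    }
    p->counts[entities0[i]] += k;
    left -= k;
    wsum -= weights[i];
  }
  for (int i = 0; i < entities0.size(); ++i)
    p->refresh_entity(entities0[i]);
}

// [[Rcpp::export]]
double solver_time(SEXP ptr) { return XPtr<Solver>(ptr)->t; }

// [[Rcpp::export]]
void solver_set_time(SEXP ptr, double t) { XPtr<Solver>(ptr)->t = t; }

// [[Rcpp::export]]
double solver_a0(SEXP ptr) { return XPtr<Solver>(ptr)->a0(); }

// [[Rcpp::export]]
double solver_run(SEXP ptr, double t_end) {
  XPtr<Solver> p(ptr);
  if (t_end < p->t) stop("t_end is before current simulation time");
  return (double)p->run_until(t_end);
}

// [[Rcpp::export]]
double solver_step(SEXP ptr) {
  XPtr<Solver> p(ptr);
  if (!p->step_once()) return NA_REAL;
  return p->t;
}

// [[Rcpp::export]]
NumericVector solver_propensities(SEXP ptr, bool rebuild = false) {
  XPtr<Solver> p(ptr);
  if (!rebuild) return NumericVector(p->prop.begin(), p->prop.end());
  NumericVector out(p->nch);
  for (int ch = 0; ch < p->nch; ++ch) out[ch] = p->channel_prop(ch);
  return out;
}
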