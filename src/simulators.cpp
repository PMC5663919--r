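#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Offspring draw from a cdf (cdf[k] = P(X <= k), last element == 1),
// or Poisson(xi) when pois != 0.  Uses R's RNG so runs are reproducible
// from set.seed().
static inline int draw_offspring(const NumericVector &cdf, int pois, double xi) {
  if (pois) return (int) R::rpois(xi);
  double u = unif_rand();
  return (int) (std::lower_bound(cdf.begin(), cdf.end(), u) - cdf.begin());
}

// ---------------------------------------------------------------------------
// Discrete Galton-Watson ensemble.  Profile = generation sizes Z_t
// (Z_0 = 1); duration = last t with Z_t > 0; size = total individuals.
// [[Rcpp::export]]
List gw_ensemble_cpp(NumericVector cdf, int pois, double xi, int nA, int tcap) {
  NumericVector durations(nA), sizes(nA);
  LogicalVector term(nA);
  List profiles(nA);
  for (int a = 0; a < nA; ++a) {
    std::vector<int> prof;
    long long Z = 1, size = 0;
    int t = 0;
    bool terminated = false;
    while (true) {
      prof.push_back((int) Z);
      size += Z;
      if (t >= tcap) break;
      long long births = 0;
      for (long long i = 0; i < Z; ++i) births += draw_offspring(cdf, pois, xi);
      if (births == 0) { terminated = true; break; }
      Z = births;
      ++t;
    }
    durations[a] = t;
    sizes[a] = (double) size;
    term[a] = terminated;
    profiles[a] = IntegerVector(prof.begin(), prof.end());
  }
  return List::create(_["durations"] = durations, _["sizes"] = sizes,
                      _["profiles"] = profiles, _["terminated"] = term);
}

// ---------------------------------------------------------------------------
// Continuous-time Markov branching ensemble.  Each alive individual carries
// an independent Exp(rate) clock; at its event it dies and leaves k ~ q_k
// children.  Implemented as a global next-event draw with rate
// alive * rate.  Profile = alive count sampled at bin centers
// (m + 0.5) * bin while the avalanche is alive; duration = final event
// time; size = total events (branchings).
// [[Rcpp::export]]
List ct_ensemble_cpp(NumericVector cdf, int pois, double xi, double rate,
                     int nA, double tcap, double bin) {
  NumericVector durations(nA), sizes(nA);
  LogicalVector term(nA);
  List profiles(nA);
  for (int a = 0; a < nA; ++a) {
    std::vector<int> prof;
    long long alive = 1, size = 0;
    double t = 0.0;
    int m = 0;
    bool terminated = false;
    double duration = tcap;
    while (true) {
      double tn = t + exp_rand() / (rate * (double) alive);
      while ((m + 0.5) * bin < tn && (m + 0.5) * bin <= tcap) {
        prof.push_back((int) alive);
        ++m;
      }
      if (tn > tcap) break;
      ++size;
      int k = draw_offspring(cdf, pois, xi);
      alive += k - 1;
      t = tn;
      if (alive == 0) { terminated = true; duration = t; break; }
    }
    durations[a] = duration;
    sizes[a] = (double) std::max(size, 1LL);
    term[a] = terminated;
    profiles[a] = IntegerVector(prof.begin(), prof.end());
  }
  return List::create(_["durations"] = durations, _["sizes"] = sizes,
                      _["profiles"] = profiles, _["terminated"] = term);
}

// Single continuous-time avalanche, returning raw event (branching) times.
// [[Rcpp::export]]
List ct_single_cpp(NumericVector cdf, int pois, double xi, double rate,
                   double tcap) {
  std::vector<double> ev;
  long long alive = 1;
  double t = 0.0;
  bool terminated = false;
  while (true) {
    t += exp_rand() / (rate * (double) alive);
    if (t > tcap) { t = tcap; break; }
    ev.push_back(t);
    int k = draw_offspring(cdf, pois, xi);
    alive += k - 1;
    if (alive == 0) { terminated = true; break; }
  }
  return List::create(_["event_times"] = NumericVector(ev.begin(), ev.end()),
                      _["duration"] = ev.empty() ? 0.0 : ev.back(),
                      _["terminated"] = terminated);
}

// ---------------------------------------------------------------------------
// Neuronal cascade on a weighted directed network (CSR offs/targ, 0-based).
// Synchronous steps; a firing neuron activates each follower j with
// probability phi_ij ~ U(0, phi_max), weights redrawn lazily per avalanche;
// neurons return to inactive after firing and may refire later.
// Profile = newly activated count per step (V(0) = 1, the seed).
// When record_step >= 0, children counts of parents active at that step are
// appended to `offspring_counts` (attribution by triggering edge).
// [[Rcpp::export]]
List neuronal_ensemble_cpp(IntegerVector offs, IntegerVector targ, int N,
                           double phi_max, int nA, int tcap,
                           int record_step = -1) {
  long E = targ.size();
  std::vector<double> w(E);
  std::vector<int> wstamp(E, -1);
  std::vector<int> newstamp(N, -1);
  NumericVector durations(nA), sizes(nA);
  LogicalVector term(nA);
  List profiles(nA);
  std::vector<int> offspring_counts;
  int stepkey = 0;
  for (int a = 0; a < nA; ++a) {
    std::vector<int> prof;
    std::vector<int> frontier, nxt;
    int seed = (int) (unif_rand() * N);
    if (seed >= N) seed = N - 1;
    frontier.push_back(seed);
    prof.push_back(1);
    long long size = 1;
    int t = 0;
    bool terminated = false;
    while (!frontier.empty()) {
      if (t >= tcap) break;
      ++stepkey;
      nxt.clear();
      for (size_t fi = 0; fi < frontier.size(); ++fi) {
        int i = frontier[fi];
        int kids = 0;
        for (int e = offs[i]; e < offs[i + 1]; ++e) {
          if (wstamp[e] != a) { w[e] = unif_rand() * phi_max; wstamp[e] = a; }
          if (unif_rand() < w[e]) {
            int j = targ[e];
            if (newstamp[j] != stepkey) {
              newstamp[j] = stepkey;
              nxt.push_back(j);
              ++kids;
            }
          }
        }
        if (record_step >= 0 && t == record_step)
          offspring_counts.push_back(kids);
      }
      if (nxt.empty()) { terminated = true; break; }
      ++t;
      prof.push_back((int) nxt.size());
      size += nxt.size();
      frontier.swap(nxt);
    }
    durations[a] = t;
    sizes[a] = (double) size;
    term[a] = terminated;
    profiles[a] = IntegerVector(prof.begin(), prof.end());
  }
  return List::create(_["durations"] = durations, _["sizes"] = sizes,
                      _["profiles"] = profiles, _["terminated"] = term,
                      _["offspring_counts"] =
                        IntegerVector(offspring_counts.begin(),
                                      offspring_counts.end()));
}

// ---------------------------------------------------------------------------
// Threshold cascade on an undirected network (CSR with both edge
// directions).  Thresholds R_i ~ U(0, theta_max), redrawn lazily per
// avalanche.  watts != 0: activate when m_i / k_i >= R_i; else (Centola-
// Macy) when m_i >= R_i.  Monotone, synchronous; profile = newly activated
// per step.
// [[Rcpp::export]]
List threshold_ensemble_cpp(IntegerVector offs, IntegerVector targ, int N,
                            int watts, double theta_max, int nA, int tcap,
                            int record_step = -1) {
  std::vector<double> thr(N);
  std::vector<int> tstamp(N, -1), astamp(N, -1), mstamp(N, -1);
  std::vector<int> mcount(N, 0);
  NumericVector durations(nA), sizes(nA);
  LogicalVector term(nA);
  List profiles(nA);
  std::vector<int> offspring_counts;
  for (int a = 0; a < nA; ++a) {
    std::vector<int> prof;
    std::vector<int> frontier, nxt;
    int seed = (int) (unif_rand() * N);
    if (seed >= N) seed = N - 1;
    astamp[seed] = a;
    frontier.push_back(seed);
    prof.push_back(1);
    long long size = 1;
    int t = 0;
    bool terminated = false;
    while (!frontier.empty()) {
      if (t >= tcap) break;
      nxt.clear();
      for (size_t fi = 0; fi < frontier.size(); ++fi) {
        int i = frontier[fi];
        int kids = 0;
        for (int e = offs[i]; e < offs[i + 1]; ++e) {
          int j = targ[e];
          if (astamp[j] == a) continue;
          if (mstamp[j] != a) { mstamp[j] = a; mcount[j] = 0; }
          mcount[j] += 1;
          if (tstamp[j] != a) { thr[j] = unif_rand() * theta_max; tstamp[j] = a; }
          double lhs = watts ? ((double) mcount[j]) / (offs[j + 1] - offs[j])
                             : (double) mcount[j];
          if (lhs >= thr[j]) {
            astamp[j] = a;
            nxt.push_back(j);
            ++kids;
          }
        }
        if (record_step >= 0 && t == record_step)
          offspring_counts.push_back(kids);
      }
      if (nxt.empty()) { terminated = true; break; }
      ++t;
      prof.push_back((int) nxt.size());
      size += nxt.size();
      frontier.swap(nxt);
    }
    durations[a] = t;
    sizes[a] = (double) size;
    term[a] = terminated;
    profiles[a] = IntegerVector(prof.begin(), prof.end());
  }
  return List::create(_["durations"] = durations, _["sizes"] = sizes,
                      _["profiles"] = profiles, _["terminated"] = term,
                      _["offspring_counts"] =
                        IntegerVector(offspring_counts.begin(),
                                      offspring_counts.end()));
}

// ---------------------------------------------------------------------------
// Meme propagation on a directed network, reduced to the focal meme's
// screen set S.  offs/targ: follower lists (out-edges); ioffs/itarg:
// transpose (in-edges).  Each elementary step (dt = 1/N) picks a uniform
// node; only nodes in W = S  U  {nodes with a follower in S} can change S,
// so the chain jumps geometrically between W-hits (exact).  A chosen node
// in S retweets the focal meme (probability 1 - mu): one event, followers'
// screens set to focal.  Any other tweet overwrites followers' screens.
// Avalanche seeded by one forced focal tweet from a uniform node at t = 0;
// terminates when S is empty.  Profile = binned focal-tweet counts.
// [[Rcpp::export]]
List meme_ensemble_cpp(IntegerVector offs, IntegerVector targ,
                       IntegerVector ioffs, IntegerVector itarg, int N,
                       double mu, int nA, double tcap, double bin) {
  std::vector<char> inS(N, 0);
  std::vector<int> cnt(N, 0);          // followers currently in S
  std::vector<int> stamp(N, -1);       // avalanche stamp for inS/cnt validity
  std::vector<int> wpos(N, -1);        // position in W, valid when wstamp == a
  std::vector<int> wstamp(N, -1);
  std::vector<int> W;
  NumericVector durations(nA), sizes(nA);
  LogicalVector term(nA);
  List profiles(nA);

  for (int a = 0; a < nA; ++a) {
    W.clear();
    int sizeS = 0;

    // local helpers via lambdas
    auto valid = [&](int i) { if (stamp[i] != a) { stamp[i] = a; inS[i] = 0; cnt[i] = 0; } };
    auto inW = [&](int i) { return wstamp[i] == a && wpos[i] >= 0; };
    auto addW = [&](int i) {
      if (!inW(i)) { wstamp[i] = a; wpos[i] = (int) W.size(); W.push_back(i); }
    };
    auto delW = [&](int i) {
      if (inW(i)) {
        int p = wpos[i], last = W.back();
        W[p] = last; wpos[last] = p; W.pop_back(); wpos[i] = -1;
      }
    };
    auto joinS = [&](int f) {
      valid(f);
      if (inS[f]) return;
      inS[f] = 1; ++sizeS; addW(f);
      for (int e = ioffs[f]; e < ioffs[f + 1]; ++e) {
        int u = itarg[e];
        valid(u);
        cnt[u] += 1; addW(u);
      }
    };
    auto leaveS = [&](int f) {
      valid(f);
      if (!inS[f]) return;
      inS[f] = 0; --sizeS;
      for (int e = ioffs[f]; e < ioffs[f + 1]; ++e) {
        int u = itarg[e];
        valid(u);
        cnt[u] -= 1;
        if (cnt[u] == 0 && !inS[u]) delW(u);
      }
      if (cnt[f] == 0) delW(f);
    };

    std::vector<int> prof;
    int seed = (int) (unif_rand() * N);
    if (seed >= N) seed = N - 1;
    double t = 0.0, last_t = 0.0;
    long long size = 1;
    prof.push_back(1);                       // seeding tweet at t = 0
    // the forced seeding tweet reaches the followers' screens; the focal
    // avalanche tracks those screens (S), so a seed without followers
    // terminates immediately with size 1
    for (int e = offs[seed]; e < offs[seed + 1]; ++e) joinS(targ[e]);
    bool terminated = false;

    while (sizeS > 0) {
      double p = (double) W.size() / (double) N;
      double g;                               // steps until a W member is hit
      if (p >= 1.0) g = 1.0;
      else g = std::floor(std::log(unif_rand()) / std::log1p(-p)) + 1.0;
      t += g / (double) N;
      if (t > tcap) break;
      int chosen = W[(int) (unif_rand() * W.size()) % (int) W.size()];
      bool innovate = unif_rand() < mu;
      valid(chosen);
      if (inS[chosen] && !innovate) {
        // focal retweet: one event, followers' screens set to focal
        ++size;
        last_t = t;
        int b = (int) (t / bin);
        if ((int) prof.size() <= b) prof.resize(b + 1, 0);
        prof[b] += 1;
        for (int e = offs[chosen]; e < offs[chosen + 1]; ++e) joinS(targ[e]);
      } else {
        // a non-focal tweet overwrites followers' screens
        if (innovate) leaveS(chosen);
        for (int e = offs[chosen]; e < offs[chosen + 1]; ++e) leaveS(targ[e]);
      }
    }
    terminated = (sizeS == 0);
    durations[a] = terminated ? last_t : tcap;
    sizes[a] = (double) size;
    term[a] = terminated;
    int nb = (int) (last_t / bin) + 1;
    if ((int) prof.size() > nb) prof.resize(nb);
    profiles[a] = IntegerVector(prof.begin(), prof.end());
  }
  return List::create(_["durations"] = durations, _["sizes"] = sizes,
                      _["profiles"] = profiles, _["terminated"] = term);
}

// ---------------------------------------------------------------------------
// Zero-padded per-position sums and sums of squares over selected profiles;
// backbone of the shape/variance estimators for large ensembles.
// [[Rcpp::export]]
List profile_moments_cpp(List profiles, IntegerVector idx, int nb) {
  NumericVector s(nb), s2(nb);
  for (int ii = 0; ii < idx.size(); ++ii) {
    IntegerVector p = profiles[idx[ii] - 1];
    int L = p.size();
    for (int j = 0; j < nb; ++j) {
      double v = (j < L) ? (double) p[j] : 0.0;
      s[j] += v;
      s2[j] += v * v;
    }
  }
  return List::create(_["sum"] = s, _["sumsq"] = s2, _["n"] = idx.size());
}
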