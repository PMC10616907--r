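#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

// Joint-count machinery for the plug-in transfer entropy on binary spike
// series. All spike times are 0-based bin indices; the valid time range for
// delay d is t in [max(1, d), T-1] so that i_t, i_{t-1} and j_{t-d} all
// exist without padding.

static inline int count_in_range(const std::vector<int>& v, int lo, int hi) {
    if (hi < lo) return 0;
    return (int)(std::upper_bound(v.begin(), v.end(), hi) -
                 std::lower_bound(v.begin(), v.end(), lo));
}

// 8-cell joint counts (a = i_t, b = i_{t-1}, c = j_{t-d}; cell index
// a*4 + b*2 + c) for every delay d = 0..D of one ordered pair j -> i.
// Joint counts are gathered cross-correlogram style: every (target spike,
// nearby source spike) pair increments one delay cell, so the cost scales
// with the number of spike pairs inside the delay window rather than with
// |spikes| x delays.
static void pair_counts(const std::vector<int>& ti, const std::vector<int>& tj,
                        int T, int D,
                        std::vector<double>& counts /* (D+1) x 8 */) {
    std::fill(counts.begin(), counts.end(), 0.0);
    std::vector<int> Cij(D + 1, 0), Cbj(D + 1, 0), Cibj(D + 1, 0);
    // consecutive-spike times of the target (i_t = 1 and i_{t-1} = 1)
    std::vector<int> ti_pair;
    for (size_t k = 1; k < ti.size(); ++k)
        if (ti[k - 1] == ti[k] - 1) ti_pair.push_back(ti[k]);
    // Cij / Cibj: t in ti with t >= 1, source spike s in [t-D, t], d = t-s.
    {
        size_t lo = 0;
        for (size_t k = 0; k < ti.size(); ++k) {
            const int t = ti[k];
            if (t < 1 || t > T - 1) continue;
            while (lo < tj.size() && tj[lo] < t - D) ++lo;
            const bool prev = (k > 0 && ti[k - 1] == t - 1);
            for (size_t q = lo; q < tj.size() && tj[q] <= t; ++q) {
                const int d = t - tj[q];
                ++Cij[d];
                if (prev) ++Cibj[d];
            }
        }
    }
    // Cbj: s' in ti with s' <= T-2 (i_{t-1} = 1 at t = s'+1), source spike
    // s in [s'+1-D, s'+1], d = s'+1-s.
    {
        size_t lo = 0;
        for (size_t k = 0; k < ti.size(); ++k) {
            const int t = ti[k] + 1;   // the bin whose past is this spike
            if (t > T - 1 + 1) break;
            if (t - 1 > T - 2) continue;
            while (lo < tj.size() && tj[lo] < t - D) ++lo;
            for (size_t q = lo; q < tj.size() && tj[q] <= t; ++q)
                ++Cbj[t - tj[q]];
        }
    }
    for (int d = 0; d <= D; ++d) {
        const int t0 = std::max(1, d);
        const int N = T - t0;
        if (N <= 0) continue;
        const int Ci  = count_in_range(ti, t0, T - 1);
        const int Cb  = count_in_range(ti, t0 - 1, T - 2);
        const int Cj  = count_in_range(tj, t0 - d, T - 1 - d);
        const int Cib = count_in_range(ti_pair, t0, T - 1);
        // joint counters above included every d <= t; delays below t0 for
        // this d never occur (s >= 0 implies d <= t), so no correction is
        // needed beyond the t >= 1 guard already applied
        double* n = &counts[(size_t)d * 8];
        n[7] = Cibj[d];                              // a=1 b=1 c=1
        n[6] = Cib - Cibj[d];                        // 1 1 0
        n[5] = Cij[d] - Cibj[d];                     // 1 0 1
        n[4] = Ci - Cib - Cij[d] + Cibj[d];          // 1 0 0
        n[3] = Cbj[d] - Cibj[d];                     // 0 1 1
        n[2] = Cb - Cib - Cbj[d] + Cibj[d];          // 0 1 0
        n[1] = Cj - Cij[d] - Cbj[d] + Cibj[d];       // 0 0 1
        n[0] = N - n[1] - n[2] - n[3] - n[4] - n[5] - n[6] - n[7];
    }
}

// Plug-in TE and SLTE (natural log) from one delay's 8-cell count table.
static void te_slte_from_cells(const double* n, double N, double& te, double& slte) {
    te = 0.0; slte = 0.0;
    if (N <= 0) return;
    double bc[4], ab[4], b[2];
    for (int k = 0; k < 4; ++k) bc[k] = n[k] + n[4 + k];           // sum over a
    for (int k = 0; k < 4; ++k) ab[k] = n[2 * k] + n[2 * k + 1];   // sum over c
    b[0] = bc[0] + bc[1]; b[1] = bc[2] + bc[3];
    for (int a = 0; a <= 1; ++a) for (int bb = 0; bb <= 1; ++bb) for (int c = 0; c <= 1; ++c) {
        const double nk = n[a * 4 + bb * 2 + c];
        if (nk <= 0) continue;
        const double num = nk / bc[bb * 2 + c];
        const double den = ab[a * 2 + bb] / b[bb];
        const double term = (nk / N) * std::log(num / den);
        te += term;
        slte += (a == c ? term : -term);
    }
    if (te < 0 && te > -1e-12) te = 0.0;  // guard against roundoff only
}

// [[Rcpp::export]]
NumericMatrix pair_counts_cpp(IntegerVector ti, IntegerVector tj, int T, int D) {
    std::vector<int> vi(ti.begin(), ti.end()), vj(tj.begin(), tj.end());
    std::sort(vi.begin(), vi.end()); std::sort(vj.begin(), vj.end());
    std::vector<double> counts((size_t)(D + 1) * 8);
    pair_counts(vi, vj, T, D, counts);
    NumericMatrix out(D + 1, 8);
    for (int d = 0; d <= D; ++d)
        for (int k = 0; k < 8; ++k) out(d, k) = counts[(size_t)d * 8 + k];
    return out;
}

// [[Rcpp::export]]
List pair_profile_cpp(IntegerVector ti, IntegerVector tj, int T, int D) {
    std::vector<int> vi(ti.begin(), ti.end()), vj(tj.begin(), tj.end());
    std::sort(vi.begin(), vi.end()); std::sort(vj.begin(), vj.end());
    std::vector<double> counts((size_t)(D + 1) * 8);
    pair_counts(vi, vj, T, D, counts);
    NumericVector te(D + 1), slte(D + 1);
    for (int d = 0; d <= D; ++d) {
        double tev, sltev;
        const int N = T - std::max(1, d);
        te_slte_from_cells(&counts[(size_t)d * 8], (double)N, tev, sltev);
        te[d] = tev; slte[d] = sltev;
    }
    return List::create(_["te"] = te, _["slte"] = slte);
}

// Delay profiles for all ordered pairs (source j from `src`, target i from
// `tgt`, j != i by index). src and tgt must describe the same neurons over
// the same T; src may be a jitter-shuffled copy. Returns te and slte arrays
// of dim (n, n, D+1) indexed [source, target, d+1].
// [[Rcpp::export]]
List profiles_all_pairs_cpp(List src, List tgt, int T, int D) {
    const int n = src.size();
    if (tgt.size() != n) stop("source and target rasters disagree on neuron count");
    std::vector<std::vector<int> > S(n), Tg(n);
    for (int k = 0; k < n; ++k) {
        IntegerVector a = src[k], b = tgt[k];
        S[k].assign(a.begin(), a.end()); std::sort(S[k].begin(), S[k].end());
        Tg[k].assign(b.begin(), b.end()); std::sort(Tg[k].begin(), Tg[k].end());
    }
    NumericVector te(Dimension(n, n, D + 1)), slte(Dimension(n, n, D + 1));
    std::fill(te.begin(), te.end(), NA_REAL);
    std::fill(slte.begin(), slte.end(), NA_REAL);
    std::vector<double> counts((size_t)(D + 1) * 8);
    const size_t nn = (size_t)n * n;
    for (int j = 0; j < n; ++j) {
        for (int i = 0; i < n; ++i) {
            if (i == j) continue;
            pair_counts(Tg[i], S[j], T, D, counts);
            for (int d = 0; d <= D; ++d) {
                double tev, sltev;
                const int N = T - std::max(1, d);
                te_slte_from_cells(&counts[(size_t)d * 8], (double)N, tev, sltev);
                te[(size_t)d * nn + (size_t)i * n + j] = tev;
                slte[(size_t)d * nn + (size_t)i * n + j] = sltev;
            }
        }
        Rcpp::checkUserInterrupt();
    }
    return List::create(_["te"] = te, _["slte"] = slte);
}

// Jitter shuffle of one spike series: each spike is relocated, in temporal
// order, uniformly among bins within +/- window that were spike-free in the
// ORIGINAL series and are not already taken by a previously relocated spike.
// A spike with no admissible destination stays put (counted as fallback).
// Uses R's RNG.
// [[Rcpp::export]]
List shuffle_times_cpp(IntegerVector ts, int T, int window) {
    std::vector<int> orig(ts.begin(), ts.end());
    std::sort(orig.begin(), orig.end());
    std::unordered_set<int> occ(orig.begin(), orig.end());
    std::unordered_set<int> taken;
    std::vector<int> out; out.reserve(orig.size());
    int fallback = 0;
    std::vector<int> cand; cand.reserve(2 * window + 1);
    for (int t : orig) {
        cand.clear();
        for (int b = t - window; b <= t + window; ++b) {
            if (b < 0 || b >= T) continue;
            if (occ.count(b) || taken.count(b)) continue;
            cand.push_back(b);
        }
        int dest;
        if (cand.empty()) { dest = t; ++fallback; }
        else {
            int idx = (int)std::floor(unif_rand() * cand.size());
            if (idx >= (int)cand.size()) idx = (int)cand.size() - 1;
            dest = cand[idx];
            taken.insert(dest);
        }
        out.push_back(dest);
    }
    std::sort(out.begin(), out.end());
    return List::create(_["times"] = wrap(out), _["fallback"] = fallback);
}

// Discrete-time Bernoulli-GLM spiking dynamics: at each 1 ms bin,
// P(neuron i spikes) = logistic(logit_base_i + summed lagged synaptic
// input), with an absolute refractory period. Synaptic input from a spike
// of j at t arrives at t + delay_ji with signed weight w. Uses R's RNG.
// [[Rcpp::export]]
List simulate_spikes_cpp(int n, int T, NumericVector logit_base,
                         IntegerVector e_src, IntegerVector e_tgt,
                         IntegerVector e_delay, NumericVector e_w,
                         int refractory) {
    const int m = e_src.size();
    int maxd = 1;
    for (int e = 0; e < m; ++e) if (e_delay[e] > maxd) maxd = e_delay[e];
    const int W = maxd + 1;
    std::vector<std::vector<int> > out_e(n);
    for (int e = 0; e < m; ++e) out_e[e_src[e]].push_back(e);
    std::vector<double> buf((size_t)n * W, 0.0);
    std::vector<int> last(n, -1000000);
    std::vector<std::vector<int> > spikes(n);
    for (int t = 0; t < T; ++t) {
        const int slot = t % W;
        for (int i = 0; i < n; ++i) {
            const double x = logit_base[i] + buf[(size_t)i * W + slot];
            const double p = 1.0 / (1.0 + std::exp(-x));
            const bool draw = unif_rand() < p;
            if (draw && t - last[i] > refractory) {
                spikes[i].push_back(t);
                last[i] = t;
                for (int e : out_e[i]) {
                    const int ta = t + e_delay[e];
                    if (ta < T) buf[(size_t)e_tgt[e] * W + ta % W] += e_w[e];
                }
            }
        }
        for (int i = 0; i < n; ++i) buf[(size_t)i * W + slot] = 0.0;
        if (t % 100000 == 0) Rcpp::checkUserInterrupt();
    }
    List res(n);
    for (int i = 0; i < n; ++i) res[i] = wrap(spikes[i]);
    return res;
}
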