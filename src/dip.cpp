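#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Hartigan dip statistic: dip(F_n) = min over unimodal CDFs G of sup_x |F_n(x) - G(x)|.
//
// Collapse the sorted sample to unique values u_1..u_m with ECDF heights F_j; at
// each knot the ECDF contributes a lower anchor B_j = F_j (value from the right)
// and an upper anchor A_j = F_{j-1} (value from the left).  A unimodal G is convex
// left of its mode and concave right of it, may carry an atom only at the mode,
// and must pass within +/- d of the anchor band at every knot; at the mode knot
// the left limit is tested against A_j and the value against B_j.
//
// Two ingredients:
//  (1) hull profiles give the one-sided requirements:  for the mode at knot j the
//      convex side needs d >= L*[j] = max_{i<j} (B_i - gcm_i)/2 over the greatest
//      convex minorant (lower hull) of the upper anchors on knots 1..j; mirrored
//      R*[j] for the concave side.  dip0 = min_j max(L*[j], R*[j]) is an exact
//      lower bound.
//  (2) the two half-fits must join monotonically at the mode (left limit <= value).
//      Whether they can is decided exactly by propagating, knot by knot, the convex
//      region of reachable (value, arrival-slope) states of a chain inside the
//      bands; the region's lower/upper boundaries are piecewise linear in the
//      arrival slope.  The signed joining margin is continuous and decreasing in d,
//      so the exact dip is the root of the margin, found by bracketed secant
//      (Illinois) iteration starting from dip0.
//
// Correctness is checked in the test suite against an independent linear-
// programming solution of the definitional minimisation.

namespace {

struct Knots {
    std::vector<double> u, A, B;    // forward
    std::vector<double> ur, Ar, Br; // mirrored (negated/reversed, anchors swapped)
    int m;
};

static void build_knots(const double* xs, int n, Knots& K) {
    K.u.clear(); K.A.clear(); K.B.clear();
    int i = 0;
    while (i < n) {
        int j = i;
        while (j < n && xs[j] == xs[i]) ++j;
        K.u.push_back(xs[i]);
        K.A.push_back((double)i / n);
        K.B.push_back((double)j / n);
        i = j;
    }
    K.m = (int)K.u.size();
    K.ur.resize(K.m); K.Ar.resize(K.m); K.Br.resize(K.m);
    for (int j = 0; j < K.m; ++j) {
        K.ur[j] = -K.u[K.m - 1 - j];
        K.Ar[j] = 1.0 - K.B[K.m - 1 - j];
        K.Br[j] = 1.0 - K.A[K.m - 1 - j];
    }
}

// hull profile: out[j] = max_{i<j} (B_i - gcmfit_i) over the lower convex hull of
// (u_i, A_i) restricted to points 0..j (own knot's lower anchor exempt; unhalved)
static void left_profile(const std::vector<double>& u,
                         const std::vector<double>& A,
                         const std::vector<double>& B,
                         std::vector<double>& out) {
    const int m = (int)u.size();
    static thread_local std::vector<int> h;
    static thread_local std::vector<double> hmax;
    h.clear(); hmax.clear();
    out.resize(m);
    for (int j = 0; j < m; ++j) {
        while (h.size() >= 2) {
            int p1 = h[h.size() - 2], p2 = h[h.size() - 1];
            double lhs = (A[p2] - A[p1]) * (u[j] - u[p2]);
            double rhs = (A[j] - A[p2]) * (u[p2] - u[p1]);
            if (lhs >= rhs) { h.pop_back(); hmax.pop_back(); } else break;
        }
        double base = 0.0;
        if (!h.empty()) {
            int p = h.back();
            base = hmax.back();
            double dx = u[j] - u[p];
            // long spans are scanned with a stride: the profile then remains a
            // valid lower bound, which is all its consumers require (the exact
            // decisions are always made by the feasibility sweep)
            int span = j - p;
            int stride = (span <= 64) ? 1 : span / 64;
            for (int i = p; i < j; i += stride) {
                double fit = A[p] + (A[j] - A[p]) * (u[i] - u[p]) / dx;
                double dev = B[i] - fit;
                if (dev > base) base = dev;
            }
            if (stride > 1) {
                double fit = A[p] + (A[j] - A[p]) * (u[j - 1] - u[p]) / dx;
                double dev = B[j - 1] - fit;
                if (dev > base) base = dev;
            }
        }
        h.push_back(j);
        hmax.push_back(base);
        out[j] = base;
    }
}

// ---- exact chain propagation ----------------------------------------------
// State: slope grid ss with lower/upper reachable values lo (convex in s) and
// hi (concave in s).  One workspace per thread; all buffers reused.

struct Sweep {
    std::vector<double> ss, lo, hi;       // current state
    std::vector<double> Ms, Mv, Xv;       // running min of lo / running max of hi
    std::vector<double> gs, ga, gb;       // refined grid with clipped bounds
    std::vector<double> ts, tlo, thi;     // truncated next state
};

// advance one knot; gap > 0, band [L, U]; amin_out = minimal arrival value at the
// next knot before its band applies.  Returns false when the chain dies.
static bool sweep_step(Sweep& W, double gap, double L, double U, double& amin_out) {
    const size_t n = W.ss.size();
    // running min of lo (convex -> min at a breakpoint), running max of hi
    size_t kmin = 0, kmax = 0;
    for (size_t i = 1; i < n; ++i) {
        if (W.lo[i] < W.lo[kmin]) kmin = i;
        if (W.hi[i] > W.hi[kmax]) kmax = i;
    }
    W.Ms.clear(); W.Mv.clear(); W.Xv.clear();
    size_t kboth = std::max(kmin, kmax);
    for (size_t i = 0; i <= kboth; ++i) {
        W.Ms.push_back(W.ss[i]);
        W.Mv.push_back(i <= kmin ? W.lo[i] : W.lo[kmin]);
        W.Xv.push_back(i <= kmax ? W.hi[i] : W.hi[kmax]);
    }
    if (kboth + 1 < n) {
        W.Ms.push_back(W.ss[n - 1]);
        W.Mv.push_back(W.lo[kmin]);
        W.Xv.push_back(W.hi[kmax]);
    }
    // minimal arrival value: min over s of M(s) + s*gap
    double amin = R_PosInf;
    for (size_t i = 0; i < W.Ms.size(); ++i)
        amin = std::min(amin, W.Mv[i] + W.Ms[i] * gap);
    amin_out = amin;
    // extend domain so the lower bound eventually exceeds any upper bound (<= 2)
    double s_end = std::max(W.Ms.back(), (2.0 - W.Mv.back()) / gap) + 1.0;
    W.Ms.push_back(s_end); W.Mv.push_back(W.Mv.back()); W.Xv.push_back(W.Xv.back());
    // refined grid: a(s) = max(L, M(s)+s*gap), b(s) = min(U, MX(s)+s*gap)
    W.gs.clear(); W.ga.clear(); W.gb.clear();
    const size_t q = W.Ms.size();
    double pa = 0, pb = 0, ps = 0;
    for (size_t i = 0; i < q; ++i) {
        double s = W.Ms[i];
        double araw = W.Mv[i] + s * gap;
        double braw = W.Xv[i] + s * gap;
        if (i > 0) {
            // kink insertion where araw crosses L or braw crosses U inside segment
            double s0 = ps, a0 = pa, b0 = pb;
            double c1 = R_PosInf, c2 = R_PosInf;
            if ((a0 - L) * (araw - L) < 0) c1 = s0 + (L - a0) / (araw - a0) * (s - s0);
            if ((b0 - U) * (braw - U) < 0) c2 = s0 + (U - b0) / (braw - b0) * (s - s0);
            if (c2 < c1) std::swap(c1, c2);
            for (double c : {c1, c2}) {
                if (R_finite(c) && c > s0 && c < s) {
                    double t = (c - s0) / (s - s0);
                    double av = a0 + t * (araw - a0), bv = b0 + t * (braw - b0);
                    W.gs.push_back(c);
                    W.ga.push_back(std::max(L, av));
                    W.gb.push_back(std::min(U, bv));
                }
            }
        }
        W.gs.push_back(s);
        W.ga.push_back(std::max(L, araw));
        W.gb.push_back(std::min(U, braw));
        ps = s; pa = araw; pb = braw;
    }
    // feasible range { s : a(s) <= b(s) }, refining the boundary crossings
    const size_t g = W.gs.size();
    int first = -1, last = -1;
    for (size_t i = 0; i < g; ++i)
        if (W.ga[i] <= W.gb[i]) { if (first < 0) first = (int)i; last = (int)i; }
    if (first < 0) return false;
    W.ts.clear(); W.tlo.clear(); W.thi.clear();
    if (first > 0) {
        double f0 = W.ga[first - 1] - W.gb[first - 1];
        double f1 = W.ga[first] - W.gb[first];
        if (f0 > 0.0 && f0 > f1) {
            double t = f0 / (f0 - f1);
            double sx = W.gs[first - 1] + t * (W.gs[first] - W.gs[first - 1]);
            if (sx < W.gs[first]) {
                double av = W.ga[first - 1] + t * (W.ga[first] - W.ga[first - 1]);
                W.ts.push_back(sx); W.tlo.push_back(av); W.thi.push_back(av);
            }
        }
    }
    for (int i = first; i <= last; ++i) {
        W.ts.push_back(W.gs[i]); W.tlo.push_back(W.ga[i]); W.thi.push_back(W.gb[i]);
    }
    if (last + 1 < (int)g) {
        double f0 = W.ga[last] - W.gb[last];
        double f1 = W.ga[last + 1] - W.gb[last + 1];
        if (f1 > 0.0 && f1 > f0) {
            double t = (0.0 - f0) / (f1 - f0);
            double sx = W.gs[last] + t * (W.gs[last + 1] - W.gs[last]);
            if (sx > W.gs[last]) {
                double av = W.ga[last] + t * (W.ga[last + 1] - W.ga[last]);
                W.ts.push_back(sx); W.tlo.push_back(av); W.thi.push_back(av);
            }
        }
    }
    // prune collinear interior points (both curves), write back into state
    const size_t tn = W.ts.size();
    W.ss.clear(); W.lo.clear(); W.hi.clear();
    W.ss.push_back(W.ts[0]); W.lo.push_back(W.tlo[0]); W.hi.push_back(W.thi[0]);
    for (size_t i = 1; i + 1 < tn; ++i) {
        double s0 = W.ss.back(), s1 = W.ts[i], s2 = W.ts[i + 1];
        double w = (s1 - s0) / (s2 - s0);
        double plo = W.lo.back() + w * (W.tlo[i + 1] - W.lo.back());
        double phi = W.hi.back() + w * (W.thi[i + 1] - W.hi.back());
        double tol = 1e-14 * (1.0 + std::abs(W.tlo[i]) + std::abs(W.thi[i]));
        if (std::abs(plo - W.tlo[i]) <= tol && std::abs(phi - W.thi[i]) <= tol) continue;
        W.ss.push_back(s1); W.lo.push_back(W.tlo[i]); W.hi.push_back(W.thi[i]);
    }
    if (tn > 1) {
        W.ss.push_back(W.ts[tn - 1]); W.lo.push_back(W.tlo[tn - 1]); W.hi.push_back(W.thi[tn - 1]);
    }
    return true;
}

// one-sided sweep to a single target knot: returns the chain's minimal arrival
// value at `jstop` (before its band) in amin_out, or false when the chain dies
static bool chain_sweep_until(const std::vector<double>& u,
                              const std::vector<double>& A,
                              const std::vector<double>& B,
                              double d, int jstop, Sweep& W, double& amin_out) {
    amin_out = 0.0;
    if (jstop == 0) return true;  // no chain needed for the first knot
    double L0 = std::max(B[0] - d, 0.0), U0 = std::min(A[0] + d, 1.0);
    if (L0 > U0) return false;
    W.ss.assign(1, 0.0); W.lo.assign(1, L0); W.hi.assign(1, U0);
    for (int j = 1; j <= jstop; ++j) {
        double a;
        bool alive = sweep_step(W, u[j] - u[j - 1],
                                std::max(B[j] - d, 0.0), std::min(A[j] + d, 1.0), a);
        if (j == jstop) { amin_out = a; return true; }
        if (!alive) return false;
    }
    return false;  // unreachable
}

// one-sided sweep at level d: amin[j] = minimal arrival value of a chain over
// knots 0..j-1 at knot j (before knot j's own band), ok[j] = chain exists.
static void chain_sweep(const std::vector<double>& u,
                        const std::vector<double>& A,
                        const std::vector<double>& B,
                        double d, Sweep& W,
                        std::vector<double>& amin, std::vector<char>& ok) {
    const int m = (int)u.size();
    amin.assign(m, 0.0);
    ok.assign(m, 0);
    ok[0] = 1;  // mode at the first knot has no left chain
    double L0 = std::max(B[0] - d, 0.0), U0 = std::min(A[0] + d, 1.0);
    if (L0 > U0) return;
    W.ss.assign(1, 0.0); W.lo.assign(1, L0); W.hi.assign(1, U0);
    for (int j = 1; j < m; ++j) {
        double a;
        bool alive = sweep_step(W, u[j] - u[j - 1],
                                std::max(B[j] - d, 0.0), std::min(A[j] + d, 1.0), a);
        amin[j] = a;
        ok[j] = 1;
        if (!alive) break;  // chains through knot j are dead; modes > j unreachable
    }
}

// signed joining margin at level d: <= 0 iff a unimodal CDF within d exists.
// +Inf when no mode admits both chains.
static double dip_margin(const Knots& K, double d, Sweep& W,
                         std::vector<double>& aL, std::vector<char>& okL,
                         std::vector<double>& aR, std::vector<char>& okR) {
    const int m = K.m;
    chain_sweep(K.u, K.A, K.B, d, W, aL, okL);
    chain_sweep(K.ur, K.Ar, K.Br, d, W, aR, okR);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
        int jr = m - 1 - j;
        if (!okL[j] || !okR[jr]) continue;
        double atopL = std::min(K.A[j] + d, 1.0);
        double atopR = std::min(K.Ar[jr] + d, 1.0);
        double lo_a = std::max(aL[j], std::max(K.A[j] - d, 0.0));
        double hi_g = 1.0 - std::max(aR[jr], std::max(K.Ar[jr] - d, 0.0));
        double v = std::max(lo_a - hi_g,
                            std::max(aL[j] - atopL, aR[jr] - atopR));
        if (v < best) best = v;
    }
    return best;
}

struct DipWork {
    Knots K;
    Sweep W;
    std::vector<double> ldx, rdx, aL, aR;
    std::vector<char> okL, okR;
};

static double dip0_bound(DipWork& D, int* jstar = NULL) {
    left_profile(D.K.u, D.K.A, D.K.B, D.ldx);
    left_profile(D.K.ur, D.K.Ar, D.K.Br, D.rdx);
    const int m = D.K.m;
    double best = R_PosInf;
    int jb = 0;
    for (int j = 0; j < m; ++j) {
        double v = std::max(D.ldx[j], D.rdx[m - 1 - j]);
        if (v < best) { best = v; jb = j; }
    }
    if (jstar) *jstar = jb;
    return best / 2.0;
}

// can the two half-fits for a mode at knot j be joined at level d?
static bool mode_joins(const Knots& K, double d, int j, Sweep& W) {
    const int m = K.m, jr = m - 1 - j;
    double aL, aR;
    if (!chain_sweep_until(K.u, K.A, K.B, d, j, W, aL)) return false;
    if (!chain_sweep_until(K.ur, K.Ar, K.Br, d, jr, W, aR)) return false;
    double atopL = std::min(K.A[j] + d, 1.0);
    double atopR = std::min(K.Ar[jr] + d, 1.0);
    if (aL > atopL || aR > atopR) return false;
    double lo_a = std::max(aL, std::max(K.A[j] - d, 0.0));
    double hi_g = 1.0 - std::max(aR, std::max(K.Ar[jr] - d, 0.0));
    return lo_a <= hi_g;
}

static double dip_from_knots(DipWork& D, double tol) {
    if (D.K.m == 1) return 0.0;
    int jstar = 0;
    double dip0 = dip0_bound(D, &jstar);
    // fast certificate: the most promising mode usually joins at dip0
    if (mode_joins(D.K, dip0 + 1e-13, jstar, D.W)) return dip0;
    double f0 = dip_margin(D.K, dip0 + 1e-13, D.W, D.aL, D.okL, D.aR, D.okR);
    if (f0 <= 0.0) return dip0;
    // bracketed root search on the margin (Illinois variant)
    double lo = dip0, hi = 0.25, fhi;
    fhi = dip_margin(D.K, hi, D.W, D.aL, D.okL, D.aR, D.okR);
    if (fhi > 0.0) return hi;  // cannot happen (dip <= 1/4); defensive
    double flo = f0;
    for (int it = 0; it < 100 && hi - lo > tol; ++it) {
        double mid;
        if (R_finite(flo) && flo > 0.0 && fhi < 0.0 && (it % 3) != 2) {
            mid = lo + flo / (flo - fhi) * (hi - lo);      // secant
            double span = hi - lo;
            if (mid <= lo + 1e-18 || mid >= hi - 1e-18) mid = lo + 0.5 * span;
        } else {
            mid = 0.5 * (lo + hi);                         // bisection fallback
        }
        double fm = dip_margin(D.K, mid, D.W, D.aL, D.okL, D.aR, D.okR);
        if (fm <= 0.0) { hi = mid; fhi = fm; } else { lo = mid; flo = fm; }
    }
    return hi;
}

static double dip_sorted(const double* xs, int n, DipWork& D, double tol = 1e-15) {
    if (n <= 1) return 0.0;
    build_knots(xs, n, D.K);
    return dip_from_knots(D, tol);
}

// exact decision dip > t without computing the dip: true iff no unimodal CDF
// within sup-distance t exists
static bool dip_exceeds(const double* xs, int n, double t, DipWork& D) {
    if (n <= 1) return 0.0 > t;
    build_knots(xs, n, D.K);
    if (D.K.m == 1) return 0.0 > t;
    int jstar = 0;
    double dip0 = dip0_bound(D, &jstar);
    if (dip0 > t) return true;
    if (mode_joins(D.K, t, jstar, D.W)) return false;
    double f = dip_margin(D.K, t, D.W, D.aL, D.okL, D.aR, D.okR);
    return f > 0.0;
}

} // namespace

// [[Rcpp::export(name = ".dip_sorted_cpp")]]
double dip_sorted_cpp(NumericVector x) {
    DipWork D;
    return dip_sorted(x.begin(), x.size(), D);
}

// dip of each row of a symmetric distance matrix, excluding the diagonal entry
// [[Rcpp::export(name = ".dip_rows_cpp")]]
NumericVector dip_rows_cpp(NumericMatrix d) {
    const int n = d.nrow();
    NumericVector out(n);
    DipWork D;
    std::vector<double> buf(n - 1);
    for (int i = 0; i < n; ++i) {
        int k = 0;
        for (int j = 0; j < n; ++j) if (j != i) buf[k++] = d(j, i);
        std::sort(buf.begin(), buf.end());
        out[i] = dip_sorted(buf.data(), n - 1, D);
    }
    return out;
}

// per-row decision dip > t on a symmetric distance matrix (diagonal excluded)
// [[Rcpp::export(name = ".dip_rows_exceed_cpp")]]
LogicalVector dip_rows_exceed_cpp(NumericMatrix d, double t) {
    const int n = d.nrow();
    LogicalVector out(n);
    DipWork D;
    std::vector<double> buf(n - 1);
    for (int i = 0; i < n; ++i) {
        int k = 0;
        for (int j = 0; j < n; ++j) if (j != i) buf[k++] = d(j, i);
        std::sort(buf.begin(), buf.end());
        out[i] = dip_exceeds(buf.data(), n - 1, t, D);
    }
    return out;
}

// dip statistics of `reps` uniform(0,1) samples of size n, drawn from R's RNG
// (so set.seed() controls them); used for the Monte-Carlo null table
// [[Rcpp::export(name = ".dip_unif_null_cpp")]]
NumericVector dip_unif_null_cpp(int n, int reps, double tol) {
    NumericVector out(reps);
    DipWork D;
    std::vector<double> buf(n);
    GetRNGstate();
    for (int r = 0; r < reps; ++r) {
        for (int i = 0; i < n; ++i) buf[i] = unif_rand();
        std::sort(buf.begin(), buf.end());
        out[r] = dip_sorted(buf.data(), n, D, tol);
    }
    PutRNGstate();
    return out;
}

// (k+1)-th largest dip among `reps` uniform(0,1) null samples of size n --
// the critical value for Monte-Carlo dip tests at level alpha = k/reps.
// Samples are drawn from R's RNG exactly like .dip_unif_null_cpp.  Exact dips
// are computed only where needed: samples are ranked by the cheap dip lower
// bound; the running threshold t (the (k+1)-th largest exact dip found so far)
// only grows, so any sample certified dip <= t by a single feasibility test
// can never enter the top k+1.
// [[Rcpp::export(name = ".dip_null_threshold_cpp")]]
double dip_null_threshold_cpp(int n, int reps, int k, double tol) {
    if (k + 1 > reps) k = reps - 1;
    std::vector<std::vector<double>> samples(reps);
    GetRNGstate();
    for (int r = 0; r < reps; ++r) {
        samples[r].resize(n);
        for (int i = 0; i < n; ++i) samples[r][i] = unif_rand();
        std::sort(samples[r].begin(), samples[r].end());
    }
    PutRNGstate();
    DipWork D;
    std::vector<double> d0(reps);
    std::vector<int> ord(reps);
    for (int r = 0; r < reps; ++r) {
        build_knots(samples[r].data(), n, D.K);
        d0[r] = dip0_bound(D);
        ord[r] = r;
    }
    std::sort(ord.begin(), ord.end(), [&](int a, int b) { return d0[a] > d0[b]; });
    std::vector<double> top;  // exact dips computed so far, kept sorted descending
    int seed_count = std::min(reps, k + 4);
    for (int i = 0; i < seed_count; ++i) {
        build_knots(samples[ord[i]].data(), n, D.K);
        top.push_back(dip_from_knots(D, tol));
    }
    std::sort(top.begin(), top.end(), std::greater<double>());
    double t = top[k];
    for (int i = seed_count; i < reps; ++i) {
        int r = ord[i];
        bool above;
        build_knots(samples[r].data(), n, D.K);
        if (d0[r] > t) {
            above = true;
        } else {
            if (D.K.m == 1) { above = false; }
            else {
                double dip0 = dip0_bound(D);
                above = (dip0 > t) ||
                        (dip_margin(D.K, t, D.W, D.aL, D.okL, D.aR, D.okR) > 0.0);
            }
        }
        if (above) {
            top.push_back(dip_from_knots(D, tol));
            std::sort(top.begin(), top.end(), std::greater<double>());
            t = top[k];
        }
    }
    return t;
}

// Order-1 Markov chain of base indices (1..4) from a 4x4 row-stochastic transition
// matrix, using R's RNG.  First state drawn from `init`.
// [[Rcpp::export(name = ".markov_chain_cpp")]]
IntegerVector markov_chain_cpp(NumericMatrix trans, NumericVector init, int len) {
    IntegerVector out(len);
    GetRNGstate();
    double r = unif_rand();
    int s = 3;
    double acc = 0.0;
    for (int b = 0; b < 4; ++b) { acc += init[b]; if (r <= acc) { s = b; break; } }
    out[0] = s + 1;
    for (int i = 1; i < len; ++i) {
        r = unif_rand();
        acc = 0.0;
        int nxt = 3;
        for (int b = 0; b < 4; ++b) { acc += trans(s, b); if (r <= acc) { nxt = b; break; } }
        s = nxt;
        out[i] = s + 1;
    }
    PutRNGstate();
    return out;
}
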