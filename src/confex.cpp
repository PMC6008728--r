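#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

typedef std::complex<double> cd;

// 2x2 complex matrix, row-major {a b; c d}
struct M2 { cd a, b, c, d; };

static inline M2 mul2(const M2 &x, const M2 &y) {
    M2 r;
    r.a = x.a * y.a + x.b * y.c;
    r.b = x.a * y.b + x.b * y.d;
    r.c = x.c * y.a + x.d * y.c;
    r.d = x.c * y.b + x.d * y.d;
    return r;
}

static inline M2 conj2(const M2 &x) {
    M2 r;
    r.a = std::conj(x.a); r.b = std::conj(x.b);
    r.c = std::conj(x.c); r.d = std::conj(x.d);
    return r;
}

// exp(A) for 2x2 complex A, closed form:
// exp(A) = e^m [cosh(s) I + sinh(s)/s (A - m I)],
// m = tr(A)/2, s^2 = ((a-d)/2)^2 + bc.  Series for small |s|.
static M2 expm2(const M2 &A) {
    cd m = (A.a + A.d) / 2.0;
    cd s2 = (A.a - A.d) * (A.a - A.d) / 4.0 + A.b * A.c;
    cd s = std::sqrt(s2);
    cd ch, shs;
    if (std::abs(s) < 1e-6) {
        ch = 1.0 + s2 / 2.0 + s2 * s2 / 24.0;
        shs = 1.0 + s2 / 6.0 + s2 * s2 / 120.0;
    } else {
        ch = std::cosh(s);
        shs = std::sinh(s) / s;
    }
    cd em = std::exp(m);
    M2 r;
    r.a = em * (ch + shs * (A.a - m));
    r.b = em * (shs * A.b);
    r.c = em * (shs * A.c);
    r.d = em * (ch + shs * (A.d - m));
    return r;
}

static M2 mpow2(M2 base, int n) {
    M2 r; r.a = 1.0; r.b = 0.0; r.c = 0.0; r.d = 1.0;
    while (n > 0) {
        if (n & 1) r = mul2(r, base);
        base = mul2(base, base);
        n >>= 1;
    }
    return r;
}

// Two-state single-quantum Bloch-McConnell R2,eff for a CPMG element train.
// Element: delta - pi - 2delta - pi - delta with delta = 1/(4 nu); the ideal
// pi pulses act as complex conjugation, so one element propagates as
// E(delta) conj(E(2delta)) E(delta).  M(0) = (pB, pE) (equilibrium, real).
// [[Rcpp::export(name = ".r2eff_bm_cpp")]]
NumericVector r2eff_bm_cpp(double kbe, double keb, double pE, double dw_rad,
                           double r20, NumericVector nu, double tcpmg,
                           IntegerVector ncyc) {
    int npt = nu.size();
    NumericVector out(npt);
    double pB = 1.0 - pE;
    for (int i = 0; i < npt; ++i) {
        double delta = 1.0 / (4.0 * nu[i]);
        // L = -R2,0 I + K + i Omega; Omega = diag(0, dw)
        M2 L;
        L.a = cd(-r20 - kbe, 0.0);
        L.b = cd(keb, 0.0);
        L.c = cd(kbe, 0.0);
        L.d = cd(-r20 - keb, dw_rad);
        M2 Ld = L, L2 = L;
        Ld.a *= delta; Ld.b *= delta; Ld.c *= delta; Ld.d *= delta;
        L2.a *= 2.0 * delta; L2.b *= 2.0 * delta;
        L2.c *= 2.0 * delta; L2.d *= 2.0 * delta;
        M2 Ed = expm2(Ld);
        M2 E2 = expm2(L2);
        M2 elem = mul2(Ed, mul2(conj2(E2), Ed));
        M2 U = mpow2(elem, ncyc[i]);
        cd mb = U.a * pB + U.b * pE;
        cd me = U.c * pB + U.d * pE;
        double sig = std::abs(mb + me);
        out[i] = -std::log(sig) / tcpmg;
    }
    return out;
}

// Sample a discrete Markov chain from a row-stochastic matrix T (n x n).
// start is a 0-based state id; returns 0-based ids.
// [[Rcpp::export(name = ".markov_chain_cpp")]]
IntegerVector markov_chain_cpp(NumericMatrix T, int nsteps, int start) {
    int n = T.nrow();
    // row-wise cumulative probabilities
    NumericMatrix cum(n, n);
    for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = 0; j < n; ++j) {
            acc += T(i, j);
            cum(i, j) = acc;
        }
    }
    IntegerVector out(nsteps);
    int s = start;
    out[0] = s;
    for (int t = 1; t < nsteps; ++t) {
        double u = unif_rand();
        int j = 0;
        while (j < n - 1 && u > cum(s, j)) ++j;
        s = j;
        out[t] = s;
    }
    return out;
}

// Overdamped Langevin (Euler-Maruyama) on a 2D potential made of Gaussian
// wells plus an isotropic harmonic confinement:
//   U(x) = 0.5 kconf |x|^2 - sum_i depth_i exp(-|x - c_i|^2 / (2 w_i^2))
// x <- x - (D/kT) grad U dt + sqrt(2 D dt) eta.
// Returns coordinates every `stride` steps (including step 0).
// [[Rcpp::export(name = ".langevin_cpp")]]
List langevin_cpp(NumericMatrix centers, NumericVector depths,
                  NumericVector widths, double kconf, double kT, double D,
                  double dt, int nsteps, NumericVector x0, int stride,
                  double rmax) {
    int nw = depths.size();
    int nout = nsteps / stride + 1;
    NumericMatrix out(nout, 2);
    double x = x0[0], y = x0[1];
    out(0, 0) = x; out(0, 1) = y;
    double mob = D / kT * dt;
    double noise = std::sqrt(2.0 * D * dt);
    bool escaped = false;
    int k = 1;
    for (int t = 1; t <= nsteps; ++t) {
        double gx = kconf * x, gy = kconf * y;
        for (int i = 0; i < nw; ++i) {
            double ddx = x - centers(i, 0), ddy = y - centers(i, 1);
            double w2 = widths[i] * widths[i];
            double e = depths[i] * std::exp(-(ddx * ddx + ddy * ddy) / (2.0 * w2)) / w2;
            gx += e * ddx;
            gy += e * ddy;
        }
        x += -mob * gx + noise * norm_rand();
        y += -mob * gy + noise * norm_rand();
        if (x * x + y * y > rmax * rmax) escaped = true;
        if (t % stride == 0) {
            out(k, 0) = x; out(k, 1) = y;
            ++k;
        }
    }
    return List::create(_["coords"] = out, _["escaped"] = escaped);
}

// Potential energy of the Gaussian-well potential on a set of points.
// [[Rcpp::export(name = ".potential_energy_cpp")]]
NumericVector potential_energy_cpp(NumericMatrix pts, NumericMatrix centers,
                                   NumericVector depths, NumericVector widths,
                                   double kconf) {
    int n = pts.nrow(), nw = depths.size();
    NumericVector out(n);
    for (int p = 0; p < n; ++p) {
        double x = pts(p, 0), y = pts(p, 1);
        double u = 0.5 * kconf * (x * x + y * y);
        for (int i = 0; i < nw; ++i) {
            double ddx = x - centers(i, 0), ddy = y - centers(i, 1);
            double w2 = widths[i] * widths[i];
            u -= depths[i] * std::exp(-(ddx * ddx + ddy * ddy) / (2.0 * w2));
        }
        out[p] = u;
    }
    return out;
}
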