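#include <Rcpp.h>
#include <cmath>
#include <cstdlib>

using namespace Rcpp;

// Joseph-style John transform: march through the voxel grid in unit steps
// along the dominant component of the (sample-frame) beam direction,
// bilinearly interpolating the field in the two transverse axes.  The
// interpolation weights are the beam-voxel overlap coefficients; each lies in
// [0, 1] and is exactly zero for voxels the traced ray does not touch.
// forward() and adjoint() use identical weights, so the pair is an exact
// matrix transpose.

namespace {

struct RaySetup {
    double p[3];     // sample-frame beam direction
    double jv[3];    // sample-frame j scan axis
    double kv[3];    // sample-frame k scan axis
    int dom;         // dominant (marching) axis
    int a1, a2;      // transverse axes
};

inline RaySetup setup_ray(const double* p, const double* jv, const double* kv) {
    RaySetup r;
    for (int i = 0; i < 3; ++i) { r.p[i] = p[i]; r.jv[i] = jv[i]; r.kv[i] = kv[i]; }
    int dom = 0;
    double best = std::fabs(p[0]);
    for (int i = 1; i < 3; ++i) {
        double a = std::fabs(p[i]);
        if (a > best) { best = a; dom = i; }
    }
    if (best <= 0.0) stop("beam direction has zero norm");
    r.dom = dom;
    r.a1 = (dom == 0) ? 1 : 0;
    r.a2 = (dom == 2) ? 1 : 2;
    return r;
}

} // namespace

// field: [X, Y, Z, N]; returns [S, J, K, N].
// pmat/jmat/kmat: S x 3 sample-frame beam/scan axes; offsets in voxel units.
// [[Rcpp::export]]
NumericVector cpp_forward(NumericVector field, IntegerVector shape,
                          int J, int K,
                          NumericMatrix pmat, NumericMatrix jmat,
                          NumericMatrix kmat,
                          NumericVector joff, NumericVector koff) {
    const int X = shape[0], Y = shape[1], Z = shape[2], N = shape[3];
    const int S = pmat.nrow();
    if ((R_xlen_t)X * Y * Z * N != field.size())
        stop("field size does not match shape");
    NumericVector out((R_xlen_t)S * J * K * N);
    const double* f = field.begin();
    double* o = out.begin();
    const int dims[3] = {X, Y, Z};
    const R_xlen_t chanStrideF = (R_xlen_t)X * Y * Z;
    const R_xlen_t chanStrideO = (R_xlen_t)S * J * K;

    for (int s = 0; s < S; ++s) {
        double p[3] = {pmat(s, 0), pmat(s, 1), pmat(s, 2)};
        double jv[3] = {jmat(s, 0), jmat(s, 1), jmat(s, 2)};
        double kv[3] = {kmat(s, 0), kmat(s, 1), kmat(s, 2)};
        RaySetup r = setup_ray(p, jv, kv);
        const int D = dims[r.dom], N1 = dims[r.a1], N2 = dims[r.a2];
        const double c1h = 0.5 * (N1 - 1), c2h = 0.5 * (N2 - 1);
        const double cdh = 0.5 * (D - 1);
        for (int k = 0; k < K; ++k) {
            double ck = k - 0.5 * (K - 1) + koff[s];
            for (int j = 0; j < J; ++j) {
                double cj = j - 0.5 * (J - 1) + joff[s];
                double org[3];
                for (int i = 0; i < 3; ++i)
                    org[i] = cj * jv[i] + ck * kv[i];
                const R_xlen_t rayBase = s + (R_xlen_t)S * (j + (R_xlen_t)J * k);
                for (int g = 0; g < D; ++g) {
                    double t = ((g - cdh) - org[r.dom]) / r.p[r.dom];
                    double u1 = org[r.a1] + t * r.p[r.a1] + c1h;
                    double u2 = org[r.a2] + t * r.p[r.a2] + c2h;
                    int i1 = (int)std::floor(u1), i2 = (int)std::floor(u2);
                    double f1 = u1 - i1, f2 = u2 - i2;
                    for (int t1 = 0; t1 < 2; ++t1) {
                        int v1 = i1 + t1;
                        if (v1 < 0 || v1 >= N1) continue;
                        double w1 = t1 ? f1 : 1.0 - f1;
                        if (w1 == 0.0) continue;
                        for (int t2 = 0; t2 < 2; ++t2) {
                            int v2 = i2 + t2;
                            if (v2 < 0 || v2 >= N2) continue;
                            double w = w1 * (t2 ? f2 : 1.0 - f2);
                            if (w == 0.0) continue;
                            int vox[3];
                            vox[r.dom] = g; vox[r.a1] = v1; vox[r.a2] = v2;
                            R_xlen_t vi = vox[0] + (R_xlen_t)X *
                                (vox[1] + (R_xlen_t)Y * vox[2]);
                            for (int n = 0; n < N; ++n)
                                o[rayBase + chanStrideO * n] +=
                                    w * f[vi + chanStrideF * n];
                        }
                    }
                }
            }
        }
    }
    out.attr("dim") = IntegerVector::create(S, J, K, N);
    return out;
}

// proj: [S, J, K, N]; returns [X, Y, Z, N].  Exact transpose of cpp_forward.
// [[Rcpp::export]]
NumericVector cpp_adjoint(NumericVector proj, IntegerVector shape,
                          int J, int K,
                          NumericMatrix pmat, NumericMatrix jmat,
                          NumericMatrix kmat,
                          NumericVector joff, NumericVector koff) {
    const int X = shape[0], Y = shape[1], Z = shape[2], N = shape[3];
    const int S = pmat.nrow();
    if ((R_xlen_t)S * J * K * N != proj.size())
        stop("projection size does not match geometry");
    NumericVector out((R_xlen_t)X * Y * Z * N);
    const double* pr = proj.begin();
    double* o = out.begin();
    const int dims[3] = {X, Y, Z};
    const R_xlen_t chanStrideF = (R_xlen_t)X * Y * Z;
    const R_xlen_t chanStrideO = (R_xlen_t)S * J * K;

    for (int s = 0; s < S; ++s) {
        double p[3] = {pmat(s, 0), pmat(s, 1), pmat(s, 2)};
        double jv[3] = {jmat(s, 0), jmat(s, 1), jmat(s, 2)};
        double kv[3] = {kmat(s, 0), kmat(s, 1), kmat(s, 2)};
        RaySetup r = setup_ray(p, jv, kv);
        const int D = dims[r.dom], N1 = dims[r.a1], N2 = dims[r.a2];
        const double c1h = 0.5 * (N1 - 1), c2h = 0.5 * (N2 - 1);
        const double cdh = 0.5 * (D - 1);
        for (int k = 0; k < K; ++k) {
            double ck = k - 0.5 * (K - 1) + koff[s];
            for (int j = 0; j < J; ++j) {
                double cj = j - 0.5 * (J - 1) + joff[s];
                double org[3];
                for (int i = 0; i < 3; ++i)
                    org[i] = cj * jv[i] + ck * kv[i];
                const R_xlen_t rayBase = s + (R_xlen_t)S * (j + (R_xlen_t)J * k);
                for (int g = 0; g < D; ++g) {
                    double t = ((g - cdh) - org[r.dom]) / r.p[r.dom];
                    double u1 = org[r.a1] + t * r.p[r.a1] + c1h;
                    double u2 = org[r.a2] + t * r.p[r.a2] + c2h;
                    int i1 = (int)std::floor(u1), i2 = (int)std::floor(u2);
                    double f1 = u1 - i1, f2 = u2 - i2;
                    for (int t1 = 0; t1 < 2; ++t1) {
                        int v1 = i1 + t1;
                        if (v1 < 0 || v1 >= N1) continue;
                        double w1 = t1 ? f1 : 1.0 - f1;
                        if (w1 == 0.0) continue;
                        for (int t2 = 0; t2 < 2; ++t2) {
                            int v2 = i2 + t2;
                            if (v2 < 0 || v2 >= N2) continue;
                            double w = w1 * (t2 ? f2 : 1.0 - f2);
                            if (w == 0.0) continue;
                            int vox[3];
                            vox[r.dom] = g; vox[r.a1] = v1; vox[r.a2] = v2;
                            R_xlen_t vi = vox[0] + (R_xlen_t)X *
                                (vox[1] + (R_xlen_t)Y * vox[2]);
                            for (int n = 0; n < N; ++n)
                                o[vi + chanStrideF * n] +=
                                    w * pr[rayBase + chanStrideO * n];
                        }
                    }
                }
            }
        }
    }
    out.attr("dim") = IntegerVector::create(X, Y, Z, N);
    return out;
}
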