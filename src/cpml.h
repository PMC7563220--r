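#ifndef SARSENSE_CPML_H
#define SARSENSE_CPML_H

#include <vector>
#include <cmath>

#if defined(__SSE2__) || defined(__x86_64__)
#include <xmmintrin.h>
#define SARSENSE_HAVE_SSE 1
#endif

// Flush-to-zero / denormals-are-zero guard for the update loops: decaying
// fields in low-loss regions otherwise sink into subnormal numbers, which
// many CPUs process orders of magnitude slower. Restores the FP environment
// on scope exit. Subnormal magnitudes (< 1e-307) are far below any field
// value the phasor extraction can resolve.
struct DenormalGuard {
#ifdef SARSENSE_HAVE_SSE
    unsigned int csr_;
    DenormalGuard() : csr_(_mm_getcsr()) { _mm_setcsr(csr_ | 0x8040u); }
    ~DenormalGuard() { _mm_setcsr(csr_); }
#else
    DenormalGuard() {}
#endif
};

// Convolutional PML stretching coefficients along one axis, at integer (E)
// and half-integer (H) sample positions. Polynomial conductivity grading of
// order m = 3 with sigma_max = 0.8 (m+1) / (eta0 dx), linearly graded
// complex-frequency-shift alpha, kappa = 1 (adequate for lossy biological
// media at the grid resolutions used here). Outer boundary is PEC-backed.
struct CpmlAxis {
    std::vector<double> b_e, c_e, b_h, c_h;
};

inline CpmlAxis cpml_axis(int n, int npml, double dx, double dt) {
    const double eps0 = 8.8541878128e-12;
    const double eta0 = 376.730313668;
    const double m = 3.0;
    const double smax = 0.8 * (m + 1.0) / (eta0 * dx);
    const double amax = 0.05;

    CpmlAxis ax;
    ax.b_e.assign(n, 0.0); ax.c_e.assign(n, 0.0);
    ax.b_h.assign(n, 0.0); ax.c_h.assign(n, 0.0);

    auto coef = [&](double pos, double &b, double &c) {
        double rho = -1.0;
        if (pos < npml) rho = (npml - pos) / npml;
        else if (pos > (n - 1) - npml) rho = (pos - ((n - 1) - npml)) / npml;
        if (rho <= 0.0) { b = 0.0; c = 0.0; return; }
        if (rho > 1.0) rho = 1.0;
        double sig = smax * std::pow(rho, m);
        double alp = amax * (1.0 - rho);
        b = std::exp(-(sig + alp) * dt / eps0);
        c = (sig > 0.0) ? sig * (b - 1.0) / (sig + alp) : 0.0;
    };

    for (int i = 0; i < n; ++i) {
        coef(static_cast<double>(i), ax.b_e[i], ax.c_e[i]);
        coef(i + 0.5, ax.b_h[i], ax.c_h[i]);
    }
    return ax;
}

#endif
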