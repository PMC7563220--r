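#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "cpml.h"

// 2D transverse-magnetic (Ez, Hx, Hy) finite-difference time-domain solver
// with CPML absorbing boundaries and lossy dielectric media. Line sources
// (soft current sources in Ez) are driven sinusoidally; the steady-state
// phasor is extracted by single-frequency discrete Fourier projection over
// the final drive period (and, for a steady-state check, the penultimate
// period). Phasor convention: instantaneous field = Re{E exp(+j w t)}.

// [[Rcpp::export]]
Rcpp::List fdtd2d_solve_cpp(Rcpp::NumericMatrix eps_r,
                            Rcpp::NumericMatrix sigma,
                            double dx, double freq, int periods,
                            int pml_cells, double courant,
                            Rcpp::IntegerVector src_i,
                            Rcpp::IntegerVector src_j,
                            Rcpp::NumericVector src_amp,
                            Rcpp::NumericVector src_phase,
                            double ramp_periods) {
    DenormalGuard fp_guard;
    const double c0 = 299792458.0;
    const double eps0 = 8.8541878128e-12;
    const double mu0 = 4.0e-7 * M_PI;

    const int nx = eps_r.nrow(), ny = eps_r.ncol();
    const double T = 1.0 / freq;
    const double dt_max = courant * dx / (c0 * std::sqrt(2.0));
    const int spp = static_cast<int>(std::ceil(T / dt_max));
    const double dt = T / spp;
    const long nt = static_cast<long>(periods) * spp;
    const double w = 2.0 * M_PI * freq;

    std::vector<double> Ez(nx * ny, 0.0), Hx(nx * ny, 0.0), Hy(nx * ny, 0.0);
    std::vector<double> Ca(nx * ny), Cb(nx * ny);
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            const int id = i + nx * j;
            const double eps = eps_r(i, j) * eps0;
            const double s = sigma(i, j) * dt / (2.0 * eps);
            Ca[id] = (1.0 - s) / (1.0 + s);
            Cb[id] = (dt / eps) / (1.0 + s);
        }

    CpmlAxis px = cpml_axis(nx, pml_cells, dx, dt);
    CpmlAxis py = cpml_axis(ny, pml_cells, dx, dt);

    std::vector<double> psiEzx(nx * ny, 0.0), psiEzy(nx * ny, 0.0);
    std::vector<double> psiHxy(nx * ny, 0.0), psiHyx(nx * ny, 0.0);

    std::vector<double> accLr(nx * ny, 0.0), accLi(nx * ny, 0.0);
    std::vector<double> accPr(nx * ny, 0.0), accPi(nx * ny, 0.0);

    const int nsrc = src_i.size();
    const double ramp_T = ramp_periods * T;
    const double hdtmu = dt / mu0;

    for (long n = 0; n < nt; ++n) {
        // H update from Ez at time n*dt
        for (int j = 0; j < ny - 1; ++j)
            for (int i = 0; i < nx; ++i) {
                const int id = i + nx * j;
                const double dEzy = (Ez[id + nx] - Ez[id]) / dx;
                psiHxy[id] = py.b_h[j] * psiHxy[id] + py.c_h[j] * dEzy;
                Hx[id] -= hdtmu * (dEzy + psiHxy[id]);
            }
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx - 1; ++i) {
                const int id = i + nx * j;
                const double dEzx = (Ez[id + 1] - Ez[id]) / dx;
                psiHyx[id] = px.b_h[i] * psiHyx[id] + px.c_h[i] * dEzx;
                Hy[id] += hdtmu * (dEzx + psiHyx[id]);
            }

        // E update to time (n+1)*dt; PEC on the outermost ring
        for (int j = 1; j < ny - 1; ++j)
            for (int i = 1; i < nx - 1; ++i) {
                const int id = i + nx * j;
                const double dHyx = (Hy[id] - Hy[id - 1]) / dx;
                const double dHxy = (Hx[id] - Hx[id - nx]) / dx;
                psiEzx[id] = px.b_e[i] * psiEzx[id] + px.c_e[i] * dHyx;
                psiEzy[id] = py.b_e[j] * psiEzy[id] + py.c_e[j] * dHxy;
                Ez[id] = Ca[id] * Ez[id] +
                    Cb[id] * ((dHyx + psiEzx[id]) - (dHxy + psiEzy[id]));
            }

        const double tE = (n + 1) * dt;
        double ramp = 1.0;
        if (ramp_T > 0.0 && tE < ramp_T)
            ramp = 0.5 * (1.0 - std::cos(M_PI * tE / ramp_T));
        for (int s = 0; s < nsrc; ++s) {
            const int id = src_i[s] + nx * src_j[s];
            Ez[id] -= Cb[id] * src_amp[s] * ramp *
                std::sin(w * tE + src_phase[s]) / (dx * dx);
        }

        // phasor projection over the last two periods
        if (n >= nt - 2L * spp) {
            const double cw = std::cos(w * tE), sw = std::sin(w * tE);
            if (n >= nt - spp) {
                for (int id = 0; id < nx * ny; ++id) {
                    accLr[id] += Ez[id] * cw;
                    accLi[id] -= Ez[id] * sw;
                }
            } else {
                for (int id = 0; id < nx * ny; ++id) {
                    accPr[id] += Ez[id] * cw;
                    accPi[id] -= Ez[id] * sw;
                }
            }
        }

        if ((n + 1) % spp == 0) {
            double m = 0.0;
            for (int id = 0; id < nx * ny; ++id) {
                const double a = std::fabs(Ez[id]);
                if (a > m) m = a;
            }
            if (!std::isfinite(m) || m > 1e30)
                Rcpp::stop("FDTD instability detected (field divergence); "
                           "reduce the Courant factor or time step");
        }
    }

    const double sc = 2.0 / spp;
    Rcpp::NumericMatrix Er(nx, ny), Ei(nx, ny), Epr(nx, ny), Epi(nx, ny);
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            const int id = i + nx * j;
            Er(i, j) = sc * accLr[id];
            Ei(i, j) = sc * accLi[id];
            Epr(i, j) = sc * accPr[id];
            Epi(i, j) = sc * accPi[id];
        }

    return Rcpp::List::create(
        Rcpp::Named("re") = Er, Rcpp::Named("im") = Ei,
        Rcpp::Named("re_prev") = Epr, Rcpp::Named("im_prev") = Epi,
        Rcpp::Named("dt") = dt, Rcpp::Named("steps_per_period") = spp);
}
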