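#include <Rcpp.h>
using namespace Rcpp;

// 2-D transverse-magnetic (Ez, Hx, Hy) finite-difference time-domain update on a
// Yee grid, with a graded-conductivity sponge absorbing layer.  The grid passed
// in already includes the sponge region (filled with the background medium);
// `sponge_n` cells on every edge receive an additional polynomial-graded
// electric conductivity with matched magnetic loss so that outgoing waves are
// absorbed rather than reflected.
//
// Conventions:
//  - eps_r / sigma are (nx x ny) R matrices; index 1 = x, index 2 = y.
//  - Ez lives at integer nodes (nx x ny); Hx at (i, j+1/2) [(nx) x (ny-1)];
//    Hy at (i+1/2, j) [(nx-1) x ny].
//  - A soft additive source drives Ez at one node; receivers sample Ez nodes.
//  - Time loop: at step n (0-based) H is advanced with Ez^n, then Ez^{n+1} is
//    formed, the source sample s(t_{n+1}) is added, and outputs at requested
//    times are accumulated by linear interpolation between internal steps.

static const double C0   = 299792458.0;
static const double EPS0 = 8.8541878128e-12;
static const double MU0  = 1.25663706212e-6;

// [[Rcpp::export(name = ".fdtd_run_cpp")]]
List fdtd_run_cpp(NumericMatrix eps_r, NumericMatrix sigma,
                  double dx, double dt, int n_steps,
                  int src_i, int src_j,            // 0-based Ez node of the source
                  NumericVector src_wave,          // length n_steps, s(t_{n+1})
                  IntegerMatrix rec_ij,            // n_rec x 2, 0-based Ez nodes
                  NumericVector out_times,         // seconds, ascending
                  int sponge_n, double eps_bg,
                  bool energy_trace) {
  const int nx = eps_r.nrow(), ny = eps_r.ncol();
  const int n_rec = rec_ij.nrow();
  const int n_out = out_times.size();
  if (sigma.nrow() != nx || sigma.ncol() != ny)
    stop("eps_r and sigma dimensions differ");
  if (src_wave.size() < n_steps) stop("source waveform shorter than n_steps");

  // CFL check for the fastest medium present
  double eps_min = R_PosInf;
  for (int k = 0; k < nx * ny; ++k) eps_min = std::min(eps_min, eps_r[k]);
  double v_max = C0 / std::sqrt(eps_min);
  double dt_max = dx / (v_max * std::sqrt(2.0));
  if (dt > dt_max * (1.0 + 1e-12))
    stop("CFL violation: dt=%g exceeds stability bound %g for dx=%g", dt, dt_max, dx);

  // Sponge conductivity profile (cubic grading, impedance-matched magnetic loss)
  const int m_grade = 3;
  double eta_bg = std::sqrt(MU0 / (EPS0 * eps_bg));
  double sig_max = 0.8 * (m_grade + 1) / (eta_bg * dx);
  std::vector<double> sig_e(nx * ny), sm_ratio(nx * ny);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double d = 0.0; // penetration depth into the sponge, in cells
      if (sponge_n > 0) {
        double dxl = std::max(0.0, (double)(sponge_n - i));
        double dxr = std::max(0.0, (double)(i - (nx - 1 - sponge_n)));
        double dyl = std::max(0.0, (double)(sponge_n - j));
        double dyr = std::max(0.0, (double)(j - (ny - 1 - sponge_n)));
        d = std::max(std::max(dxl, dxr), std::max(dyl, dyr));
      }
      double s_sp = (d > 0.0) ? sig_max * std::pow(d / sponge_n, m_grade) : 0.0;
      sig_e[i + nx * j] = sigma(i, j) + s_sp;
      // matched magnetic conductivity ratio sigma_m/mu = sigma_sponge/eps
      sm_ratio[i + nx * j] = (d > 0.0) ? s_sp / (EPS0 * eps_bg) : 0.0;
    }
  }

  // Ez update coefficients per node
  std::vector<double> Ca(nx * ny), Cb(nx * ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double eps = EPS0 * eps_r(i, j);
      double a = sig_e[i + nx * j] * dt / (2.0 * eps);
      Ca[i + nx * j] = (1.0 - a) / (1.0 + a);
      Cb[i + nx * j] = (dt / (eps * dx)) / (1.0 + a);
    }

  std::vector<double> Ez(nx * ny, 0.0), Hx(nx * (ny - 1), 0.0), Hy((nx - 1) * ny, 0.0);
  // Magnetic update coefficients at H locations (average adjacent node ratios)
  std::vector<double> DaHx(nx * (ny - 1)), DbHx(nx * (ny - 1));
  for (int j = 0; j < ny - 1; ++j)
    for (int i = 0; i < nx; ++i) {
      double r = 0.5 * (sm_ratio[i + nx * j] + sm_ratio[i + nx * (j + 1)]);
      double a = r * dt / 2.0;
      DaHx[i + nx * j] = (1.0 - a) / (1.0 + a);
      DbHx[i + nx * j] = (dt / (MU0 * dx)) / (1.0 + a);
    }
  std::vector<double> DaHy((nx - 1) * ny), DbHy((nx - 1) * ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx - 1; ++i) {
      double r = 0.5 * (sm_ratio[i + nx * j] + sm_ratio[(i + 1) + nx * j]);
      double a = r * dt / 2.0;
      DaHy[i + (nx - 1) * j] = (1.0 - a) / (1.0 + a);
      DbHy[i + (nx - 1) * j] = (dt / (MU0 * dx)) / (1.0 + a);
    }

  // Output interpolation bookkeeping: out value = (1-w)*Ez^{k0} + w*Ez^{k0+1}
  // where internal state Ez^{k} is at time k*dt (k = 0..n_steps).
  NumericMatrix rec(n_out, n_rec);
  std::vector<int> k0(n_out);
  std::vector<double> wgt(n_out);
  for (int q = 0; q < n_out; ++q) {
    double tk = out_times[q] / dt;
    int k = (int)std::floor(tk + 1e-9);
    if (k < 0) k = 0;
    if (k >= n_steps) { k = n_steps - 1; tk = (double)n_steps; }
    k0[q] = k;
    wgt[q] = tk - k;
    if (wgt[q] < 0) wgt[q] = 0;
    if (wgt[q] > 1) wgt[q] = 1;
  }
  // initial state (k = 0) contributions are all zero fields: nothing to add.

  NumericVector energy(energy_trace ? n_steps : 0);

  for (int n = 0; n < n_steps; ++n) {
    // H updates from Ez^n
    for (int j = 0; j < ny - 1; ++j) {
      const int off = nx * j;
      for (int i = 0; i < nx; ++i) {
        const int k = i + off;
        Hx[k] = DaHx[k] * Hx[k] - DbHx[k] * (Ez[i + nx * (j + 1)] - Ez[i + nx * j]);
      }
    }
    for (int j = 0; j < ny; ++j) {
      const int offh = (nx - 1) * j, offe = nx * j;
      for (int i = 0; i < nx - 1; ++i) {
        const int k = i + offh;
        Hy[k] = DaHy[k] * Hy[k] + DbHy[k] * (Ez[(i + 1) + offe] - Ez[i + offe]);
      }
    }
    // Ez update (interior nodes; boundary nodes stay 0 = PEC behind the sponge)
    for (int j = 1; j < ny - 1; ++j) {
      const int offe = nx * j;
      for (int i = 1; i < nx - 1; ++i) {
        const int k = i + offe;
        double curl = (Hy[i + (nx - 1) * j] - Hy[(i - 1) + (nx - 1) * j])
                    - (Hx[i + nx * j] - Hx[i + nx * (j - 1)]);
        Ez[k] = Ca[k] * Ez[k] + Cb[k] * curl;
      }
    }
    // soft source at t_{n+1}
    Ez[src_i + nx * src_j] += src_wave[n];

    // accumulate interpolated outputs for internal state index n+1
    for (int q = 0; q < n_out; ++q) {
      double w = 0.0;
      if (k0[q] == n + 1) w = 1.0 - wgt[q];
      else if (k0[q] + 1 == n + 1) w = wgt[q];
      if (w != 0.0)
        for (int r = 0; r < n_rec; ++r)
          rec(q, r) += w * Ez[rec_ij(r, 0) + nx * rec_ij(r, 1)];
    }

    if (energy_trace) {
      double e = 0.0;
      for (int k = 0; k < nx * ny; ++k) e += 0.5 * EPS0 * eps_r[k] * Ez[k] * Ez[k] * dx * dx;
      for (size_t k = 0; k < Hx.size(); ++k) e += 0.5 * MU0 * Hx[k] * Hx[k] * dx * dx;
      for (size_t k = 0; k < Hy.size(); ++k) e += 0.5 * MU0 * Hy[k] * Hy[k] * dx * dx;
      energy[n] = e;
    }
  }

  return List::create(_["rec"] = rec, _["energy"] = energy,
                      _["dt_internal"] = dt, _["n_steps"] = n_steps);
}
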