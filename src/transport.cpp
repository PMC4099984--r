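// Simplified voxel Monte Carlo kernels.
//
// Photon transport: analog tracking on the labeled lattice with per-voxel
// attenuation, photoelectric-style absorption (total minus Klein-Nishina
// incoherent) and free-electron Compton scattering; energy scored with the
// track-length kerma estimator (segment length x E x mu_en). Electrons in
// CSDA mode deposit uniformly in mass-path along a straight line. One
// master seed; each history runs its own counter-derived substream, so
// results are independent of execution order.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// --- counter-based RNG (splitmix64 stream per history) ---------------------
static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}
struct Rng {
  uint64_t s;
  Rng(uint64_t seed, uint64_t stream) {
    s = seed ^ (0xD2B74407B1CE6E93ULL * (stream + 1));
    for (int i = 0; i < 3; ++i) splitmix64(s);
  }
  double u() { return (splitmix64(s) >> 11) * 1.1102230246251565e-16; }
};

// log-log interpolation on an increasing grid (clamped)
static inline double loglog_interp(const std::vector<double> &lx,
                                   const std::vector<double> &ly, double x) {
  double l = std::log(x);
  size_t n = lx.size();
  if (l <= lx[0]) return std::exp(ly[0]);
  if (l >= lx[n - 1]) return std::exp(ly[n - 1]);
  size_t hi = std::upper_bound(lx.begin(), lx.end(), l) - lx.begin();
  size_t lo = hi - 1;
  double f = (l - lx[lo]) / (lx[hi] - lx[lo]);
  return std::exp(ly[lo] + f * (ly[hi] - ly[lo]));
}

static inline double kn_sigma(double E) { // cm^2 per electron
  double a = E / 0.51099895;
  const double re2 = 7.940787e-26;
  double t1 = (1 + a) / (a * a) * (2 * (1 + a) / (1 + 2 * a) -
                                   std::log(1 + 2 * a) / a);
  double t2 = std::log(1 + 2 * a) / (2 * a);
  double t3 = -(1 + 3 * a) / ((1 + 2 * a) * (1 + 2 * a));
  return 2 * M_PI * re2 * (t1 + t2 + t3);
}

// sample E'/E from the Klein-Nishina distribution by rejection on
// d sigma / d eps ~ (eps + 1/eps - sin^2 theta), eps in [1/(1+2a), 1]
static inline double kn_sample_eps(Rng &rng, double E) {
  double a = E / 0.51099895;
  double eps_min = 1.0 / (1.0 + 2.0 * a);
  double M = 1.0 / eps_min + 1.0;
  for (;;) {
    double eps = eps_min + (1.0 - eps_min) * rng.u();
    double ct = 1.0 - (1.0 / eps - 1.0) / a;
    double s2 = 1.0 - ct * ct;
    double g = eps + 1.0 / eps - s2;
    if (rng.u() * M <= g) return eps;
  }
}

struct Grid {
  int nx, ny, nz;
  double dx, dy, dz;            // mm
  const int *lab;
  inline bool inside(int i, int j, int k) const {
    return i >= 0 && j >= 0 && k >= 0 && i < nx && j < ny && k < nz;
  }
  inline int label(int i, int j, int k) const {
    return lab[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
  }
  inline size_t lin(int i, int j, int k) const {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  }
};

static inline void iso_dir(Rng &rng, double d[3]) {
  double mu = 2.0 * rng.u() - 1.0;
  double phi = 2.0 * M_PI * rng.u();
  double s = std::sqrt(std::max(0.0, 1.0 - mu * mu));
  d[0] = s * std::cos(phi); d[1] = s * std::sin(phi); d[2] = mu;
}

static inline void rotate_dir(Rng &rng, double d[3], double ct) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * rng.u();
  double sp = std::sin(phi), cp = std::cos(phi);
  double u = d[0], v = d[1], w = d[2];
  double a = std::sqrt(std::max(1e-30, 1.0 - w * w));
  double nu, nv, nw;
  if (a > 1e-10) {
    nu = u * ct + st * (u * w * cp - v * sp) / a;
    nv = v * ct + st * (v * w * cp + u * sp) / a;
    nw = w * ct - a * st * cp;
  } else {            // travelling along +-z
    nu = st * cp; nv = st * sp; nw = (w > 0 ? ct : -ct);
  }
  double norm = std::sqrt(nu * nu + nv * nv + nw * nw);
  d[0] = nu / norm; d[1] = nv / norm; d[2] = nw / norm;
}

// [[Rcpp::export(name = ".cpp_transport_photons")]]
List cpp_transport_photons(IntegerVector labels, IntegerVector dims,
                           NumericVector spacing, IntegerVector lab2mat,
                           NumericVector lab2dens, NumericVector loggrid,
                           NumericMatrix logmu, NumericMatrix logmen,
                           NumericVector electrons_per_g,
                           IntegerVector lab2grp, int ngrp,
                           IntegerVector source_vox, double energy,
                           int n_hist, double seed, double cutoff,
                           double rr_threshold, double rr_weight,
                           bool want_mesh, bool track_first_flight) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.dx = spacing[0]; g.dy = spacing[1]; g.dz = spacing[2];
  g.lab = INTEGER(labels);
  int nlab = lab2mat.size();           // indexed by label (0..max_label)
  int ng = loggrid.size();
  int nmat = logmu.ncol();
  std::vector<std::vector<double> > lmu(nmat), lmen(nmat);
  std::vector<double> lx(ng);
  for (int i = 0; i < ng; ++i) lx[i] = loggrid[i];
  for (int m = 0; m < nmat; ++m) {
    lmu[m].resize(ng); lmen[m].resize(ng);
    for (int i = 0; i < ng; ++i) {
      lmu[m][i] = logmu(i, m); lmen[m][i] = logmen(i, m);
    }
  }
  (void)nlab;
  std::vector<double> sum(ngrp, 0.0), sum2(ngrp, 0.0), buf(ngrp, 0.0);
  std::vector<int> touched; touched.reserve(64);
  std::vector<double> mesh;
  if (want_mesh) mesh.assign((size_t)g.nx * g.ny * g.nz, 0.0);
  double emitted = 0, transferred = 0, escaped = 0, cut_dep = 0;
  double rr_killed = 0;
  double ff_sum = 0; long ff_n = 0;
  uint64_t useed = (uint64_t)seed;
  int nsv = source_vox.size();

  for (int h = 0; h < n_hist; ++h) {
    Rng rng(useed, (uint64_t)h);
    // start point: uniform in a uniformly chosen source voxel
    int sv = source_vox[(int)(rng.u() * nsv) % nsv];
    int k0 = sv / (g.nx * g.ny), r = sv % (g.nx * g.ny);
    int j0 = r / g.nx, i0 = r % g.nx;
    double x = (i0 + rng.u()) * g.dx;
    double y = (j0 + rng.u()) * g.dy;
    double z = (k0 + rng.u()) * g.dz;
    double d[3]; iso_dir(rng, d);
    double E = energy;
    double w = 1.0;          // statistical weight (Russian roulette)
    emitted += E;
    touched.clear();
    bool first = true; double flight = 0;
    int i = i0, j = j0, k = k0;
    bool alive = true;
    while (alive) {
      double tau = -std::log(std::max(1e-300, rng.u()));
      // propagate tau optical depths
      for (;;) {
        if (!g.inside(i, j, k)) { escaped += E * w; alive = false; break; }
        int lb = g.lab[g.lin(i, j, k)];
        int m = lab2mat[lb];
        double rho = lab2dens[lb];
        double mu = loglog_interp(lx, lmu[m], E) * rho;   // 1/cm
        double men = loglog_interp(lx, lmen[m], E) * rho; // 1/cm
        // distance to next voxel boundary (mm)
        double tb = 1e30;
        int di = 0, dj = 0, dk = 0;
        if (d[0] > 1e-12) { double t = ((i + 1) * g.dx - x) / d[0]; if (t < tb) { tb = t; di = 1; dj = dk = 0; } }
        else if (d[0] < -1e-12) { double t = (i * g.dx - x) / d[0]; if (t < tb) { tb = t; di = -1; dj = dk = 0; } }
        if (d[1] > 1e-12) { double t = ((j + 1) * g.dy - y) / d[1]; if (t < tb) { tb = t; dj = 1; di = dk = 0; } }
        else if (d[1] < -1e-12) { double t = (j * g.dy - y) / d[1]; if (t < tb) { tb = t; dj = -1; di = dk = 0; } }
        if (d[2] > 1e-12) { double t = ((k + 1) * g.dz - z) / d[2]; if (t < tb) { tb = t; dk = 1; di = dj = 0; } }
        else if (d[2] < -1e-12) { double t = (k * g.dz - z) / d[2]; if (t < tb) { tb = t; dk = -1; di = dj = 0; } }
        if (tb < 0) tb = 0;
        double t_int = (mu > 0) ? tau / (mu / 10.0) : 1e30; // mm
        double step = std::min(tb + 1e-9, t_int);
        double score = w * E * men * (step / 10.0);         // MeV (kerma)
        int gp = lab2grp[lb];
        if (gp >= 0) {
          if (buf[gp] == 0.0 && score > 0) touched.push_back(gp);
          buf[gp] += score;
        }
        if (want_mesh) mesh[g.lin(i, j, k)] += score;
        if (first) flight += step;
        x += step * d[0]; y += step * d[1]; z += step * d[2];
        if (t_int <= tb) {            // interaction here
          if (first && track_first_flight) { ff_sum += flight; ++ff_n; }
          first = false;
          double pinc = kn_sigma(E) * electrons_per_g[m] /
            loglog_interp(lx, lmu[m], E);
          if (pinc > 1) pinc = 1;
          if (rng.u() < pinc) {       // incoherent scatter
            double eps = kn_sample_eps(rng, E);
            double ct = 1.0 - (1.0 / eps - 1.0) / (E / 0.51099895);
            transferred += w * E * (1.0 - eps);
            E *= eps;
            rotate_dir(rng, d, ct);
            if (E <= cutoff) { cut_dep += w * E; alive = false; }
            else if (rr_threshold > 0 && E < rr_threshold) {
              if (rng.u() < 1.0 / rr_weight) w *= rr_weight;
              else { rr_killed += w * E; alive = false; }
            }
          } else {                    // absorption (photoelectric-type)
            transferred += w * E;
            alive = false;
          }
          break;                      // new tau (or history end)
        } else {
          tau -= mu * tb / 10.0;
          i += di; j += dj; k += dk;
        }
      }
    }
    for (size_t t = 0; t < touched.size(); ++t) {
      int gp = touched[t];
      sum[gp] += buf[gp];
      sum2[gp] += buf[gp] * buf[gp];
      buf[gp] = 0.0;
    }
  }
  List out = List::create(
    _["sum"] = NumericVector(sum.begin(), sum.end()),
    _["sum2"] = NumericVector(sum2.begin(), sum2.end()),
    _["n_hist"] = n_hist,
    _["emitted"] = emitted, _["transferred"] = transferred,
    _["escaped"] = escaped, _["cutoff_deposited"] = cut_dep,
    _["rr_killed"] = rr_killed,
    _["first_flight_mean_mm"] = (ff_n > 0 ? ff_sum / ff_n : NA_REAL),
    _["first_flight_n"] = (double)ff_n);
  if (want_mesh) out["mesh"] = NumericVector(mesh.begin(), mesh.end());
  return out;
}

// CSDA electrons: straight line, uniform deposition in mass path length.
// [[Rcpp::export(name = ".cpp_transport_electrons_csda")]]
List cpp_transport_electrons_csda(IntegerVector labels, IntegerVector dims,
                                  NumericVector spacing,
                                  NumericVector lab2dens,
                                  IntegerVector lab2grp, int ngrp,
                                  IntegerVector source_vox, double energy,
                                  double range_gcm2, int n_hist, double seed,
                                  bool want_mesh) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.dx = spacing[0]; g.dy = spacing[1]; g.dz = spacing[2];
  g.lab = INTEGER(labels);
  std::vector<double> sum(ngrp, 0.0), sum2(ngrp, 0.0), buf(ngrp, 0.0);
  std::vector<int> touched; touched.reserve(64);
  std::vector<double> mesh;
  if (want_mesh) mesh.assign((size_t)g.nx * g.ny * g.nz, 0.0);
  double emitted = 0, deposited = 0, escaped = 0;
  uint64_t useed = (uint64_t)seed;
  int nsv = source_vox.size();
  for (int h = 0; h < n_hist; ++h) {
    Rng rng(useed, (uint64_t)h + 0x100000000ULL);
    int sv = source_vox[(int)(rng.u() * nsv) % nsv];
    int k0 = sv / (g.nx * g.ny), r = sv % (g.nx * g.ny);
    int j0 = r / g.nx, i0 = r % g.nx;
    double x = (i0 + rng.u()) * g.dx;
    double y = (j0 + rng.u()) * g.dy;
    double z = (k0 + rng.u()) * g.dz;
    double d[3]; iso_dir(rng, d);
    emitted += energy;
    touched.clear();
    double remain = range_gcm2;       // g/cm^2 of path left
    int i = i0, j = j0, k = k0;
    while (remain > 0) {
      if (!g.inside(i, j, k)) { escaped += energy * (remain / range_gcm2); break; }
      int lb = g.lab[g.lin(i, j, k)];
      double rho = lab2dens[lb];
      double tb = 1e30; int di = 0, dj = 0, dk = 0;
      if (d[0] > 1e-12) { double t = ((i + 1) * g.dx - x) / d[0]; if (t < tb) { tb = t; di = 1; dj = dk = 0; } }
      else if (d[0] < -1e-12) { double t = (i * g.dx - x) / d[0]; if (t < tb) { tb = t; di = -1; dj = dk = 0; } }
      if (d[1] > 1e-12) { double t = ((j + 1) * g.dy - y) / d[1]; if (t < tb) { tb = t; dj = 1; di = dk = 0; } }
      else if (d[1] < -1e-12) { double t = (j * g.dy - y) / d[1]; if (t < tb) { tb = t; dj = -1; di = dk = 0; } }
      if (d[2] > 1e-12) { double t = ((k + 1) * g.dz - z) / d[2]; if (t < tb) { tb = t; dk = 1; di = dj = 0; } }
      else if (d[2] < -1e-12) { double t = (k * g.dz - z) / d[2]; if (t < tb) { tb = t; dk = -1; di = dj = 0; } }
      if (tb < 0) tb = 0;
      double seg_gcm2 = rho * ((tb + 1e-9) / 10.0);
      double used = std::min(seg_gcm2, remain);
      double frac = used / range_gcm2;
      double score = energy * frac;
      int gp = lab2grp[lb];
      if (gp >= 0) {
        if (buf[gp] == 0.0 && score > 0) touched.push_back(gp);
        buf[gp] += score;
      }
      if (want_mesh) mesh[g.lin(i, j, k)] += score;
      deposited += score;
      remain -= used;
      if (used < seg_gcm2) break;     // range exhausted inside this voxel
      double step = tb + 1e-9;
      x += step * d[0]; y += step * d[1]; z += step * d[2];
      i += di; j += dj; k += dk;
    }
    for (size_t t = 0; t < touched.size(); ++t) {
      int gp = touched[t];
      sum[gp] += buf[gp]; sum2[gp] += buf[gp] * buf[gp]; buf[gp] = 0.0;
    }
  }
  List out = List::create(
    _["sum"] = NumericVector(sum.begin(), sum.end()),
    _["sum2"] = NumericVector(sum2.begin(), sum2.end()),
    _["n_hist"] = n_hist, _["emitted"] = emitted,
    _["transferred"] = deposited, _["escaped"] = escaped,
    _["cutoff_deposited"] = 0.0,
    _["first_flight_mean_mm"] = NA_REAL, _["first_flight_n"] = 0.0);
  if (want_mesh) out["mesh"] = NumericVector(mesh.begin(), mesh.end());
  return out;
}
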