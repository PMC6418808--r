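// DPD pair-force kernels and integrator.
//
// Pair forces: soft conservative repulsion a_ij (1 - r) e_ij below the
// cutoff, pairwise dissipative friction -eta (1-r)^2 (e.v) e and pairwise
// random force sigma (1-r) xi dt^{-1/2} e (together the momentum-conserving
// thermostat), plus harmonic bond springs -C r_ij.  Integration is the
// lambda velocity-Verlet scheme.  Boundaries are periodic, optionally
// Lees-Edwards sheared along X with gradient along Y.
//
// Per-pair noise is counter-based: splitmix64 keyed on (seed, step, sorted
// pair), so xi_ij == xi_ji by construction and trajectories are reproducible
// independent of pair iteration order.  xi is uniform with zero mean and
// unit variance, which is all the fluctuation-dissipation relation requires.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// (step, i, j) packed into one word: supports up to 2^21 beads and 2^22
// steps per run segment, far beyond the published system sizes.
static inline double pair_noise(uint64_t seed, uint64_t step,
                                uint64_t i, uint64_t j) {
  uint64_t key = (step << 42) ^ (i << 21) ^ j;
  uint64_t h = splitmix64(splitmix64(seed ^ 0x6A09E667F3BCC909ULL) ^ key);
  double u = (double)(h >> 11) * (1.0 / 9007199254740992.0); // [0, 1)
  return (u - 0.5) * 3.4641016151377544;  // sqrt(12): unit variance
}

// Minimum image under (optionally sheared) cubic periodicity.
static inline void min_image(double &dx, double &dy, double &dz,
                             double L, double off) {
  double cy = std::nearbyint(dy / L);
  dy -= cy * L;
  dx -= cy * off;
  dx -= L * std::nearbyint(dx / L);
  dz -= L * std::nearbyint(dz / L);
}

static const int HALF_OFF[13][3] = {
  {1, 0, 0},
  {-1, 1, 0}, {0, 1, 0}, {1, 1, 0},
  {-1, -1, 1}, {0, -1, 1}, {1, -1, 1},
  {-1, 0, 1}, {0, 0, 1}, {1, 0, 1},
  {-1, 1, 1}, {0, 1, 1}, {1, 1, 1}
};

// Visit every unordered pair with minimum-image distance < rcut exactly
// once, via a counting-sorted cell list.  Periodic images are handled by
// per-cell-offset coordinate shifts (no per-pair rounding).  Under
// Lees-Edwards offsets the y-wrapping cell routes are replaced by an
// explicit pass over the two boundary rows with the sheared minimum image
// (correct for any fractional offset).  The callback receives dvx, the
// x-velocity of j's image relative to j (+-gamma*L for pairs interacting
// across the sheared face, 0 otherwise), which the dissipative force must
// subtract from the relative velocity.
template <class FUN>
static void for_each_pair(const double *x, const double *y, const double *z,
                          int n, double L, double rcut, double off,
                          bool le, double gL, FUN fun) {
  const int nc = (int)std::floor(L / rcut);
  if (nc < 3)
    stop("box too small for the cell list: need box_edge >= 3 * r_cut");
  const double cw = L / nc;
  const int ncells = nc * nc * nc;
  const double rc2 = rcut * rcut;
  std::vector<int> cellOf(n), start(ncells + 1, 0);
  for (int i = 0; i < n; ++i) {
    int ix = (int)(x[i] / cw); if (ix >= nc) ix = nc - 1; if (ix < 0) ix = 0;
    int iy = (int)(y[i] / cw); if (iy >= nc) iy = nc - 1; if (iy < 0) iy = 0;
    int iz = (int)(z[i] / cw); if (iz >= nc) iz = nc - 1; if (iz < 0) iz = 0;
    int c = (iz * nc + iy) * nc + ix;
    cellOf[i] = c;
    ++start[c + 1];
  }
  for (int c = 0; c < ncells; ++c) start[c + 1] += start[c];
  std::vector<int> idx(n), fill(start.begin(), start.end() - 1);
  for (int i = 0; i < n; ++i) idx[fill[cellOf[i]]++] = i;
  std::vector<double> xs(n), ys(n), zs(n);
  for (int k = 0; k < n; ++k) {
    int i = idx[k];
    xs[k] = x[i]; ys[k] = y[i]; zs[k] = z[i];
  }
  for (int iz = 0; iz < nc; ++iz)
    for (int iy = 0; iy < nc; ++iy)
      for (int ix = 0; ix < nc; ++ix) {
        const int c = (iz * nc + iy) * nc + ix;
        const int a0 = start[c], a1 = start[c + 1];
        for (int a = a0; a < a1; ++a)
          for (int b = a + 1; b < a1; ++b) {
            double dx = xs[a] - xs[b], dy = ys[a] - ys[b],
                   dz = zs[a] - zs[b];
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 < rc2) fun(idx[a], idx[b], dx, dy, dz, r2, 0.0);
          }
        for (int k = 0; k < 13; ++k) {
          int jx = ix + HALF_OFF[k][0];
          int jy = iy + HALF_OFF[k][1];
          int jz = iz + HALF_OFF[k][2];
          double sx = 0, sy = 0, sz = 0;  // image shift applied to j
          if (jx < 0) { jx += nc; sx = -L; }
          else if (jx >= nc) { jx -= nc; sx = L; }
          if (jy < 0 || jy >= nc) {
            if (le) continue;             // boundary pass instead
            if (jy < 0) { jy += nc; sy = -L; } else { jy -= nc; sy = L; }
          }
          if (jz < 0) { jz += nc; sz = -L; }
          else if (jz >= nc) { jz -= nc; sz = L; }
          const int c2 = (jz * nc + jy) * nc + jx;
          const int b0 = start[c2], b1e = start[c2 + 1];
          for (int a = a0; a < a1; ++a) {
            const double ax = xs[a] - sx, ay = ys[a] - sy, az = zs[a] - sz;
            for (int b = b0; b < b1e; ++b) {
              double dx = ax - xs[b], dy = ay - ys[b], dz = az - zs[b];
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 < rc2) fun(idx[a], idx[b], dx, dy, dz, r2, 0.0);
            }
          }
        }
      }
  if (le) {
    // pairs across the sheared y boundary: rows 0 and nc-1 (with nc >= 3
    // no within-cutoff pair between these rows exists without wrapping)
    std::vector<int> lo, hi;
    for (int iz = 0; iz < nc; ++iz)
      for (int ix = 0; ix < nc; ++ix) {
        int c = (iz * nc + 0) * nc + ix;
        for (int a = start[c]; a < start[c + 1]; ++a) lo.push_back(idx[a]);
        c = (iz * nc + (nc - 1)) * nc + ix;
        for (int a = start[c]; a < start[c + 1]; ++a) hi.push_back(idx[a]);
      }
    for (size_t a = 0; a < hi.size(); ++a)
      for (size_t b = 0; b < lo.size(); ++b) {
        int i = hi[a], j = lo[b];
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        double cy = std::nearbyint(dy / L);
        dy -= cy * L;
        dx -= cy * off;
        dx -= L * std::nearbyint(dx / L);
        dz -= L * std::nearbyint(dz / L);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < rc2) fun(i, j, dx, dy, dz, r2, cy * gL);
      }
  }
}

// [[Rcpp::export]]
double cpp_pair_noise(double seed, double step, int i, int j) {
  uint64_t a = (uint64_t)i, b = (uint64_t)j;
  if (a > b) std::swap(a, b);
  return pair_noise((uint64_t)seed, (uint64_t)step, a, b);
}

// [[Rcpp::export]]
NumericMatrix cpp_pairs(NumericMatrix pos, double L, double rcut,
                        double offset) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i,0); y[i] = pos(i,1); z[i] = pos(i,2); }
  bool le = offset != 0.0;
  std::vector<double> rows;
  for_each_pair(x.data(), y.data(), z.data(), n, L, rcut, offset, le, 0.0,
    [&](int i, int j, double dx, double dy, double dz, double r2, double) {
      rows.push_back(i + 1); rows.push_back(j + 1);
      rows.push_back(dx); rows.push_back(dy); rows.push_back(dz);
      rows.push_back(std::sqrt(r2));
    });
  int m = (int)(rows.size() / 6);
  NumericMatrix out(m, 6);
  for (int k = 0; k < m; ++k)
    for (int c = 0; c < 6; ++c) out(k, c) = rows[(size_t)k * 6 + c];
  colnames(out) = CharacterVector::create("i", "j", "dx", "dy", "dz", "r");
  return out;
}

struct ForceCtx {
  int n;
  std::vector<double> fx, fy, fz;
  double virial;          // conservative + spring only
  bool warned_overlap;
  void reset(int n_) {
    n = n_;
    fx.assign(n, 0.0); fy.assign(n, 0.0); fz.assign(n, 0.0);
    virial = 0.0;
    warned_overlap = false;
  }
};

// One full force evaluation at given positions/velocities.
static void compute_forces(const double *x, const double *y, const double *z,
                           const double *vx, const double *vy,
                           const double *vz,
                           const int *sp, const double *amat, int nsp,
                           const int *b1, const int *b2, int nb,
                           double eta, double sigma, double springC,
                           double L, double off, bool le, double gL,
                           double inv_sqrt_dt, uint64_t seed, uint64_t step,
                           ForceCtx &ctx) {
  const bool noise_on = sigma != 0.0;
  for_each_pair(x, y, z, ctx.n, L, 1.0, off, le, gL,
    [&](int i, int j, double dx, double dy, double dz, double r2,
        double dvx_im) {
      if (r2 < 1e-24) {
        if (!ctx.warned_overlap) {
          Rf_warning("coincident beads: conservative force set to zero");
          ctx.warned_overlap = true;
        }
        return;
      }
      double r = std::sqrt(r2);
      double inv_r = 1.0 / r;
      double ex = dx * inv_r, ey = dy * inv_r, ez = dz * inv_r;
      double w = 1.0 - r;
      double a = amat[sp[i] * nsp + sp[j]];
      double fc = a * w;
      ctx.virial += fc * r;
      double dvx = vx[i] - vx[j] - dvx_im,
             dvy = vy[i] - vy[j], dvz = vz[i] - vz[j];
      double ev = ex * dvx + ey * dvy + ez * dvz;
      double f = fc - eta * w * w * ev;
      if (noise_on) {
        uint64_t a0 = (uint64_t)i, b0 = (uint64_t)j;
        if (a0 > b0) std::swap(a0, b0);
        f += sigma * w * pair_noise(seed, step, a0, b0) * inv_sqrt_dt;
      }
      double gx = f * ex, gy = f * ey, gz = f * ez;
      ctx.fx[i] += gx; ctx.fy[i] += gy; ctx.fz[i] += gz;
      ctx.fx[j] -= gx; ctx.fy[j] -= gy; ctx.fz[j] -= gz;
    });
  for (int k = 0; k < nb; ++k) {
    int i = b1[k], j = b2[k];
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    min_image(dx, dy, dz, L, off);
    double gx = -springC * dx, gy = -springC * dy, gz = -springC * dz;
    ctx.fx[i] += gx; ctx.fy[i] += gy; ctx.fz[i] += gz;
    ctx.fx[j] -= gx; ctx.fy[j] -= gy; ctx.fz[j] -= gz;
    ctx.virial += dx * gx + dy * gy + dz * gz;
  }
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericMatrix vel, IntegerVector species0,
                NumericMatrix a, IntegerMatrix bonds0, double eta,
                double sigma, double springC, double L, double offset,
                double shear_rate, double dt, double seed, double step,
                bool fdt_scaling = true) {
  int n = pos.nrow(), nsp = a.nrow(), nb = bonds0.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i,0); y[i] = pos(i,1); z[i] = pos(i,2);
    vx[i] = vel(i,0); vy[i] = vel(i,1); vz[i] = vel(i,2);
  }
  std::vector<double> am((size_t)nsp * nsp);
  for (int i = 0; i < nsp; ++i)
    for (int j = 0; j < nsp; ++j) am[(size_t)i * nsp + j] = a(i, j);
  std::vector<int> b1(nb), b2(nb);
  for (int k = 0; k < nb; ++k) { b1[k] = bonds0(k,0); b2[k] = bonds0(k,1); }
  bool le = (offset != 0.0) || (shear_rate != 0.0);
  double isd = fdt_scaling ? 1.0 / std::sqrt(dt) : 1.0;
  ForceCtx ctx; ctx.reset(n);
  compute_forces(x.data(), y.data(), z.data(), vx.data(), vy.data(),
                 vz.data(), species0.begin(), am.data(), nsp,
                 b1.data(), b2.data(), nb, eta, sigma, springC, L, offset,
                 le, shear_rate * L, isd, (uint64_t)seed, (uint64_t)step,
                 ctx);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) {
    F(i,0) = ctx.fx[i]; F(i,1) = ctx.fy[i]; F(i,2) = ctx.fz[i];
  }
  return List::create(_["forces"] = F, _["virial"] = ctx.virial);
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, NumericMatrix unw,
             IntegerVector species0, NumericMatrix a, IntegerMatrix bonds0,
             double eta, double sigma, double springC, double L, double dt,
             int n_steps, double lambda, double shear_rate, double offset0,
             double time0, double seed, double step0, int thermo_every,
             int traj_every, bool record_frames, bool fdt_scaling = true) {
  int n = pos.nrow(), nsp = a.nrow(), nb = bonds0.nrow();
  if (dt <= 0) stop("dt must be positive");
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n),
      ux(n), uy(n), uz(n), vpx(n), vpy(n), vpz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i,0); y[i] = pos(i,1); z[i] = pos(i,2);
    vx[i] = vel(i,0); vy[i] = vel(i,1); vz[i] = vel(i,2);
    ux[i] = unw(i,0); uy[i] = unw(i,1); uz[i] = unw(i,2);
  }
  std::vector<double> am((size_t)nsp * nsp);
  for (int i = 0; i < nsp; ++i)
    for (int j = 0; j < nsp; ++j) am[(size_t)i * nsp + j] = a(i, j);
  std::vector<int> b1(nb), b2(nb);
  for (int k = 0; k < nb; ++k) { b1[k] = bonds0(k,0); b2[k] = bonds0(k,1); }
  const bool le = (shear_rate != 0.0) || (offset0 != 0.0);
  const double isd = fdt_scaling ? 1.0 / std::sqrt(dt) : 1.0;
  const uint64_t useed = (uint64_t)seed;
  double offset = offset0;
  const double V = L * L * L;
  const double rho = n / V;
  const double gL = shear_rate * L;

  ForceCtx ctx; ctx.reset(n);
  compute_forces(x.data(), y.data(), z.data(), vx.data(), vy.data(),
                 vz.data(), species0.begin(), am.data(), nsp, b1.data(),
                 b2.data(), nb, eta, sigma, springC, L, offset, le, gL,
                 isd, useed, (uint64_t)step0, ctx);
  std::vector<double> fx = ctx.fx, fy = ctx.fy, fz = ctx.fz;
  double virial = ctx.virial;

  std::vector<double> th_step, th_time, th_T, th_P, th_px, th_py, th_pz;
  auto sample_thermo = [&](double step_now, double time_now) {
    double ke2 = 0.0, px = 0.0, py = 0.0, pz = 0.0;
    for (int i = 0; i < n; ++i) {
      double wx = vx[i];
      if (le) wx -= shear_rate * (y[i] - 0.5 * L);  // peculiar velocity
      ke2 += wx * wx + vy[i] * vy[i] + vz[i] * vz[i];
      px += vx[i]; py += vy[i]; pz += vz[i];
    }
    double T = ke2 / (3.0 * n - 3.0);
    th_step.push_back(step_now); th_time.push_back(time_now);
    th_T.push_back(T);
    th_P.push_back(rho * T + virial / (3.0 * V));
    th_px.push_back(px); th_py.push_back(py); th_pz.push_back(pz);
  };
  List fr_pos, fr_unw, fr_vel;
  std::vector<double> fr_step, fr_time, fr_off;
  auto snapshot = [&](double step_now, double time_now) {
    NumericMatrix P(n, 3), U(n, 3), W(n, 3);
    for (int i = 0; i < n; ++i) {
      P(i,0) = x[i]; P(i,1) = y[i]; P(i,2) = z[i];
      U(i,0) = ux[i]; U(i,1) = uy[i]; U(i,2) = uz[i];
      W(i,0) = vx[i]; W(i,1) = vy[i]; W(i,2) = vz[i];
    }
    fr_pos.push_back(P); fr_unw.push_back(U); fr_vel.push_back(W);
    fr_step.push_back(step_now); fr_time.push_back(time_now);
    fr_off.push_back(offset);
  };
  if (thermo_every > 0) sample_thermo(step0, time0);
  if (record_frames && traj_every > 0) snapshot(step0, time0);

  const double h2 = 0.5 * dt * dt, lh = lambda * dt, hh = 0.5 * dt;
  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n; ++i) {
      double dxi = dt * vx[i] + h2 * fx[i];
      double dyi = dt * vy[i] + h2 * fy[i];
      double dzi = dt * vz[i] + h2 * fz[i];
      x[i] += dxi; y[i] += dyi; z[i] += dzi;
      ux[i] += dxi; uy[i] += dyi; uz[i] += dzi;
      vpx[i] = vx[i] + lh * fx[i];
      vpy[i] = vy[i] + lh * fy[i];
      vpz[i] = vz[i] + lh * fz[i];
    }
    if (shear_rate != 0.0) {
      offset += gL * dt;
      offset -= L * std::floor(offset / L);
    }
    for (int i = 0; i < n; ++i) {
      while (y[i] >= L) {
        y[i] -= L;
        if (le) { x[i] -= offset; ux[i] -= offset; vx[i] -= gL; vpx[i] -= gL; }
      }
      while (y[i] < 0) {
        y[i] += L;
        if (le) { x[i] += offset; ux[i] += offset; vx[i] += gL; vpx[i] += gL; }
      }
      x[i] -= L * std::floor(x[i] / L);
      z[i] -= L * std::floor(z[i] / L);
    }
    ctx.reset(n);
    compute_forces(x.data(), y.data(), z.data(), vpx.data(), vpy.data(),
                   vpz.data(), species0.begin(), am.data(), nsp, b1.data(),
                   b2.data(), nb, eta, sigma, springC, L, offset, le, gL,
                   isd, useed, (uint64_t)(step0 + s), ctx);
    virial = ctx.virial;
    bool bad = false;
    for (int i = 0; i < n; ++i) {
      vx[i] += hh * (fx[i] + ctx.fx[i]);
      vy[i] += hh * (fy[i] + ctx.fy[i]);
      vz[i] += hh * (fz[i] + ctx.fz[i]);
      fx[i] = ctx.fx[i]; fy[i] = ctx.fy[i]; fz[i] = ctx.fz[i];
      if (!std::isfinite(x[i]) || !std::isfinite(vx[i])) bad = true;
    }
    if (bad)
      stop("non-finite coordinate or velocity at step %d", (int)(step0 + s));
    double time_now = time0 + s * dt;
    if (thermo_every > 0 && s % thermo_every == 0)
      sample_thermo(step0 + s, time_now);
    if (record_frames && traj_every > 0 && s % traj_every == 0)
      snapshot(step0 + s, time_now);
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix P(n, 3), Vl(n, 3), U(n, 3);
  for (int i = 0; i < n; ++i) {
    P(i,0) = x[i]; P(i,1) = y[i]; P(i,2) = z[i];
    Vl(i,0) = vx[i]; Vl(i,1) = vy[i]; Vl(i,2) = vz[i];
    U(i,0) = ux[i]; U(i,1) = uy[i]; U(i,2) = uz[i];
  }
  DataFrame thermo = DataFrame::create(
      _["step"] = th_step, _["time"] = th_time,
      _["temperature"] = th_T, _["pressure"] = th_P,
      _["px"] = th_px, _["py"] = th_py, _["pz"] = th_pz);
  return List::create(
      _["positions"] = P, _["velocities"] = Vl, _["unwrapped"] = U,
      _["shear_offset"] = offset, _["time"] = time0 + n_steps * dt,
      _["thermo"] = thermo,
      _["frames"] = List::create(_["step"] = fr_step, _["time"] = fr_time,
                                 _["shear_offset"] = fr_off,
                                 _["positions"] = fr_pos,
                                 _["unwrapped"] = fr_unw,
                                 _["velocities"] = fr_vel));
}
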