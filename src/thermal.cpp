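// Explicit forward-Euler bioheat solver: 7-point conduction stencil with
// harmonic-mean face conductivities, optional Pennes perfusion sink,
// duty-cycled volumetric source, selectable boundary handling.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// boundary codes: 0 insulated, 1 fixed T_fixed, 2 convective (h, T_amb),
// 3 mixed (top face convective, all other faces fixed)
// [[Rcpp::export(name = ".fd_bioheat")]]
List fd_bioheat(IntegerVector labels, IntegerVector dims, double dx,
                NumericVector rho, NumericVector cp, NumericVector kcond,
                NumericVector perf, NumericVector baseline,
                NumericVector source, double dt, int n_steps,
                int sched_mode, double period_s, double pulse_s,
                int bc_code, double h_conv, double T_amb, double T_fixed,
                double T_blood, bool use_perfusion,
                IntegerMatrix probes, int store_every) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const std::size_t nvox = (std::size_t)nx * ny * nz;
  std::vector<double> T(nvox), Tn(nvox);
  std::vector<double> vk(nvox), vrc(nvox), vq(nvox), vwb(nvox);
  std::vector<char> active(nvox);
  for (std::size_t i = 0; i < nvox; ++i) {
    int lab = labels[i];
    active[i] = lab != 0; // background voxels are inactive
    T[i] = baseline[lab];
    vk[i] = kcond[lab];
    vrc[i] = rho[lab] * cp[lab];
    vq[i] = source[i];
    vwb[i] = use_perfusion ? rho[lab] * cp[lab] * perf[lab] : 0.0;
  }
  const int n_probes = probes.nrow();
  NumericMatrix probe_trace(n_steps + 1, n_probes);
  std::vector<std::size_t> pidx(n_probes);
  for (int p = 0; p < n_probes; ++p) {
    pidx[p] = (probes(p, 0) - 1) +
              (std::size_t)nx * ((probes(p, 1) - 1) +
                                 (std::size_t)ny * (probes(p, 2) - 1));
    probe_trace(0, p) = T[pidx[p]];
  }
  int n_stored = (store_every > 0) ? n_steps / store_every : 0;
  NumericMatrix stored(n_stored > 0 ? nvox : 1, std::max(n_stored, 1));
  NumericVector stored_times(std::max(n_stored, 1));
  int store_ct = 0;

  auto face_flux = [&](std::size_t i, std::size_t j) {
    // conduction flux density (W/m^3 contribution) from neighbor j into i
    double kf = 2.0 * vk[i] * vk[j] / (vk[i] + vk[j]);
    return kf * (T[j] - T[i]) / (dx * dx);
  };
  auto boundary_term = [&](std::size_t i, bool is_top) {
    int code = bc_code;
    if (bc_code == 3) code = is_top ? 2 : 1;
    if (code == 0) return 0.0;                       // insulated
    if (code == 1) return vk[i] * (T_fixed - T[i]) / (dx * dx);
    return h_conv * (T_amb - T[i]) / dx;             // convective
  };

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    bool on = true;
    if (sched_mode == 1) {
      double cycles = t / period_s;
      double phase = (cycles - std::floor(cycles + 1e-9)) * period_s;
      on = phase < pulse_s - 1e-9 * period_s;
    }
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix) {
          std::size_t i = ix + (std::size_t)nx * (iy + (std::size_t)ny * iz);
          if (!active[i]) { Tn[i] = T[i]; continue; }
          double acc = 0.0;
          // six faces; inactive or out-of-grid neighbors take the boundary rule
          const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
          for (int f = 0; f < 6; ++f) {
            int jx = ix + off[f][0], jy = iy + off[f][1], jz = iz + off[f][2];
            bool inside = jx >= 0 && jx < nx && jy >= 0 && jy < ny &&
                          jz >= 0 && jz < nz;
            std::size_t j = inside ? jx + (std::size_t)nx * (jy + (std::size_t)ny * jz) : 0;
            if (inside && active[j]) acc += face_flux(i, j);
            else acc += boundary_term(i, f == 4); // face toward -z = illuminated top
          }
          if (on) acc += vq[i];
          acc -= vwb[i] * (T[i] - T_blood);
          Tn[i] = T[i] + dt * acc / vrc[i];
        }
    std::swap(T, Tn);
    for (int p = 0; p < n_probes; ++p) probe_trace(step + 1, p) = T[pidx[p]];
    if (store_every > 0 && (step + 1) % store_every == 0 && store_ct < n_stored) {
      for (std::size_t i = 0; i < nvox; ++i) stored(i, store_ct) = T[i];
      stored_times[store_ct] = (step + 1) * dt;
      ++store_ct;
    }
  }
  NumericVector final_field(nvox);
  for (std::size_t i = 0; i < nvox; ++i) final_field[i] = T[i];
  return List::create(_["probe_trace"] = probe_trace,
                      _["final"] = final_field,
                      _["stored"] = stored,
                      _["stored_times"] = stored_times,
                      _["n_stored"] = store_ct);
}
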