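#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Explicit FTCS integration of the cleft diffusion problem on a quarter
// unit cell (reflecting lateral boundaries exploit the 4-fold symmetry of
// the centred-disk periodic problem).
//
// Field convention: the integrated field is the ligand density phi (the
// negated concentration of the model's sign convention), so the source disk
// injects at rate u(t) and the sink disk absorbs with phi = 0 on its face.
//
// src_w, snk_w: per-lateral-cell weights in [0,1] (area fraction of the cell
// covered by the respective disk), flattened j*nx + i. u_steps holds the
// per-step average source flux density, already rescaled so that the
// discrete injected total matches pi*R^2 * int u dt exactly.
//
// Returns J(t) sampled every out_every steps (value at the step's start
// time, from the pre-update field), plus the cumulative absorbed amount and
// the final resident mass for the conservation audit. All reported
// quantities are per full unit cell (quarter-cell sums times 4).
// [[Rcpp::export]]
List fd_run_cpp(int nx, int ny, int nz,
                double dx, double dy, double dz,
                double D, double dt,
                NumericVector src_w, NumericVector snk_w,
                NumericVector u_steps, int out_every) {
  const int n_steps = u_steps.size();
  const size_t plane = (size_t)nx * ny;
  const size_t ncell = plane * nz;
  std::vector<double> C(ncell, 0.0), Cn(ncell, 0.0);
  const double ax = D * dt / (dx * dx);
  const double ay = D * dt / (dy * dy);
  const double az = D * dt / (dz * dz);
  const double cell_area = dx * dy;

  double src_cells_eff = 0.0;
  std::vector<size_t> src_id, snk_id;
  std::vector<double> src_v, snk_v;
  for (size_t q = 0; q < plane; ++q) {
    if (src_w[q] > 0.0) { src_id.push_back(q); src_v.push_back(src_w[q]); }
    if (snk_w[q] > 0.0) { snk_id.push_back(q); snk_v.push_back(snk_w[q]); }
    src_cells_eff += src_w[q];
  }

  std::vector<double> out_t, out_J;
  out_t.reserve(n_steps / out_every + 2);
  out_J.reserve(n_steps / out_every + 2);
  double absorbed = 0.0, injected = 0.0;
  const size_t topo = (size_t)(nz - 1) * plane;

  for (int step = 0; step < n_steps; ++step) {
    // instantaneous absorption flux from the current field
    double Jnow = 0.0;
    for (size_t q = 0; q < snk_id.size(); ++q) {
      Jnow += snk_v[q] * C[topo + snk_id[q]];
    }
    Jnow *= 2.0 * D / dz * cell_area * 4.0;
    if (step % out_every == 0) {
      out_t.push_back(step * dt);
      out_J.push_back(Jnow);
    }

    // interior diffusion with reflecting (Neumann) lateral walls; a missing
    // neighbour is replaced by the cell itself (mirror), giving a zero term
    for (int k = 0; k < nz; ++k) {
      const double* Ck = &C[(size_t)k * plane];
      const double* Ckm = (k > 0) ? Ck - plane : Ck;
      const double* Ckp = (k < nz - 1) ? Ck + plane : Ck;
      for (int j = 0; j < ny; ++j) {
        const double* Cj = Ck + (size_t)j * nx;
        const double* Cjm = (j > 0) ? Cj - nx : Cj;
        const double* Cjp = (j < ny - 1) ? Cj + nx : Cj;
        const double* Zm = Ckm + (size_t)j * nx;
        const double* Zp = Ckp + (size_t)j * nx;
        double* out = &Cn[(size_t)k * plane + (size_t)j * nx];
        const int ilast = nx - 1;
        {
          const double c = Cj[0];
          out[0] = c + ax * (Cj[1] - c) +
            ay * (Cjm[0] - 2.0 * c + Cjp[0]) +
            az * (Zm[0] - 2.0 * c + Zp[0]);
        }
        for (int i = 1; i < ilast; ++i) {
          const double c = Cj[i];
          out[i] = c + ax * (Cj[i - 1] - 2.0 * c + Cj[i + 1]) +
            ay * (Cjm[i] - 2.0 * c + Cjp[i]) +
            az * (Zm[i] - 2.0 * c + Zp[i]);
        }
        {
          const double c = Cj[ilast];
          out[ilast] = c + ax * (Cj[ilast - 1] - c) +
            ay * (Cjm[ilast] - 2.0 * c + Cjp[ilast]) +
            az * (Zm[ilast] - 2.0 * c + Zp[ilast]);
        }
      }
    }

    // source influx through the bottom face (z = 0)
    const double u = u_steps[step];
    if (u != 0.0) {
      for (size_t q = 0; q < src_id.size(); ++q) {
        Cn[src_id[q]] += dt * u * src_v[q] / dz;
      }
      injected += u * src_cells_eff * cell_area * 4.0 * dt;
    }
    // absorbing sink on the top face (z = Lz): Dirichlet phi = 0 on the
    // covered area fraction, applied as a half-cell gradient
    for (size_t q = 0; q < snk_id.size(); ++q) {
      Cn[topo + snk_id[q]] -=
        dt * 2.0 * D / (dz * dz) * snk_v[q] * C[topo + snk_id[q]];
    }
    absorbed += Jnow * dt;
    C.swap(Cn);
  }

  // closing sample at t_end
  double Jend = 0.0;
  for (size_t q = 0; q < snk_id.size(); ++q) {
    Jend += snk_v[q] * C[topo + snk_id[q]];
  }
  Jend *= 2.0 * D / dz * cell_area * 4.0;
  out_t.push_back(n_steps * dt);
  out_J.push_back(Jend);

  double mass = 0.0;
  for (size_t id = 0; id < ncell; ++id) mass += C[id];
  mass *= dx * dy * dz * 4.0;

  return List::create(_["times"] = out_t, _["J"] = out_J,
                      _["absorbed"] = absorbed, _["injected"] = injected,
                      _["mass_end"] = mass);
}
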