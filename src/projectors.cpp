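#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Circular cone-beam geometry conventions (shared with the R side):
//  * volume: N x N x N array, index (ix,iy,iz) 0-based here; world position of a
//    voxel centre is ((i - (N-1)/2) * vs) in mm, volume centred on the rotation axis.
//  * source at angle b: S = (-Rs cos b, -Rs sin b, 0); detector centre C = (Rd cos b,
//    Rd sin b, 0); detector axes e_u = (-sin b, cos b, 0) (transaxial columns) and
//    e_v = (0,0,1) (axial rows). u = v = 0 at the detector centre.
//  * projections: nu x nv x Na array, u fastest.
//  * volumes hold attenuation in 1/cm while lengths are mm, so accumulated path
//    lengths are converted mm -> cm (factor 0.1) to keep -ln(I/I0) dimensionless.

static const double MM_TO_CM = 0.1;

// slab intersection of ray S + t*d with the cube [-h,h]^3; returns false if missed
static inline bool box_range(const double S[3], const double d[3], double h,
                             double &t0, double &t1) {
  t0 = -1e30; t1 = 1e30;
  for (int ax = 0; ax < 3; ++ax) {
    if (std::fabs(d[ax]) < 1e-12) {
      if (S[ax] < -h || S[ax] > h) return false;
    } else {
      double ta = (-h - S[ax]) / d[ax], tb = (h - S[ax]) / d[ax];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  return t1 > t0;
}

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, int N, double vs,
                                  NumericVector angles, int nu, int nv,
                                  double ps, double Rs, double Rd,
                                  double step_frac) {
  const int Na = angles.size();
  NumericVector out(static_cast<R_xlen_t>(nu) * nv * Na);
  const double *V = vol.begin();
  const double h = 0.5 * N * vs;
  const double c0 = 0.5 * (N - 1);
  const double cu = 0.5 * (nu - 1), cv = 0.5 * (nv - 1);
  const double base_dt = step_frac * vs;

  for (int a = 0; a < Na; ++a) {
    const double cb = std::cos(angles[a]), sb = std::sin(angles[a]);
    const double S[3] = { -Rs * cb, -Rs * sb, 0.0 };
    const double C[3] = { Rd * cb, Rd * sb, 0.0 };
    const double eu[3] = { -sb, cb, 0.0 };
    double *page = out.begin() + static_cast<R_xlen_t>(a) * nu * nv;
    for (int jv = 0; jv < nv; ++jv) {
      const double v = (jv - cv) * ps;
      for (int ju = 0; ju < nu; ++ju) {
        const double u = (ju - cu) * ps;
        double P[3] = { C[0] + u * eu[0], C[1] + u * eu[1], v };
        double d[3] = { P[0] - S[0], P[1] - S[1], P[2] - S[2] };
        const double nrm = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
        d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
        double t0, t1;
        if (!box_range(S, d, h, t0, t1)) continue;
        const int nst = (int)std::ceil((t1 - t0) / base_dt);
        const double dt = (t1 - t0) / nst;
        double gx = (S[0] + (t0 + 0.5 * dt) * d[0]) / vs + c0;
        double gy = (S[1] + (t0 + 0.5 * dt) * d[1]) / vs + c0;
        double gz = (S[2] + (t0 + 0.5 * dt) * d[2]) / vs + c0;
        const double dgx = dt * d[0] / vs, dgy = dt * d[1] / vs,
                     dgz = dt * d[2] / vs;
        double acc = 0.0;
        for (int s = 0; s < nst; ++s, gx += dgx, gy += dgy, gz += dgz) {
          const int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
                    k0 = (int)std::floor(gz);
          const double fx = gx - i0, fy = gy - j0, fz = gz - k0;
          if (i0 >= 0 && i0 < N - 1 && j0 >= 0 && j0 < N - 1 &&
              k0 >= 0 && k0 < N - 1) {
            const double *p000 = V + (static_cast<R_xlen_t>(k0) * N + j0) * N + i0;
            const double *p010 = p000 + N;
            const double *p001 = p000 + static_cast<R_xlen_t>(N) * N;
            const double *p011 = p001 + N;
            acc += (1 - fz) * ((1 - fy) * ((1 - fx) * p000[0] + fx * p000[1]) +
                               fy * ((1 - fx) * p010[0] + fx * p010[1])) +
                   fz * ((1 - fy) * ((1 - fx) * p001[0] + fx * p001[1]) +
                         fy * ((1 - fx) * p011[0] + fx * p011[1]));
          } else if (i0 >= -1 && i0 <= N - 1 && j0 >= -1 && j0 <= N - 1 &&
                     k0 >= -1 && k0 <= N - 1) {
            for (int dk = 0; dk < 2; ++dk) {
              const int k = k0 + dk;
              if (k < 0 || k >= N) continue;
              const double wz = dk ? fz : 1.0 - fz;
              for (int dj = 0; dj < 2; ++dj) {
                const int j = j0 + dj;
                if (j < 0 || j >= N) continue;
                const double wyz = wz * (dj ? fy : 1.0 - fy);
                for (int di = 0; di < 2; ++di) {
                  const int i = i0 + di;
                  if (i < 0 || i >= N) continue;
                  acc += wyz * (di ? fx : 1.0 - fx) *
                    V[(static_cast<R_xlen_t>(k) * N + j) * N + i];
                }
              }
            }
          }
        }
        page[static_cast<R_xlen_t>(jv) * nu + ju] = acc * dt * MM_TO_CM;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nu, nv, Na);
  return out;
}

// exact transpose of cpp_forward_project (same rays, same samples, scatter adds)
// [[Rcpp::export]]
NumericVector cpp_backproject_matched(NumericVector proj, int N, double vs,
                                      NumericVector angles, int nu, int nv,
                                      double ps, double Rs, double Rd,
                                      double step_frac) {
  const int Na = angles.size();
  NumericVector out(static_cast<R_xlen_t>(N) * N * N);
  double *V = out.begin();
  const double h = 0.5 * N * vs;
  const double c0 = 0.5 * (N - 1);
  const double cu = 0.5 * (nu - 1), cv = 0.5 * (nv - 1);
  const double base_dt = step_frac * vs;

  for (int a = 0; a < Na; ++a) {
    const double cb = std::cos(angles[a]), sb = std::sin(angles[a]);
    const double S[3] = { -Rs * cb, -Rs * sb, 0.0 };
    const double C[3] = { Rd * cb, Rd * sb, 0.0 };
    const double eu[3] = { -sb, cb, 0.0 };
    const double *page = proj.begin() + static_cast<R_xlen_t>(a) * nu * nv;
    for (int jv = 0; jv < nv; ++jv) {
      const double v = (jv - cv) * ps;
      for (int ju = 0; ju < nu; ++ju) {
        const double u = (ju - cu) * ps;
        const double val0 = page[static_cast<R_xlen_t>(jv) * nu + ju];
        double P[3] = { C[0] + u * eu[0], C[1] + u * eu[1], v };
        double d[3] = { P[0] - S[0], P[1] - S[1], P[2] - S[2] };
        const double nrm = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
        d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
        double t0, t1;
        if (!box_range(S, d, h, t0, t1)) continue;
        const int nst = (int)std::ceil((t1 - t0) / base_dt);
        const double dt = (t1 - t0) / nst;
        const double val = val0 * dt * MM_TO_CM;
        if (val == 0.0) continue;
        // sample positions must match cpp_forward_project exactly (transpose)
        double gx = (S[0] + (t0 + 0.5 * dt) * d[0]) / vs + c0;
        double gy = (S[1] + (t0 + 0.5 * dt) * d[1]) / vs + c0;
        double gz = (S[2] + (t0 + 0.5 * dt) * d[2]) / vs + c0;
        const double dgx = dt * d[0] / vs, dgy = dt * d[1] / vs,
                     dgz = dt * d[2] / vs;
        for (int s = 0; s < nst; ++s, gx += dgx, gy += dgy, gz += dgz) {
          const int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
                    k0 = (int)std::floor(gz);
          const double fx = gx - i0, fy = gy - j0, fz = gz - k0;
          if (i0 >= 0 && i0 < N - 1 && j0 >= 0 && j0 < N - 1 &&
              k0 >= 0 && k0 < N - 1) {
            double *p000 = V + (static_cast<R_xlen_t>(k0) * N + j0) * N + i0;
            double *p010 = p000 + N;
            double *p001 = p000 + static_cast<R_xlen_t>(N) * N;
            double *p011 = p001 + N;
            p000[0] += val * (1 - fz) * (1 - fy) * (1 - fx);
            p000[1] += val * (1 - fz) * (1 - fy) * fx;
            p010[0] += val * (1 - fz) * fy * (1 - fx);
            p010[1] += val * (1 - fz) * fy * fx;
            p001[0] += val * fz * (1 - fy) * (1 - fx);
            p001[1] += val * fz * (1 - fy) * fx;
            p011[0] += val * fz * fy * (1 - fx);
            p011[1] += val * fz * fy * fx;
          } else if (i0 >= -1 && i0 <= N - 1 && j0 >= -1 && j0 <= N - 1 &&
                     k0 >= -1 && k0 <= N - 1) {
            for (int dk = 0; dk < 2; ++dk) {
              const int k = k0 + dk;
              if (k < 0 || k >= N) continue;
              const double wz = dk ? fz : 1.0 - fz;
              for (int dj = 0; dj < 2; ++dj) {
                const int j = j0 + dj;
                if (j < 0 || j >= N) continue;
                const double wyz = wz * (dj ? fy : 1.0 - fy);
                for (int di = 0; di < 2; ++di) {
                  const int i = i0 + di;
                  if (i < 0 || i >= N) continue;
                  V[(static_cast<R_xlen_t>(k) * N + j) * N + i] +=
                    val * wyz * (di ? fx : 1.0 - fx);
                }
              }
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(N, N, N);
  return out;
}

// voxel-driven backprojection with bilinear detector interpolation; weighted = true
// applies the Feldkamp distance weight (Rs / (Rs + s))^2, s the voxel coordinate
// along the source-to-centre axis. Normalisation (angular step, detector pitch) is
// applied by the R wrapper.
// [[Rcpp::export]]
NumericVector cpp_backproject_voxel(NumericVector proj, int N, double vs,
                                    NumericVector angles, int nu, int nv,
                                    double ps, double Rs, double Rd,
                                    bool weighted) {
  const int Na = angles.size();
  NumericVector out(static_cast<R_xlen_t>(N) * N * N);
  double *V = out.begin();
  const double c0 = 0.5 * (N - 1);
  const double cu = 0.5 * (nu - 1), cv = 0.5 * (nv - 1);
  const double D = Rs + Rd;

  for (int a = 0; a < Na; ++a) {
    const double cb = std::cos(angles[a]), sb = std::sin(angles[a]);
    const double *page = proj.begin() + static_cast<R_xlen_t>(a) * nu * nv;
    for (int iy = 0; iy < N; ++iy) {
      const double y = (iy - c0) * vs;
      for (int ix = 0; ix < N; ++ix) {
        const double x = (ix - c0) * vs;
        const double tax = x * cb + y * sb + Rs;       // distance along optical axis
        if (tax <= 1e-9) continue;
        const double f = D / tax;
        const double gu = (f * (-x * sb + y * cb)) / ps + cu;
        const int iu0 = (int)std::floor(gu);
        if (iu0 < -1 || iu0 >= nu) continue;
        const double fu = gu - iu0;
        const double w = weighted ? (Rs / tax) * (Rs / tax) : 1.0;
        const double zfac = f * vs / ps;
        const double gv_base = (-c0 * vs) * f / ps + cv;
        double *col = V + (static_cast<R_xlen_t>(iy) * N + ix);
        for (int iz = 0; iz < N; ++iz) {
          const double gv = gv_base + iz * zfac;
          const int iv0 = (int)std::floor(gv);
          if (iv0 < -1 || iv0 >= nv) continue;
          const double fv = gv - iv0;
          double val = 0.0;
          for (int dv = 0; dv < 2; ++dv) {
            const int jv = iv0 + dv;
            if (jv < 0 || jv >= nv) continue;
            const double wv = dv ? fv : 1.0 - fv;
            const double *row = page + static_cast<R_xlen_t>(jv) * nu;
            if (iu0 >= 0)       val += wv * (1.0 - fu) * row[iu0];
            if (iu0 + 1 < nu)   val += wv * fu * row[iu0 + 1];
          }
          col[static_cast<R_xlen_t>(iz) * N * N] += w * val;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(N, N, N);
  return out;
}
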