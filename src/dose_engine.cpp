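// Analytic broad-beam 6 MV photon dose kernel.
//
// D(v) = weight * ((SAD + dmax) / r)^2 * PDD(d_eff) * F(u, v)
//   r      source-to-voxel distance
//   d_eff  radiological depth: density line integral along the source ray,
//          ray-marched with a fixed step
//   PDD    linear build-up to 1 at dmax, then exp(-mu (d - dmax))
//   F      aperture fluence: transmission + (1 - transmission) * open
//          fraction, with error-function edges of width sigma at the
//          projected jaw and MLC edges (isocenter-plane coordinates)

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double edge(double a, double invs) {
  // 0 -> 0.5 -> 1 soft step of width sigma (invs = 1 / (sqrt(2) sigma))
  return 0.5 * (1.0 + std::erf(a * invs));
}

// [[Rcpp::export(name = ".beamDoseCpp")]]
NumericVector beam_dose_cpp(NumericVector density, IntegerVector dims,
                            NumericVector spacing, NumericVector origin,
                            NumericVector src, NumericVector eu,
                            NumericVector ev, NumericVector w,
                            double sadMM, NumericVector jawsMM,
                            NumericVector leafEdgesMM, NumericVector leafLeftMM,
                            NumericVector leafRightMM, double muPerMM,
                            double dmaxMM, double sigmaMM, double transmission,
                            double weight, double stepMM) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double sx = src[0], sy = src[1], sz = src[2];
  const double invs = 1.0 / (std::sqrt(2.0) * sigmaMM);
  const int nLeaf = leafLeftMM.size();
  const double *dens = density.begin();
  NumericVector out(density.size());
  out.attr("dim") = dims;

  // grid bounding box (voxel centres padded by half a voxel)
  const double bx0 = ox - dx / 2, bx1 = ox + (nx - 0.5) * dx;
  const double by0 = oy - dy / 2, by1 = oy + (ny - 0.5) * dy;
  const double bz0 = oz - dz / 2, bz1 = oz + (nz - 0.5) * dz;

  double refDist = sadMM + dmaxMM;  // 1 Gy/weight at dmax, on-axis, SSD = SAD

  size_t k = 0;
  for (int iz = 0; iz < nz; ++iz) {
    const double pz = oz + iz * dz;
    for (int iy = 0; iy < ny; ++iy) {
      const double py = oy + iy * dy;
      for (int ix = 0; ix < nx; ++ix, ++k) {
        const double px = ox + ix * dx;
        const double vx = px - sx, vy = py - sy, vz = pz - sz;
        const double t = vx * w[0] + vy * w[1] + vz * w[2];
        if (t <= 1e-6) { out[k] = 0.0; continue; }
        const double r2 = vx * vx + vy * vy + vz * vz;
        const double r = std::sqrt(r2);

        // BEV isocenter-plane coordinates
        const double scale = sadMM / t;
        const double u = scale * (vx * eu[0] + vy * eu[1] + vz * eu[2]);
        const double v = scale * (vx * ev[0] + vy * ev[1] + vz * ev[2]);

        // aperture fluence: Gaussian-smoothed jaw/MLC opening. Without MLC,
        // a separable product of the four jaw edges; with MLC, a sum over
        // leaf tracks of (smoothed v-indicator of the jaw-clipped track) x
        // (u edge factor of the jaw-clipped leaf opening). The per-track
        // indicators telescope across contiguous tracks, so coincident leaf
        // and jaw edges are not double-counted.
        double open;
        if (nLeaf == 0) {
          open = edge(u - jawsMM[0], invs) * edge(jawsMM[1] - u, invs) *
                 edge(v - jawsMM[2], invs) * edge(jawsMM[3] - v, invs);
        } else {
          open = 0.0;
          const double reach = 5.0 * sigmaMM;
          for (int j = 0; j < nLeaf; ++j) {
            const double a = std::max(leafEdgesMM[j], jawsMM[2]);
            const double b = std::min(leafEdgesMM[j + 1], jawsMM[3]);
            if (b <= a) continue;
            if (v < a - reach || v > b + reach) continue;
            const double uL = std::max(leafLeftMM[j], jawsMM[0]);
            const double uR = std::min(leafRightMM[j], jawsMM[1]);
            if (uR <= uL) continue;
            const double vw = edge(v - a, invs) - edge(v - b, invs);
            if (vw <= 0.0) continue;
            open += vw * edge(u - uL, invs) * edge(uR - u, invs);
          }
          if (open > 1.0) open = 1.0;
        }
        const double F = transmission + (1.0 - transmission) * open;

        // radiological depth: march from grid entry to the voxel
        const double ux = vx / r, uy = vy / r, uz = vz / r;
        double t0 = 0.0, t1r = r;
        bool miss = false;
        // slab clipping of [0, r] against the grid box
        {
          double tmin = 0.0, tmax = r;
          const double o3[3] = {sx, sy, sz};
          const double u3[3] = {ux, uy, uz};
          const double b0[3] = {bx0, by0, bz0}, b1[3] = {bx1, by1, bz1};
          for (int a = 0; a < 3 && !miss; ++a) {
            if (std::fabs(u3[a]) < 1e-12) {
              if (o3[a] < b0[a] || o3[a] > b1[a]) miss = true;
            } else {
              double ta = (b0[a] - o3[a]) / u3[a];
              double tb = (b1[a] - o3[a]) / u3[a];
              if (ta > tb) std::swap(ta, tb);
              if (ta > tmin) tmin = ta;
              if (tb < tmax) tmax = tb;
              if (tmin > tmax) miss = true;
            }
          }
          t0 = tmin; t1r = tmax;
        }
        double deff = 0.0;
        if (!miss && t1r > t0) {
          const double span = r - t0;  // march up to the voxel itself
          const int nstep = (int)(span / stepMM);
          double tcur = t0 + stepMM * 0.5;
          for (int sI = 0; sI < nstep; ++sI, tcur += stepMM) {
            const double qx = sx + ux * tcur, qy = sy + uy * tcur, qz = sz + uz * tcur;
            const int jx = (int)std::lround((qx - ox) / dx);
            const int jy = (int)std::lround((qy - oy) / dy);
            const int jz = (int)std::lround((qz - oz) / dz);
            if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
              continue;
            deff += dens[(size_t)jz * nx * ny + (size_t)jy * nx + jx] * stepMM;
          }
          const double rem = span - nstep * stepMM;
          if (rem > 1e-9) {
            const double tm = t0 + nstep * stepMM + rem * 0.5;
            const double qx = sx + ux * tm, qy = sy + uy * tm, qz = sz + uz * tm;
            const int jx = (int)std::lround((qx - ox) / dx);
            const int jy = (int)std::lround((qy - oy) / dy);
            const int jz = (int)std::lround((qz - oz) / dz);
            if (jx >= 0 && jx < nx && jy >= 0 && jy < ny && jz >= 0 && jz < nz)
              deff += dens[(size_t)jz * nx * ny + (size_t)jy * nx + jx] * rem;
          }
        }

        double pdd;
        if (deff <= dmaxMM) pdd = deff / dmaxMM;
        else pdd = std::exp(-muPerMM * (deff - dmaxMM));

        const double invsq = (refDist / r) * (refDist / r);
        out[k] = weight * invsq * pdd * F;
      }
    }
  }
  return out;
}
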