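#include <Rcpp.h>
#include <complex>
#include <vector>
using namespace Rcpp;

// Coherent ISF accumulator.
//
// coords: F x N x 3 array (Angstrom), dirs: M x 3 unit vectors, Q: nQ moduli
// (1/Angstrom), lags: integer frame lags (>= 0), origin_stride: stride over
// time origins. Returns nQ x nLags matrix of
//   (1/M) sum_m < Re[ A_m(t0+lag) * conj(A_m(t0)) ] >_{t0}
// with A_m(f) = sum_j b_j exp(i Q u_m . r_j(f)).
//
// When Q is an arithmetic grid the per-atom phase factors are obtained by a
// complex recurrence (two sincos per atom-frame-direction instead of nQ).
// [[Rcpp::export]]
NumericMatrix cpp_isf(NumericVector coords, NumericVector b,
                      NumericMatrix dirs, NumericVector Q,
                      IntegerVector lags, int origin_stride) {
  IntegerVector dim = coords.attr("dim");
  const int F = dim[0], N = dim[1];
  const int M = dirs.nrow(), nQ = Q.size(), nL = lags.size();
  if (origin_stride < 1) origin_stride = 1;

  bool arith = nQ >= 3;
  double dQ = nQ > 1 ? Q[1] - Q[0] : 0.0;
  for (int k = 2; k < nQ; ++k)
    if (std::abs((Q[k] - Q[k - 1]) - dQ) > 1e-12 * std::max(1.0, std::abs(dQ)))
      arith = false;

  NumericMatrix out(nQ, nL);
  std::vector<std::complex<double>> A((size_t)F * nQ);
  const double *cd = coords.begin();

  for (int m = 0; m < M; ++m) {
    const double ux = dirs(m, 0), uy = dirs(m, 1), uz = dirs(m, 2);
    std::fill(A.begin(), A.end(), std::complex<double>(0.0, 0.0));
    for (int f = 0; f < F; ++f) {
      std::complex<double> *Af = &A[(size_t)f * nQ];
      for (int j = 0; j < N; ++j) {
        const double x = cd[f + (size_t)F * j];
        const double y = cd[f + (size_t)F * (j + N)];
        const double z = cd[f + (size_t)F * (j + 2 * N)];
        const double d = ux * x + uy * y + uz * z;
        const double bj = b[j];
        if (arith) {
          std::complex<double> e(std::cos(Q[0] * d), std::sin(Q[0] * d));
          const std::complex<double> step(std::cos(dQ * d), std::sin(dQ * d));
          for (int k = 0; k < nQ; ++k) { Af[k] += bj * e; e *= step; }
        } else {
          for (int k = 0; k < nQ; ++k) {
            const double ph = Q[k] * d;
            Af[k] += std::complex<double>(bj * std::cos(ph), bj * std::sin(ph));
          }
        }
      }
    }
    for (int l = 0; l < nL; ++l) {
      const int lag = lags[l];
      for (int k = 0; k < nQ; ++k) {
        double acc = 0.0; long cnt = 0;
        for (int t0 = 0; t0 + lag < F; t0 += origin_stride) {
          const std::complex<double> v =
            A[(size_t)(t0 + lag) * nQ + k] * std::conj(A[(size_t)t0 * nQ + k]);
          acc += v.real(); ++cnt;
        }
        out(k, l) += acc / (double)cnt;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  for (int l = 0; l < nL; ++l)
    for (int k = 0; k < nQ; ++k) out(k, l) /= (double)M;
  return out;
}

static inline void rodrigues(const double wx, const double wy, const double wz,
                             double R[9]) {
  // rotation matrix exp(skew(w)), column-major 3x3
  const double th = std::sqrt(wx * wx + wy * wy + wz * wz);
  if (th < 1e-14) {
    R[0] = 1; R[1] = 0; R[2] = 0; R[3] = 0; R[4] = 1; R[5] = 0;
    R[6] = 0; R[7] = 0; R[8] = 1;
    return;
  }
  const double kx = wx / th, ky = wy / th, kz = wz / th;
  const double c = std::cos(th), s = std::sin(th), v = 1.0 - c;
  R[0] = c + kx * kx * v;      R[3] = kx * ky * v - kz * s; R[6] = kx * kz * v + ky * s;
  R[1] = ky * kx * v + kz * s; R[4] = c + ky * ky * v;      R[7] = ky * kz * v - kx * s;
  R[2] = kz * kx * v - ky * s; R[5] = kz * ky * v + kx * s; R[8] = c + kz * kz * v;
}

static inline void mat3mul(const double *A, const double *B, double *C) {
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i)
      C[i + 3 * j] = A[i] * B[3 * j] + A[i + 3] * B[1 + 3 * j] + A[i + 6] * B[2 + 3 * j];
}

static inline void orthonormalize(double *R) {
  // Gram-Schmidt on columns
  double n0 = std::sqrt(R[0] * R[0] + R[1] * R[1] + R[2] * R[2]);
  for (int i = 0; i < 3; ++i) R[i] /= n0;
  double d = R[0] * R[3] + R[1] * R[4] + R[2] * R[5];
  for (int i = 0; i < 3; ++i) R[3 + i] -= d * R[i];
  double n1 = std::sqrt(R[3] * R[3] + R[4] * R[4] + R[5] * R[5]);
  for (int i = 0; i < 3; ++i) R[3 + i] /= n1;
  // third column = cross of first two (det +1)
  R[6] = R[1] * R[5] - R[2] * R[4];
  R[7] = R[2] * R[3] - R[0] * R[5];
  R[8] = R[0] * R[4] - R[1] * R[3];
}

// Rigid-body Brownian propagation.
//
// r0: N x 3 body-frame coordinates (relative to the diffusion center),
// Bt, Br: 3x3 lower Cholesky factors of 2*D_T*dt and 2*D_R*dt (body frame),
// zt, zr: (F-1) x 3 standard normal draws for translation / rotation.
// Frame 1 is the input pose (identity orientation, center at origin).
// Returns list(coords = F x N x 3, rotations = F x 9, centers = F x 3).
// [[Rcpp::export]]
List cpp_rigid_bd(NumericMatrix r0, NumericMatrix Bt, NumericMatrix Br,
                  NumericMatrix zt, NumericMatrix zr) {
  const int N = r0.nrow();
  const int F = zt.nrow() + 1;
  NumericVector coords((size_t)F * N * 3);
  coords.attr("dim") = IntegerVector::create(F, N, 3);
  NumericMatrix rotations(F, 9), centers(F, 3);

  double R[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
  double cx = 0, cy = 0, cz = 0;
  double *cd = coords.begin();

  for (int f = 0; f < F; ++f) {
    if (f > 0) {
      // body-frame translational kick rotated to lab frame
      const double tx = Bt(0, 0) * zt(f - 1, 0);
      const double ty = Bt(1, 0) * zt(f - 1, 0) + Bt(1, 1) * zt(f - 1, 1);
      const double tz = Bt(2, 0) * zt(f - 1, 0) + Bt(2, 1) * zt(f - 1, 1) + Bt(2, 2) * zt(f - 1, 2);
      cx += R[0] * tx + R[3] * ty + R[6] * tz;
      cy += R[1] * tx + R[4] * ty + R[7] * tz;
      cz += R[2] * tx + R[5] * ty + R[8] * tz;
      const double wx = Br(0, 0) * zr(f - 1, 0);
      const double wy = Br(1, 0) * zr(f - 1, 0) + Br(1, 1) * zr(f - 1, 1);
      const double wz = Br(2, 0) * zr(f - 1, 0) + Br(2, 1) * zr(f - 1, 1) + Br(2, 2) * zr(f - 1, 2);
      double dR[9], Rn[9];
      rodrigues(wx, wy, wz, dR);
      mat3mul(R, dR, Rn);          // body-frame composition
      for (int i = 0; i < 9; ++i) R[i] = Rn[i];
      orthonormalize(R);
    }
    for (int i = 0; i < 9; ++i) rotations(f, i) = R[i];
    centers(f, 0) = cx; centers(f, 1) = cy; centers(f, 2) = cz;
    for (int j = 0; j < N; ++j) {
      const double bx = r0(j, 0), by = r0(j, 1), bz = r0(j, 2);
      cd[f + (size_t)F * j]           = cx + R[0] * bx + R[3] * by + R[6] * bz;
      cd[f + (size_t)F * (j + N)]     = cy + R[1] * bx + R[4] * by + R[7] * bz;
      cd[f + (size_t)F * (j + 2 * N)] = cz + R[2] * bx + R[5] * by + R[8] * bz;
    }
  }
  return List::create(_["coords"] = coords, _["rotations"] = rotations,
                      _["centers"] = centers);
}

// Add body-frame internal displacements to a rigid trajectory.
//
// coords: F x N x 3 (modified copy returned), rotations: F x 9 body->lab,
// U: (3N) x K orthonormal mode directions (atom-major: rows 3j..3j+2 are
// atom j), X: F x K mode amplitude series.
// [[Rcpp::export]]
NumericVector cpp_add_modes(NumericVector coords, NumericMatrix rotations,
                            NumericMatrix U, NumericMatrix X) {
  IntegerVector dim = coords.attr("dim");
  const int F = dim[0], N = dim[1], K = U.ncol();
  NumericVector out = clone(coords);
  double *cd = out.begin();
  for (int f = 0; f < F; ++f) {
    double R[9];
    for (int i = 0; i < 9; ++i) R[i] = rotations(f, i);
    for (int j = 0; j < N; ++j) {
      double dx = 0, dy = 0, dz = 0;
      for (int k = 0; k < K; ++k) {
        const double a = X(f, k);
        dx += a * U(3 * j, k);
        dy += a * U(3 * j + 1, k);
        dz += a * U(3 * j + 2, k);
      }
      cd[f + (size_t)F * j]           += R[0] * dx + R[3] * dy + R[6] * dz;
      cd[f + (size_t)F * (j + N)]     += R[1] * dx + R[4] * dy + R[7] * dz;
      cd[f + (size_t)F * (j + 2 * N)] += R[2] * dx + R[5] * dy + R[8] * dz;
    }
  }
  return out;
}
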