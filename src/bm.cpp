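// Bloch-McConnell continuous-wave saturation engine.
//
// State vector per pool: (Mx, My, Mz), pools ordered water first, then
// solutes. Each solute exchanges with water only (star topology). The
// evolution under CW irradiation is linear, dM/dt = A M + b, and is
// propagated over the full saturation interval with the exact solution
// M(t) = Mss + expm(A t) (M0 - Mss), Mss = -A^{-1} b.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double GAMMA_UT = 2.0 * M_PI * 42.577; // rad/s per microtesla
static const double TWO_PI = 2.0 * M_PI;

// Build the system matrix A and constant b for one RF offset.
// pools: n x 5 matrix, columns (shift_ppm, k_exch, frac, R1, R2).
static void bm_system(const mat& pools, double r1w, double r2w,
                      double f0, double w1, double offset_ppm,
                      double b0_ppm, mat& A, vec& b, vec& M0) {
  const uword n = pools.n_rows;       // solute pools
  const uword d = 3 * (n + 1);
  A.zeros(d, d);
  b.zeros(d);
  M0.zeros(d);

  // total forward exchange out of water
  double ka = 0.0;
  for (uword p = 0; p < n; ++p) ka += pools(p, 1) * pools(p, 2);

  const double dw = TWO_PI * f0 * (b0_ppm - offset_ppm); // water offset, rad/s
  // water block
  A(0, 0) = -r2w - ka; A(0, 1) = -dw;
  A(1, 0) = dw;        A(1, 1) = -r2w - ka; A(1, 2) = w1;
  A(2, 1) = -w1;       A(2, 2) = -r1w - ka;
  b(2) = r1w;
  M0(2) = 1.0;

  for (uword p = 0; p < n; ++p) {
    const uword i = 3 * (p + 1);
    const double k = pools(p, 1), f = pools(p, 2);
    const double r1 = pools(p, 3), r2 = pools(p, 4);
    const double kaw = k * f; // water -> pool p
    const double dp = TWO_PI * f0 * (b0_ppm + pools(p, 0) - offset_ppm);
    A(i, i)         = -r2 - k; A(i, i + 1)     = -dp;
    A(i + 1, i)     = dp;      A(i + 1, i + 1) = -r2 - k; A(i + 1, i + 2) = w1;
    A(i + 2, i + 1) = -w1;     A(i + 2, i + 2) = -r1 - k;
    // exchange coupling with water, component-wise
    for (uword c = 0; c < 3; ++c) {
      A(c, i + c) += k;
      A(i + c, c) += kaw;
    }
    b(i + 2) = r1 * f;
    M0(i + 2) = f;
  }
}

static double bm_z_one(const mat& pools, double r1w, double r2w, double f0,
                       double w1, double tsat, double offset_ppm,
                       double b0_ppm, mat& A, vec& b, vec& M0) {
  bm_system(pools, r1w, r2w, f0, w1, offset_ppm, b0_ppm, A, b, M0);
  vec Mss = solve(A, -b);
  mat E = expmat(A * tsat);
  vec Mt = Mss + E * (M0 - Mss);
  return Mt(2); // water Mz, equilibrium-normalized
}

//' @noRd
// [[Rcpp::export(name = ".bm_zspectrum_cpp")]]
arma::vec bm_zspectrum_cpp(const arma::vec& offsets_ppm, const arma::mat& pools,
                           double water_r1, double water_r2, double f0_hz_ppm,
                           double b1_ut, double tsat_s, double b0_ppm) {
  const double w1 = GAMMA_UT * b1_ut;
  mat A; vec b, M0;
  vec z(offsets_ppm.n_elem);
  for (uword i = 0; i < offsets_ppm.n_elem; ++i)
    z(i) = bm_z_one(pools, water_r1, water_r2, f0_hz_ppm, w1, tsat_s,
                    offsets_ppm(i), b0_ppm, A, b, M0);
  return z;
}

// Voxelwise spectra: the fraction of pool `vary_pool` (1-based row into
// `pools`, 0 = none) is replaced per voxel by frac(v); b0/b1 vary per voxel.
//' @noRd
// [[Rcpp::export(name = ".bm_zspectrum_image_cpp")]]
arma::mat bm_zspectrum_image_cpp(const arma::vec& offsets_ppm,
                                 const arma::mat& pools, int vary_pool,
                                 const arma::vec& frac, const arma::vec& b0_ppm,
                                 const arma::vec& b1_scale, double water_r1,
                                 double water_r2, double f0_hz_ppm,
                                 double b1_ut, double tsat_s) {
  const uword nv = frac.n_elem;
  mat z(nv, offsets_ppm.n_elem);
  mat pl = pools;
  mat A; vec b, M0;
  for (uword v = 0; v < nv; ++v) {
    if (vary_pool > 0) pl(vary_pool - 1, 2) = frac(v);
    const double w1 = GAMMA_UT * b1_ut * b1_scale(v);
    for (uword i = 0; i < offsets_ppm.n_elem; ++i)
      z(v, i) = bm_z_one(pl, water_r1, water_r2, f0_hz_ppm, w1, tsat_s,
                         offsets_ppm(i), b0_ppm(v), A, b, M0);
  }
  return z;
}
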