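#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic RNG (xoshiro256++, seeded via splitmix64).
//
// The coverage simulations draw ~1e10 standard normals; R's inversion sampler
// is the bottleneck at that scale, so noise and bootstrap multipliers are
// generated here from explicit integer seeds. The generator is self-contained
// and platform-independent, which keeps `--seed` reproducible across runs.
// ---------------------------------------------------------------------------

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed into the full state
    uint64_t z = seed;
    for (int i = 0; i < 4; i++) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0, 1), 53-bit resolution; never exactly 0
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // uniform on (-1, 1)
  inline double unifs() {
    return 2.0 * unif() - 1.0;
  }
  // standard normal via Marsaglia's polar method (exact, no table)
  double spare = 0.0;
  bool has_spare = false;
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s2;
    do {
      u = unifs(); v = unifs();
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * f; has_spare = true;
    return u * f;
  }
};

static inline uint64_t seed_from_sexp(double seed) {
  // seeds arrive from R as doubles holding non-negative integers < 2^53
  return (uint64_t)seed;
}

// Collision-free derivation of sub-stream seeds (splitmix64 scramble of
// seed ^ key); the result is reduced below 2^53 so it round-trips exactly
// through an R double.
// [[Rcpp::export]]
double cpp_derive_seed(double seed, double key) {
  uint64_t z = seed_from_sexp(seed) ^ (seed_from_sexp(key) * 0x9e3779b97f4a7c15ULL);
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  z = z ^ (z >> 31);
  return (double)(z >> 11);  // 53 bits
}

// [[Rcpp::export]]
NumericMatrix cpp_white_stack(int npix, int n, double seed) {
  Xoshiro rng(seed_from_sexp(seed));
  NumericMatrix out(npix, n);
  double *p = REAL(out);
  R_xlen_t m = (R_xlen_t)npix * n;
  for (R_xlen_t i = 0; i < m; i++) p[i] = rng.norm();
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_rademacher(int n, int B, double seed) {
  Xoshiro rng(seed_from_sexp(seed));
  NumericMatrix out(n, B);
  double *p = REAL(out);
  R_xlen_t m = (R_xlen_t)n * B;
  // 64 draws per invocation of the generator
  R_xlen_t i = 0;
  while (i < m) {
    uint64_t bits = rng.next();
    for (int b = 0; b < 64 && i < m; b++, i++)
      p[i] = (bits & (1ULL << b)) ? 1.0 : -1.0;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_mammen(int n, int B, double seed) {
  Xoshiro rng(seed_from_sexp(seed));
  NumericMatrix out(n, B);
  double *p = REAL(out);
  const double s5 = std::sqrt(5.0);
  const double lo = -(s5 - 1.0) / 2.0;   // prob (sqrt(5)+1)/(2 sqrt(5))
  const double hi = (s5 + 1.0) / 2.0;    // prob (sqrt(5)-1)/(2 sqrt(5))
  const double p_lo = (s5 + 1.0) / (2.0 * s5);
  R_xlen_t m = (R_xlen_t)n * B;
  for (R_xlen_t i = 0; i < m; i++) p[i] = (rng.unif() < p_lo) ? lo : hi;
  return out;
}

// In-place mixing z2 <- rho * z1 + sqrt(1 - rho^2) * z2 (cross-condition
// correlation is induced on the white noise, before smoothing).
// [[Rcpp::export]]
void cpp_mix_inplace(NumericMatrix z1, NumericMatrix z2, double rho) {
  if (z1.nrow() != z2.nrow() || z1.ncol() != z2.ncol())
    stop("white-noise stacks must have identical dimensions");
  const double *a = REAL(z1);
  double *b = REAL(z2);
  const double c = std::sqrt(1.0 - rho * rho);
  R_xlen_t m = (R_xlen_t)z1.nrow() * z1.ncol();
  for (R_xlen_t i = 0; i < m; i++) b[i] = rho * a[i] + c * b[i];
}

// ---------------------------------------------------------------------------
// Separable convolution of a stack of fields.
//
// x is (nr*nc) x n, each column one field in column-major (nr rows) order.
// Zero padding outside the grid; the caller is expected to have generated
// the noise on a grid padded by the kernel radius and to crop afterwards
// (crop > 0 returns the interior (nr-2*crop) x (nc-2*crop) region directly).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_smooth_stack(NumericMatrix x, int nr, int nc,
                               NumericVector kernel, int crop) {
  const int nk = kernel.size();
  if (nk % 2 != 1) stop("kernel must have odd length");
  const int rad = (nk - 1) / 2;
  const int n = x.ncol();
  if ((R_xlen_t)nr * nc != x.nrow()) stop("stack rows != nr*nc");
  const int nr_out = nr - 2 * crop, nc_out = nc - 2 * crop;
  if (nr_out < 1 || nc_out < 1) stop("crop exceeds grid extent");
  const double *k = REAL(kernel);

  NumericMatrix out(nr_out * nc_out, n);
  std::vector<double> tmp((size_t)nr * nc);

  for (int f = 0; f < n; f++) {
    const double *in = REAL(x) + (R_xlen_t)f * nr * nc;
    // pass 1: convolve down columns (contiguous)
    for (int c = 0; c < nc; c++) {
      const double *col = in + (R_xlen_t)c * nr;
      double *tcol = tmp.data() + (size_t)c * nr;
      for (int r = 0; r < nr; r++) {
        double acc = 0.0;
        int j0 = std::max(-rad, -r), j1 = std::min(rad, nr - 1 - r);
        for (int j = j0; j <= j1; j++) acc += k[j + rad] * col[r + j];
        tcol[r] = acc;
      }
    }
    // pass 2: convolve across rows, writing only the cropped interior
    double *o = REAL(out) + (R_xlen_t)f * nr_out * nc_out;
    for (int c = crop; c < nc - crop; c++) {
      double *ocol = o + (R_xlen_t)(c - crop) * nr_out;
      for (int r = 0; r < nr_out; r++) ocol[r] = 0.0;
      int j0 = std::max(-rad, -c), j1 = std::min(rad, nc - 1 - c);
      for (int j = j0; j <= j1; j++) {
        const double kj = k[j + rad];
        const double *tcol = tmp.data() + (size_t)(c + j) * nr + crop;
        for (int r = 0; r < nr_out; r++) ocol[r] += kj * tcol[r];
      }
    }
  }
  return out;
}

// One-pass per-pixel mean and residual standard deviation across
// observations; x is npix x n (pixels as rows), ddof subtracted from n.
// [[Rcpp::export]]
List cpp_row_mean_sd(NumericMatrix x, int ddof) {
  const int npix = x.nrow();
  const int n = x.ncol();
  if (n - ddof <= 0) stop("not enough observations for the variance d.o.f.");
  NumericVector mean(npix), sd(npix);
  std::vector<double> sum(npix, 0.0), sumsq(npix, 0.0);
  const double *p = REAL(x);
  for (int c = 0; c < n; c++) {
    const double *col = p + (R_xlen_t)c * npix;
    for (int r = 0; r < npix; r++) {
      sum[r] += col[r];
      sumsq[r] += col[r] * col[r];
    }
  }
  for (int r = 0; r < npix; r++) {
    double m = sum[r] / n;
    double ss = sumsq[r] - n * m * m;
    if (ss < 0) ss = 0;
    mean[r] = m;
    sd[r] = std::sqrt(ss / (n - ddof));
  }
  return List::create(_["mean"] = mean, _["sd"] = sd);
}

// Residual sum of squares per pixel: rss[r] = sum_c (Y[r,c] - (C Q')[r,c])^2
// computed directly (no Y^2 - fitted^2 shortcut, which cancels
// catastrophically when the residual scale is tiny relative to the signal).
// Y is npix x n, C npix x p, Q n x p.
// [[Rcpp::export]]
NumericVector cpp_row_resid_sumsq(NumericMatrix Y, NumericMatrix C,
                                  NumericMatrix Q) {
  const int npix = Y.nrow(), n = Y.ncol(), p = C.ncol();
  if (C.nrow() != npix || Q.nrow() != n || Q.ncol() != p)
    stop("dimension mismatch");
  NumericVector out(npix);
  double *o = REAL(out);
  const double *y = REAL(Y), *cc = REAL(C), *q = REAL(Q);
  for (int c = 0; c < n; c++) {
    const double *ycol = y + (R_xlen_t)c * npix;
    for (int r = 0; r < npix; r++) {
      double fit = 0.0;
      for (int k = 0; k < p; k++)
        fit += cc[(R_xlen_t)k * npix + r] * q[(R_xlen_t)k * n + c];
      const double e = ycol[r] - fit;
      o[r] += e * e;
    }
  }
  return out;
}

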