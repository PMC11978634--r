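// 256-point radix-2 decimation-in-time FFT in single precision, organized the
// way the hardware is: bit-reversal address reordering, a precomputed
// single-precision twiddle ROM W_256^m (m = 0..127), and 8 butterfly stages
// whose adds/multiplies all round to fp32.

#include "epicircuit.h"
using namespace Rcpp;

static const int FFT_N = 256;
static const int FFT_LOG2N = 8;

static bool is_pow2(int n) { return n > 0 && (n & (n - 1)) == 0; }

//' @noRd
// [[Rcpp::export(name = ".bit_reverse_perm_cpp")]]
IntegerVector bit_reverse_perm_cpp(int n) {
  if (!is_pow2(n)) stop("n must be a power of two");
  int bits = 0;
  while ((1 << bits) < n) ++bits;
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    int r = 0;
    for (int b = 0; b < bits; ++b) if (k & (1 << b)) r |= 1 << (bits - 1 - b);
    out[k] = r;
  }
  return out;
}

// Twiddle ROM: W_256^m = exp(-2*pi*i*m/256), m = 0..127, computed in double
// precision and rounded once to fp32.
static void twiddle_rom(float* wr, float* wi) {
  for (int m = 0; m < FFT_N / 2; ++m) {
    double a = -2.0 * M_PI * (double)m / (double)FFT_N;
    wr[m] = (float)std::cos(a);
    wi[m] = (float)std::sin(a);
  }
}

//' @noRd
// [[Rcpp::export(name = ".twiddle_table_cpp")]]
ComplexVector twiddle_table_cpp() {
  float wr[FFT_N / 2], wi[FFT_N / 2];
  twiddle_rom(wr, wi);
  ComplexVector out(FFT_N / 2);
  for (int m = 0; m < FFT_N / 2; ++m) {
    out[m].r = (double)wr[m];
    out[m].i = (double)wi[m];
  }
  return out;
}

static void fft256_core(const double* x, float* re, float* im) {
  static float wr[FFT_N / 2], wi[FFT_N / 2];
  static bool rom_ready = false;
  if (!rom_ready) { twiddle_rom(wr, wi); rom_ready = true; }

  IntegerVector rev = bit_reverse_perm_cpp(FFT_N);
  for (int k = 0; k < FFT_N; ++k) {
    re[k] = (float)x[rev[k]];
    im[k] = 0.0f;
  }
  // 8 butterfly stages, fixed order
  for (int s = 1; s <= FFT_LOG2N; ++s) {
    int m = 1 << s;        // butterfly span
    int half = m >> 1;
    int stride = FFT_N / m;  // twiddle index stride
    for (int base = 0; base < FFT_N; base += m) {
      for (int j = 0; j < half; ++j) {
        float twr = wr[j * stride], twi = wi[j * stride];
        int a = base + j, b = base + j + half;
        float tr = twr * re[b] - twi * im[b];
        float ti = twr * im[b] + twi * re[b];
        re[b] = re[a] - tr;
        im[b] = im[a] - ti;
        re[a] = re[a] + tr;
        im[a] = im[a] + ti;
      }
    }
  }
}

//' @noRd
// [[Rcpp::export(name = ".fft256_cpp")]]
ComplexVector fft256_cpp(NumericVector x) {
  if (x.size() != FFT_N) stop("fft256: input length must be 256, got %td", (ptrdiff_t)x.size());
  for (int k = 0; k < FFT_N; ++k)
    if (!R_finite(x[k])) stop("fft256: non-finite sample at position %d", k + 1);
  float re[FFT_N], im[FFT_N];
  fft256_core(REAL(x), re, im);
  ComplexVector out(FFT_N);
  for (int k = 0; k < FFT_N; ++k) {
    out[k].r = (double)re[k];
    out[k].i = (double)im[k];
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".amplitude_matrix_cpp")]]
NumericMatrix amplitude_matrix_cpp(NumericMatrix frame) {
  int nc = frame.nrow(), ns = frame.ncol();
  if (ns != FFT_N) stop("amplitude spectrum: frames must have 256 samples per channel");
  NumericMatrix out(nc, ns);
  std::vector<double> row(FFT_N);
  float re[FFT_N], im[FFT_N];
  for (int c = 0; c < nc; ++c) {
    for (int k = 0; k < FFT_N; ++k) row[k] = frame(c, k);
    fft256_core(row.data(), re, im);
    for (int k = 0; k < FFT_N; ++k) {
      float mag2 = re[k] * re[k] + im[k] * im[k];
      out(c, k) = (double)std::sqrt(mag2);
    }
  }
  return out;
}
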