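// Hyperbolic CORDIC in the SVM's exponential/logarithm unit.
//
// The unit mirrors a 16-iteration shift-and-add circuit: every iteration uses
// one right shift and three add/subtracts on the (x, y, z) registers, with
// the rotation angles atanh(2^-i) held in a ROM. Iterations i = 4 and i = 13
// are repeated, the standard requirement for hyperbolic convergence. Inputs
// and outputs are IEEE-754 single precision.
//
// Two register implementations are provided (the circuit description leaves
// the datapath open):
//   core = 0 ("fixed"): signed 64-bit fixed-point registers with 40
//     fractional guard bits and true arithmetic shifts -- the conventional
//     CORDIC datapath, wrapped by float pack/unpack at the boundary. Default.
//   core = 1 ("float"): fp32 registers with the shift realized as an fp32
//     multiply by the exact power of two 2^-i.
// A mode-controlled post-processing step folds the residual rotation angle
// back into the result (first order), which is what keeps the relative error
// of ln near its zero crossing at v = 1 bounded.

#include "epicircuit.h"
#include <cstdint>
using namespace Rcpp;

std::vector<int> cordic_schedule(int niter) {
  if (niter < 1 || niter > 16) stop("iteration count must be in 1..16");
  std::vector<int> s;
  for (int i = 1; i <= niter; ++i) {
    s.push_back(i);
    if (i == 4 || i == 13) s.push_back(i);  // convergence repeats
  }
  return s;
}

static float atanh_rom_f(int i) {
  return (float)std::atanh(std::ldexp(1.0, -i));
}

float cordic_inv_gain(const std::vector<int>& sched) {
  double kh = 1.0;
  for (int i : sched) kh *= std::sqrt(1.0 - std::ldexp(1.0, -2 * i));
  return (float)(1.0 / kh);
}

static double schedule_range(const std::vector<int>& sched) {
  double r = 0.0;
  for (int i : sched) r += std::atanh(std::ldexp(1.0, -i));
  return r;
}

// ---- fixed-point core: Q23.40, arithmetic shifts ----

static const int CORDIC_FRAC = 40;

static inline int64_t to_fix(float v) {
  return (int64_t)std::llround((double)v * (double)(1LL << CORDIC_FRAC));
}
static inline float from_fix(int64_t v) {
  return (float)((double)v / (double)(1LL << CORDIC_FRAC));
}

static int64_t atanh_rom_fix(int i) {
  return (int64_t)std::llround(std::atanh(std::ldexp(1.0, -i)) *
                               (double)(1LL << CORDIC_FRAC));
}

static void iterate_fixed(int64_t& x, int64_t& y, int64_t& z,
                          const std::vector<int>& sched, bool rotation) {
  for (int i : sched) {
    int64_t xs = x >> i, ys = y >> i;
    int d = rotation ? ((z >= 0) ? 1 : -1) : ((y < 0) ? 1 : -1);
    int64_t rom = atanh_rom_fix(i);
    if (d > 0) { x += ys; y += xs; z -= rom; }
    else       { x -= ys; y -= xs; z += rom; }
  }
}

// ---- fp32 core: shifts as multiplies by 2^-i ----

static void iterate_float(float& x, float& y, float& z,
                          const std::vector<int>& sched, bool rotation) {
  for (int i : sched) {
    float t = std::ldexp(1.0f, -i);
    float xs = x * t, ys = y * t;
    int d = rotation ? ((z >= 0.0f) ? 1 : -1) : ((y < 0.0f) ? 1 : -1);
    float rom = atanh_rom_f(i);
    if (d > 0) { x = x + ys; y = y + xs; z = z - rom; }
    else       { x = x - ys; y = y - xs; z = z + rom; }
  }
}

// Run the schedule on fp32 boundary values; core selects the register type.
static void cordic_run(float& x, float& y, float& z,
                       const std::vector<int>& sched, bool rotation, int core) {
  if (core == 0) {
    int64_t xi = to_fix(x), yi = to_fix(y), zi = to_fix(z);
    iterate_fixed(xi, yi, zi, sched, rotation);
    x = from_fix(xi); y = from_fix(yi); z = from_fix(zi);
  } else {
    iterate_float(x, y, z, sched, rotation);
  }
}

//' @noRd
// [[Rcpp::export(name = ".cordic_core_cpp")]]
List cordic_core_cpp(NumericVector input, std::string mode, int niter = 16,
                     std::string core = "fixed") {
  std::vector<int> sched = cordic_schedule(niter);
  double range = schedule_range(sched);
  int corei = (core == "float") ? 1 : 0;
  float x, y, z;
  bool rotation;
  if (mode == "rotation") {
    if (input.size() != 1) stop("rotation mode takes a single angle input");
    if (!R_finite(input[0]) || std::fabs(input[0]) > range)
      stop("rotation input outside the CORDIC convergence domain [-%.4f, %.4f]; apply range reduction first",
           range, range);
    rotation = true;
    x = cordic_inv_gain(sched);  // pre-scaled so outputs are cosh/sinh directly
    y = 0.0f;
    z = (float)input[0];
  } else if (mode == "vectoring") {
    if (input.size() != 2) stop("vectoring mode takes an (x, y) pair");
    float x0 = (float)input[0], y0 = (float)input[1];
    if (!std::isfinite(x0) || !std::isfinite(y0) || x0 <= 0.0f)
      stop("vectoring input requires finite x > 0");
    if (std::fabs((double)y0 / (double)x0) >= std::tanh(range))
      stop("vectoring input outside the atanh convergence domain; apply range reduction first");
    rotation = false;
    x = x0; y = y0; z = 0.0f;
  } else {
    stop("mode must be 'rotation' or 'vectoring'");
  }
  cordic_run(x, y, z, sched, rotation, corei);
  return List::create(_["x"] = (double)x, _["y"] = (double)y, _["z"] = (double)z);
}

// Cody-Waite split of ln 2 for fp32 range reduction: the high part has its
// trailing mantissa bits zeroed so m * LN2_HI is exact for moderate m.
static const float LN2_HI_F = 6.93145752e-01f;   // 0x1.62e3p-1
static const float LN2_LO_F = 1.42860677e-06f;
static const float INV_LN2_F = 1.44269504f;

float cordic_exp_core(float v, int niter, bool correct, int core) {
  std::vector<int> sched = cordic_schedule(niter);
  // v = m * ln2 + r with |r| <= ln2/2
  float mf = std::nearbyint(v * INV_LN2_F);
  int m = (int)mf;
  float r = (v - mf * LN2_HI_F) - mf * LN2_LO_F;
  float x = cordic_inv_gain(sched), y = 0.0f, z = r;
  cordic_run(x, y, z, sched, true, core);
  float er = x + y;                       // cosh r + sinh r = e^r
  if (correct) er = er + er * z;          // residual-angle post-correction
  // scale by 2^m through exponent arithmetic; underflow to 0 is permitted
  return std::ldexp(er, m);
}

float cordic_ln_core(float v, int niter, bool correct, int core) {
  std::vector<int> sched = cordic_schedule(niter);
  // v = 2^e * f, with f normalized to [1/sqrt(2), sqrt(2)) so that v near 1
  // gives e = 0 and the final e*ln2 + ln f sum cannot cancel catastrophically
  int e;
  float f = std::frexp(v, &e);  // f in [0.5, 1)
  f = f * 2.0f; e = e - 1;
  if (f > 1.41421356f) { f = f * 0.5f; e = e + 1; }
  // ln f = 2 atanh((f-1)/(f+1)) via vectoring mode
  float x = f + 1.0f, y = f - 1.0f, z = 0.0f;
  cordic_run(x, y, z, sched, false, core);
  if (correct && x != 0.0f) z = z + y / x;  // residual atanh(y/x) ~ y/x
  float lnf = z + z;
  return ((float)e * LN2_HI_F + ((float)e * LN2_LO_F + lnf));
}

float cordic_exp_f(float v, int niter, bool correct) {
  return cordic_exp_core(v, niter, correct, 0);
}
float cordic_ln_f(float v, int niter, bool correct) {
  return cordic_ln_core(v, niter, correct, 0);
}

//' @noRd
// [[Rcpp::export(name = ".cordic_exp_cpp")]]
NumericVector cordic_exp_cpp(NumericVector v, int niter = 16, bool correct = true,
                             std::string core = "fixed") {
  int corei = (core == "float") ? 1 : 0;
  R_xlen_t n = v.size();
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    if (!R_finite(v[k])) stop("cordicExp: non-finite input at position %td", (ptrdiff_t)(k + 1));
    float vf = (float)v[k];
    if (vf == 0.0f) { out[k] = 1.0; continue; }
    out[k] = (double)cordic_exp_core(vf, niter, correct, corei);
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cordic_ln_cpp")]]
NumericVector cordic_ln_cpp(NumericVector v, int niter = 16, bool correct = true,
                            std::string core = "fixed") {
  int corei = (core == "float") ? 1 : 0;
  R_xlen_t n = v.size();
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    if (!R_finite(v[k]) || v[k] <= 0.0)
      stop("cordicLn: input must be finite and positive (position %td)", (ptrdiff_t)(k + 1));
    float vf = (float)v[k];
    if (vf == 1.0f) { out[k] = 0.0; continue; }
    out[k] = (double)cordic_ln_core(vf, niter, correct, corei);
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cordic_gain_cpp")]]
double cordic_gain_cpp(int niter = 16) {
  std::vector<int> sched = cordic_schedule(niter);
  double kh = 1.0;
  for (int i : sched) kh *= std::sqrt(1.0 - std::ldexp(1.0, -2 * i));
  return kh;
}

//' @noRd
// [[Rcpp::export(name = ".cordic_rom_cpp")]]
NumericVector cordic_rom_cpp(int niter = 16) {
  std::vector<int> sched = cordic_schedule(niter);
  NumericVector rom(sched.size());
  for (size_t s = 0; s < sched.size(); ++s) rom[s] = (double)atanh_rom_f(sched[s]);
  return rom;
}

//' @noRd
// [[Rcpp::export(name = ".fp32_round_cpp")]]
NumericVector fp32_round_cpp(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t k = 0; k < x.size(); ++k) out[k] = (double)(float)x[k];
  return out;
}
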