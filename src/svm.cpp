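// Quasi-Gaussian-kernel SVM decision function in single precision, with two
// equivalent evaluation routes: a direct arithmetic reference and an emulation
// of the hardware DPU sequence (negate-add subtraction, squaring multiplier,
// kernel-scale multiply, CORDIC exponential, multiply-accumulate with the
// dual coefficients, final addition of the negated offset).

#include "epicircuit.h"
using namespace Rcpp;

// fp32 kernel value exp(-gamma_eff * sum_j (u_j - v_j)^2); u, v are the
// feature/support values, optionally ln-transformed through the CORDIC unit.
static float kernel_f(const double* x, const double* sv, int k, float gamma,
                      bool log_transform, float eps_floor, int niter, bool correct) {
  float acc = 0.0f;
  for (int j = 0; j < k; ++j) {
    float u = (float)x[j], v = (float)sv[j];
    if (log_transform) {
      if (u <= 0.0f) {
        if (eps_floor > 0.0f) u = u + eps_floor;
        if (u <= 0.0f)
          stop("kernelEval: nonpositive feature value %g under log transform; enable the epsilon floor", (double)u);
      }
      if (v <= 0.0f) {
        if (eps_floor > 0.0f) v = v + eps_floor;
        if (v <= 0.0f)
          stop("kernelEval: nonpositive support-vector value %g under log transform; enable the epsilon floor", (double)v);
      }
      u = cordic_ln_f(u, niter, correct);
      v = cordic_ln_f(v, niter, correct);
    }
    float d = u - v;
    acc = acc + d * d;
  }
  float arg = -(gamma * acc);
  if (arg == 0.0f) return 1.0f;
  float kv = cordic_exp_f(arg, niter, correct);
  if (kv > 1.0f) kv = 1.0f;  // kernel of a nonpositive exponent cannot exceed 1
  return kv;
}

//' @noRd
// [[Rcpp::export(name = ".kernel_eval_cpp")]]
double kernel_eval_cpp(NumericVector x, NumericVector sv, double gamma_eff,
                       bool log_transform, double eps_floor,
                       int niter = 16, bool correct = true) {
  if (x.size() != sv.size()) stop("feature and support vectors differ in length");
  return (double)kernel_f(REAL(x), REAL(sv), (int)x.size(), (float)gamma_eff,
                          log_transform, (float)eps_floor, niter, correct);
}

//' @noRd
// [[Rcpp::export(name = ".decision_score_cpp")]]
double decision_score_cpp(NumericVector x, NumericMatrix sv, NumericVector alphas,
                          double b, double gamma_eff, bool log_transform,
                          double eps_floor, int niter = 16, bool correct = true) {
  int L = sv.nrow(), k = sv.ncol();
  if ((int)x.size() != k) stop("feature vector length %td does not match support vectors (%d)",
                               (ptrdiff_t)x.size(), k);
  if ((int)alphas.size() != L) stop("alpha length does not match support-vector count");
  std::vector<double> row(k);
  float acc = 0.0f;
  for (int i = 0; i < L; ++i) {            // fixed ascending accumulation order
    for (int j = 0; j < k; ++j) row[j] = sv(i, j);
    float kv = kernel_f(REAL(x), row.data(), k, (float)gamma_eff,
                        log_transform, (float)eps_floor, niter, correct);
    acc = acc + (float)alphas[i] * kv;
  }
  return (double)(acc - (float)b);
}

//' @noRd
// [[Rcpp::export(name = ".dpu_score_cpp")]]
double dpu_score_cpp(NumericVector x, NumericMatrix sv, NumericVector alphas,
                     double b, double gamma_eff, bool log_transform,
                     double eps_floor, int niter = 16, bool correct = true) {
  int L = sv.nrow(), k = sv.ncol();
  if ((int)x.size() != k) stop("feature vector length does not match support vectors");
  if ((int)alphas.size() != L) stop("alpha length does not match support-vector count");
  // DPU stage 1: optional ln-normalization of the feature vector (once) and
  // of each support vector as it streams out of the ROM.
  std::vector<float> xf(k);
  for (int j = 0; j < k; ++j) {
    float u = (float)x[j];
    if (log_transform) {
      if (u <= 0.0f && (float)eps_floor > 0.0f) u = u + (float)eps_floor;
      if (u <= 0.0f) stop("dpuDataflowEval: nonpositive feature value under log transform");
      u = cordic_ln_f(u, niter, correct);
    }
    xf[j] = u;
  }
  float macc = 0.0f;
  for (int i = 0; i < L; ++i) {
    float dist = 0.0f;
    for (int j = 0; j < k; ++j) {
      float v = (float)sv(i, j);
      if (log_transform) {
        if (v <= 0.0f && (float)eps_floor > 0.0f) v = v + (float)eps_floor;
        if (v <= 0.0f) stop("dpuDataflowEval: nonpositive support-vector value under log transform");
        v = cordic_ln_f(v, niter, correct);
      }
      float d = xf[j] + (-v);        // subtraction as addition of the inverse code
      float sq = d * d;              // squaring through the multiplier
      dist = dist + sq;
    }
    float arg = -((float)gamma_eff * dist);
    float kv;
    if (arg == 0.0f) kv = 1.0f;
    else {
      kv = cordic_exp_f(arg, niter, correct);
      if (kv > 1.0f) kv = 1.0f;
    }
    macc = macc + (float)alphas[i] * kv;   // MAC with the dual coefficient
  }
  return (double)(macc + (-(float)b));     // final addition of the negated offset
}
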