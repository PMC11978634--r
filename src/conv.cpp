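// Valid 2-D convolution (stride 1, no padding) and 2x2/stride-2 max pooling
// in single precision.
//
// Two code paths compute each convolution: a direct nested-loop reference and
// an emulation of the pipelined hardware, in which K parallel row units (each
// a chain of K multiply-add-register PEs) form per-row partial sums that are
// then combined across rows. Both paths use the identical fp32 summation
// order — within a kernel row left to right (the PE chain), then across rows
// top to bottom, with the bias injected at the head of row 0 — so their
// outputs are bit-identical.

#include "epicircuit.h"
using namespace Rcpp;

static void check_conv_args(const NumericMatrix& input, const NumericMatrix& w) {
  int K = w.nrow();
  if (w.ncol() != K || (K != 1 && K != 3 && K != 5))
    stop("kernel must be square with size 1, 3 or 5");
  if (input.nrow() < K || input.ncol() < K)
    stop("input (%d x %d) smaller than kernel (%d x %d)",
         input.nrow(), input.ncol(), K, K);
}

// fp32 partial sum of kernel row kr at output position (r, c); bias enters at
// the head of row 0 (the first PE adds Bias after X00*W00, per the row-unit
// dataflow).
static inline float conv_row_sum(const NumericMatrix& input, const NumericMatrix& w,
                                 int r, int c, int kr, int K, float bias) {
  float s = (float)input(r + kr, c) * (float)w(kr, 0);
  if (kr == 0) s = s + bias;
  for (int kc = 1; kc < K; ++kc)
    s = s + (float)input(r + kr, c + kc) * (float)w(kr, kc);
  return s;
}

//' @noRd
// [[Rcpp::export(name = ".conv2d_direct_cpp")]]
NumericMatrix conv2d_direct_cpp(NumericMatrix input, NumericMatrix w,
                                double bias, bool relu) {
  check_conv_args(input, w);
  int K = w.nrow();
  int Ho = input.nrow() - K + 1, Wo = input.ncol() - K + 1;
  float biasf = (float)bias;
  NumericMatrix out(Ho, Wo);
  for (int r = 0; r < Ho; ++r) {
    for (int c = 0; c < Wo; ++c) {
      float tot = conv_row_sum(input, w, r, c, 0, K, biasf);
      for (int kr = 1; kr < K; ++kr)
        tot = tot + conv_row_sum(input, w, r, c, kr, K, biasf);
      if (relu && tot < 0.0f) tot = 0.0f;
      out(r, c) = (double)tot;
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".conv2d_pipelined_cpp")]]
List conv2d_pipelined_cpp(NumericMatrix input, NumericMatrix w,
                          double bias, bool relu) {
  check_conv_args(input, w);
  int K = w.nrow();
  int Ho = input.nrow() - K + 1, Wo = input.ncol() - K + 1;
  float biasf = (float)bias;
  NumericMatrix out(Ho, Wo);
  // Row-unit emulation: for each output row, the K row units sweep their
  // input row; unit kr holds the sliding partial sum of kernel row kr. A new
  // result leaves the array every cycle once the K-stage PE chains are full.
  std::vector<float> partial(K);
  for (int r = 0; r < Ho; ++r) {
    for (int c = 0; c < Wo; ++c) {
      for (int kr = 0; kr < K; ++kr)
        partial[kr] = conv_row_sum(input, w, r, c, kr, K, biasf);
      float tot = partial[0];
      for (int kr = 1; kr < K; ++kr) tot = tot + partial[kr];  // adder tree, top to bottom
      if (relu && tot < 0.0f) tot = 0.0f;
      out(r, c) = (double)tot;
    }
  }
  // Cycle model: K fill cycles for the PE chain, then one result per cycle.
  double cycles = (double)K + (double)Ho * (double)Wo;
  return List::create(_["output"] = out, _["cycles"] = cycles);
}

//' @noRd
// [[Rcpp::export(name = ".maxpool_two_stage_cpp")]]
List maxpool_two_stage_cpp(NumericMatrix input) {
  int H = input.nrow(), W = input.ncol();
  int Ho = H / 2, Wo = W / 2;
  if (H < 1 || W < 1) stop("maxpool: empty input");
  if (Ho < 1 || Wo < 1)
    stop("maxpool: input %d x %d leaves no complete 2 x 2 window", H, W);
  NumericMatrix out(Ho, Wo);
  for (int r = 0; r < Ho; ++r) {
    for (int c = 0; c < Wo; ++c) {
      // stage 1: two comparators at base clock
      float d0 = (float)input(2 * r, 2 * c),     d1 = (float)input(2 * r, 2 * c + 1);
      float d2 = (float)input(2 * r + 1, 2 * c), d3 = (float)input(2 * r + 1, 2 * c + 1);
      float m1 = (d0 > d1) ? d0 : d1;
      float m2 = (d2 > d3) ? d2 : d3;
      // stage 2: one comparator at half clock
      out(r, c) = (double)((m1 > m2) ? m1 : m2);
    }
  }
  // two comparison levels per window; the half-rate second level costs one
  // extra base-clock cycle per window
  double cycles = 2.0 * (double)Ho * (double)Wo;
  return List::create(_["output"] = out, _["cycles"] = cycles);
}
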