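#ifndef EPICIRCUIT_H
#define EPICIRCUIT_H

#include <Rcpp.h>
#include <cmath>
#include <vector>

// Hyperbolic CORDIC micro-iteration schedule: indices i = 1..niter with the
// standard convergence repeats at i = 4 and i = 13. niter <= 16.
std::vector<int> cordic_schedule(int niter);

// 1/K_h for a given schedule, rounded to single precision.
float cordic_inv_gain(const std::vector<int>& sched);

// Scalar fp32 CORDIC evaluations (range reduction included).
float cordic_exp_f(float v, int niter, bool correct);
float cordic_ln_f(float v, int niter, bool correct);

#endif
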