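---
title: "Methods: a bit-faithful software model of a CNN-SVM seizure-detection circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a bit-faithful software model of a CNN-SVM seizure-detection circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicircuit)
```

## The problem and the model

Epileptic seizures show up in scalp EEG as a characteristic spectral shift —
high-frequency power rises, low-frequency background activity falls, and
epileptiform transients (spikes, sharp waves) appear. A detector that runs on
a low-power chip next to the patient must classify short multichannel windows
(here 20 channels x 256 samples, single precision) as *ictal* (seizure) or
*interictal* (between seizures) quickly and with minimal arithmetic.

`epicircuit` is a software model of such a circuit, faithful down to the
arithmetic: every inference stage computes in IEEE-754 single precision, in a
fixed summation order, so the pipeline produces the numbers the datapath
would. The chain is

1. **FFT front end** — a 256-point radix-2 decimation-in-time FFT per
   channel; the classifier consumes the amplitude spectrum.
2. **CNN feature extractor** — three valid (no-padding, stride-1)
   convolution layers with 5x5, 3x3 and 1x1 kernels, each followed by ReLU
   and 2x2/stride-2 max pooling. A 20x256 input shrinks as
   16x252 -> 8x126 -> 6x124 -> 3x62 -> 3x62 -> 1x31, i.e. a length-31
   feature vector.
3. **Quasi-Gaussian-kernel SVM** — the decision function

   f(x) = sum_i alpha_i * exp( -gamma_eff * sum_j (x_j - sv_ij)^2 ) - b,

   where `gamma_eff = (max(s) - min(s))^2 / (sigma * (max(f) - min(f))^2)`
   folds the kernel width `sigma` and the min-max normalizers of the
   support-vector values `s` and training features `f` into one positive
   constant, precomputed at model build. The label is ictal when
   f(x) >= 0 (the standard SVM sign rule; nothing in the circuit suggests a
   different threshold). The exponential — and, on the hardware
   normalization path, the elementwise logarithm of features and support
   vectors — run through a 16-iteration hyperbolic CORDIC unit.

Because the typeset form of the kernel leaves the binding of the normalizers
and of `sigma` ambiguous, the package treats `gamma_eff` as the canonical
quantity: training calibrates it directly, and the stored `sigma` is
back-derived so the folded-constant identity holds exactly for every exported
bundle.

## Frame geometry and windowing

The 20x256 window is interpreted as 20 channels x 256 samples (1 s at
256 Hz). `segmentRecording()` supports two layouts:

* 20-channel recordings: one window per frame, channel-aligned,
  non-overlapping, trailing partial window dropped; windows that do not hold
  exactly 256 samples are linearly resampled to 256 columns.
* single-channel recordings: a 20 s window at 256 Hz holds exactly
  20 x 256 samples and is reshaped row-wise onto the frame. This reconciles
  "20-second segments" with the 20x256 input geometry for single-channel
  archives, and is the default (`windowS = 20`) for one-channel input.

The window length is exposed as `windowS` because the two conventions are
genuinely both in use; the frame type itself is fixed at 20x256.

## FFT front end

* The full two-sided amplitude spectrum is kept (not a one-sided 129-bin
  half), so the CNN input stays 20x256 and the 1x31 feature length is
  reachable. Rows are conjugate-symmetric in amplitude — with the
  symmetric fp32 twiddle ROM this symmetry holds *bit-exactly*, and the
  class validity relies on it.
* No window function is applied before the transform.
* Twiddle factors `W_256^m` are computed in double precision and rounded
  once to fp32 (the ROM contents); butterflies accumulate in fp32 to mirror
  the butterfly unit. Against an O(n^2) double-precision DFT the amplitude
  error stays below 1e-4 of the spectral peak (measured ~1.5e-7); "relative
  error" for spectra is always normalized by the largest oracle magnitude,
  since exact spectral zeros make per-bin ratios meaningless.
* Whether the CNN should see the raw window or its spectrum is left
  configurable (`pipelineConfig(useFFTFrontend = )`); the default is the
  spectral path, which is also what the synthetic study uses.

## Convolution and pooling

The convolution engine exists twice on purpose. `conv2dDirect()` is the
reference; `conv2dPipelined()` emulates the hardware organization — K
parallel row-operation units, each a chain of K multiply-add-register PEs,
with the bias injected at the head of row 0 and the K row partial sums
combined top to bottom. Both paths use that identical summation order
(within a kernel row left to right, then across rows), so they are
**bit-identical** in fp32, which the test suite asserts on thousands of
randomized cases. Max pooling uses the two-stage comparator scheme —
(Data0 vs Data1), (Data2 vs Data3), then the two winners — which equals the
window maximum exactly; ties are value-ties and need no tie-break rule, and
NaNs are rejected upstream by the frame invariants. Odd trailing rows or
columns are dropped (floor), the only convention that reproduces
3x62 -> 1x31.

## The CORDIC unit

Hyperbolic CORDIC with the standard repeated iterations at i = 4 and 13
(16 distinct indices, 18 micro-iterations; the repeats are required for
convergence). Rotation mode starts `x = 1/K_h` so the registers converge to
(cosh z, sinh z) directly; `exp(v)` uses Cody-Waite range reduction
`v = m ln2 + r`, `|r| <= ln2/2`, and rescales by `2^m` through exponent
arithmetic. `ln(v)` extracts the binary exponent, normalizes the mantissa to
`[1/sqrt(2), sqrt(2))` — so inputs near 1 produce exponent 0 and the final
`e*ln2 + ln f` sum cannot cancel catastrophically — and uses vectoring mode
on `ln f = 2 atanh((f-1)/(f+1))`.

Two register implementations are provided because the circuit description
fixes only the iteration count, not the datapath:

* `core = "fixed"` (default): 64-bit fixed-point registers with 40
  fractional guard bits and true arithmetic shifts — the conventional CORDIC
  datapath with guard bits, wrapped by float pack/unpack at the boundary.
* `core = "float"`: fp32 registers with the shift realized as an fp32
  multiply by the exact power of two `2^-i`.

The default is the fixed-point core: a pure fp32 angle accumulator loses
~1e-7 absolutely to cancellation of the large early rotation angles, which
is fatal to *relative* accuracy where `ln v` crosses zero. A mode-controlled
post-processing step folds the residual rotation angle back into the result
at first order (`z + y/x` in vectoring, `*(1 + z)` in rotation); with it the
measured worst-case relative error over 1e5-point sweeps is ~1.1e-6 for exp
on [-30, 30] and ~1.4e-7 for ln on [2^-30, 2^30], against a stated contract
of 1e-4 (the angle-ROM granularity at i = 16 is ~2^-16, which the residual
correction removes). The iteration count and the correction are exposed so
the raw 16- vs 12-iteration convergence behaviour can be examined
(`correct = FALSE`).

`exp` underflow to 0 below the fp32 range is permitted — relevant when the
epsilon floor (below) maps a zero feature to `ln(1e-7)` and the squared
distance becomes large.

## SVM evaluation routes

`decisionFunction()` is the direct arithmetic route; `dpuDataflowEval()`
emulates the data-processing-unit sequence (subtraction as addition of the
inverse code, squaring through the multiplier, kernel-scale multiply, CORDIC
exponential, multiply-accumulate with the dual coefficients, final addition
of the negated offset). Both honour the model's `logTransform` flag, use the
same fixed accumulation order (ascending support-vector index), and agree on
the label with score differences at 1e-6 or below (measured: bit-identical).
The kernel clamps to 1 from above — a nonpositive exponent cannot exceed 1,
and the clamp only removes post-correction rounding overshoot of order 1e-7.
ReLU features are nonnegative, so the ln-normalization path offers an
optional epsilon floor (1e-7) to admit exact zeros; without it a nonpositive
value is a domain error naming the option.

## Training

The circuit infers; training happens at desk scale and exports bundles.

* **CNN**: the three-layer stack plus a temporary linear head is fit by
  mini-batch SGD (momentum 0.9) on the logistic cross-entropy, in double
  precision; the head is discarded. Inputs are rescaled by one global factor
  (1/sd of the training values) for gradient stability; because the first
  layer is linear in its input before ReLU, the factor is folded *exactly*
  into the exported first-layer weights, so inference operates on raw data.
  The single 1x1 weight is initialized positive — a negative draw would make
  the third ReLU layer dead from the start. Defaults (12 epochs, learning
  rate 0.05, batch 16) were chosen once for stable convergence of the head
  on the default generator and are all exposed in `trainConfig()`.
* **SVM**: simplified SMO (pairwise coordinate ascent with the usual box
  constraints and KKT tolerance) on the training features extracted through
  the *fp32 inference path* — the same code that serves, so there is no
  train/serve skew; the trainer returns those features so tests can assert
  it. The kernel scale is calibrated as `gamma = 1` over the median pairwise
  squared feature distance when `sigma` is not given (the classic RBF
  heuristic), or provisionally as `1/sigma` when it is; after a first fit
  the scale is recomputed from the realized support-vector extrema per the
  folded-constant formula and the solver rerun once if it moved by more than
  1%. Exported weights round to fp32.
* Every random draw (initialization, shuffling, SMO partner choice, splits)
  comes from a private seeded stream; identical configurations reproduce
  identical bundles bit for bit, and the caller's RNG state is untouched.

## The synthetic generator

`generateFrames()` draws the two classes the detector must separate:

* interictal: per channel, three sinusoids with random frequencies in
  2-12 Hz, amplitudes 5-15, random phases, plus Gaussian noise (sd 2) — a
  band-limited stylization of posterior background rhythms;
* ictal: the same background attenuated by 0.5, three added 16-64 Hz
  components scaled by `highFreqGain` (default 2.5), and Poisson-placed
  (3/s per channel) biphasic spike-and-wave transients (~25 ms sharp phase,
  ~75 ms slow wave, peak 40-80 in signal units, random polarity).

This reproduces the qualitative ictal signature — raised high-band power,
lowered low-band power, discharges — with few parameters, and the band-power
ratio (16-64 Hz)/(1-8 Hz) separates the classes by construction. It does
**not** emulate real EEG's 1/f background, inter-channel correlation,
artifacts (muscle, eye, electrode), nonstationary seizure evolution, or
patient variability. Passing the end-to-end recovery test therefore shows
that the pipeline, training and inference are *correct and internally
consistent* on data with the assumed spectral structure — not that the
detector reaches any particular clinical accuracy. Clinical figures require
real archives (EDF recordings can be ingested via `readEDF()` +
`segmentRecording()`), which this package deliberately does not ship.

## Cycle model and latency

Latency is modelled in clock cycles, converted at a configurable clock
(default 10 MHz):

* K x K convolution over an `Ho x Wo` output: `K + Ho*Wo` (K fill cycles
  for the PE chain, then one result per cycle). An independent event-queue
  simulation of the row units reproduces these counts in the tests.
* pooling: 2 cycles per 2x2 window (two comparator levels; the second runs
  at half rate).
* SVM, per support vector: k subtract-square-accumulate cycles (k = 31),
  18 CORDIC micro-iterations for the exponential, and 2 MAC cycles; when
  the hardware normalization path is counted
  (`countNormalizationCycles = TRUE`, the default), each of the k streamed
  support-vector elements additionally passes through an 18-micro-iteration
  CORDIC ln, giving 609 cycles per support vector. Counting the
  normalization is what makes the SVM stage dominate the total for models
  with 100 or more support vectors, and puts a ~115-support-vector model at
  roughly 8 ms per detection at 10 MHz — the regime such a circuit operates
  in. Without it (51 cycles per SV) the convolution stages dominate until
  L ~ 146.

This is a dataflow model, not an RTL-validated count: control overhead,
memory stalls and bus contention are not represented, so per-stage counts
should be read as lower bounds with the relative stage weights being the
meaningful output.

```{r latency}
rep <- new("CycleReport",
           cycles = c(conv1 = 4037, pool1 = 2016, conv2 = 747, pool2 = 372,
                      conv3 = 187, pool3 = 62, svm = 115 * 609),
           clockHz = 1e7)
latencyReport(rep)
```

## Numerical conventions, in one place

* All inference values are fp32; `fp32Round()` is exposed and frame/model
  constructors apply it.
* Fixed summation orders everywhere two routes must agree bit for bit.
* Pooling comparisons use IEEE ordered `>`; frame validity rejects
  non-finite values upstream.
* Metric percentages round half-to-even to one decimal at reporting.
* JSON bundles store full-precision decimals; since every stored value is
  fp32-representable the round trip is exact.

## Problem sizes

The shipped tests train on up to 1,000 generated frames (the end-to-end
recovery study; ~25 s), sweep the CORDIC unit on 1e5-point grids, and check
datapath equivalence on ~1,000 randomized convolution cases and 1,000
random SVM models — sizes chosen so the whole suite exercises every
contract at full depth in about a minute of compute.

## Known limitations

* The trainer is desk-scale: single feature map per layer (forced by the
  1x31 output geometry), no augmentation, no hyperparameter search, no
  multiclass extension, no probability calibration.
* The ln-normalization training path approximates the CORDIC logarithm with
  the library `log` when building the kernel matrix; inference uses the
  CORDIC unit. The discrepancy (~1e-7 relative) is far below the margin of
  any trained model.
* The EDF reader covers the standard 16-bit EDF/EDF+ layout used by public
  EEG archives (annotation channels are dropped), not the full EDF+
  annotation model.
* No artifact removal or filtering front end: frames are classified as
  framed.
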