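Package: epicircuit
Title: Bit-Faithful Emulation of a Hybrid CNN-SVM EEG Seizure-Detection Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Software emulation of a hardware epilepsy-detection pipeline for
    multichannel EEG: a 256-point radix-2 FFT amplitude-spectrum front end, a
    three-layer configurable convolution stack with pipelined multiply-accumulate
    dataflow and cycle accounting, two-stage max pooling, and a quasi-Gaussian
    kernel support vector machine whose exponential and logarithmic operations
    run through a 16-iteration hyperbolic CORDIC unit. All inference arithmetic
    is carried out in IEEE-754 single precision to mirror the circuit datapath.
    Includes a synthetic ictal/interictal EEG generator, EDF and delimited-text
    readers, desk-scale CNN and SMO-based SVM training, confusion-count metrics,
    and per-stage latency reporting at a configurable clock frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
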