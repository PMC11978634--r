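## S4 classes for the detection circuit's data objects.

N_CHANNELS <- 20L
N_SAMPLES <- 256L
N_FEATURES <- 31L

#' One EEG analysis window
#'
#' A 20-channel x 256-sample window of single-precision voltage samples with
#' an optional ictal/interictal label. All values are stored rounded to fp32
#' so every downstream stage sees exactly what the circuit datapath would.
#'
#' @slot data 20 x 256 numeric matrix (values fp32-representable).
#' @slot label integer; 1 = ictal, 0 = interictal, NA = unlabelled.
#' @slot sampleRateHz positive sampling rate, default 256.
#' @exportClass EEGFrame
setClass("EEGFrame",
  representation(data = "matrix", label = "integer", sampleRateHz = "numeric"),
  prototype(label = NA_integer_, sampleRateHz = 256))

setValidity("EEGFrame", function(object) {
  d <- object@data
  if (!is.numeric(d) || !identical(dim(d), c(N_CHANNELS, N_SAMPLES)))
    return(sprintf("data must be a %d x %d numeric matrix", N_CHANNELS, N_SAMPLES))
  if (!all(is.finite(d))) return("data contains non-finite values")
  if (!identical(unname(d), unname(fp32Round(d))))
    return("data values must be single-precision representable")
  if (length(object@label) != 1L || !(is.na(object@label) || object@label %in% c(0L, 1L)))
    return("label must be a single value: 0, 1 or NA")
  if (length(object@sampleRateHz) != 1L || !is.finite(object@sampleRateHz) ||
      object@sampleRateHz <= 0)
    return("sampleRateHz must be a positive number")
  TRUE
})

#' Amplitude spectrum of an EEG window
#'
#' Two-sided FFT amplitude spectrum keeping the 20 x 256 geometry so the CNN
#' input shape is preserved; rows are conjugate-symmetric in amplitude because
#' the time-domain input is real.
#'
#' @slot amplitude 20 x 256 matrix of nonnegative single-precision values.
#' @slot sourceLabel label carried over from the source frame.
#' @exportClass SpectralFrame
setClass("SpectralFrame",
  representation(amplitude = "matrix", sourceLabel = "integer"),
  prototype(sourceLabel = NA_integer_))

setValidity("SpectralFrame", function(object) {
  a <- object@amplitude
  if (!is.numeric(a) || !identical(dim(a), c(N_CHANNELS, N_SAMPLES)))
    return(sprintf("amplitude must be a %d x %d numeric matrix", N_CHANNELS, N_SAMPLES))
  if (!all(is.finite(a)) || any(a < 0)) return("amplitudes must be finite and >= 0")
  TRUE
})

#' Synthetic-EEG generator configuration
#'
#' @slot seed integer RNG seed; identical configurations reproduce identical
#'   frame sets bit for bit.
#' @slot nFrames number of frames to generate.
#' @slot ictalFraction fraction of frames labelled ictal, in [0, 1].
#' @slot backgroundBandHz two-element band (low, high) of the interictal
#'   background oscillations, Hz.
#' @slot spikeRatePerS expected epileptiform spike count per second per
#'   channel in ictal frames.
#' @slot highFreqGain amplitude scale of the 16-64 Hz components added to
#'   ictal frames.
#' @slot noiseSd standard deviation of the additive Gaussian noise.
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(seed = "integer", nFrames = "integer", ictalFraction = "numeric",
                 backgroundBandHz = "numeric", spikeRatePerS = "numeric",
                 highFreqGain = "numeric", noiseSd = "numeric"))

setValidity("SynthConfig", function(object) {
  bad <- function(field, msg) sprintf("invalid '%s': %s", field, msg)
  if (length(object@seed) != 1L || is.na(object@seed)) return(bad("seed", "must be a single integer"))
  if (length(object@nFrames) != 1L || is.na(object@nFrames) || object@nFrames < 0L)
    return(bad("nFrames", "must be a nonnegative integer"))
  if (length(object@ictalFraction) != 1L || !is.finite(object@ictalFraction) ||
      object@ictalFraction < 0 || object@ictalFraction > 1)
    return(bad("ictalFraction", "must lie in [0, 1]"))
  b <- object@backgroundBandHz
  if (length(b) != 2L || !all(is.finite(b)) || b[1] <= 0 || b[2] <= b[1])
    return(bad("backgroundBandHz", "must be (low, high) with 0 < low < high"))
  if (length(object@spikeRatePerS) != 1L || !is.finite(object@spikeRatePerS) ||
      object@spikeRatePerS < 0)
    return(bad("spikeRatePerS", "must be nonnegative"))
  if (length(object@highFreqGain) != 1L || !is.finite(object@highFreqGain) ||
      object@highFreqGain <= 0)
    return(bad("highFreqGain", "must be positive"))
  if (length(object@noiseSd) != 1L || !is.finite(object@noiseSd) || object@noiseSd <= 0)
    return(bad("noiseSd", "must be positive"))
  TRUE
})

#' One configurable convolution layer
#'
#' @slot weights K x K single-precision kernel, K in {1, 3, 5}.
#' @slot bias scalar bias.
#' @slot activation "relu" or "none".
#' @exportClass ConvLayerSpec
setClass("ConvLayerSpec",
  representation(weights = "matrix", bias = "numeric", activation = "character"),
  prototype(bias = 0, activation = "relu"))

setValidity("ConvLayerSpec", function(object) {
  w <- object@weights
  if (!is.numeric(w) || nrow(w) != ncol(w) || !(nrow(w) %in% c(1L, 3L, 5L)))
    return("weights must be a square 1x1, 3x3 or 5x5 matrix")
  if (!all(is.finite(w))) return("weights must be finite")
  if (length(object@bias) != 1L || !is.finite(object@bias)) return("bias must be a finite scalar")
  if (!(object@activation %in% c("relu", "none"))) return("activation must be 'relu' or 'none'")
  TRUE
})

#' The three-layer CNN feature extractor
#'
#' Ordered 5x5, 3x3, 1x1 convolution layers, each followed by 2x2/stride-2
#' max pooling; applying the stack to a 20 x 256 input yields a length-31
#' feature vector.
#'
#' @slot layers list of exactly three \linkS4class{ConvLayerSpec} objects
#'   with kernel sizes 5, 3, 1 in that order.
#' @slot fitInfo list of training diagnostics (may be empty).
#' @exportClass CNNModel
setClass("CNNModel",
  representation(layers = "list", fitInfo = "list"),
  prototype(fitInfo = list()))

setValidity("CNNModel", function(object) {
  ls <- object@layers
  if (length(ls) != 3L || !all(vapply(ls, is, logical(1), "ConvLayerSpec")))
    return("layers must be a list of three ConvLayerSpec objects")
  ks <- vapply(ls, function(l) nrow(l@weights), integer(1))
  if (!identical(ks, c(5L, 3L, 1L)))
    return("kernel sizes must be 5, 3, 1 in order")
  TRUE
})

#' Quasi-Gaussian-kernel SVM model
#'
#' Decision function f(x) = sum_i alpha_i exp(-gamma_eff * sum_j
#' (x_j - sv_ij)^2) - b, with the min-max normalizers and the kernel width
#' sigma folded into the single positive scale
#' gamma_eff = (sMax - sMin)^2 / (sigma * (fMax - fMin)^2).
#'
#' @slot supportVectors L x 31 matrix of support vectors.
#' @slot alphas length-L signed dual coefficients (class labels folded in).
#' @slot b decision offset (subtracted from the kernel sum).
#' @slot sigma positive kernel width in squared-feature units.
#' @slot sMax,sMin extrema of the support-vector values.
#' @slot fMax,fMin extrema of the training feature values.
#' @slot gammaEff precomputed kernel scale.
#' @slot logTransform logical; evaluate the kernel on elementwise
#'   CORDIC-ln-transformed features (the hardware normalization path).
#' @slot epsFloor nonnegative floor added to nonpositive values before the log
#'   transform (0 disables it).
#' @exportClass SVMModel
setClass("SVMModel",
  representation(supportVectors = "matrix", alphas = "numeric", b = "numeric",
                 sigma = "numeric", sMax = "numeric", sMin = "numeric",
                 fMax = "numeric", fMin = "numeric", gammaEff = "numeric",
                 logTransform = "logical", epsFloor = "numeric"),
  prototype(logTransform = FALSE, epsFloor = 0))

setValidity("SVMModel", function(object) {
  sv <- object@supportVectors
  if (!is.numeric(sv) || nrow(sv) < 1L || ncol(sv) != N_FEATURES)
    return(sprintf("supportVectors must be an L x %d matrix with L >= 1", N_FEATURES))
  if (length(object@alphas) != nrow(sv)) return("alphas must have one entry per support vector")
  if (!all(is.finite(object@alphas)) || !all(is.finite(sv))) return("model values must be finite")
  if (length(object@gammaEff) != 1L || !is.finite(object@gammaEff) || object@gammaEff <= 0)
    return("gammaEff must be a positive scalar")
  if (object@sigma <= 0) return("sigma must be positive")
  if (!(object@fMax > object@fMin)) return("fMax must exceed fMin")
  if (object@sMax < object@sMin) return("sMax must be >= sMin")
  if (object@epsFloor < 0) return("epsFloor must be nonnegative")
  TRUE
})

#' Classification decision
#'
#' @slot score single-precision decision score f(x).
#' @slot label "ictal" if score >= 0, "interictal" otherwise.
#' @exportClass Decision
setClass("Decision", representation(score = "numeric", label = "character"))

setValidity("Decision", function(object) {
  if (length(object@score) != 1L || !is.finite(object@score)) return("score must be a finite scalar")
  want <- if (object@score >= 0) "ictal" else "interictal"
  if (!identical(object@label, want))
    return("label must be 'ictal' iff score >= 0")
  TRUE
})

#' Per-stage cycle counts
#'
#' Cycle counts for the seven pipeline stages, convertible to latency at a
#' configured clock frequency (default 10 MHz).
#'
#' @slot cycles named numeric vector of positive integers with names conv1,
#'   pool1, conv2, pool2, conv3, pool3, svm.
#' @slot clockHz positive clock frequency in Hz.
#' @exportClass CycleReport
setClass("CycleReport",
  representation(cycles = "numeric", clockHz = "numeric"),
  prototype(clockHz = 1e7))

CYCLE_STAGES <- c("conv1", "pool1", "conv2", "pool2", "conv3", "pool3", "svm")

setValidity("CycleReport", function(object) {
  cy <- object@cycles
  if (!identical(names(cy), CYCLE_STAGES))
    return(paste("cycles must be named", paste(CYCLE_STAGES, collapse = ", ")))
  if (!all(is.finite(cy)) || any(cy <= 0) || any(cy != round(cy)))
    return("cycle counts must be positive integers")
  if (length(object@clockHz) != 1L || !is.finite(object@clockHz) || object@clockHz <= 0)
    return("clockHz must be positive")
  TRUE
})

#' Confusion counts for the ictal-positive convention
#'
#' @slot TP,FP,TN,FN nonnegative integer counts; ictal is the positive class.
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
  representation(TP = "integer", FP = "integer", TN = "integer", FN = "integer"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@TP, object@FP, object@TN, object@FN)
  if (length(v) != 4L || any(is.na(v)) || any(v < 0L))
    return("TP, FP, TN, FN must be single nonnegative integers")
  TRUE
})

#' Training configuration
#'
#' @slot epochs CNN training epochs.
#' @slot learningRate SGD step size (0 freezes the weights at initialization).
#' @slot batchSize mini-batch size.
#' @slot seed RNG seed fixing initialization and shuffling.
#' @slot smoC SMO box constraint C.
#' @slot smoTol SMO KKT tolerance.
#' @slot smoMaxPasses SMO pass budget without alpha changes.
#' @slot sigma kernel width; NA selects it from the median pairwise squared
#'   feature distance at training time.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(epochs = "integer", learningRate = "numeric", batchSize = "integer",
                 seed = "integer", smoC = "numeric", smoTol = "numeric",
                 smoMaxPasses = "integer", sigma = "numeric"))

setValidity("TrainConfig", function(object) {
  if (object@epochs < 1L) return("epochs must be positive")
  if (!is.finite(object@learningRate) || object@learningRate < 0)
    return("learningRate must be nonnegative")
  if (object@batchSize < 1L) return("batchSize must be positive")
  if (is.na(object@seed)) return("seed must be an integer")
  if (object@smoC <= 0 || object@smoTol <= 0 || object@smoMaxPasses < 1L)
    return("smoC, smoTol and smoMaxPasses must be positive")
  if (!is.na(object@sigma) && object@sigma <= 0) return("sigma must be positive or NA (auto)")
  TRUE
})

#' Pipeline configuration
#'
#' @slot useFFTFrontend feed the CNN the FFT amplitude spectrum (TRUE, the
#'   default) or the raw time-domain window.
#' @slot clockHz clock frequency used for latency reporting; default 1e7.
#' @slot svmEvalPath "direct" or "dpu" (hardware-dataflow emulation).
#' @slot countNormalizationCycles include the CORDIC ln-normalization of each
#'   streamed support-vector element in the SVM-stage cycle count (the
#'   hardware normalizes; the arithmetic path need not).
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(useFFTFrontend = "logical", clockHz = "numeric",
                 svmEvalPath = "character", countNormalizationCycles = "logical"),
  prototype(useFFTFrontend = TRUE, clockHz = 1e7, svmEvalPath = "direct",
            countNormalizationCycles = TRUE))

setValidity("PipelineConfig", function(object) {
  if (length(object@clockHz) != 1L || !is.finite(object@clockHz) || object@clockHz <= 0)
    return("clockHz must be positive")
  if (!(object@svmEvalPath %in% c("direct", "dpu")))
    return("svmEvalPath must be 'direct' or 'dpu'")
  TRUE
})
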