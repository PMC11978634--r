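#' Round to single precision
#'
#' Rounds numeric values to the nearest IEEE-754 single-precision value (the
#' representation used throughout the emulated datapath), returned as doubles.
#'
#' @param x numeric vector or matrix.
#' @return `x` with every element rounded to fp32; dimensions preserved.
#' @export
#' @examples
#' fp32Round(0.1) == 0.1
fp32Round <- function(x) {
  stopifnot(is.numeric(x))
  out <- .fp32_round_cpp(as.numeric(x))
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

#' Construct an EEG analysis window
#'
#' @param data 20 x 256 numeric matrix of voltage samples; rounded to fp32.
#' @param label 1 (ictal), 0 (interictal) or NA (unlabelled).
#' @param sampleRateHz sampling rate, default 256.
#' @return An \linkS4class{EEGFrame}.
#' @export
eegFrame <- function(data, label = NA_integer_, sampleRateHz = 256) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("shape error: 'data' must be a numeric matrix")
  if (!identical(dim(data), c(N_CHANNELS, N_SAMPLES)))
    stop(sprintf("shape error: expected %d x %d, observed %d x %d",
                 N_CHANNELS, N_SAMPLES, nrow(data), ncol(data)))
  new("EEGFrame", data = unname(fp32Round(data)), label = as.integer(label),
      sampleRateHz = as.numeric(sampleRateHz))
}

#' Synthetic-EEG generator configuration
#'
#' Defaults describe the emulated recording conditions: a 2-12 Hz band-limited
#' interictal background with Gaussian noise, and ictal windows with the low
#' band attenuated, 16-64 Hz components added and Poisson-placed biphasic
#' spike-wave transients.
#'
#' @param seed integer RNG seed.
#' @param nFrames number of frames.
#' @param ictalFraction fraction of ictal frames.
#' @param backgroundBandHz interictal oscillation band, Hz.
#' @param spikeRatePerS expected spikes per second per channel (ictal).
#' @param highFreqGain amplitude scale of the ictal high-frequency components.
#' @param noiseSd additive noise standard deviation.
#' @return A \linkS4class{SynthConfig}.
#' @export
synthConfig <- function(seed = 1L, nFrames = 100L, ictalFraction = 0.5,
                        backgroundBandHz = c(2, 12), spikeRatePerS = 3,
                        highFreqGain = 2.5, noiseSd = 2) {
  new("SynthConfig", seed = as.integer(seed), nFrames = as.integer(nFrames),
      ictalFraction = as.numeric(ictalFraction),
      backgroundBandHz = as.numeric(backgroundBandHz),
      spikeRatePerS = as.numeric(spikeRatePerS),
      highFreqGain = as.numeric(highFreqGain), noiseSd = as.numeric(noiseSd))
}

#' Construct a convolution layer
#'
#' @param weights square 1x1, 3x3 or 5x5 numeric kernel; rounded to fp32.
#' @param bias scalar bias; rounded to fp32.
#' @param activation "relu" or "none".
#' @return A \linkS4class{ConvLayerSpec}.
#' @export
convLayerSpec <- function(weights, bias = 0, activation = c("relu", "none")) {
  activation <- match.arg(activation)
  new("ConvLayerSpec", weights = unname(fp32Round(as.matrix(weights))),
      bias = fp32Round(bias), activation = activation)
}

#' Construct the three-layer CNN model
#'
#' @param layers list of three \linkS4class{ConvLayerSpec}s (5x5, 3x3, 1x1).
#' @param fitInfo optional list of training diagnostics.
#' @return A \linkS4class{CNNModel}.
#' @export
cnnModel <- function(layers, fitInfo = list()) {
  new("CNNModel", layers = layers, fitInfo = fitInfo)
}

#' Construct a quasi-Gaussian-kernel SVM model
#'
#' `gammaEff` defaults to the precomputed scale
#' `(sMax - sMin)^2 / (sigma * (fMax - fMin)^2)` that folds the kernel width
#' and the min-max normalizers of the decision function into one constant.
#'
#' @param supportVectors L x 31 matrix.
#' @param alphas length-L signed dual coefficients.
#' @param b decision offset.
#' @param sigma kernel width (squared-feature units).
#' @param fMax,fMin training-feature extrema.
#' @param sMax,sMin support-vector extrema; default computed from
#'   `supportVectors`.
#' @param gammaEff kernel scale; default from the closed form above.
#' @param logTransform evaluate the kernel on CORDIC-ln-transformed values.
#' @param epsFloor floor added to nonpositive values before the log transform.
#' @return An \linkS4class{SVMModel}.
#' @export
svmModel <- function(supportVectors, alphas, b, sigma, fMax, fMin,
                     sMax = max(supportVectors), sMin = min(supportVectors),
                     gammaEff = NULL, logTransform = FALSE, epsFloor = 0) {
  supportVectors <- unname(fp32Round(as.matrix(supportVectors)))
  if (is.null(gammaEff))
    gammaEff <- (sMax - sMin)^2 / (sigma * (fMax - fMin)^2)
  new("SVMModel", supportVectors = supportVectors,
      alphas = fp32Round(as.numeric(alphas)), b = fp32Round(b),
      sigma = as.numeric(sigma), sMax = as.numeric(sMax), sMin = as.numeric(sMin),
      fMax = as.numeric(fMax), fMin = as.numeric(fMin),
      gammaEff = fp32Round(gammaEff), logTransform = isTRUE(logTransform),
      epsFloor = as.numeric(epsFloor))
}

#' Construct confusion counts (ictal = positive class)
#'
#' @param TP,FP,TN,FN nonnegative integer counts.
#' @return A \linkS4class{ConfusionCounts}.
#' @export
confusionCounts <- function(TP = 0L, FP = 0L, TN = 0L, FN = 0L) {
  new("ConfusionCounts", TP = as.integer(TP), FP = as.integer(FP),
      TN = as.integer(TN), FN = as.integer(FN))
}

#' Training configuration
#'
#' @param epochs CNN epochs (default 12).
#' @param learningRate SGD step size (default 0.05; 0 freezes initialization).
#' @param batchSize mini-batch size (default 16).
#' @param seed RNG seed (default 1).
#' @param smoC SMO box constraint (default 1).
#' @param smoTol SMO tolerance (default 1e-3).
#' @param smoMaxPasses SMO pass budget (default 10).
#' @param sigma kernel width; NA (default) selects it from the median pairwise
#'   squared feature distance.
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(epochs = 12L, learningRate = 0.05, batchSize = 16L,
                        seed = 1L, smoC = 1, smoTol = 1e-3, smoMaxPasses = 10L,
                        sigma = NA_real_) {
  new("TrainConfig", epochs = as.integer(epochs), learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), seed = as.integer(seed),
      smoC = as.numeric(smoC), smoTol = as.numeric(smoTol),
      smoMaxPasses = as.integer(smoMaxPasses), sigma = as.numeric(sigma))
}

#' Pipeline configuration
#'
#' @param useFFTFrontend feed the CNN the FFT amplitude spectrum (default TRUE).
#' @param clockHz clock frequency for latency conversion (default 1e7).
#' @param svmEvalPath "direct" arithmetic or "dpu" dataflow emulation.
#' @param countNormalizationCycles count the CORDIC ln-normalization of
#'   streamed support-vector elements in the SVM-stage cycles (default TRUE).
#' @return A \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(useFFTFrontend = TRUE, clockHz = 1e7,
                           svmEvalPath = c("direct", "dpu"),
                           countNormalizationCycles = TRUE) {
  svmEvalPath <- match.arg(svmEvalPath)
  new("PipelineConfig", useFFTFrontend = isTRUE(useFFTFrontend),
      clockHz = as.numeric(clockHz), svmEvalPath = svmEvalPath,
      countNormalizationCycles = isTRUE(countNormalizationCycles))
}
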