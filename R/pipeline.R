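## End-to-end orchestration: preprocess -> FFT -> CNN -> SVM -> metrics, with
## per-stage cycle accounting and latency reporting.

# SVM-stage cycle model, per support vector: k subtract-square-accumulate
# cycles + 18 CORDIC micro-iterations for the exponential + 2 MAC cycles;
# when the hardware normalization path is counted, each of the k streamed
# support-vector elements additionally passes through an 18-micro-iteration
# CORDIC ln.
svmStageCycles <- function(L, k = N_FEATURES, countNormalization = TRUE,
                           microIter = 18L) {
  per <- k + microIter + 2L
  if (countNormalization) per <- per + k * microIter
  as.numeric(L) * per
}

#' Run one detection through the full circuit
#'
#' Optional FFT amplitude-spectrum front end, the three-layer conv/pool
#' feature extractor, and the SVM decision (direct arithmetic or DPU dataflow
#' emulation), with per-stage cycle counts.
#'
#' @param frame an \linkS4class{EEGFrame}.
#' @param cnn a \linkS4class{CNNModel}.
#' @param svm an \linkS4class{SVMModel}.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @return List with `decision` (\linkS4class{Decision}), `report`
#'   (\linkS4class{CycleReport}) and `features`.
#' @export
runDetection <- function(frame, cnn, svm, cfg = pipelineConfig()) {
  stopifnot(is(frame, "EEGFrame"), is(cnn, "CNNModel"), is(svm, "SVMModel"),
            is(cfg, "PipelineConfig"))
  input <- if (cfg@useFFTFrontend) amplitudeSpectrum(frame) else frame
  fx <- extractFeatures(input, cnn)
  evalFun <- if (cfg@svmEvalPath == "dpu") dpuDataflowEval else decisionFunction
  decision <- evalFun(fx$features, svm)
  cycles <- c(fx$cycles,
              svm = svmStageCycles(nrow(svm@supportVectors),
                                   countNormalization = cfg@countNormalizationCycles))
  report <- new("CycleReport", cycles = cycles[CYCLE_STAGES], clockHz = cfg@clockHz)
  list(decision = decision, report = report, features = fx$features)
}

#' Evaluate the circuit over a labelled frame set
#'
#' Runs [runDetection()] per frame, accumulates confusion counts and computes
#' the three evaluation statistics.
#'
#' @param frames nonempty list of labelled \linkS4class{EEGFrame}s.
#' @param cnn,svm model bundles.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @return List with `counts` (\linkS4class{ConfusionCounts}), `metrics`
#'   (list), `decisions` and `report` (the per-frame
#'   \linkS4class{CycleReport}, identical across frames).
#' @export
runEvaluation <- function(frames, cnn, svm, cfg = pipelineConfig()) {
  if (length(frames) == 0L) stop("empty frame set")
  labels <- vapply(frames, frameLabel, integer(1))
  if (anyNA(labels)) stop("argument error: unlabelled frame in evaluation set")
  runs <- lapply(frames, runDetection, cnn = cnn, svm = svm, cfg = cfg)
  counts <- accumulateCounts(lapply(runs, `[[`, "decision"), labels)
  list(counts = counts, metrics = metricsReport(counts),
       decisions = lapply(runs, `[[`, "decision"),
       report = runs[[1L]]$report)
}

#' Per-stage latency table
#'
#' Converts a \linkS4class{CycleReport} to a stage table with cycles,
#' milliseconds at the configured clock, and a cumulative latency column
#' (monotone nondecreasing; the SVM stage is listed last).
#'
#' @param report a \linkS4class{CycleReport}.
#' @return data.frame with columns `stage`, `cycles`, `ms`, `cumulative_ms`.
#' @export
#' @examples
#' rep <- new("CycleReport",
#'            cycles = c(conv1 = 4037, pool1 = 2016, conv2 = 747, pool2 = 372,
#'                       conv3 = 187, pool3 = 62, svm = 60900),
#'            clockHz = 1e7)
#' latencyReport(rep)
latencyReport <- function(report) {
  stopifnot(is(report, "CycleReport"))
  cy <- report@cycles
  ms <- 1e3 * cy / report@clockHz
  data.frame(stage = names(cy), cycles = unname(cy), ms = unname(ms),
             cumulative_ms = cumsum(unname(ms)))
}
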