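## Quasi-Gaussian-kernel SVM decision function (fp32), two evaluation routes.

#' Kernel value between a feature vector and one support vector
#'
#' `exp(-gammaEff * sum_j (u_j - v_j)^2)` in fp32, where `(u, v)` are the
#' feature/support values or their elementwise CORDIC-ln images when the
#' model's log transform is on; the exponential is computed by [cordicExp()].
#' The value lies in (0, 1], reaching 1 exactly when the transformed vectors
#' coincide.
#'
#' @param x numeric feature vector (length 31).
#' @param svRow one support vector (length 31).
#' @param model an \linkS4class{SVMModel} (supplies `gammaEff`,
#'   `logTransform`, `epsFloor`).
#' @return Kernel value in (0, 1].
#' @export
kernelEval <- function(x, svRow, model) {
  stopifnot(is(model, "SVMModel"))
  .kernel_eval_cpp(as.numeric(x), as.numeric(svRow), model@gammaEff,
                   model@logTransform, model@epsFloor)
}

#' SVM decision function (direct arithmetic route)
#'
#' `score = sum_i alpha_i * K(x, sv_i) - b`, accumulated in fp32 in ascending
#' support-vector order; the label is ictal when the score is >= 0.
#'
#' @param x numeric feature vector (length 31) or the `features` element of
#'   [extractFeatures()].
#' @param model an \linkS4class{SVMModel}.
#' @return A \linkS4class{Decision}.
#' @export
decisionFunction <- function(x, model) {
  stopifnot(is(model, "SVMModel"))
  score <- .decision_score_cpp(as.numeric(x), model@supportVectors,
                               model@alphas, model@b, model@gammaEff,
                               model@logTransform, model@epsFloor)
  newDecision(score)
}

#' SVM decision function (DPU dataflow emulation)
#'
#' Emulates the hardware data-processing-unit sequence: optional CORDIC
#' ln-normalization of the feature vector and of each support vector streamed
#' from the ROM, subtraction as addition of the inverse code, squaring
#' through the multiplier, scaling by `gammaEff`, CORDIC exponential,
#' multiply-accumulate with the dual coefficients, and final addition of the
#' negated offset. Labels agree with [decisionFunction()]; scores agree to
#' within 1e-6.
#'
#' @inheritParams decisionFunction
#' @return A \linkS4class{Decision}.
#' @export
dpuDataflowEval <- function(x, model) {
  stopifnot(is(model, "SVMModel"))
  score <- .dpu_score_cpp(as.numeric(x), model@supportVectors,
                          model@alphas, model@b, model@gammaEff,
                          model@logTransform, model@epsFloor)
  newDecision(score)
}

newDecision <- function(score) {
  new("Decision", score = score,
      label = if (score >= 0) "ictal" else "interictal")
}

#' Random SVM model
#'
#' Seeded random model with L support vectors, used by property tests and the
#' latency model.
#'
#' @param seed RNG seed.
#' @param L number of support vectors.
#' @param gammaEff kernel scale.
#' @param logTransform hardware normalization path on/off.
#' @param positive force all support-vector values positive (needed under the
#'   log transform).
#' @return An \linkS4class{SVMModel}.
#' @export
randomSVMModel <- function(seed = 1L, L = 50L, gammaEff = 0.5,
                           logTransform = FALSE, positive = logTransform) {
  withLocalSeed(seed, {
    sv <- matrix(runif(L * N_FEATURES, if (positive) 0.1 else -1, 1),
                 L, N_FEATURES)
    alphas <- rnorm(L)
    fMax <- max(sv) + 0.5
    fMin <- min(sv) - 0.5
    sigma <- (max(sv) - min(sv))^2 / (gammaEff * (fMax - fMin)^2)
    svmModel(sv, alphas, b = rnorm(1, sd = 0.1), sigma = sigma,
             fMax = fMax, fMin = fMin, gammaEff = gammaEff,
             logTransform = logTransform,
             epsFloor = if (logTransform) 1e-7 else 0)
  })
}
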