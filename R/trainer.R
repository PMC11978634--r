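## Desk-scale training: CNN feature extractor by mini-batch SGD with a
## discardable linear head, then an SMO-trained quasi-Gaussian-kernel SVM on
## the extracted features. Training runs in double precision; weights are
## rounded to fp32 at bundle export so inference honours the datapath
## contract.

# Linear indices for im2col: row p of the result indexes output position
# (r, c) in column-major order; column t indexes kernel tap (kr, kc) in
# column-major order.
im2colIndex <- function(H, W, K) {
  Ho <- H - K + 1L
  Wo <- W - K + 1L
  r <- rep(seq_len(Ho), Wo)
  cc <- rep(seq_len(Wo), each = Ho)
  idx <- matrix(0L, Ho * Wo, K * K)
  t <- 0L
  for (kc in seq_len(K)) for (kr in seq_len(K)) {
    t <- t + 1L
    idx[, t] <- (cc + kc - 2L) * H + (r + kr - 1L)
  }
  idx
}

convFwdD <- function(A, idx, wvec, bias, Ho, Wo) {
  C <- A[idx]
  dim(C) <- dim(idx)
  Z <- C %*% wvec + bias
  dim(Z) <- c(Ho, Wo)
  list(Z = Z, C = C)
}

convBwdD <- function(cache, dZ, wvec, Hin, Win, idx, needInput = TRUE) {
  dZv <- as.numeric(dZ)
  dW <- crossprod(cache$C, dZv)
  db <- sum(dZv)
  dA <- NULL
  if (needInput) {
    dA <- numeric(Hin * Win)
    for (t in seq_along(wvec)) dA[idx[, t]] <- dA[idx[, t]] + dZv * wvec[t]
    dim(dA) <- c(Hin, Win)
  }
  list(dW = as.numeric(dW), db = db, dA = dA)
}

poolFwdD <- function(A) {
  H <- nrow(A); W <- ncol(A)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  r0 <- seq_len(Ho) * 2L - 1L
  c0 <- seq_len(Wo) * 2L - 1L
  win <- list(A[r0, c0, drop = FALSE], A[r0 + 1L, c0, drop = FALSE],
              A[r0, c0 + 1L, drop = FALSE], A[r0 + 1L, c0 + 1L, drop = FALSE])
  P <- win[[1L]]
  arg <- matrix(1L, Ho, Wo)
  for (k in 2:4) {
    sel <- win[[k]] > P
    P[sel] <- win[[k]][sel]
    arg[sel] <- k
  }
  radd <- c(0L, 1L, 0L, 1L)[arg]
  cadd <- c(0L, 0L, 1L, 1L)[arg]
  rr <- matrix(r0, Ho, Wo)
  cc <- matrix(c0, Ho, Wo, byrow = TRUE)
  lin <- (cc + cadd - 1L) * H + (rr + radd)
  list(P = P, lin = as.integer(lin), H = H, W = W)
}

poolBwdD <- function(cache, dP) {
  dA <- numeric(cache$H * cache$W)
  dA[cache$lin] <- as.numeric(dP)
  dim(dA) <- c(cache$H, cache$W)
  dA
}

# Full forward/backward pass for one sample; par holds w1..w3 (vectors),
# b1..b3, head weights wh, bh. Returns loss gradient contributions.
cnnTrainPass <- function(A0, y, par, geom) {
  f1 <- convFwdD(A0, geom$idx1, par$w1, par$b1, 16L, 252L)
  A1 <- pmax(f1$Z, 0)
  p1 <- poolFwdD(A1)
  f2 <- convFwdD(p1$P, geom$idx2, par$w2, par$b2, 6L, 124L)
  A2 <- pmax(f2$Z, 0)
  p2 <- poolFwdD(A2)
  f3 <- convFwdD(p2$P, geom$idx3, par$w3, par$b3, 3L, 62L)
  A3 <- pmax(f3$Z, 0)
  p3 <- poolFwdD(A3)
  x <- as.numeric(p3$P)
  logit <- sum(par$wh * x) + par$bh
  p <- plogis(logit)
  loss <- -(y * log(max(p, 1e-12)) + (1 - y) * log(max(1 - p, 1e-12)))

  dlogit <- p - y
  dwh <- dlogit * x
  dbh <- dlogit
  dx <- dlogit * par$wh
  dA3 <- poolBwdD(p3, matrix(dx, 1L, 31L))
  dZ3 <- dA3 * (f3$Z > 0)
  g3 <- convBwdD(f3, dZ3, par$w3, 3L, 62L, geom$idx3)
  dA2 <- poolBwdD(p2, g3$dA)
  dZ2 <- dA2 * (f2$Z > 0)
  g2 <- convBwdD(f2, dZ2, par$w2, 8L, 126L, geom$idx2)
  dA1 <- poolBwdD(p1, g2$dA)
  dZ1 <- dA1 * (f1$Z > 0)
  g1 <- convBwdD(f1, dZ1, par$w1, 20L, 256L, geom$idx1, needInput = FALSE)

  list(loss = loss, correct = as.integer((logit > 0) == (y == 1)),
       grads = list(w1 = g1$dW, b1 = g1$db, w2 = g2$dW, b2 = g2$db,
                    w3 = g3$dW, b3 = g3$db, wh = dwh, bh = dbh))
}

trainInputMatrix <- function(f) {
  if (is(f, "EEGFrame")) f@data
  else if (is(f, "SpectralFrame")) f@amplitude
  else if (is.matrix(f)) f
  else stop("frames must be EEGFrame, SpectralFrame or matrix objects")
}

trainInputLabel <- function(f) {
  if (is(f, "EEGFrame") || is(f, "SpectralFrame")) frameLabel(f) else NA_integer_
}

#' Train the CNN feature extractor
#'
#' Fits the 5x5 / 3x3 / 1x1 convolution stack with a temporary linear
#' classification head by mini-batch SGD (momentum 0.9) on the logistic
#' cross-entropy; the head is discarded and only the kernels and biases are
#' returned. Training runs in double precision on inputs rescaled by a single
#' global factor for gradient stability; the factor is folded exactly into
#' the exported first-layer weights, so the returned model operates on raw
#' inputs. Deterministic under the configuration seed.
#'
#' @param frames list of labelled \linkS4class{EEGFrame} or
#'   \linkS4class{SpectralFrame} objects (or matrices, with `labels`
#'   supplied).
#' @param cfg a \linkS4class{TrainConfig}.
#' @param labels optional explicit 0/1 labels overriding the frame labels.
#' @return A \linkS4class{CNNModel}; `@fitInfo` holds the per-epoch loss, the
#'   final training accuracy of the temporary head (`headAccuracy`) and the
#'   folded input scale.
#' @export
trainCNN <- function(frames, cfg, labels = NULL) {
  stopifnot(is(cfg, "TrainConfig"))
  validObject(cfg)
  mats <- lapply(frames, trainInputMatrix)
  if (is.null(labels)) labels <- vapply(frames, trainInputLabel, integer(1))
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("training error: all frames must be labelled")
  if (length(unique(labels)) < 2L)
    stop("training error: both classes must be present")

  scale <- 1 / max(sd(unlist(lapply(mats, as.numeric))), 1e-12)
  mats <- lapply(mats, function(m) m * scale)
  geom <- list(idx1 = im2colIndex(20L, 256L, 5L),
               idx2 = im2colIndex(8L, 126L, 3L),
               idx3 = im2colIndex(3L, 62L, 1L))
  n <- length(mats)
  withLocalSeed(cfg@seed, {
    # He-style kernels; the single 1x1 weight starts positive so the third
    # ReLU layer cannot be dead at initialization
    par <- list(w1 = rnorm(25, sd = sqrt(2 / 25)), b1 = 0,
                w2 = rnorm(9, sd = sqrt(2 / 9)), b2 = 0,
                w3 = abs(rnorm(1, sd = 1)) + 0.5, b3 = 0,
                wh = numeric(31), bh = 0)
    init <- par
    vel <- lapply(par, function(p) p * 0)
    lr <- cfg@learningRate
    mom <- 0.9
    lossHist <- numeric(cfg@epochs)
    headAcc <- NA_real_
    for (ep in seq_len(cfg@epochs)) {
      ord <- sample.int(n)
      epLoss <- 0
      nCorrect <- 0L
      for (start in seq(1L, n, by = cfg@batchSize)) {
        batch <- ord[start:min(start + cfg@batchSize - 1L, n)]
        acc <- NULL
        for (i in batch) {
          pass <- cnnTrainPass(mats[[i]], labels[i], par, geom)
          epLoss <- epLoss + pass$loss
          nCorrect <- nCorrect + pass$correct
          acc <- if (is.null(acc)) pass$grads
                 else Map(`+`, acc, pass$grads)
        }
        if (lr > 0) {
          acc <- lapply(acc, function(g) g / length(batch))
          vel <- Map(function(v, g) mom * v - lr * g, vel, acc)
          par <- Map(`+`, par, vel)
        }
      }
      lossHist[ep] <- epLoss / n
      headAcc <- nCorrect / n
    }
    if (lr == 0) par <- init
    layers <- list(
      convLayerSpec(matrix(par$w1, 5, 5) * scale, par$b1, "relu"),
      convLayerSpec(matrix(par$w2, 3, 3), par$b2, "relu"),
      convLayerSpec(matrix(par$w3, 1, 1), par$b3, "relu"))
    cnnModel(layers, fitInfo = list(loss = lossHist, headAccuracy = headAcc,
                                    inputScale = scale, seed = cfg@seed))
  })
}

# Simplified SMO (pairwise coordinate ascent on the dual) over a precomputed
# kernel matrix; returns alphas (box-constrained) and the threshold b with
# the score convention f(x) = sum_i alpha_i y_i K(x_i, x) - b.
smoFit <- function(Kmat, y, C, tol, maxPasses) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  Fv <- numeric(n)  # current sum_i alpha_i y_i K(., i)
  passes <- 0L
  iterGuard <- 0L
  while (passes < maxPasses) {
    changed <- 0L
    for (i in seq_len(n)) {
      Ei <- Fv[i] - b - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) || (y[i] * Ei > tol && alpha[i] > 0)) {
        j <- sample.int(n - 1L, 1L)
        if (j >= i) j <- j + 1L
        Ej <- Fv[j] - b - y[j]
        aI <- alpha[i]; aJ <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aJ - aI); H <- min(C, C + aJ - aI)
        } else {
          L <- max(0, aI + aJ - C); H <- min(C, aI + aJ)
        }
        if (L >= H) next
        eta <- 2 * Kmat[i, j] - Kmat[i, i] - Kmat[j, j]
        if (eta >= 0) next
        aJnew <- aJ - y[j] * (Ei - Ej) / eta
        aJnew <- min(max(aJnew, L), H)
        if (abs(aJnew - aJ) < 1e-7) next
        aInew <- aI + y[i] * y[j] * (aJ - aJnew)
        dI <- (aInew - aI) * y[i]
        dJ <- (aJnew - aJ) * y[j]
        b1 <- b + Ei + dI * Kmat[i, i] + dJ * Kmat[i, j]
        b2 <- b + Ej + dI * Kmat[i, j] + dJ * Kmat[j, j]
        b <- if (aInew > 0 && aInew < C) b1
             else if (aJnew > 0 && aJnew < C) b2
             else (b1 + b2) / 2
        alpha[i] <- aInew
        alpha[j] <- aJnew
        Fv <- Fv + dI * Kmat[, i] + dJ * Kmat[, j]
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
    iterGuard <- iterGuard + 1L
    if (iterGuard > 200L) break  # safety valve on pathological inputs
  }
  list(alpha = alpha, b = b)
}

#' Train the quasi-Gaussian-kernel SVM
#'
#' SMO on the dual problem with the kernel
#' `exp(-gamma * sum_j (x_j - x'_j)^2)`. The scale `gamma` comes from the
#' configured width `sigma` (provisionally assuming the support-vector
#' extrema equal the feature extrema, i.e. `gamma = 1/sigma`) or, when
#' `sigma` is NA, from the median pairwise squared feature distance. After a
#' first fit the scale is recomputed from the realized support-vector extrema
#' per the folded-constant formula and the solver is rerun once if it moved
#' by more than 1%. The stored `sigma` is back-derived so that
#' `gammaEff = (sMax - sMin)^2 / (sigma * (fMax - fMin)^2)` holds exactly for
#' the exported bundle.
#'
#' @param features n x 31 numeric matrix of feature vectors.
#' @param labels 0/1 (or -1/+1) class labels, 1 = ictal.
#' @param cfg a \linkS4class{TrainConfig}.
#' @param logTransform build the model with the hardware ln-normalization
#'   path enabled (features are ln-transformed before distance computation,
#'   both here and at inference).
#' @return An \linkS4class{SVMModel}.
#' @export
trainSVM <- function(features, labels, cfg, logTransform = FALSE) {
  stopifnot(is(cfg, "TrainConfig"))
  features <- as.matrix(features)
  y <- ifelse(as.numeric(labels) > 0, 1, -1)
  if (length(unique(y)) < 2L) stop("training error: both classes must be present")
  if (nrow(features) != length(y)) stop("feature/label length mismatch")
  epsFloor <- if (logTransform) 1e-7 else 0
  X <- if (logTransform) log(pmax(features, 0) + max(epsFloor, 1e-7)) else features
  if (nrow(unique(X)) == 1L)
    stop("training error: degenerate features (all identical)")

  fMax <- max(X); fMin <- min(X)
  if (!(fMax > fMin)) stop("training error: degenerate features (zero range)")
  D2 <- as.matrix(dist(X))^2
  withLocalSeed(cfg@seed, {
    if (is.na(cfg@sigma)) {
      med <- median(D2[upper.tri(D2)][D2[upper.tri(D2)] > 0])
      gamma <- 1 / med
    } else {
      gamma <- 1 / cfg@sigma
    }
    fit <- smoFit(exp(-gamma * D2), y, cfg@smoC, cfg@smoTol, cfg@smoMaxPasses)
    svIdx <- which(fit$alpha > 1e-8)
    if (length(svIdx) == 0L) stop("training error: no support vectors found")
    sRange <- diff(range(X[svIdx, ]))
    gamma2 <- gamma * (sRange / (fMax - fMin))^2
    if (abs(gamma2 - gamma) / gamma > 0.01) {
      fit <- smoFit(exp(-gamma2 * D2), y, cfg@smoC, cfg@smoTol, cfg@smoMaxPasses)
      svIdx <- which(fit$alpha > 1e-8)
      if (length(svIdx) == 0L) stop("training error: no support vectors found")
      gamma <- gamma2
    }
    sv <- features[svIdx, , drop = FALSE]
    sMax <- max(X[svIdx, ]); sMin <- min(X[svIdx, ])
    sigmaStored <- (sMax - sMin)^2 / (gamma * (fMax - fMin)^2)
    svmModel(sv, alphas = fit$alpha[svIdx] * y[svIdx], b = fit$b,
             sigma = sigmaStored, fMax = fMax, fMin = fMin,
             sMax = sMax, sMin = sMin, gammaEff = gamma,
             logTransform = logTransform, epsFloor = epsFloor)
  })
}

#' Train the full detection pipeline
#'
#' Stratified 80/20 split under the configuration seed, CNN training on the
#' training split, feature extraction for all frames through the fp32
#' inference path (no train/serve skew), SVM training on the training-split
#' features, and evaluation on the held-out split.
#'
#' @param frames list of labelled \linkS4class{EEGFrame}s.
#' @param cfg a \linkS4class{TrainConfig}.
#' @param pipeCfg a \linkS4class{PipelineConfig}; controls the FFT front end
#'   and the SVM evaluation route used for held-out scoring.
#' @return List with `cnn` (\linkS4class{CNNModel}), `svm`
#'   (\linkS4class{SVMModel}), `counts` (held-out
#'   \linkS4class{ConfusionCounts}), `features` (n x 31 matrix), `split`
#'   (train/test indices) and `labels`.
#' @export
trainPipeline <- function(frames, cfg, pipeCfg = pipelineConfig()) {
  stopifnot(is(cfg, "TrainConfig"), is(pipeCfg, "PipelineConfig"))
  labels <- vapply(frames, frameLabel, integer(1))
  if (anyNA(labels)) stop("training error: all frames must be labelled")
  if (length(unique(labels)) < 2L)
    stop("training error: both classes must be present")
  inputs <- if (pipeCfg@useFFTFrontend) lapply(frames, amplitudeSpectrum) else frames

  idx <- withLocalSeed(cfg@seed + 1L, {
    test <- unlist(lapply(split(seq_along(labels), labels), function(ix)
      sample(ix, max(1L, round(0.2 * length(ix))))))
    list(test = sort(test), train = sort(setdiff(seq_along(labels), test)))
  })

  cnn <- trainCNN(inputs[idx$train], cfg)
  features <- t(vapply(inputs, function(f)
    extractFeatures(f, cnn)$features, numeric(N_FEATURES)))
  svm <- trainSVM(features[idx$train, , drop = FALSE], labels[idx$train], cfg)

  evalFun <- if (pipeCfg@svmEvalPath == "dpu") dpuDataflowEval else decisionFunction
  decisions <- lapply(idx$test, function(i) evalFun(features[i, ], svm))
  counts <- accumulateCounts(decisions, labels[idx$test])
  list(cnn = cnn, svm = svm, counts = counts, features = features,
       split = idx, labels = labels)
}
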