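# CNN and SVM training.

smallFrames <- function(n = 60, seed = 21)
  generateFrames(synthConfig(seed = seed, nFrames = n))

test_that("zero learning rate leaves the weights at their initialization", {
  frames <- smallFrames(20)
  specs <- lapply(frames, amplitudeSpectrum)
  a <- trainCNN(specs, trainConfig(epochs = 1, learningRate = 0, seed = 3))
  b <- trainCNN(specs, trainConfig(epochs = 4, learningRate = 0, seed = 3))
  expect_identical(lapply(convLayers(a), function(l) l@weights),
                   lapply(convLayers(b), function(l) l@weights))
})

test_that("training is deterministic under the seed", {
  frames <- smallFrames(30)
  specs <- lapply(frames, amplitudeSpectrum)
  cfg <- trainConfig(epochs = 2, seed = 5)
  m1 <- trainCNN(specs, cfg)
  m2 <- trainCNN(specs, cfg)
  expect_identical(lapply(convLayers(m1), function(l) l@weights),
                   lapply(convLayers(m2), function(l) l@weights))
  expect_identical(m1@fitInfo$loss, m2@fitInfo$loss)
})

test_that("single-class input is a training error", {
  frames <- generateFrames(synthConfig(seed = 6, nFrames = 10, ictalFraction = 0))
  expect_error(trainCNN(frames, trainConfig(epochs = 1)), "both classes")
  expect_error(trainPipeline(frames, trainConfig(epochs = 1)), "both classes")
  expect_error(trainSVM(matrix(rnorm(310), 10, 31), rep(1, 10), trainConfig()),
               "both classes")
})

test_that("the temporary head separates the default synthetic classes", {
  frames <- generateFrames(synthConfig(seed = 8, nFrames = 400))
  specs <- lapply(frames, amplitudeSpectrum)
  cnn <- trainCNN(specs, trainConfig(epochs = 20, seed = 1))
  expect_gte(cnn@fitInfo$headAccuracy, 0.9)
})

test_that("SMO separates linearly separable clusters perfectly", {
  sep <- separableFeatures(n = 40)
  m <- trainSVM(sep$X, sep$y, trainConfig(seed = 1))
  pred <- vapply(seq_len(nrow(sep$X)), function(i)
    decisionLabel(decisionFunction(fp32Round(sep$X[i, ]), m)), character(1))
  expect_identical(pred, ifelse(sep$y == 1, "ictal", "interictal"))
})

test_that("the Gaussian kernel solves the XOR layout a linear machine cannot", {
  xor <- xorFeatures(nPerCluster = 15)
  m <- trainSVM(xor$X, xor$y, trainConfig(seed = 2))
  pred <- vapply(seq_len(nrow(xor$X)), function(i)
    decisionLabel(decisionFunction(fp32Round(xor$X[i, ]), m)) == "ictal",
    logical(1))
  expect_gt(mean(pred == (xor$y == 1)), 0.9)
  skip_if_not_installed("e1071")
  # linear oracle on the informative subspace: XOR admits no separating
  # hyperplane (the noise dimensions would only let it overfit)
  lin <- e1071::svm(xor$X[, 1:2], factor(xor$y), kernel = "linear", scale = FALSE)
  linAcc <- mean(predict(lin, xor$X[, 1:2]) == factor(xor$y))
  expect_lte(linAcc, 0.75)  # a halfplane gets at most 3 of the 4 clusters
})

test_that("SMO solutions satisfy the dual constraints", {
  sep <- separableFeatures(n = 30, gap = 3, seed = 9)
  cfg <- trainConfig(seed = 3, smoC = 1)
  m <- trainSVM(sep$X, sep$y, cfg)
  # alphas carry the label sign; magnitudes respect the box constraint
  expect_true(all(abs(m@alphas) <= cfg@smoC + cfg@smoTol))
  expect_true(all(abs(m@alphas) > 0))
  # sum alpha_i y_i = 0 over the full solution (non-SV terms are zero)
  expect_lt(abs(sum(m@alphas)), cfg@smoTol * nrow(sep$X))
})

test_that("degenerate identical features are a training error", {
  X <- matrix(1, 20, 31)
  expect_error(trainSVM(X, rep(c(0, 1), 10), trainConfig()), "degenerate")
})

test_that("the stored model is exactly self-consistent with the folded constant", {
  sep <- separableFeatures(n = 30, seed = 11)
  m <- trainSVM(sep$X, sep$y, trainConfig(seed = 4))
  want <- (m@sMax - m@sMin)^2 / (m@sigma * (m@fMax - m@fMin)^2)
  expect_equal(m@gammaEff, want, tolerance = 1e-6)  # stored as fp32
})

test_that("the pipeline trains end to end, reproducibly, without train/serve skew", {
  frames <- smallFrames(80, seed = 13)
  cfg <- trainConfig(epochs = 3, seed = 2)
  r1 <- trainPipeline(frames, cfg)
  r2 <- trainPipeline(frames, cfg)
  expect_identical(countsVector(r1$counts), countsVector(r2$counts))
  expect_identical(r1$features, r2$features)
  expect_s4_class(r1$svm, "SVMModel")
  # the features stored by the trainer are the fp32 inference-path outputs
  i <- r1$split$test[1]
  spec <- amplitudeSpectrum(frames[[i]])
  expect_identical(extractFeatures(spec, r1$cnn)$features, r1$features[i, ])
  # held-out accuracy on the easily separable default generator
  expect_gte(accuracy(r1$counts), 90)
})
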