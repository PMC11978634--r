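# Convolution engine, pooling and the feature stack.

test_that("1x1 convolution is elementwise scaling plus bias", {
  m <- fp32Round(matrix(rnorm(24), 4, 6))
  layer <- convLayerSpec(matrix(2, 1, 1), bias = 0, activation = "none")
  expect_identical(conv2dDirect(m, layer), fp32Round(m * 2))
})

test_that("valid convolution shape arithmetic holds on the 20 x 256 input", {
  inp <- matrix(0, 20, 256)
  l5 <- convLayerSpec(matrix(1, 5, 5))
  expect_identical(dim(conv2dDirect(inp, l5)), c(16L, 252L))
  expect_error(conv2dDirect(matrix(0, 3, 3), l5), "smaller than kernel")
})

test_that("direct path matches the triple-loop double-precision oracle", {
  set.seed(20)
  inp <- fp32Round(matrix(rnorm(64), 8, 8))
  w <- fp32Round(matrix(rnorm(9), 3, 3))
  layer <- convLayerSpec(w, bias = fp32Round(0.3), activation = "none")
  got <- conv2dDirect(inp, layer)
  want <- convOracle(inp, layer@weights, layer@bias)
  expect_lt(max(abs(got - want)), 1e-5 * max(abs(want)))
})

test_that("pipelined path is bit-identical to the direct path (all kernel sizes)", {
  for (K in c(1L, 3L, 5L)) {
    for (case in 1:80) {
      rc <- randomConvCase(K, seed = K * 1000 + case)
      d <- conv2dDirect(rc$input, rc$layer)
      p <- conv2dPipelined(rc$input, rc$layer)
      expect_identical(p$output, d)
    }
  }
})

test_that("pipelined cycle counts equal the event-driven simulator", {
  for (K in c(1L, 3L, 5L)) {
    rc <- randomConvCase(K, seed = K)
    p <- conv2dPipelined(rc$input, rc$layer)
    H <- nrow(rc$input); W <- ncol(rc$input)
    expect_identical(p$cycles, as.numeric(eventDrivenConvCycles(H, W, K)))
  }
  # 5x5 layer on the full 20 x 256 input
  l5 <- convLayerSpec(matrix(0.1, 5, 5))
  p <- conv2dPipelined(matrix(1, 20, 256), l5)
  expect_identical(p$cycles, as.numeric(eventDrivenConvCycles(20, 256, 5)))
  expect_identical(p$cycles, 5 + 16 * 252)
})

test_that("a 3x3 row unit's partial sum completes at cycle 3 of its window", {
  # a window entering its 3-stage PE chain at cycle 1 finishes the row
  # partial sum in the third clock cycle; the combined result is latched the
  # following cycle, so a single window costs K + 1 cycles in total
  K <- 3L
  enter <- 1L
  expect_identical(enter + K - 1L, 3L)
  expect_identical(eventDrivenConvCycles(3, 3, 3), 4)
})

test_that("two-stage max pooling equals the brute-force window maximum", {
  expect_identical(maxPoolTwoStage(matrix(c(1, 3, 2, 4), 2, 2)), matrix(4, 1, 1))
  expect_identical(dim(maxPoolTwoStage(matrix(0, 3, 62))), c(1L, 31L))
  set.seed(30)
  for (case in 1:50) {
    m <- fp32Round(matrix(rnorm(100), 10, 10))
    expect_identical(maxPoolTwoStage(m), bruteMaxPool(m))
  }
  # odd trailing row/column dropped
  m <- fp32Round(matrix(rnorm(35), 5, 7))
  expect_identical(maxPoolTwoStage(m), bruteMaxPool(m))
  expect_error(maxPoolTwoStage(matrix(1, 1, 1)), "window")
})

test_that("pooling output values are members of their input window", {
  set.seed(31)
  m <- fp32Round(matrix(rnorm(48), 6, 8))
  P <- maxPoolTwoStage(m)
  for (r in 1:3) for (c in 1:4)
    expect_true(P[r, c] %in% m[(2 * r - 1):(2 * r), (2 * c - 1):(2 * c)])
})

test_that("ReLU is idempotent through the layer activation", {
  rc <- randomConvCase(3L, seed = 77)
  layer <- convLayerSpec(rc$layer@weights, rc$layer@bias, "relu")
  once <- conv2dDirect(rc$input, layer)
  expect_identical(pmax(once, 0), once)
})

test_that("the full stack maps 20 x 256 to a length-31 feature vector", {
  model <- randomCNNModel(seed = 40)
  f <- generateFrames(synthConfig(seed = 41, nFrames = 1))[[1]]
  ef <- extractFeatures(f, model)
  expect_length(ef$features, 31L)
  expect_true(all(is.finite(ef$features)))
  expect_identical(ef$shapes,
                   list(conv1 = c(16L, 252L), pool1 = c(8L, 126L),
                        conv2 = c(6L, 124L), pool2 = c(3L, 62L),
                        conv3 = c(3L, 62L), pool3 = c(1L, 31L)))
  expect_error(extractFeatures(matrix(0, 10, 10), model), "shape error")
})

test_that("a zero input with zero biases yields the zero feature vector", {
  layers <- list(convLayerSpec(matrix(0.5, 5, 5), 0),
                 convLayerSpec(matrix(0.5, 3, 3), 0),
                 convLayerSpec(matrix(0.5, 1, 1), 0))
  ef <- extractFeatures(matrix(0, 20, 256), cnnModel(layers))
  expect_identical(ef$features, rep(0, 31))
})

test_that("model constructor enforces the 5/3/1 kernel-size order", {
  good <- lapply(c(5, 3, 1), function(K) convLayerSpec(matrix(0, K, K)))
  expect_s4_class(cnnModel(good), "CNNModel")
  expect_error(cnnModel(rev(good)), "kernel sizes")
  expect_error(convLayerSpec(matrix(0, 2, 2)), "1x1, 3x3 or 5x5")
})
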