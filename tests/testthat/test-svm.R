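# Quasi-Gaussian-kernel SVM decision function.

test_that("kernel is 1 exactly at coincidence and bounded in (0, 1]", {
  m <- randomSVMModel(seed = 1, L = 5, gammaEff = 0.5)
  sv <- supportVectors(m)
  expect_identical(kernelEval(sv[2, ], sv[2, ], m), 1)
  set.seed(2)
  for (i in 1:50) {
    x <- fp32Round(runif(31, -2, 2))
    k <- kernelEval(x, sv[1 + i %% 5, ], m)
    expect_gt(k, 0)
    expect_lte(k, 1)
  }
})

test_that("kernel decreases monotonically with the scale for distinct vectors", {
  sv <- fp32Round(runif(31))
  x <- fp32Round(sv + 0.3)
  ks <- vapply(c(0.1, 1, 10, 100), function(g) {
    m <- randomSVMModel(seed = 1, L = 1, gammaEff = g)
    .k <- kernelEval(x, sv, m)
  }, numeric(1))
  expect_true(all(diff(ks) < 0))
  expect_lt(ks[4], 1e-10)   # large gamma drives the kernel toward 0
})

test_that("kernel matches the double-precision direct formula within 5e-4", {
  set.seed(3)
  m <- randomSVMModel(seed = 4, L = 10, gammaEff = 0.5)
  sv <- supportVectors(m)
  for (i in 1:100) {
    x <- fp32Round(runif(31, -1, 1))
    row <- sv[1 + i %% 10, ]
    want <- exp(-m@gammaEff * sum((x - row)^2))
    got <- kernelEval(x, row, m)
    expect_lt(abs(got - want) / want, 5e-4)
  }
})

test_that("decision function worked examples", {
  sv <- matrix(fp32Round(runif(31)), 1, 31)
  m1 <- svmModel(sv, alphas = 1, b = 0, sigma = 1, fMax = 2, fMin = 0,
                 gammaEff = 0.5)
  d <- decisionFunction(sv[1, ], m1)
  expect_identical(decisionScore(d), 1)
  expect_identical(decisionLabel(d), "ictal")

  # b larger than sum |alpha| forces interictal for any x
  m2 <- svmModel(supportVectors(randomSVMModel(seed = 9, L = 8)),
                 alphas = rep(0.5, 8), b = 5, sigma = 1, fMax = 2, fMin = 0,
                 gammaEff = 0.3)
  set.seed(5)
  for (i in 1:20)
    expect_identical(decisionLabel(decisionFunction(runif(31, -3, 3), m2)),
                     "interictal")
})

test_that("decision function agrees with the double-precision oracle (L = 50)", {
  m <- randomSVMModel(seed = 6, L = 50, gammaEff = 0.5)
  set.seed(7)
  nAgree <- 0L
  for (i in 1:500) {
    x <- fp32Round(runif(31, -1.5, 1.5))
    got <- decisionScore(decisionFunction(x, m))
    want <- svmScoreOracle(x, m)
    expect_lt(abs(got - want), 1e-3)
    if (abs(want) > 1e-3)
      expect_identical(decisionLabel(decisionFunction(x, m)),
                       if (want >= 0) "ictal" else "interictal")
  }
})

test_that("DPU dataflow route is label-identical and score-close to the direct route", {
  for (seed in 1:50) {
    m <- randomSVMModel(seed = seed, L = 1 + seed %% 40,
                        gammaEff = 0.2 + seed / 50,
                        logTransform = seed %% 4 == 0)
    set.seed(seed + 100)
    x <- fp32Round(runif(31, if (m@logTransform) 0.05 else -1, 1))
    d1 <- decisionFunction(x, m)
    d2 <- dpuDataflowEval(x, m)
    expect_identical(decisionLabel(d2), decisionLabel(d1))
    expect_lte(abs(decisionScore(d2) - decisionScore(d1)), 1e-6)
  }
  # single-SV model evaluated at its own support vector: score = alpha - b
  sv <- matrix(fp32Round(runif(31)), 1, 31)
  m <- svmModel(sv, alphas = 0.8, b = 0.25, sigma = 1, fMax = 2, fMin = 0,
                gammaEff = 1)
  expect_equal(decisionScore(dpuDataflowEval(sv[1, ], m)),
               fp32Round(0.8) - fp32Round(0.25), tolerance = 1e-7)
})

test_that("permuting support vectors with their alphas leaves the label unchanged", {
  m <- randomSVMModel(seed = 8, L = 30, gammaEff = 0.4)
  set.seed(9)
  perm <- sample(30)
  mp <- svmModel(supportVectors(m)[perm, ], m@alphas[perm], b = m@b,
                 sigma = m@sigma, fMax = m@fMax, fMin = m@fMin,
                 sMax = m@sMax, sMin = m@sMin, gammaEff = m@gammaEff)
  for (i in 1:30) {
    x <- fp32Round(runif(31, -1, 1))
    s1 <- decisionScore(decisionFunction(x, m))
    s2 <- decisionScore(decisionFunction(x, mp))
    expect_lt(abs(s1 - s2), 1e-5)
    if (abs(s1) > 1e-5)
      expect_identical(decisionLabel(decisionFunction(x, mp)),
                       decisionLabel(decisionFunction(x, m)))
  }
})

test_that("log transform rejects nonpositive values unless the epsilon floor is on", {
  sv <- matrix(fp32Round(runif(31, 0.1, 1)), 1, 31)
  m0 <- svmModel(sv, 1, b = 0, sigma = 1, fMax = 1, fMin = 0, gammaEff = 0.5,
                 logTransform = TRUE, epsFloor = 0)
  x <- fp32Round(runif(31, 0.1, 1)); x[5] <- 0
  expect_error(kernelEval(x, sv[1, ], m0), "epsilon floor")
  mf <- svmModel(sv, 1, b = 0, sigma = 1, fMax = 1, fMin = 0, gammaEff = 0.5,
                 logTransform = TRUE, epsFloor = 1e-7)
  # the floored zero maps to ln(1e-7) ~ -16; the huge distance may underflow
  # the kernel to 0, which the exponential unit permits
  k <- kernelEval(x, sv[1, ], mf)
  expect_true(is.finite(k) && k >= 0 && k <= 1)
})

test_that("gammaEff defaults to the folded min-max/sigma constant", {
  sv <- matrix(fp32Round(runif(31, 0.2, 0.8)), 2, 31, byrow = TRUE)
  m <- svmModel(sv, c(1, -1), b = 0, sigma = 2, fMax = 1, fMin = -1)
  want <- (max(sv) - min(sv))^2 / (2 * (1 - -1)^2)
  expect_equal(m@gammaEff, fp32Round(want))
})
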