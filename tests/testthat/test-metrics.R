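# Confusion counts and the three evaluation statistics.

test_that("published confusion counts reproduce the printed percentages", {
  c <- confusionCounts(TP = 137, FN = 4, TN = 559, FP = 14)
  expect_identical(sensitivity(c), 97.2)   # 137 / 141
  expect_identical(specificity(c), 97.6)   # 559 / 573
  expect_identical(accuracy(c), 97.5)      # 696 / 714
})

test_that("degenerate and extreme counts behave per the definitions", {
  expect_identical(sensitivity(confusionCounts(TP = 0, FN = 5)), 0)
  expect_identical(sensitivity(confusionCounts(TP = 7, FN = 0)), 100)
  expect_identical(specificity(confusionCounts(TN = 0, FP = 1)), 0)
  expect_identical(specificity(confusionCounts(TN = 1, FP = 0)), 100)
  expect_error(sensitivity(confusionCounts(TN = 3, FP = 1)), "undefined")
  expect_error(specificity(confusionCounts(TP = 3, FN = 1)), "undefined")
  expect_error(accuracy(confusionCounts()), "undefined")
})

test_that("accumulation counts decisions against ground truth", {
  expect_identical(countsVector(accumulateCounts(character(0), integer(0))),
                   c(TP = 0L, FP = 0L, TN = 0L, FN = 0L))
  pred <- c(rep("ictal", 5), rep("interictal", 5))
  truth <- c(rep(1L, 5), rep(0L, 5))
  expect_identical(countsVector(accumulateCounts(pred, truth)),
                   c(TP = 5L, FP = 0L, TN = 5L, FN = 0L))
  # inverting the predictions swaps TP<->FN and TN<->FP
  inv <- ifelse(pred == "ictal", "interictal", "ictal")
  expect_identical(countsVector(accumulateCounts(inv, truth)),
                   c(TP = 0L, FP = 5L, TN = 0L, FN = 5L))
  expect_error(accumulateCounts(pred, truth[1:5]), "argument error")
  expect_error(accumulateCounts(pred, c(truth[1:9], NA)), "argument error")
})

test_that("accuracy equals the brute-force ratio on random counts", {
  set.seed(50)
  for (i in 1:50) {
    v <- sample(0:200, 4, replace = TRUE)
    if (sum(v) == 0) next
    c <- confusionCounts(TP = v[1], FP = v[2], TN = v[3], FN = v[4])
    expect_identical(accuracy(c, digits = NA), 100 * (v[1] + v[3]) / sum(v))
    expect_true(accuracy(c) >= 0 && accuracy(c) <= 100)
    if (v[1] + v[4] > 0 && v[2] + v[3] > 0) {
      # correct-count identity linking the three statistics
      tpRecovered <- sensitivity(c, digits = NA) * (v[1] + v[4]) / 100
      tnRecovered <- specificity(c, digits = NA) * (v[2] + v[3]) / 100
      expect_identical(round(tpRecovered + tnRecovered), as.numeric(v[1] + v[3]))
      expect_true(sensitivity(c) >= 0 && sensitivity(c) <= 100)
      expect_true(specificity(c) >= 0 && specificity(c) <= 100)
    }
  }
})

test_that("reporting rounds half-to-even to one decimal", {
  # 25/160 = 15.625% -> 15.6 under round-half-even
  expect_identical(sensitivity(confusionCounts(TP = 25, FN = 135)), 15.6)
  rep <- metricsReport(confusionCounts(TP = 137, FN = 4, TN = 559, FP = 14))
  expect_identical(rep$accuracy_pct, 97.5)
  expect_identical(rep$counts$TP, 137L)
})
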