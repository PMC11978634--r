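# Synthetic EEG generator and frame segmentation.

test_that("generator handles the empty case and rejects bad configurations", {
  expect_identical(generateFrames(synthConfig(nFrames = 0)), list())
  expect_error(synthConfig(ictalFraction = 1.5), "ictalFraction")
  expect_error(synthConfig(noiseSd = -1), "noiseSd")
  expect_error(synthConfig(backgroundBandHz = c(12, 2)), "backgroundBandHz")
})

test_that("identical configurations reproduce identical frame sets", {
  cfg <- synthConfig(seed = 1, nFrames = 10)
  a <- generateFrames(cfg)
  b <- generateFrames(cfg)
  expect_identical(lapply(a, frameData), lapply(b, frameData))
  expect_identical(vapply(a, frameLabel, integer(1)),
                   vapply(b, frameLabel, integer(1)))
  # a private RNG stream is used: the global seed state is untouched
  set.seed(99); before <- .Random.seed
  invisible(generateFrames(cfg))
  expect_identical(.Random.seed, before)
})

test_that("label balance matches round(nFrames * ictalFraction)", {
  for (frac in c(0, 0.25, 0.5, 0.8, 1)) {
    frames <- generateFrames(synthConfig(seed = 3, nFrames = 40, ictalFraction = frac))
    expect_identical(sum(vapply(frames, frameLabel, integer(1))),
                     as.integer(round(40 * frac)))
  }
})

test_that("frames are valid fp32 20 x 256 windows", {
  frames <- generateFrames(synthConfig(seed = 2, nFrames = 5))
  for (f in frames) {
    expect_true(validObject(f))
    expect_identical(dim(frameData(f)), c(20L, 256L))
    expect_identical(frameData(f), fp32Round(frameData(f)))
  }
})

test_that("ictal frames carry more 16-64 Hz power and a larger band ratio (DFT oracle)", {
  frames <- generateFrames(synthConfig(seed = 1, nFrames = 200, ictalFraction = 0.5))
  labs <- vapply(frames, frameLabel, integer(1))
  hi <- vapply(frames, oracleBandPower, numeric(1), 16, 64)
  lo <- vapply(frames, oracleBandPower, numeric(1), 1, 8)
  expect_gt(mean(hi[labs == 1]), mean(hi[labs == 0]))
  # stochastic dominance of the (16-64)/(1-8) ratio, testable over >= 100 frames
  ratio <- hi / lo
  expect_gt(min(ratio[labs == 1]), max(ratio[labs == 0]))
})

test_that("segmentation floors to whole windows and preserves constants", {
  chans <- replicate(20, rnorm(256), simplify = FALSE)
  expect_length(segmentRecording(chans, 256, windowS = 1), 1L)

  chans2 <- replicate(20, rnorm(640), simplify = FALSE)  # 2.5 windows
  expect_length(segmentRecording(chans2, 256, windowS = 1), 2L)

  const <- replicate(20, rep(1.5, 512), simplify = FALSE)
  frames <- segmentRecording(const, 256, windowS = 1)
  expect_length(frames, 2L)
  expect_identical(frameData(frames[[1]]), frameData(frames[[2]]))
  expect_true(all(frameData(frames[[1]]) == fp32Round(1.5)))

  expect_warning(out <- segmentRecording(replicate(20, rnorm(100), simplify = FALSE),
                                         256, windowS = 1),
                 "shorter than one")
  expect_identical(out, list())
})

test_that("single-channel recordings map 20 s windows onto the 20 x 256 frame", {
  x <- rnorm(20 * 256 * 2 + 100)
  frames <- segmentRecording(list(x), 256, windowS = 20)
  expect_length(frames, 2L)
  expect_identical(frameData(frames[[1]]),
                   fp32Round(matrix(x[1:5120], 20, 256, byrow = TRUE)))
})
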