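# Hyperbolic CORDIC exponential/logarithm unit.

test_that("rotation mode reproduces cosh/sinh and the exponential", {
  r0 <- cordicCore(0, "rotation")
  expect_equal(r0$x, 1, tolerance = 1e-4)   # cosh 0
  # raw-core residual oscillation is bounded by the i = 16 angle (~1.5e-5)
  expect_lt(abs(r0$y), 1e-4)                # sinh 0
  r <- cordicCore(0.5, "rotation")
  expect_lt(abs((r$x + r$y) - exp(0.5)) / exp(0.5), 1e-4)
  expect_equal(r$x, cosh(0.5), tolerance = 1e-4)
})

test_that("vectoring mode accumulates atanh", {
  v <- cordicCore(c(1.25, 0.25), "vectoring")
  expect_lt(abs(v$z - atanh(0.2)), 1e-4)
  expect_lt(abs(v$y), 1e-4)   # y driven to zero
})

test_that("core rejects inputs outside the convergence domain", {
  expect_error(cordicCore(1.2, "rotation"), "convergence")
  expect_error(cordicCore(c(1, 0.9), "vectoring"), "convergence")
  expect_error(cordicCore(c(-1, 0.1), "vectoring"), "x > 0")
})

test_that("cordicExp matches closed forms and the library oracle on a sweep", {
  expect_identical(cordicExp(0), 1)
  expect_lt(abs(cordicExp(log(2)) - 2) / 2, 1e-4)
  xs <- seq(-30, 30, length.out = 2e4)
  rel <- abs(cordicExp(xs) - exp(xs)) / exp(xs)
  expect_lt(max(rel), 1e-4)
  expect_error(cordicExp(Inf), "non-finite")
})

test_that("cordicLn matches closed forms and the library oracle on a log sweep", {
  expect_identical(cordicLn(1), 0)
  expect_lt(abs(cordicLn(fp32Round(exp(1))) - 1), 1e-4)
  xs <- fp32Round(exp(seq(log(2^-30), log(2^30), length.out = 2e4)))
  rel <- abs(cordicLn(xs) - log(xs)) / pmax(abs(log(xs)), .Machine$double.xmin)
  rel[log(xs) == 0] <- abs(cordicLn(xs)[log(xs) == 0])
  expect_lt(max(rel), 1e-4)
  # absolute error near v = 1
  near <- fp32Round(1 + seq(-5e-3, 5e-3, length.out = 401))
  expect_lt(max(abs(cordicLn(near) - log(near))), 1e-6)
  expect_error(cordicLn(-1), "positive")
  expect_error(cordicLn(0), "positive")
})

test_that("exp and ln round-trip within 3e-4", {
  v <- fp32Round(exp(seq(log(2^-25), log(2^25), length.out = 5e3)))
  back <- cordicExp(cordicLn(v))
  expect_lt(max(abs(back - v) / v), 3e-4)
})

test_that("outputs are monotone on the sweep grids", {
  xs <- seq(-25, 25, length.out = 5e3)
  expect_true(all(diff(cordicExp(xs)) >= 0))
  vs <- fp32Round(exp(seq(log(2^-25), log(2^25), length.out = 5e3)))
  expect_true(all(diff(cordicLn(vs)) >= 0))
})

test_that("the gain constant matches the closed-form product", {
  sched <- c(1:4, 4, 5:13, 13, 14:16)   # repeats at 4 and 13
  expect_length(cordicAngleROM(16), 18L)
  closed <- prod(sqrt(1 - 2^(-2 * sched)))
  expect_lt(abs(cordicGain(16) - closed), 1e-7)
})

test_that("the angle ROM is positive and decreasing in the iteration index", {
  rom <- cordicAngleROM(16)
  expect_true(all(rom > 0))
  expect_true(all(diff(rom) <= 0))
})

test_that("16 iterations are at least as accurate as 12 (raw core, no correction)", {
  xs <- seq(-10, 10, length.out = 2e3)
  err16 <- max(abs(cordicExp(xs, iterations = 16, correct = FALSE) - exp(xs)) / exp(xs))
  err12 <- max(abs(cordicExp(xs, iterations = 12, correct = FALSE) - exp(xs)) / exp(xs))
  expect_lte(err16, err12)
  vs <- fp32Round(exp(seq(log(0.1), log(10), length.out = 2e3)))
  e16 <- max(abs(cordicLn(vs, iterations = 16, correct = FALSE) - log(vs)))
  e12 <- max(abs(cordicLn(vs, iterations = 12, correct = FALSE) - log(vs)))
  expect_lte(e16, e12)
})

test_that("the fp32-register core variant stays within the coarse error budget", {
  xs <- seq(-10, 10, length.out = 2e3)
  rel <- abs(cordicExp(xs, core = "float") - exp(xs)) / exp(xs)
  expect_lt(max(rel), 1e-4)
  vs <- fp32Round(exp(seq(log(0.5), log(2000), length.out = 2e3)))
  expect_lt(max(abs(cordicLn(vs, core = "float") - log(vs)) / abs(log(vs))), 1e-3)
})
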