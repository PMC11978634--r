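## Hyperbolic CORDIC exponential / logarithm (fp32), R surface.

#' Run the hyperbolic CORDIC core
#'
#' Executes the iteration schedule (indices 1..`iterations` with the standard
#' convergence repeats at 4 and 13) on the fp32 `(x, y, z)` registers. In
#' rotation mode the input is an angle `z`; the outputs are
#' `(cosh z, sinh z, residual)` because the `x` register is pre-scaled by the
#' inverse gain `1/K_h`. In vectoring mode the input is an `(x, y)` pair and
#' `z` accumulates `atanh(y/x)` while `y` is driven to zero.
#'
#' @param input a single angle (rotation) or an `(x, y)` pair (vectoring).
#' @param mode `"rotation"` or `"vectoring"`.
#' @param iterations distinct iteration indices, default 16.
#' @param core register implementation, "fixed" (default) or "float".
#' @return Named list with elements `x`, `y`, `z`.
#' @export
#' @examples
#' cordicCore(0.5, "rotation")        # x + y ~ exp(0.5)
#' cordicCore(c(1.25, 0.25), "vectoring")$z  # ~ atanh(0.2)
cordicCore <- function(input, mode = c("rotation", "vectoring"), iterations = 16L,
                       core = c("fixed", "float")) {
  mode <- match.arg(mode)
  core <- match.arg(core)
  .cordic_core_cpp(as.numeric(input), mode, as.integer(iterations), core)
}

#' CORDIC exponential
#'
#' `exp(v)` through the rotation-mode hyperbolic CORDIC unit with range
#' reduction `v = m ln 2 + r`, `|r| <= ln2 / 2`; the core evaluates `e^r` as
#' `cosh r + sinh r` and the result is rescaled by `2^m` through exponent
#' arithmetic. All arithmetic is fp32. Underflow to 0 below the fp32
#' subnormal range is permitted.
#'
#' @param v finite numeric vector.
#' @param iterations distinct CORDIC iterations (default 16).
#' @param correct apply the first-order residual-angle post-correction
#'   (default TRUE).
#' @param core register implementation: "fixed" (64-bit fixed-point with 40
#'   fractional guard bits and true arithmetic shifts, the default) or
#'   "float" (fp32 registers, shifts as multiplies by 2^-i).
#' @return `exp(v)` evaluated by the emulated circuit.
#' @export
#' @examples
#' cordicExp(log(2))  # ~ 2
cordicExp <- function(v, iterations = 16L, correct = TRUE,
                      core = c("fixed", "float")) {
  core <- match.arg(core)
  .cordic_exp_cpp(as.numeric(v), as.integer(iterations), isTRUE(correct), core)
}

#' CORDIC natural logarithm
#'
#' `ln(v)` for positive `v` via exponent extraction `v = 2^e f`, `f` in
#' `[1, 2)`, and the vectoring-mode identity `ln f = 2 atanh((f-1)/(f+1))`;
#' the result is `e ln 2 + ln f`, all in fp32.
#'
#' @inheritParams cordicExp
#' @param v positive finite numeric vector.
#' @return `log(v)` evaluated by the emulated circuit.
#' @export
#' @examples
#' cordicLn(exp(1))  # ~ 1
cordicLn <- function(v, iterations = 16L, correct = TRUE,
                     core = c("fixed", "float")) {
  core <- match.arg(core)
  .cordic_ln_cpp(as.numeric(v), as.integer(iterations), isTRUE(correct), core)
}

#' Hyperbolic CORDIC gain
#'
#' The magnitude gain `K_h = prod sqrt(1 - 2^(-2i))` over the iteration
#' schedule (including repeats), computed in double precision.
#'
#' @param iterations distinct iteration indices, default 16.
#' @return The gain `K_h`.
#' @export
cordicGain <- function(iterations = 16L) .cordic_gain_cpp(as.integer(iterations))

#' Angle-ROM contents
#'
#' The single-precision `atanh(2^-i)` rotation angles in schedule order
#' (repeats at 4 and 13 included).
#'
#' @param iterations distinct iteration indices, default 16.
#' @return Numeric vector of ROM angles.
#' @export
cordicAngleROM <- function(iterations = 16L) .cordic_rom_cpp(as.integer(iterations))

#' Error sweep of the CORDIC unit
#'
#' Evaluates [cordicExp()] or [cordicLn()] on a grid and reports the relative
#' error against the double-precision library function.
#'
#' @param fun `"exp"` or `"ln"`.
#' @param n grid size.
#' @param range sweep range: exp sweeps `[range[1], range[2]]` linearly, ln
#'   log-spaced.
#' @param iterations,correct passed to the CORDIC evaluator.
#' @return A data.frame with columns `input`, `output`, `reference`,
#'   `relError`.
#' @export
cordicErrorSweep <- function(fun = c("exp", "ln"), n = 1e5,
                             range = if (match.arg(fun) == "exp") c(-30, 30)
                                     else c(2^-30, 2^30),
                             iterations = 16L, correct = TRUE) {
  fun <- match.arg(fun)
  if (fun == "exp") {
    xs <- seq(range[1], range[2], length.out = n)
    out <- cordicExp(xs, iterations, correct)
    ref <- exp(xs)
  } else {
    xs <- exp(seq(log(range[1]), log(range[2]), length.out = n))
    xs <- fp32Round(xs)
    out <- cordicLn(xs, iterations, correct)
    ref <- log(xs)
  }
  rel <- ifelse(ref == 0, abs(out - ref), abs(out - ref) / abs(ref))
  data.frame(input = xs, output = out, reference = ref, relError = rel)
}
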