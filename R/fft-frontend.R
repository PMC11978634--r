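## 256-point radix-2 FFT front end (fp32), exposed at the R level.

#' Bit-reversal address permutation
#'
#' The address-reordering map of a radix-2 decimation-in-time FFT: entry `k`
#' (0-based) is `k` with its `log2(n)` bits reversed. The map is bijective and
#' self-inverse.
#'
#' @param n transform length; must be a power of two.
#' @return Integer vector of 0-based reversed indices.
#' @export
#' @examples
#' bitReversePermutation(8)  # 0 4 2 6 1 5 3 7
bitReversePermutation <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1 || bitwAnd(as.integer(n), as.integer(n) - 1L) != 0L)
    stop("n must be a power of two")
  .bit_reverse_perm_cpp(as.integer(n))
}

#' Twiddle-factor ROM
#'
#' The 128 complex roots of unity `W_256^m = exp(-2*pi*i*m/256)`,
#' `m = 0..127`, computed in double precision and rounded once to fp32 -- the
#' contents of the hardware twiddle ROM.
#'
#' @return Complex vector of length 128.
#' @export
twiddleTable <- function() .twiddle_table_cpp()

#' 256-point radix-2 FFT in single precision
#'
#' Decimation-in-time FFT with bit-reversed input ordering and 8 butterfly
#' stages; every multiply and add rounds to fp32, mirroring the hardware
#' butterfly unit.
#'
#' @param x real numeric vector of length 256.
#' @return Complex vector of length 256 (fp32-valued parts).
#' @export
fft256 <- function(x) {
  if (length(x) != 256L)
    stop(sprintf("fft256: input length must be 256, got %d", length(x)))
  .fft256_cpp(as.numeric(x))
}

#' Amplitude spectrum of an EEG frame
#'
#' Applies [fft256()] to each channel and takes the per-bin modulus. The full
#' two-sided spectrum is kept so the 20 x 256 CNN input geometry is preserved;
#' rows are conjugate-symmetric in amplitude because the input is real.
#'
#' @param frame an \linkS4class{EEGFrame}.
#' @return A \linkS4class{SpectralFrame}.
#' @export
amplitudeSpectrum <- function(frame) {
  stopifnot(is(frame, "EEGFrame"))
  new("SpectralFrame", amplitude = .amplitude_matrix_cpp(frame@data),
      sourceLabel = frame@label)
}
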