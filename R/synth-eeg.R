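## Synthetic labelled EEG frames.
##
## Interictal windows: a band-limited (default 2-12 Hz) sum of sinusoids per
## channel plus Gaussian noise. Ictal windows: the same background with the
## low band attenuated (x 0.5), added 16-64 Hz oscillations and Poisson-placed
## biphasic spike-wave transients -- the qualitative spectral signature of a
## seizure (raised high-frequency power, reduced low-frequency power,
## epileptiform discharges).

ICTAL_LOW_ATTEN <- 0.5       # low-band amplitude factor in ictal frames
ICTAL_HF_BAND <- c(16, 64)   # Hz band of the added ictal components
N_BACKGROUND_COMP <- 3L      # sinusoids per channel in the background
N_HF_COMP <- 3L              # added high-frequency sinusoids per ictal channel

# Run expr with a private RNG stream; the caller's .Random.seed is untouched.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# One biphasic spike-and-wave template (sharp positive deflection followed by
# a slower negative wave), about 100 ms at 256 Hz, unit peak amplitude.
spikeTemplate <- function(sampleRateHz = 256) {
  nSharp <- max(4L, round(0.025 * sampleRateHz))   # ~25 ms sharp component
  nWave <- max(8L, round(0.075 * sampleRateHz))    # ~75 ms slow wave
  sharp <- sin(pi * seq_len(nSharp) / (nSharp + 1))^2
  wave <- -0.5 * sin(pi * seq_len(nWave) / (nWave + 1))
  c(sharp, wave)
}

synthOneChannel <- function(ictal, cfg, tt) {
  band <- cfg@backgroundBandHz
  freqs <- runif(N_BACKGROUND_COMP, band[1], band[2])
  amps <- runif(N_BACKGROUND_COMP, 5, 15)
  phases <- runif(N_BACKGROUND_COMP, 0, 2 * pi)
  if (ictal) amps <- amps * ICTAL_LOW_ATTEN
  x <- drop(amps %*% sin(outer(2 * pi * freqs, tt) + phases))
  if (ictal) {
    hf <- runif(N_HF_COMP, ICTAL_HF_BAND[1], ICTAL_HF_BAND[2])
    hfAmp <- runif(N_HF_COMP, 5, 15) * cfg@highFreqGain
    hfPh <- runif(N_HF_COMP, 0, 2 * pi)
    x <- x + drop(hfAmp %*% sin(outer(2 * pi * hf, tt) + hfPh))
    dur <- length(tt) * diff(tt[1:2])
    nSpike <- rpois(1, cfg@spikeRatePerS * dur)
    if (nSpike > 0) {
      tmpl <- spikeTemplate(1 / diff(tt[1:2]))
      for (s in seq_len(nSpike)) {
        pos <- sample.int(length(tt) - length(tmpl) + 1L, 1L)
        amp <- runif(1, 40, 80) * sample(c(-1, 1), 1)
        idx <- pos:(pos + length(tmpl) - 1L)
        x[idx] <- x[idx] + amp * tmpl
      }
    }
  }
  x + rnorm(length(tt), sd = cfg@noiseSd)
}

#' Generate labelled synthetic EEG frames
#'
#' Draws `nFrames` 20 x 256 windows from the generator described above; ictal
#' windows carry boosted 16-64 Hz power, attenuated low-band power and
#' spike-wave transients relative to interictal windows. The number of ictal
#' frames is `round(nFrames * ictalFraction)` and their positions within the
#' returned list are a seeded random permutation. Output is bit-reproducible
#' for identical configurations.
#'
#' @param cfg a \linkS4class{SynthConfig}.
#' @return A list of \linkS4class{EEGFrame}s with labels attached.
#' @export
#' @examples
#' frames <- generateFrames(synthConfig(seed = 1, nFrames = 4))
#' vapply(frames, frameLabel, integer(1))
generateFrames <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  validObject(cfg)
  n <- cfg@nFrames
  if (n == 0L) return(list())
  nIctal <- round(n * cfg@ictalFraction)
  withLocalSeed(cfg@seed, {
    labels <- sample(c(rep(1L, nIctal), rep(0L, n - nIctal)))
    tt <- (seq_len(N_SAMPLES) - 1L) / 256
    lapply(seq_len(n), function(i) {
      m <- t(vapply(seq_len(N_CHANNELS),
                    function(ch) synthOneChannel(labels[i] == 1L, cfg, tt),
                    numeric(N_SAMPLES)))
      eegFrame(m, label = labels[i], sampleRateHz = 256)
    })
  })
}

#' Segment multichannel sample streams into analysis windows
#'
#' Cuts non-overlapping consecutive windows of `windowS` seconds and maps each
#' to a 20 x 256 frame; the trailing partial window is discarded. Two layouts
#' are supported: 20 channels (each channel contributes one row, resampled to
#' 256 columns when the window does not hold exactly 256 samples) and a single
#' channel (the window is split into 20 consecutive equal segments stacked as
#' rows -- a 20 s single-channel window at 256 Hz fills the 20 x 256 frame
#' exactly).
#'
#' @param samples list of per-channel numeric vectors (equal lengths), or a
#'   channels x samples matrix.
#' @param sampleRateHz sampling rate of the streams.
#' @param windowS window length in seconds; defaults to 1 for 20-channel
#'   input and 20 for single-channel input.
#' @return A list of unlabelled \linkS4class{EEGFrame}s (empty, with a
#'   warning, if the stream is shorter than one window).
#' @export
segmentRecording <- function(samples, sampleRateHz = 256, windowS = NULL) {
  if (is.matrix(samples)) samples <- asplit(samples, 1)
  samples <- lapply(samples, as.numeric)
  nchan <- length(samples)
  if (nchan < 1L) stop("at least one channel is required")
  len <- unique(lengths(samples))
  if (length(len) != 1L) stop("all channels must have the same length")
  if (!(nchan %in% c(1L, N_CHANNELS)))
    stop(sprintf("unsupported channel count %d: provide %d channels or a single channel",
                 nchan, N_CHANNELS))
  if (is.null(windowS)) windowS <- if (nchan == 1L) 20 else 1
  winLen <- round(windowS * sampleRateHz)
  if (winLen < N_CHANNELS && nchan == 1L)
    stop("window too short to fill a frame from a single channel")
  nWin <- len %/% winLen
  if (nWin == 0L) {
    warning(sprintf("stream of %d samples is shorter than one %d-sample window; no frames produced",
                    len, winLen))
    return(list())
  }
  resampleRow <- function(x) {
    if (length(x) == N_SAMPLES) x
    else approx(seq_along(x), x, n = N_SAMPLES)$y
  }
  lapply(seq_len(nWin), function(w) {
    idx <- ((w - 1L) * winLen + 1L):(w * winLen)
    if (nchan == N_CHANNELS) {
      m <- t(vapply(samples, function(ch) resampleRow(ch[idx]), numeric(N_SAMPLES)))
    } else {
      seg <- samples[[1L]][idx]
      per <- length(seg) %/% N_CHANNELS
      m <- t(vapply(seq_len(N_CHANNELS), function(r)
        resampleRow(seg[((r - 1L) * per + 1L):(r * per)]), numeric(N_SAMPLES)))
    }
    eegFrame(m, sampleRateHz = sampleRateHz)
  })
}
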