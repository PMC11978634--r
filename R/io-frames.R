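## Frame I/O: delimited-text matrices, frame-set directories with a manifest,
## and a minimal EDF/EDF+ reader for clinical recordings.

#' Read one frame from a delimited text file
#'
#' The file must hold a numeric 20 x 256 matrix, comma or whitespace
#' delimited. Values are cast to single precision.
#'
#' @param path file path.
#' @param label optional label to attach (1, 0 or NA).
#' @param sampleRateHz sampling rate to record, default 256.
#' @return An \linkS4class{EEGFrame}.
#' @export
readDelimitedFrame <- function(path, label = NA_integer_, sampleRateHz = 256) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    cells <- strsplit(trimws(lines[[i]]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1]
      stop(sprintf("parse error: non-numeric cell at row %d, column %d ('%s')",
                   i, j, cells[j]))
    }
    vals
  })
  ncols <- unique(lengths(rows))
  if (length(rows) != N_CHANNELS || length(ncols) != 1L || ncols != N_SAMPLES)
    stop(sprintf("shape error: expected %d x %d, observed %d x %s",
                 N_CHANNELS, N_SAMPLES, length(rows),
                 paste(ncols, collapse = "/")))
  eegFrame(do.call(rbind, rows), label = label, sampleRateHz = sampleRateHz)
}

#' Write one frame to a delimited text file
#'
#' Values are written with enough digits (9 significant) to round-trip fp32
#' exactly, so `readDelimitedFrame(writeDelimitedFrame(f, p))` reproduces the
#' frame bit for bit.
#'
#' @param frame an \linkS4class{EEGFrame}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDelimitedFrame <- function(frame, path) {
  stopifnot(is(frame, "EEGFrame"))
  txt <- apply(frame@data, 1, function(r) paste(sprintf("%.9g", r), collapse = ","))
  writeLines(txt, path)
  invisible(path)
}

#' Write a frame set as one file per frame plus a manifest
#'
#' The manifest is a tab-separated table with columns `id`, `file`, `label`
#' and `sample_rate_hz`, one row per frame.
#'
#' @param frames list of \linkS4class{EEGFrame}s.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeFrameSet <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("frame_%05d.csv", seq_along(frames))
  for (i in seq_along(frames)) writeDelimitedFrame(frames[[i]], file.path(dir, files[i]))
  manifest <- data.frame(
    id = seq_along(frames), file = files,
    label = vapply(frames, frameLabel, integer(1)),
    sample_rate_hz = vapply(frames, function(f) f@sampleRateHz, numeric(1)))
  path <- file.path(dir, "manifest.tsv")
  write.table(manifest, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a frame set written by [writeFrameSet()]
#'
#' @param dir directory containing `manifest.tsv`.
#' @return A list of \linkS4class{EEGFrame}s.
#' @export
readFrameSet <- function(dir) {
  manifest <- read.table(file.path(dir, "manifest.tsv"), sep = "\t", header = TRUE)
  lapply(seq_len(nrow(manifest)), function(i)
    readDelimitedFrame(file.path(dir, manifest$file[i]),
                       label = manifest$label[i],
                       sampleRateHz = manifest$sample_rate_hz[i]))
}

#' Read an EDF/EDF+ recording
#'
#' Minimal reader for the European Data Format used by clinical EEG archives:
#' parses the ASCII header, decodes the 16-bit little-endian data records and
#' applies the per-signal physical/digital calibration. Annotation channels
#' (EDF+) are dropped.
#'
#' @param path EDF file path.
#' @return A list with `channels` (list of numeric vectors), `labels`
#'   (channel names) and `sampleRateHz` (per channel).
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  field <- function(s, from, len) trimws(substr(s, from, from + len - 1L))
  nHeaderBytes <- as.integer(field(hdr, 185, 8))
  nRecords <- as.integer(field(hdr, 237, 8))
  recordDurS <- as.numeric(field(hdr, 245, 8))
  ns <- as.integer(field(hdr, 253, 4))
  if (is.na(ns) || ns < 1L) stop("not an EDF file: bad signal count in header")
  sigHdr <- readChar(con, 256L * ns, useBytes = TRUE)
  # field offsets (bytes per signal): label 16, transducer 80, dimension 8,
  # physical min 8, physical max 8, digital min 8, digital max 8,
  # prefiltering 80, samples per record 8, reserved 32
  offs <- cumsum(c(0L, 16L, 80L, 8L, 8L, 8L, 8L, 8L, 80L, 8L))
  getField <- function(k, len) {
    base <- offs[k] * ns
    vapply(seq_len(ns), function(i)
      trimws(substr(sigHdr, base + (i - 1L) * len + 1L, base + i * len)), character(1))
  }
  labels <- getField(1L, 16L)
  physMin <- as.numeric(getField(4L, 8L))
  physMax <- as.numeric(getField(5L, 8L))
  digMin <- as.numeric(getField(6L, 8L))
  digMax <- as.numeric(getField(7L, 8L))
  sampPerRec <- as.integer(getField(9L, 8L))
  seek(con, nHeaderBytes)
  raw <- readBin(con, "integer", n = nRecords * sum(sampPerRec), size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < nRecords * sum(sampPerRec))
    stop("EDF file truncated: expected more data records")
  channels <- vector("list", ns)
  for (i in seq_len(ns)) channels[[i]] <- numeric(nRecords * sampPerRec[i])
  pos <- 0L
  fill <- integer(ns)
  for (r in seq_len(nRecords)) {
    for (i in seq_len(ns)) {
      n <- sampPerRec[i]
      channels[[i]][(fill[i] + 1L):(fill[i] + n)] <- raw[(pos + 1L):(pos + n)]
      fill[i] <- fill[i] + n
      pos <- pos + n
    }
  }
  scale <- (physMax - physMin) / (digMax - digMin)
  for (i in seq_len(ns))
    channels[[i]] <- (channels[[i]] - digMin[i]) * scale[i] + physMin[i]
  keep <- !grepl("^EDF Annotations", labels)
  list(channels = channels[keep], labels = labels[keep],
       sampleRateHz = (sampPerRec / recordDurS)[keep])
}
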