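# Fixture builders (all fixtures are generated in code at test time).

# Minimal EDF writer for reader tests: 16-bit little-endian records, one
# data record per second.
writeTestEDF <- function(path, channels, sampleRateHz = 256, recordDurS = 1) {
  ns <- length(channels)
  sampPerRec <- as.integer(sampleRateHz * recordDurS)
  nRecords <- length(channels[[1]]) %/% sampPerRec
  physMin <- -500; physMax <- 500
  digMin <- -32768; digMax <- 32767
  pad <- function(x, n) formatC(as.character(x), width = n, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("test patient", 80), pad("test recording", 80),
                pad("01.01.26", 8), pad("00.00.00", 8),
                pad(256 + 256 * ns, 8), pad("", 44),
                pad(nRecords, 8), pad(recordDurS, 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  sig <- paste0(
    paste(vapply(seq_len(ns), function(i) pad(sprintf("EEG ch%d", i), 16), ""), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(rep(pad(physMin, 8), ns), collapse = ""),
    paste(rep(pad(physMax, 8), ns), collapse = ""),
    paste(rep(pad(digMin, 8), ns), collapse = ""),
    paste(rep(pad(digMax, 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(sampPerRec, 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = ""))
  writeChar(sig, con, eos = NULL)
  scale <- (digMax - digMin) / (physMax - physMin)
  for (r in seq_len(nRecords)) {
    for (i in seq_len(ns)) {
      seg <- channels[[i]][((r - 1) * sampPerRec + 1):(r * sampPerRec)]
      dig <- as.integer(round((seg - physMin) * scale + digMin))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

# A labelled random feature matrix with two well-separated clusters.
separableFeatures <- function(n = 40, gap = 6, seed = 1) {
  set.seed(seed)
  half <- n %/% 2
  X <- rbind(matrix(rnorm(half * 31, mean = 0), half, 31),
             matrix(rnorm((n - half) * 31, mean = gap / sqrt(31)), n - half, 31))
  list(X = X, y = c(rep(0L, half), rep(1L, n - half)))
}

# XOR-style layout: two clusters per class at opposite corners; linearly
# inseparable by construction.
xorFeatures <- function(nPerCluster = 25, seed = 2) {
  set.seed(seed)
  centers <- list(c(0, 0), c(4, 4), c(0, 4), c(4, 0))
  lab <- c(0L, 0L, 1L, 1L)
  X <- NULL; y <- integer(0)
  for (k in 1:4) {
    # informative structure in dims 1-2 only; the rest is near-zero noise so
    # a linear machine cannot exploit spurious high-dimensional separability
    base <- matrix(rnorm(nPerCluster * 31, sd = 0.02), nPerCluster, 31)
    base[, 1] <- rnorm(nPerCluster, centers[[k]][1], 0.5)
    base[, 2] <- rnorm(nPerCluster, centers[[k]][2], 0.5)
    X <- rbind(X, base)
    y <- c(y, rep(lab[k], nPerCluster))
  }
  list(X = X, y = y)
}
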