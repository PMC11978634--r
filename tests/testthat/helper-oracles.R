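# Independent double-precision oracles used to check the fp32 datapaths.

# O(n^2) direct DFT (double precision). The 256 x 256 coefficient matrix is
# cached across calls.
dftOracle <- local({
  W <- NULL
  function(x) {
    n <- length(x)
    if (is.null(W) || nrow(W) != n) {
      k <- 0:(n - 1)
      W <<- exp(-2i * pi * outer(k, k) / n)
    }
    as.vector(W %*% x)
  }
})

# Band power of one frame in [loHz, hiHz], per the DFT oracle (256 Hz frame).
oracleBandPower <- function(frame, loHz, hiHz) {
  A <- t(apply(epicircuit::frameData(frame), 1, function(ch) abs(dftOracle(ch))^2))
  bins <- which((0:255) >= loHz & (0:255) <= hiHz)
  mean(A[, bins])
}

# Naive triple-loop valid cross-correlation in double precision.
convOracle <- function(input, w, bias = 0, relu = FALSE) {
  K <- nrow(w)
  Ho <- nrow(input) - K + 1
  Wo <- ncol(input) - K + 1
  out <- matrix(0, Ho, Wo)
  for (r in seq_len(Ho)) for (c in seq_len(Wo)) {
    s <- bias
    for (kr in seq_len(K)) for (kc in seq_len(K))
      s <- s + input[r + kr - 1, c + kc - 1] * w[kr, kc]
    out[r, c] <- if (relu) max(s, 0) else s
  }
  out
}

# Brute-force 2x2/stride-2 window maximum.
bruteMaxPool <- function(m) {
  Ho <- nrow(m) %/% 2
  Wo <- ncol(m) %/% 2
  out <- matrix(0, Ho, Wo)
  for (r in seq_len(Ho)) for (c in seq_len(Wo))
    out[r, c] <- max(m[(2 * r - 1):(2 * r), (2 * c - 1):(2 * c)])
  out
}

# Event-driven simulation of the pipelined convolution array: one new output
# window enters the K-stage PE chains per cycle after the weights are loaded;
# a window's row partial sums complete K cycles after it enters and the
# cross-row sum completes in the same cycle. Returns the cycle in which the
# last output leaves the array.
eventDrivenConvCycles <- function(H, W, K) {
  Ho <- H - K + 1
  Wo <- W - K + 1
  events <- data.frame(window = seq_len(Ho * Wo))
  events$enter <- events$window     # one issue per cycle, after weight preload
  events$done <- events$enter + K - 1 + 1   # K-stage chain, result latched next cycle
  max(events$done)
}

# Double-precision decision-function oracle for the quasi-Gaussian kernel.
svmScoreOracle <- function(x, model) {
  sv <- epicircuit::supportVectors(model)
  u <- as.numeric(x)
  V <- sv
  if (model@logTransform) {
    u <- log(u + model@epsFloor * (u <= 0))
    V <- log(V + model@epsFloor * (V <= 0))
  }
  kv <- exp(-model@gammaEff * colSums((t(V) - u)^2))
  sum(model@alphas * kv) - model@b
}

# Random valid conv layer + input for property tests.
randomConvCase <- function(K, seed) {
  set.seed(seed)
  H <- sample(K:15, 1)
  W <- sample(K:20, 1)
  list(input = epicircuit::fp32Round(matrix(rnorm(H * W, sd = 2), H, W)),
       layer = epicircuit::convLayerSpec(matrix(rnorm(K * K), K, K),
                                         bias = rnorm(1),
                                         activation = sample(c("relu", "none"), 1)))
}
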