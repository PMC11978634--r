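## Three-layer convolution / two-stage max-pooling feature extractor.

#' Direct valid convolution (fp32 reference path)
#'
#' Valid (no padding) stride-1 cross-correlation with bias and optional ReLU,
#' all arithmetic in single precision. The summation order is fixed -- within
#' a kernel row left to right, then across rows top to bottom, bias injected
#' at the head of row 0 -- so the result is bit-identical to the pipelined
#' path.
#'
#' @param input H x W numeric matrix, H and W at least the kernel size.
#' @param layer a \linkS4class{ConvLayerSpec}.
#' @return (H-K+1) x (W-K+1) matrix.
#' @export
conv2dDirect <- function(input, layer) {
  stopifnot(is(layer, "ConvLayerSpec"))
  .conv2d_direct_cpp(asConvInput(input), layer@weights, layer@bias,
                     layer@activation == "relu")
}

#' Pipelined-dataflow convolution with cycle count
#'
#' Emulates the K parallel row-operation units of the configurable
#' convolution circuit, each a chain of K multiply-add-register PEs: per
#' output element the row partial sums complete after K cycles and are summed
#' across rows. The output is bit-identical to [conv2dDirect()]; the cycle
#' count follows the pipeline model `K + H_out * W_out` (K fill cycles, then
#' one result per cycle).
#'
#' @inheritParams conv2dDirect
#' @return List with `output` (matrix) and `cycles` (count).
#' @export
conv2dPipelined <- function(input, layer) {
  stopifnot(is(layer, "ConvLayerSpec"))
  .conv2d_pipelined_cpp(asConvInput(input), layer@weights, layer@bias,
                        layer@activation == "relu")
}

asConvInput <- function(input) {
  if (is(input, "EEGFrame")) input <- input@data
  if (is(input, "SpectralFrame")) input <- input@amplitude
  if (!is.matrix(input) || !is.numeric(input))
    stop("shape error: convolution input must be a numeric matrix")
  input
}

#' Two-stage max pooling
#'
#' Non-overlapping 2 x 2 windows with stride 2, emulating the two-level
#' comparator scheme: stage 1 compares (Data0, Data1) and (Data2, Data3) at
#' the base clock, stage 2 compares the two winners at half rate. Trailing
#' odd rows/columns are dropped (floor).
#'
#' @param input H x W numeric matrix with at least one complete window.
#' @return `floor(H/2) x floor(W/2)` matrix of window maxima.
#' @export
maxPoolTwoStage <- function(input) {
  .maxpool_two_stage_cpp(asConvInput(input))$output
}

#' Run the full feature-extraction stack
#'
#' conv(5x5) -> pool -> conv(3x3) -> pool -> conv(1x1) -> pool on a 20 x 256
#' input, producing the length-31 feature vector (the final 1 x 31 map
#' flattened row-major) and the per-stage cycle counts of the pipelined
#' dataflow. Intermediate shapes: 16x252 -> 8x126 -> 6x124 -> 3x62 -> 3x62 ->
#' 1x31.
#'
#' @param input 20 x 256 matrix, \linkS4class{EEGFrame} or
#'   \linkS4class{SpectralFrame}.
#' @param model a \linkS4class{CNNModel}.
#' @return List with `features` (numeric length 31), `cycles` (named vector:
#'   conv1, pool1, conv2, pool2, conv3, pool3) and `shapes` (list of
#'   intermediate dims).
#' @export
extractFeatures <- function(input, model) {
  stopifnot(is(model, "CNNModel"))
  x <- asConvInput(input)
  if (!identical(dim(x), c(N_CHANNELS, N_SAMPLES)))
    stop(sprintf("shape error: expected %d x %d input, observed %d x %d",
                 N_CHANNELS, N_SAMPLES, nrow(x), ncol(x)))
  cycles <- numeric(0)
  shapes <- list()
  for (i in 1:3) {
    cv <- conv2dPipelined(x, model@layers[[i]])
    cycles[sprintf("conv%d", i)] <- cv$cycles
    shapes[[sprintf("conv%d", i)]] <- dim(cv$output)
    pl <- .maxpool_two_stage_cpp(cv$output)
    cycles[sprintf("pool%d", i)] <- pl$cycles
    shapes[[sprintf("pool%d", i)]] <- dim(pl$output)
    x <- pl$output
  }
  if (!identical(dim(x), c(1L, 31L)))
    stop("internal shape contract violated: final map is not 1 x 31")
  list(features = as.numeric(t(x)), cycles = cycles, shapes = shapes)
}

#' Random fp32 CNN model
#'
#' Convenience constructor of a valid three-layer model with seeded Gaussian
#' kernels, used for property tests and the latency model.
#'
#' @param seed RNG seed.
#' @param sd kernel weight standard deviation.
#' @param activation activation for all three layers.
#' @return A \linkS4class{CNNModel}.
#' @export
randomCNNModel <- function(seed = 1L, sd = 0.1, activation = "relu") {
  withLocalSeed(seed, {
    layers <- lapply(c(5L, 3L, 1L), function(K)
      convLayerSpec(matrix(rnorm(K * K, sd = sd), K, K),
                    bias = rnorm(1, sd = sd), activation = activation))
    cnnModel(layers)
  })
}
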