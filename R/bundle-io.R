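## Model-bundle serialization: one JSON document per model, numbers written
## at full precision (all stored values are fp32-representable, so the
## decimal round trip is exact).

#' Write a CNN or SVM model bundle
#'
#' @param model a \linkS4class{CNNModel} or \linkS4class{SVMModel}.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeModelBundle <- function(model, path) {
  if (is(model, "CNNModel")) {
    obj <- list(type = "cnn",
                layers = lapply(model@layers, function(l)
                  list(kernel_size = nrow(l@weights),
                       weights = as.numeric(l@weights), bias = l@bias,
                       activation = l@activation)))
  } else if (is(model, "SVMModel")) {
    obj <- list(type = "svm",
                support_vectors = unname(apply(model@supportVectors, 1, as.numeric,
                                               simplify = FALSE)),
                alphas = model@alphas, b = model@b, sigma = model@sigma,
                s_max = model@sMax, s_min = model@sMin,
                f_max = model@fMax, f_min = model@fMin,
                gamma_eff = model@gammaEff, log_transform = model@logTransform,
                eps_floor = model@epsFloor)
  } else stop("model must be a CNNModel or SVMModel")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model bundle written by [writeModelBundle()]
#'
#' The loader validates the class invariants (kernel sizes, support-vector
#' geometry, positive kernel scale).
#'
#' @param path JSON path.
#' @return A \linkS4class{CNNModel} or \linkS4class{SVMModel}.
#' @export
readModelBundle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "cnn")) {
    layers <- lapply(seq_len(nrow(obj$layers)), function(i) {
      K <- obj$layers$kernel_size[i]
      convLayerSpec(matrix(obj$layers$weights[[i]], K, K),
                    bias = obj$layers$bias[i],
                    activation = obj$layers$activation[i])
    })
    cnnModel(layers)
  } else if (identical(obj$type, "svm")) {
    sv <- obj$support_vectors
    if (is.list(sv)) sv <- do.call(rbind, sv)
    sv <- matrix(as.numeric(sv), nrow = length(obj$alphas))
    svmModel(sv, alphas = obj$alphas, b = obj$b, sigma = obj$sigma,
             fMax = obj$f_max, fMin = obj$f_min,
             sMax = obj$s_max, sMin = obj$s_min, gammaEff = obj$gamma_eff,
             logTransform = obj$log_transform, epsFloor = obj$eps_floor)
  } else stop("unrecognized bundle type: ", obj$type)
}
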