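#' @import methods
NULL

#' Estimate the noise level of a single image
#'
#' Generic for patch-based single-image noise estimation. See
#' \code{\link{estimateNoise,ImageGrid-method}} for the default method.
#'
#' @param img an image (\code{\linkS4class{ImageGrid}} or numeric matrix).
#' @param ... method arguments such as \code{patchSize} and \code{stride}.
#' @return An \code{\linkS4class{EnlReport}}.
#' @export
setGeneric("estimateNoise", function(img, ...) standardGeneric("estimateNoise"))

#' Predict the noise component of a noisy image
#'
#' Generic for the denoiser contract: given the upsampled condition, the
#' noisy state and the cumulative signal fraction gamma, return the
#' predicted standard-normal noise field.
#'
#' @param denoiser a denoiser object (or plain function for stubs).
#' @param xup upsampled low-resolution condition, model scale.
#' @param yt noisy image at the current timestep, model scale.
#' @param gamma scalar cumulative signal fraction in (0, 1).
#' @param ... further arguments.
#' @return A matrix of the same shape as \code{yt}.
#' @export
setGeneric("predictNoise", function(denoiser, xup, yt, gamma, ...)
  standardGeneric("predictNoise"))

#' @rdname ImageGrid-class
#' @param x an \code{ImageGrid}.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname ImageGrid-class
#' @export
setGeneric("valueRange", function(x) standardGeneric("valueRange"))

#' @rdname ImageGrid-class
#' @export
setGeneric("isModelScale", function(x) standardGeneric("isModelScale"))

#' @rdname NoiseSchedule-class
#' @param x a \code{NoiseSchedule}.
#' @export
setGeneric("alphas", function(x) standardGeneric("alphas"))

#' @rdname NoiseSchedule-class
#' @export
setGeneric("gammas", function(x) standardGeneric("gammas"))

#' @rdname NoiseSchedule-class
#' @export
setGeneric("numSteps", function(x) standardGeneric("numSteps"))
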