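#' 2-D grayscale image with declared intensity range
#'
#' The elementary container used throughout the package. An \code{ImageGrid}
#' is a real-valued matrix in (row, column) order together with the declared
#' storage intensity interval (for example \code{c(0, 255)} for 8-bit data)
#' and a flag stating whether the pixels currently live on the model scale
#' \eqn{[-1, 1]} used by the diffusion process.
#'
#' @slot pixels numeric matrix, all values finite.
#' @slot valueRange numeric(2), increasing storage intensity interval.
#' @slot modelScale logical; \code{TRUE} when pixels are on \eqn{[-1, 1]}.
#'
#' @seealso \code{\link{toModelScale}}, \code{\link{toStorageScale}}
#' @aliases pixels valueRange isModelScale
#' @export
setClass("ImageGrid",
  representation(pixels = "matrix", valueRange = "numeric",
                 modelScale = "logical"),
  prototype(valueRange = c(0, 255), modelScale = FALSE),
  validity = function(object) {
    if (!is.numeric(object@pixels))
      return("pixels must be a numeric matrix")
    if (!all(is.finite(object@pixels)))
      return("pixels must all be finite")
    if (length(object@valueRange) != 2L ||
        !all(is.finite(object@valueRange)) ||
        diff(object@valueRange) <= 0)
      return("valueRange must be an increasing numeric interval")
    if (length(object@modelScale) != 1L || is.na(object@modelScale))
      return("modelScale must be TRUE or FALSE")
    TRUE
  })

#' Diffusion noise schedule
#'
#' Per-step signal-retention coefficients \eqn{\alpha_t \in (0,1)} and their
#' cumulative products \eqn{\gamma_t = \prod_{i \le t} \alpha_i}, for
#' \eqn{t = 1 \ldots T}. The boundary convention \eqn{\gamma_0 = 1} makes the
#' closed-form posterior well defined at \eqn{t = 1}.
#'
#' @slot alpha numeric vector of per-step coefficients, each in (0, 1).
#' @slot gamma numeric vector of cumulative products.
#' @slot kind character, the schedule family used to build the object.
#' @slot params list of the parameters the schedule was built from.
#'
#' @seealso \code{\link{buildSchedule}}
#' @aliases alphas gammas numSteps
#' @export
setClass("NoiseSchedule",
  representation(alpha = "numeric", gamma = "numeric", kind = "character",
                 params = "list"),
  validity = function(object) {
    a <- object@alpha
    if (length(a) < 1L) return("schedule needs at least one step")
    bad <- which(!(a > 0 & a < 1))
    if (length(bad))
      return(sprintf("alpha must lie in (0,1); violated at step %d (alpha = %g)",
                     bad[1L], a[bad[1L]]))
    if (length(object@gamma) != length(a))
      return("gamma and alpha must have equal length")
    if (max(abs(object@gamma - cumprod(a))) >= 1e-12)
      return("gamma must equal cumprod(alpha) to 1e-12")
    if (any(diff(c(1, object@gamma)) >= 0))
      return("gamma must be strictly decreasing from gamma_0 = 1")
    TRUE
  })

#' Conditional epsilon-predicting U-Net denoiser
#'
#' Holds the configuration and trainable parameters of the conditional
#' U-Net \eqn{f_\theta(x, y_t, \gamma_t) \rightarrow \hat\varepsilon}.
#' Parameters and optimizer state live in an environment slot so training
#' can update them in place; inference is deterministic given the
#' parameters.
#'
#' @slot config list: \code{baseChannels}, \code{depthMultipliers},
#'   \code{embDim}, \code{embHidden}, \code{inputChannels}.
#' @slot state environment containing \code{P} (parameter list) and
#'   \code{opt} (Adam moments and step counter).
#' @slot seed integer seed used for parameter initialization.
#'
#' @seealso \code{\link{buildDenoiser}}, \code{\link{trainDenoiser}}
#' @export
setClass("UNetDenoiser",
  representation(config = "list", state = "environment", seed = "integer"))

#' Result of noise-level-gated sampling
#'
#' @slot image the selected high-resolution sample (\code{ImageGrid},
#'   storage scale).
#' @slot attempts number of full reverse chains run.
#' @slot enlHistory estimated noise level of each attempt, in order.
#' @slot sigmaX estimated noise level of the (upsampled) low-resolution
#'   input that the gate compared against.
#' @slot accepted \code{TRUE} when the returned sample passed the gate.
#' @slot seed integer seed the sampling run started from (NA when the
#'   caller supplied a live random source).
#'
#' @seealso \code{\link{gatedSample}}
#' @export
setClass("SRResult",
  representation(image = "ImageGrid", attempts = "integer",
                 enlHistory = "numeric", sigmaX = "numeric",
                 accepted = "logical", seed = "integer"),
  validity = function(object) {
    if (object@attempts < 1L) return("attempts must be >= 1")
    if (length(object@enlHistory) != object@attempts)
      return("enlHistory must have one entry per attempt")
    if (object@accepted &&
        object@enlHistory[object@attempts] > object@sigmaX + 1e-12)
      return("accepted result must satisfy ENL <= sigmaX")
    TRUE
  })

#' Estimated noise level of a single image
#'
#' @slot sigma estimated noise standard deviation, storage intensity units.
#' @slot sigma2 minimum eigenvalue of the patch covariance matrix
#'   (clamped at zero against round-off).
#' @slot patchSize side length of the square patches used.
#' @slot stride sampling stride of the patch grid.
#' @slot nPatches number of patches entering the covariance.
#'
#' @seealso \code{\link{estimateNoise}}
#' @export
setClass("EnlReport",
  representation(sigma = "numeric", sigma2 = "numeric", patchSize = "integer",
                 stride = "integer", nPatches = "integer"),
  validity = function(object) {
    if (object@sigma2 < 0) return("sigma2 must be non-negative")
    if (abs(object@sigma - sqrt(object@sigma2)) > 1e-12)
      return("sigma must equal sqrt(sigma2)")
    TRUE
  })

#' Per-image and aggregate image-quality report
#'
#' @slot perImage data.frame with one row per (image, method) and one
#'   column per metric.
#' @slot aggregate data.frame of mean and SD per (method, metric), plus
#'   enhancement percentages relative to the named baseline and paired
#'   Wilcoxon p-values where a baseline is present.
#' @slot baseline character, name of the baseline method ("" when none).
#'
#' @seealso \code{\link{evaluatePairs}}, \code{\link{summarizeMetrics}}
#' @export
setClass("MetricReport",
  representation(perImage = "data.frame", aggregate = "data.frame",
                 baseline = "character"))

setMethod("show", "ImageGrid", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageGrid %d x %d, range [%.3g, %.3g] of declared [%g, %g]%s\n",
              d[1L], d[2L], min(object@pixels), max(object@pixels),
              object@valueRange[1L], object@valueRange[2L],
              if (object@modelScale) " (model scale)" else ""))
})

setMethod("show", "NoiseSchedule", function(object) {
  T <- length(object@alpha)
  cat(sprintf("NoiseSchedule: T = %d, kind = '%s', gamma_T = %.3g\n",
              T, object@kind, object@gamma[T]))
})

setMethod("show", "UNetDenoiser", function(object) {
  cfg <- object@config
  np <- sum(vapply(unlist(object@state$P, recursive = TRUE),
                   length, integer(1)))
  cat(sprintf(
    "UNetDenoiser: base %d channels, depth multipliers (%s), %d parameters\n",
    cfg$baseChannels, paste(cfg$depthMultipliers, collapse = ","), np))
})

setMethod("show", "SRResult", function(object) {
  cat(sprintf(
    "SRResult: %s after %d attempt(s); ENL %.4g vs sigma_x %.4g\n",
    if (object@accepted) "accepted" else "fallback (gate not met)",
    object@attempts, object@enlHistory[object@attempts], object@sigmaX))
})

setMethod("show", "EnlReport", function(object) {
  cat(sprintf("EnlReport: sigma = %.4g (patch %dx%d, stride %d, M = %d)\n",
              object@sigma, object@patchSize, object@patchSize,
              object@stride, object@nPatches))
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport: %d per-image rows, baseline = '%s'\n",
              nrow(object@perImage), object@baseline))
  print(object@aggregate, row.names = FALSE)
})
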