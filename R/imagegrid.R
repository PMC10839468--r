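#' Construct an ImageGrid
#'
#' @param pixels numeric matrix in (row, column) order.
#' @param valueRange declared storage intensity interval, default
#'   \code{c(0, 255)} (8-bit convention).
#' @param modelScale whether \code{pixels} are already on the model scale
#'   \eqn{[-1, 1]}.
#' @return An \code{\linkS4class{ImageGrid}}.
#' @examples
#' img <- ImageGrid(matrix(0, 8, 8))
#' dim(img)
#' @export
ImageGrid <- function(pixels, valueRange = c(0, 255), modelScale = FALSE) {
  if (is.vector(pixels)) pixels <- matrix(pixels, nrow = 1L)
  new("ImageGrid", pixels = pixels, valueRange = as.numeric(valueRange),
      modelScale = isTRUE(modelScale))
}

#' @rdname ImageGrid-class
#' @export
setMethod("pixels", "ImageGrid", function(x) x@pixels)

#' @rdname ImageGrid-class
#' @export
setMethod("valueRange", "ImageGrid", function(x) x@valueRange)

#' @rdname ImageGrid-class
#' @export
setMethod("isModelScale", "ImageGrid", function(x) x@modelScale)

#' @export
setMethod("dim", "ImageGrid", function(x) dim(x@pixels))

#' @export
setMethod("as.matrix", "ImageGrid", function(x, ...) x@pixels)

# Internal: accept ImageGrid or bare matrix in computational code.
px <- function(img) {
  if (is(img, "ImageGrid")) img@pixels
  else if (is.matrix(img)) img
  else stop("expected an ImageGrid or a numeric matrix")
}

#' Map an image between storage and model scales
#'
#' The diffusion process operates on the model scale \eqn{[-1, 1]};
#' storage formats use the declared \code{valueRange} (e.g. 0--255).
#' \code{toModelScale} applies the affine map sending the storage interval
#' onto \eqn{[-1, 1]}; \code{toStorageScale} inverts it and clips to the
#' storage interval (sampled intensities can stray slightly outside).
#'
#' @param img an \code{ImageGrid}.
#' @param clip for \code{toStorageScale}: clip into the storage interval
#'   (default \code{TRUE}).
#' @return An \code{ImageGrid} on the requested scale.
#' @export
toModelScale <- function(img) {
  stopifnot(is(img, "ImageGrid"))
  if (img@modelScale) return(img)
  vr <- img@valueRange
  p <- 2 * (img@pixels - vr[1L]) / diff(vr) - 1
  new("ImageGrid", pixels = p, valueRange = vr, modelScale = TRUE)
}

#' @rdname toModelScale
#' @export
toStorageScale <- function(img, clip = TRUE) {
  stopifnot(is(img, "ImageGrid"))
  if (!img@modelScale) return(img)
  vr <- img@valueRange
  p <- (img@pixels + 1) / 2 * diff(vr) + vr[1L]
  if (clip) p <- pmin(pmax(p, vr[1L]), vr[2L])
  new("ImageGrid", pixels = p, valueRange = vr, modelScale = FALSE)
}

# Internal: require model scale, returning the pixel matrix.
modelPx <- function(img, what = "image") {
  if (is(img, "ImageGrid")) {
    if (!img@modelScale)
      stop(sprintf("%s must be on the model scale [-1, 1]; see toModelScale()",
                   what))
    img@pixels
  } else {
    px(img)
  }
}
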