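# Separable image resampling built on the Keys cubic-convolution kernel
# (a = -0.5), the classical "bicubic" of image processing. Down-sampling
# widens the kernel by the zoom factor (anti-aliasing); weights are
# renormalized per output sample so a constant image maps to the same
# constant regardless of border clamping.

keysCubic <- function(x) {
  x <- abs(x)
  ifelse(x < 1, 1.5 * x^3 - 2.5 * x^2 + 1,
         ifelse(x < 2, -0.5 * x^3 + 2.5 * x^2 - 4 * x + 2, 0))
}

boxKernel <- function(x) as.numeric(abs(x) <= 0.5)

# Dense (nOut x nIn) row-interpolation matrix for one axis.
resampleMatrix <- function(nIn, nOut, kernel = c("bicubic", "box", "nearest"),
                           antialias = TRUE) {
  kernel <- match.arg(kernel)
  scale <- nIn / nOut
  s <- if (antialias && scale > 1) scale else 1
  centers <- (seq_len(nOut) - 0.5) * scale - 0.5       # 0-based src coords
  W <- matrix(0, nOut, nIn)
  support <- switch(kernel, bicubic = 2, box = 0.5, nearest = 0.5) * s
  kf <- switch(kernel, bicubic = keysCubic, box = boxKernel,
               nearest = boxKernel)
  for (i in seq_len(nOut)) {
    lo <- max(1L, floor(centers[i] - support) + 1L)
    hi <- min(nIn, ceiling(centers[i] + support) + 1L)
    j <- lo:hi
    w <- kf((j - 1 - centers[i]) / s)
    if (kernel == "nearest") {
      jn <- min(nIn, max(1L, round(centers[i]) + 1L))
      w <- as.numeric(j == jn)
    }
    sw <- sum(w)
    if (sw <= 0) { # degenerate support (should not happen)
      jn <- min(nIn, max(1L, round(centers[i]) + 1L))
      w <- as.numeric(j == jn); sw <- 1
    }
    W[i, j] <- w / sw
  }
  W
}

# Core resampler: applies the separable kernel along rows then columns.
resampleImage <- function(m, targetShape, kernel = "bicubic",
                          antialias = TRUE) {
  stopifnot(length(targetShape) == 2L)
  Wr <- resampleMatrix(nrow(m), targetShape[1L], kernel, antialias)
  Wc <- resampleMatrix(ncol(m), targetShape[2L], kernel, antialias)
  Wr %*% m %*% t(Wc)
}

#' Bicubic up-sampling of the low-resolution condition
#'
#' Up-samples a low-resolution image to the high-resolution grid with
#' cubic-convolution (bicubic) interpolation; this is the representation
#' the denoiser is conditioned on, and also the classical "Bicubic"
#' baseline the diffusion output is compared against.
#'
#' @param lr low-resolution image (\code{ImageGrid} or matrix).
#' @param targetShape integer (height, width), each at least the
#'   corresponding input dimension.
#' @return Same type as the input, at \code{targetShape}, same intensity
#'   scale.
#' @export
upsampleCondition <- function(lr, targetShape) {
  m <- px(lr)
  if (any(targetShape < dim(m)))
    stop(sprintf("target %dx%d is smaller than input %dx%d",
                 targetShape[1L], targetShape[2L], nrow(m), ncol(m)))
  out <- resampleImage(m, targetShape, kernel = "bicubic", antialias = FALSE)
  if (is(lr, "ImageGrid"))
    new("ImageGrid", pixels = out, valueRange = lr@valueRange,
        modelScale = lr@modelScale)
  else out
}

#' Resolution degradation of a high-resolution image
#'
#' Anti-aliased down-sampling emulating the acquisition of a
#' low-resolution counterpart. The canonical full-scale geometry is
#' 256x256 down to 86x128 (a pixel-count ratio of about 6).
#'
#' @param hr high-resolution image (\code{ImageGrid} or matrix).
#' @param targetShape integer (height, width), strictly smaller than the
#'   source in both dimensions.
#' @param method resampling kernel: \code{"bicubic"} (anti-aliased,
#'   default), \code{"box"} or \code{"nearest"}.
#' @return Same type as the input, at \code{targetShape}.
#' @export
degradeImage <- function(hr, targetShape = c(86L, 128L),
                         method = c("bicubic", "box", "nearest")) {
  method <- match.arg(method)
  m <- px(hr)
  if (any(targetShape >= dim(m)))
    stop(sprintf("target %dx%d must be strictly smaller than source %dx%d",
                 targetShape[1L], targetShape[2L], nrow(m), ncol(m)))
  out <- resampleImage(m, targetShape, kernel = method, antialias = TRUE)
  if (is(hr, "ImageGrid"))
    new("ImageGrid", pixels = out, valueRange = hr@valueRange,
        modelScale = hr@modelScale)
  else out
}

#' Zero-pad an image to a larger canvas
#'
#' Centers the image in a zero background (e.g. 240x240 slices padded to
#' 256x256 before diffusion). The centering offset is attached as
#' attribute \code{"padOffset"} (top, left, 0-based) so the padding can be
#' inverted.
#'
#' @param img image (\code{ImageGrid} or matrix).
#' @param targetShape integer (height, width), at least the source size.
#' @return Padded image of the same type.
#' @export
zeroPad <- function(img, targetShape) {
  m <- px(img)
  if (any(targetShape < dim(m)))
    stop("zeroPad target must be at least the source size")
  top  <- (targetShape[1L] - nrow(m)) %/% 2L
  left <- (targetShape[2L] - ncol(m)) %/% 2L
  out <- matrix(0, targetShape[1L], targetShape[2L])
  out[top + seq_len(nrow(m)), left + seq_len(ncol(m))] <- m
  attr(out, "padOffset") <- c(top = top, left = left)
  if (is(img, "ImageGrid")) {
    res <- new("ImageGrid", pixels = out, valueRange = img@valueRange,
               modelScale = img@modelScale)
    attr(res@pixels, "padOffset") <- c(top = top, left = left)
    res
  } else out
}

# Separable Gaussian blur with edge replication; sigma in pixels.
gaussianBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  n <- length(k)
  blur1d <- function(x) {          # columns of x blurred along rows
    H <- nrow(x)
    padded <- rbind(x[rep(1L, r), , drop = FALSE], x,
                    x[rep(H, r), , drop = FALSE])
    out <- matrix(0, H, ncol(x))
    for (i in seq_len(n)) out <- out + k[i] * padded[(i - 1L) + seq_len(H), ,
                                                     drop = FALSE]
    out
  }
  t(blur1d(t(blur1d(m))))
}
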