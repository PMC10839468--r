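#' Extract flattened square patches on a stride grid
#'
#' Collects every fully-contained \code{patchSize x patchSize} patch whose
#' top-left corner lies on the stride grid, flattened row-major into the
#' columns of a matrix.
#'
#' @param img image (\code{ImageGrid} or matrix), storage scale.
#' @param patchSize patch side length (default 7).
#' @param stride sampling stride (default 3; use 1 for the exhaustive
#'   grid).
#' @return A list of class \code{"PatchSet"}: \code{patches}
#'   (\code{patchSize^2 x M} matrix), \code{M}, \code{patchSize},
#'   \code{stride}.
#' @export
extractPatches <- function(img, patchSize = 7L, stride = 3L) {
  m <- px(img)
  p <- as.integer(patchSize); s <- as.integer(stride)
  if (s < 1L) stop("stride must be >= 1")
  if (nrow(m) < p || ncol(m) < p)
    stop(sprintf("image %dx%d smaller than patch size %d",
                 nrow(m), ncol(m), p))
  ys <- seq(1L, nrow(m) - p + 1L, by = s)
  xs <- seq(1L, ncol(m) - p + 1L, by = s)
  M <- length(ys) * length(xs)
  # row-major flattening of each patch: offsets ordered by patch row
  offs <- as.vector(t(outer(seq_len(p), (seq_len(p) - 1L) * nrow(m), "+"))) - 1L
  tl <- as.vector(outer(ys, (xs - 1L) * nrow(m), "+"))
  Z <- matrix(m[rep(tl, each = p * p) + rep(offs, times = M)], p * p, M)
  structure(list(patches = Z, M = M, patchSize = p, stride = s),
            class = "PatchSet")
}

#' Patch covariance matrix
#'
#' Mean-centered second-moment matrix of the patch vectors,
#' \eqn{\Sigma_y = M^{-1} \sum_i (z_i - \bar z)(z_i - \bar z)^T}. Patches
#' are centered on the mean patch so that structured brightness (which
#' would otherwise bias every eigenvalue) does not contaminate the noise
#' eigenvalue; for a constant image the covariance is then exactly zero.
#'
#' @param patches a \code{"PatchSet"} from \code{\link{extractPatches}},
#'   or a bare \code{p^2 x M} matrix of patch columns.
#' @return A symmetric positive-semidefinite \code{p^2 x p^2} matrix.
#' @export
patchCovariance <- function(patches) {
  Z <- if (inherits(patches, "PatchSet")) patches$patches else
    as.matrix(patches)
  Zc <- Z - rowMeans(Z)
  S <- tcrossprod(Zc) / ncol(Z)
  (S + t(S)) / 2
}

#' Patch-based single-image noise level (ENL)
#'
#' Estimates the noise standard deviation of a single image as
#' \eqn{\sigma = \sqrt{\lambda_{\min}(\Sigma_y)}}, the square root of the
#' minimum eigenvalue of the patch covariance matrix. The rationale:
#' clean image content concentrates in a low-dimensional subspace of
#' patch space, while i.i.d. noise lifts every eigenvalue by
#' \eqn{\sigma^2}; the smallest eigenvalue is then dominated by the noise
#' floor. Eigenvalues marginally below zero from round-off are clamped
#' to zero.
#'
#' @param img image (\code{ImageGrid} or matrix), storage intensity scale.
#' @param patchSize patch side length, default 7.
#' @param stride patch sampling stride, default 3.
#' @param ... ignored.
#' @return An \code{\linkS4class{EnlReport}}; \code{sigma} is in the
#'   image's storage intensity units.
#' @examples
#' estimateNoise(makePhantom(c(96, 96), noiseStd = 5, rng = 7))
#' @aliases estimateNoise,matrix-method
#' @rdname estimateNoise-methods
#' @export
setMethod("estimateNoise", "ImageGrid", function(img, patchSize = 7L,
                                                 stride = 3L, ...) {
  estimateNoise(px(img), patchSize = patchSize, stride = stride)
})

#' @rdname estimateNoise-methods
#' @export
setMethod("estimateNoise", "matrix", function(img, patchSize = 7L,
                                              stride = 3L, ...) {
  ps <- extractPatches(img, patchSize = patchSize, stride = stride)
  if (ps$M < ps$patchSize^2)
    stop(sprintf(paste0("only %d patches for a %d-dimensional patch space ",
                        "(covariance cannot be full rank); use a smaller ",
                        "stride or a larger image"), ps$M, ps$patchSize^2))
  S <- patchCovariance(ps)
  lmin <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (lmin < 0) {
    if (lmin < -1e-10)
      warning(sprintf("minimum eigenvalue %g below round-off band", lmin))
    lmin <- 0
  }
  new("EnlReport", sigma = sqrt(lmin), sigma2 = lmin,
      patchSize = ps$patchSize, stride = ps$stride,
      nPatches = as.integer(ps$M))
})

#' @rdname EnlReport-class
#' @param x an \code{EnlReport}.
#' @export
enlSigma <- function(x) {
  stopifnot(is(x, "EnlReport"))
  x@sigma
}
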