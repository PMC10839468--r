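# Full-reference image quality metrics. Argument order is (ref, test)
# throughout; ref is the ground truth.

checkPair <- function(ref, test) {
  r <- px(ref); t <- px(test)
  if (!all(dim(r) == dim(t)))
    stop(sprintf("shape mismatch: ref %dx%d vs test %dx%d",
                 nrow(r), ncol(r), nrow(t), ncol(t)))
  list(r = r, t = t)
}

#' Mean absolute error
#'
#' @param ref,test images of identical shape and intensity scale.
#' @return Scalar mean of absolute per-pixel differences.
#' @export
imageMAE <- function(ref, test) {
  p <- checkPair(ref, test)
  mean(abs(p$r - p$t))
}

#' Peak signal-to-noise ratio
#'
#' \eqn{10 \log_{10}(\mathrm{peak}^2 / \mathrm{MSE})} in dB. Identical
#' images give \code{Inf} (reported as "inf" in text output).
#'
#' @param ref,test images of identical shape and intensity scale.
#' @param peak dynamic range of the intensity scale (default 255).
#' @return Scalar in dB.
#' @export
imagePSNR <- function(ref, test, peak = 255) {
  stopifnot(peak > 0)
  p <- checkPair(ref, test)
  mse <- mean((p$r - p$t)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

# Single-scale SSIM maps via an 11x11 Gaussian window (sigma 1.5), valid
# region only. Returns mean luminance*cs and mean cs terms.
ssimComponents <- function(r, t, peak, K = c(0.01, 0.03),
                           windowSize = 11L, windowSigma = 1.5) {
  g <- stats::dnorm(seq_len(windowSize) - (windowSize + 1) / 2,
                    sd = windowSigma)
  g <- g / sum(g)
  validFilter <- function(m) {
    H <- nrow(m); W <- ncol(m); n <- windowSize
    Wr <- matrix(0, H - n + 1L, H)
    for (i in seq_len(H - n + 1L)) Wr[i, i:(i + n - 1L)] <- g
    Wc <- matrix(0, W - n + 1L, W)
    for (i in seq_len(W - n + 1L)) Wc[i, i:(i + n - 1L)] <- g
    Wr %*% m %*% t(Wc)
  }
  C1 <- (K[1] * peak)^2; C2 <- (K[2] * peak)^2
  mu1 <- validFilter(r); mu2 <- validFilter(t)
  s11 <- validFilter(r * r) - mu1^2
  s22 <- validFilter(t * t) - mu2^2
  s12 <- validFilter(r * t) - mu1 * mu2
  cs  <- (2 * s12 + C2) / (s11 + s22 + C2)
  lum <- (2 * mu1 * mu2 + C1) / (mu1^2 + mu2^2 + C1)
  list(ssim = mean(lum * cs), cs = mean(cs))
}

downsample2 <- function(m) {
  H <- 2L * (nrow(m) %/% 2L); W <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(H), seq_len(W), drop = FALSE]
  0.25 * (m[seq(1L, H, 2L), seq(1L, W, 2L)] +
          m[seq(2L, H, 2L), seq(1L, W, 2L)] +
          m[seq(1L, H, 2L), seq(2L, W, 2L)] +
          m[seq(2L, H, 2L), seq(2L, W, 2L)])
}

#' Multi-scale structural similarity (MS-SSIM)
#'
#' Wang et al.'s multi-scale SSIM: contrast/structure terms at each level
#' of a dyadic pyramid, a luminance term at the coarsest level, combined
#' with the standard exponent weights (0.0448, 0.2856, 0.3001, 0.2363,
#' 0.1333). With fewer than 5 levels (small images) the leading weights
#' are renormalized to sum to one. Negative contrast terms are clamped at
#' zero before exponentiation so the measure stays real-valued on
#' anti-correlated inputs.
#'
#' @param ref,test images of identical shape.
#' @param peak dynamic range (default 255).
#' @param levels pyramid depth (default 5); the minimum image side must
#'   be at least \code{11 * 2^(levels-1)}.
#' @param weights per-level exponents; default Wang et al.
#' @return Scalar in \eqn{[-1, 1]} (1 for identical images).
#' @export
imageMSSIM <- function(ref, test, peak = 255, levels = 5L,
                       weights = c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)) {
  p <- checkPair(ref, test)
  minSide <- min(dim(p$r))
  need <- 11L * 2L^(levels - 1L)
  if (minSide < need)
    stop(sprintf(paste0("image side %d too small for %d levels (needs >= %d); ",
                        "reduce the 'levels' argument"),
                 minSide, levels, need))
  if (levels > length(weights)) stop("more levels than weights")
  w <- weights[seq_len(levels)]
  w <- w / sum(w)
  r <- p$r; t <- p$t
  val <- 1
  for (l in seq_len(levels)) {
    comp <- ssimComponents(r, t, peak)
    if (l < levels) {
      val <- val * max(comp$cs, 0)^w[l]
      r <- downsample2(r); t <- downsample2(t)
    } else {
      val <- val * max(comp$ssim, 0)^w[l]
    }
  }
  val
}

#' Enhancement percentage relative to a baseline
#'
#' Percentage improvement of a method over a baseline value, with the
#' direction of "better" made explicit: for higher-better metrics
#' \eqn{100 (m - b)/b}, for lower-better metrics \eqn{100 (b - m)/b}.
#'
#' @param baseline,method scalar metric values (baseline nonzero).
#' @param direction \code{"higher-better"} or \code{"lower-better"}.
#' @return Percentage (positive = method better).
#' @export
enhancementPct <- function(baseline, method,
                           direction = c("higher-better", "lower-better")) {
  direction <- match.arg(direction)
  if (any(baseline == 0)) stop("zero baseline")
  if (direction == "higher-better") 100 * (method - baseline) / baseline
  else 100 * (baseline - method) / baseline
}

#' Paired two-sided Wilcoxon signed-rank comparison
#'
#' Two-sided paired Wilcoxon signed-rank test between per-image metric
#' values of two methods (exact distribution for n <= 25 without ties,
#' normal approximation otherwise). Pairs with zero difference are
#' dropped per the signed-rank convention; if every difference is zero
#' the sequences are indistinguishable and p = 1.
#'
#' @param valuesA,valuesB numeric vectors of equal length >= 5, paired by
#'   image.
#' @return The p-value.
#' @export
pairedCompare <- function(valuesA, valuesB) {
  if (length(valuesA) != length(valuesB)) stop("length mismatch")
  if (length(valuesA) < 5L) stop("need at least 5 pairs")
  d <- valuesA - valuesB
  if (all(d == 0)) return(1)
  suppressWarnings(
    stats::wilcox.test(valuesA, valuesB, paired = TRUE,
                       alternative = "two.sided")$p.value)
}
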