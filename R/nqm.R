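# Noise quality measure: a degradation-model metric. The reference and
# test images are passed through a model of early vision -- a cosine-log
# contrast pyramid (Peli), a contrast sensitivity threshold
# (Mannos-Sakrison form) and linear contrast masking -- and the metric is
# the SNR between the two model-restored images. The exact computation
# implemented here is spelled out in the methods vignette; the constants
# (CSF form, masking slope 0.86 and facilitation floor 0.3) are the
# published ones.

# Contrast threshold at spatial frequency f (cycles/degree).
nqmCtf <- function(f) {
  1 / (200 * 2.6 * (0.0192 + 0.114 * f) * exp(-(0.114 * f)^1.1))
}

# Signed radial frequency grid (cycles/image) in unshifted FFT layout.
radialFreq <- function(H, W) {
  fy <- c(0:(H %/% 2), -((H - H %/% 2 - 1):1))[seq_len(H)]
  fx <- c(0:(W %/% 2), -((W - W %/% 2 - 1):1))[seq_len(W)]
  sqrt(outer(fy^2, fx^2, "+"))
}

# Raised-cosine filter bank on the log2 frequency axis; partition of
# unity: lowpass + K bands (last band keeps everything above its center).
nqmFilterBank <- function(r, K) {
  lr <- log2(pmax(r, .Machine$double.xmin))   # finite at the DC bin
  lowpass <- ifelse(r <= 1, 1, ifelse(r < 2, 0.5 * (1 + cos(pi * lr)), 0))
  bands <- vector("list", K)
  for (k in seq_len(K - 1L)) {
    inb <- r > 2^(k - 1) & r < 2^(k + 1)
    bands[[k]] <- ifelse(inb, 0.5 * (1 + cos(pi * (lr - k))), 0)
  }
  last <- ifelse(r >= 2^K, 1,
                 ifelse(r > 2^(K - 1), 0.5 * (1 + cos(pi * (lr - K))), 0))
  bands[[K]] <- last
  list(lowpass = lowpass, bands = bands)
}

bandpass <- function(Fm, filt) Re(stats::fft(Fm * filt, inverse = TRUE)) /
  length(Fm)

# Sign-preserving luminance denominator, floored at 1 intensity unit.
safeDenom <- function(l) ifelse(l >= 0, pmax(l, 1), pmin(l, -1))

#' Noise quality measure (NQM)
#'
#' Weighted SNR between the model-restored reference and test images
#' under a degradation model of early vision: both images are decomposed
#' with a cosine-log contrast pyramid, band contrasts below the contrast
#' sensitivity threshold are discarded, band distortions below the
#' masked detection threshold are replaced by the reference band, and
#' the metric is \eqn{10\log_{10}(\sum O_m^2 / \sum (O_m - I_m)^2)} dB.
#' Identical images return \code{Inf}.
#'
#' @param ref,test images of identical shape, storage intensity scale.
#' @param viewingAngle angle (degrees) subtended by the image, default 4;
#'   band center frequencies in cycles/degree are cycles/image divided by
#'   this angle.
#' @return Scalar in dB (higher = less perceived distortion).
#' @export
imageNQM <- function(ref, test, viewingAngle = 4) {
  p <- checkPair(ref, test)
  H <- nrow(p$r); W <- ncol(p$r)
  K <- min(5L, max(2L, floor(log2(min(H, W) / 2))))
  r <- radialFreq(H, W)
  fb <- nqmFilterBank(r, K)
  FO <- stats::fft(p$r); FI <- stats::fft(p$t)
  lO <- bandpass(FO, fb$lowpass); lI <- bandpass(FI, fb$lowpass)
  Omodel <- lO; Imodel <- lI
  lowO <- lO; lowI <- lI
  for (k in seq_len(K)) {
    AO <- bandpass(FO, fb$bands[[k]])
    AI <- bandpass(FI, fb$bands[[k]])
    cO <- AO / safeDenom(lowO)
    cI <- AI / safeDenom(lowI)
    ct <- nqmCtf(2^k / viewingAngle)
    detO <- abs(cO) >= ct
    # masked detection threshold for the band distortion
    Tmask <- ct * (0.3 + 0.86 * abs(cO) / ct)
    supra <- abs(cI - cO) >= Tmask
    Omodel <- Omodel + AO * detO
    Imodel <- Imodel + ifelse(supra, AI, AO * detO)
    lowO <- lowO + AO; lowI <- lowI + AI
  }
  err <- sum((Omodel - Imodel)^2)
  if (err == 0) return(Inf)
  10 * log10(sum(Omodel^2) / err)
}
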