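#' One ancestral reverse-sampling step
#'
#' Applies the learned denoising update
#' \deqn{y_{t-1} = \sqrt{1-\alpha_t}\,\varepsilon_t + \frac{1}{\sqrt{\alpha_t}}
#'   \left[y_t - \frac{1-\alpha_t}{\sqrt{1-\gamma_t}}
#'   f_\theta(x, y_t, \gamma_t)\right]}
#' with \eqn{\varepsilon_t \sim N(0, I)} for \eqn{t > 1} and
#' \eqn{\varepsilon_t = 0} at the final step, so the last update is
#' deterministic.
#'
#' @param denoiser a \code{\linkS4class{UNetDenoiser}} or stub function.
#' @param xup upsampled condition, model scale.
#' @param yt current state, model scale.
#' @param t timestep.
#' @param schedule a \code{\linkS4class{NoiseSchedule}}.
#' @param rng an \code{\link{rngSource}} (unused at \code{t = 1}).
#' @param epsT optional forced noise draw (tests).
#' @return Matrix \eqn{y_{t-1}} on the model scale.
#' @export
reverseStep <- function(denoiser, xup, yt, t, schedule, rng = NULL,
                        epsT = NULL) {
  xm <- modelPx(xup, "xup"); ym <- modelPx(yt, "yt")
  t <- checkStep(schedule, t)
  a <- schedule@alpha[t]; g <- schedule@gamma[t]
  epsHat <- predictNoise(denoiser, xm, ym, g)
  if (!all(is.finite(epsHat))) stop("non-finite denoiser output")
  mu <- (ym - (1 - a) / sqrt(1 - g) * epsHat) / sqrt(a)
  if (t == 1L) return(mu)
  if (is.null(epsT)) {
    if (is.null(rng)) stop("rng required for t > 1 (or force epsT)")
    epsT <- withRNG(asRNG(rng),
                    matrix(stats::rnorm(length(ym)), nrow(ym), ncol(ym)))
  }
  sqrt(1 - a) * epsT + mu
}

# Batched reverse chains: lrs is a list of LR images; one full chain for
# each, all advanced in lock-step so the U-Net forward runs once per t.
sampleChains <- function(denoiser, lrs, schedule, rng, targetShape) {
  B <- length(lrs)
  xups <- lapply(lrs, function(lr)
    px(toModelScale(asImageGrid(upsampleCondition(lr, targetShape)))))
  H <- targetShape[1L]; W <- targetShape[2L]
  T <- length(schedule@alpha)
  ys <- withRNG(rng, lapply(seq_len(B), function(b)
    matrix(stats::rnorm(H * W), H, W)))
  for (t in seq(T, 1L)) {
    a <- schedule@alpha[t]; g <- schedule@gamma[t]
    epsHat <- if (is.function(denoiser)) {
      lapply(seq_len(B), function(b) denoiser(xups[[b]], ys[[b]], g))
    } else predictBatch(denoiser, xups, ys, rep(g, B))
    noise <- if (t > 1L)
      withRNG(rng, lapply(seq_len(B), function(b)
        matrix(stats::rnorm(H * W), H, W)))
    else lapply(seq_len(B), function(b) 0)
    for (b in seq_len(B)) {
      mu <- (ys[[b]] - (1 - a) / sqrt(1 - g) * epsHat[[b]]) / sqrt(a)
      ys[[b]] <- sqrt(1 - a) * noise[[b]] + mu
    }
  }
  ys
}

asImageGrid <- function(img, valueRange = c(0, 255)) {
  if (is(img, "ImageGrid")) img else ImageGrid(img, valueRange = valueRange)
}

#' Sample a high-resolution image from the conditional diffusion model
#'
#' Draws \eqn{y_T} from the standard normal and runs the full reverse
#' chain conditioned on the bicubic-upsampled low-resolution input; the
#' model-scale result is mapped back to the storage range with clipping.
#'
#' @param denoiser a trained \code{\linkS4class{UNetDenoiser}} (or stub
#'   function).
#' @param lr low-resolution input (\code{ImageGrid}, storage scale).
#' @param schedule the \code{\linkS4class{NoiseSchedule}} the denoiser
#'   was trained with.
#' @param rng an \code{\link{rngSource}} or integer seed; same seed, same
#'   output.
#' @param targetShape high-resolution grid; defaults to double the LR
#'   height and width, or must be given when the geometry differs.
#' @return An \code{\linkS4class{ImageGrid}} on the storage scale.
#' @export
sampleSR <- function(denoiser, lr, schedule, rng, targetShape = NULL) {
  lr <- asImageGrid(lr)
  if (is.null(targetShape)) targetShape <- 2L * dim(lr)
  rng <- asRNG(rng)
  y <- sampleChains(denoiser, list(lr), schedule, rng, targetShape)[[1L]]
  toStorageScale(new("ImageGrid", pixels = y, valueRange = lr@valueRange,
                     modelScale = TRUE))
}

#' Noise-level-gated sampling
#'
#' The acceptance loop of the framework: estimate the noise level
#' \eqn{\sigma_x} of the input once (on the bicubic-upsampled HR grid by
#' default, so the two estimates are resolution-comparable), then run
#' fresh reverse chains until a candidate's estimated noise level
#' satisfies \eqn{\sigma_{\hat y_0} \le \sigma_x}. The first such
#' candidate is returned as accepted. If \code{maxAttempts} chains all
#' fail the gate, the candidate with the lowest ENL is returned with
#' \code{accepted = FALSE} and a warning.
#'
#' @inheritParams sampleSR
#' @param maxAttempts maximum number of full chains (default 10).
#' @param patchSize,stride ENL estimator settings (defaults 7 and 3).
#' @param estimateOn \code{"upsampled"} (default) estimates
#'   \eqn{\sigma_x} on the HR grid after bicubic upsampling;
#'   \code{"native"} uses the LR grid as recorded.
#' @param sampler sampling function
#'   \code{function(denoiser, lr, schedule, rng, targetShape)}; the
#'   default is \code{\link{sampleSR}}, tests may stub it.
#' @return An \code{\linkS4class{SRResult}}.
#' @export
gatedSample <- function(denoiser, lr, schedule, rng, maxAttempts = 10L,
                        targetShape = NULL, patchSize = 7L, stride = 3L,
                        estimateOn = c("upsampled", "native"),
                        sampler = sampleSR) {
  if (maxAttempts < 1L) stop("maxAttempts must be >= 1")
  estimateOn <- match.arg(estimateOn)
  lr <- asImageGrid(lr)
  if (is.null(targetShape)) targetShape <- 2L * dim(lr)
  rng <- asRNG(rng)
  seed <- rng$seed
  xref <- if (estimateOn == "upsampled") upsampleCondition(lr, targetShape)
          else lr
  sigmaX <- estimateNoise(xref, patchSize = patchSize,
                          stride = stride)@sigma
  enls <- numeric(0)
  best <- NULL; bestEnl <- Inf
  for (attempt in seq_len(maxAttempts)) {
    cand <- sampler(denoiser, lr, schedule, rng, targetShape = targetShape)
    cand <- asImageGrid(cand, valueRange = lr@valueRange)
    enl <- estimateNoise(cand, patchSize = patchSize, stride = stride)@sigma
    enls <- c(enls, enl)
    if (enl < bestEnl) { best <- cand; bestEnl <- enl }
    if (enl <= sigmaX)
      return(new("SRResult", image = cand, attempts = attempt,
                 enlHistory = enls, sigmaX = sigmaX, accepted = TRUE,
                 seed = seed))
  }
  warning(sprintf(
    "gate not met in %d attempts (best ENL %.4g > sigma_x %.4g); returning best candidate",
    maxAttempts, bestEnl, sigmaX))
  new("SRResult", image = best, attempts = as.integer(maxAttempts),
      enlHistory = enls, sigmaX = sigmaX, accepted = FALSE, seed = seed)
}

#' Pixel-wise average of repeated samples
#'
#' The sample-averaging protocol: running the stochastic sampler S times
#' and averaging reduces the residual noise of the result roughly as
#' \eqn{1/\sqrt{S}}.
#'
#' @param samples non-empty list of images of identical shape
#'   (\code{ImageGrid}s or matrices).
#' @return Same type as the first element.
#' @export
averageSamples <- function(samples) {
  if (length(samples) == 0L) stop("empty sample list")
  ms <- lapply(samples, px)
  d <- dim(ms[[1L]])
  if (!all(vapply(ms, function(m) all(dim(m) == d), logical(1))))
    stop("sample shapes differ")
  avg <- Reduce(`+`, ms) / length(ms)
  first <- samples[[1L]]
  if (is(first, "ImageGrid"))
    new("ImageGrid", pixels = avg, valueRange = first@valueRange,
        modelScale = first@modelScale)
  else avg
}

#' @rdname SRResult-class
#' @param x an \code{SRResult}.
#' @export
resultImage <- function(x) { stopifnot(is(x, "SRResult")); x@image }

#' @rdname SRResult-class
#' @export
isAccepted <- function(x) { stopifnot(is(x, "SRResult")); x@accepted }

#' @rdname SRResult-class
#' @export
enlHistory <- function(x) { stopifnot(is(x, "SRResult")); x@enlHistory }

#' Gated sampling for a batch of inputs
#'
#' Equivalent to calling \code{\link{gatedSample}} per image, but chains
#' for all still-active images advance in lock-step so the denoiser
#' forward pass is batched; substantially faster for cohorts.
#'
#' @inheritParams gatedSample
#' @param lrs list of low-resolution \code{ImageGrid}s of equal shape.
#' @return List of \code{\linkS4class{SRResult}}s, one per input.
#' @export
gatedSampleMany <- function(denoiser, lrs, schedule, rng, maxAttempts = 10L,
                            targetShape = NULL, patchSize = 7L, stride = 3L,
                            estimateOn = c("upsampled", "native")) {
  estimateOn <- match.arg(estimateOn)
  lrs <- lapply(lrs, asImageGrid)
  if (is.null(targetShape)) targetShape <- 2L * dim(lrs[[1L]])
  rng <- asRNG(rng)
  seed <- rng$seed
  n <- length(lrs)
  sigmaX <- vapply(lrs, function(lr) {
    xref <- if (estimateOn == "upsampled") upsampleCondition(lr, targetShape)
            else lr
    estimateNoise(xref, patchSize = patchSize, stride = stride)@sigma
  }, numeric(1))
  done <- logical(n)
  res <- vector("list", n)
  enls <- replicate(n, numeric(0), simplify = FALSE)
  best <- vector("list", n); bestEnl <- rep(Inf, n)
  for (attempt in seq_len(maxAttempts)) {
    act <- which(!done)
    if (length(act) == 0L) break
    ys <- sampleChains(denoiser, lrs[act], schedule, rng, targetShape)
    for (j in seq_along(act)) {
      i <- act[j]
      cand <- toStorageScale(new("ImageGrid", pixels = ys[[j]],
                                 valueRange = lrs[[i]]@valueRange,
                                 modelScale = TRUE))
      enl <- estimateNoise(cand, patchSize = patchSize,
                           stride = stride)@sigma
      enls[[i]] <- c(enls[[i]], enl)
      if (enl < bestEnl[i]) { best[[i]] <- cand; bestEnl[i] <- enl }
      if (enl <= sigmaX[i]) {
        done[i] <- TRUE
        res[[i]] <- new("SRResult", image = cand, attempts = attempt,
                        enlHistory = enls[[i]], sigmaX = sigmaX[i],
                        accepted = TRUE, seed = seed)
      }
    }
  }
  for (i in which(!done))
    res[[i]] <- new("SRResult", image = best[[i]],
                    attempts = as.integer(maxAttempts),
                    enlHistory = enls[[i]], sigmaX = sigmaX[i],
                    accepted = FALSE, seed = seed)
  res
}
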