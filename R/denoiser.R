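#' Configuration of the conditional U-Net denoiser
#'
#' The full-scale configuration mirrors common conditional-diffusion
#' super-resolution practice: 64 first-layer channels with depth
#' multipliers 1, 2, 4, 8, 16 over five resolution levels, and two input
#' channels (the bicubic-upsampled condition concatenated with the noisy
#' image). Desk-scale work uses far smaller settings, e.g.
#' \code{baseChannels = 16}, \code{depthMultipliers = c(1, 2, 4)} on
#' 32x32 images; the mathematics is scale-free.
#'
#' @param baseChannels channel width of the first resolution level.
#' @param depthMultipliers per-level channel multipliers; the image side
#'   must be divisible by \code{2^(length(depthMultipliers) - 1)}.
#' @param embDim dimension of the sinusoidal gamma embedding.
#' @param embHidden width of the embedding MLP hidden layer.
#' @param inputChannels number of input channels (2: condition + noisy).
#' @param condGap expected mean-square gap (model scale) between the
#'   upsampled condition and the clean target; shapes the analytic
#'   epsilon baseline the network corrects (see the methods vignette).
#' @return A validated config list.
#' @export
denoiserConfig <- function(baseChannels = 64L,
                           depthMultipliers = c(1L, 2L, 4L, 8L, 16L),
                           embDim = 16L, embHidden = 32L,
                           inputChannels = 2L, condGap = 0) {
  if (length(depthMultipliers) < 1L || any(depthMultipliers < 1))
    stop("depthMultipliers must be a non-empty positive integer sequence")
  if (embDim %% 2L != 0L) stop("embDim must be even")
  list(baseChannels = as.integer(baseChannels),
       depthMultipliers = as.integer(depthMultipliers),
       embDim = as.integer(embDim), embHidden = as.integer(embHidden),
       inputChannels = as.integer(inputChannels),
       condGap = as.numeric(condGap))
}

#' Build an initialized conditional denoiser
#'
#' @param config from \code{\link{denoiserConfig}}.
#' @param seed integer; parameter initialization is reproducible from it.
#' @return A \code{\linkS4class{UNetDenoiser}}.
#' @export
buildDenoiser <- function(config = denoiserConfig(), seed = 1L) {
  if (is.null(config$condGap)) config$condGap <- 0
  rng <- rngSource(seed)
  P <- withRNG(rng, unetInitParams(config))
  st <- new.env(parent = emptyenv())
  st$P <- P
  st$Pflat <- flattenParams(P)
  st$opt <- list(step = 0L,
                 m = lapply(st$Pflat, function(x) x * 0),
                 v = lapply(st$Pflat, function(x) x * 0))
  st$geoms <- list()
  new("UNetDenoiser", config = config, state = st, seed = as.integer(seed))
}

# Geometry cache keyed by input size and batch size.
getGeom <- function(den, H, W, B) {
  key <- sprintf("%dx%dx%d", H, W, B)
  gm <- den@state$geoms[[key]]
  if (is.null(gm)) {
    gm <- unetGeometry(H, W, B, length(den@config$depthMultipliers))
    den@state$geoms[[key]] <- gm
  }
  gm
}

# Batched prediction: xups/yts are lists of HxW matrices (model scale),
# gamma a vector of per-image cumulative signal fractions.
predictBatch <- function(den, xups, yts, gamma, withCache = FALSE) {
  B <- length(yts)
  H <- nrow(yts[[1L]]); W <- ncol(yts[[1L]])
  gm <- getGeom(den, H, W, B)
  X <- cbind(unlist(xups, use.names = FALSE),
             unlist(yts, use.names = FALSE))
  fw <- unetForward(den@state$P, X, gamma, gm, den@config)
  if (!all(is.finite(fw$out))) stop("denoiser produced non-finite output")
  eps <- lapply(seq_len(B), function(b)
    matrix(fw$out[(b - 1L) * H * W + seq_len(H * W), 1L], H, W))
  if (withCache) list(eps = eps, fw = fw, gm = gm, X = X) else eps
}

#' @describeIn predictNoise trained U-Net denoiser; deterministic given
#'   the parameters.
#' @export
setMethod("predictNoise", "UNetDenoiser", function(denoiser, xup, yt,
                                                   gamma, ...) {
  predictBatch(denoiser, list(modelPx(xup, "xup")), list(modelPx(yt, "yt")),
               gamma)[[1L]]
})

#' @describeIn predictNoise plain function \code{f(xup, yt, gamma)},
#'   used for stubs and oracles in tests.
#' @export
setMethod("predictNoise", "function", function(denoiser, xup, yt,
                                               gamma, ...) {
  denoiser(px(xup), px(yt), gamma)
})

# Draw (t, gamma, eps, yt) for each batch element and stack labels.
noiseBatch <- function(y0s, schedule, rng) {
  B <- length(y0s)
  T <- length(schedule@alpha)
  ts <- withRNG(rng, sample.int(T, B, replace = TRUE))
  eps <- withRNG(rng, lapply(y0s, function(m)
    matrix(stats::rnorm(length(m)), nrow(m), ncol(m))))
  g <- schedule@gamma[ts]
  yts <- lapply(seq_len(B), function(b)
    sqrt(1 - g[b]) * eps[[b]] + sqrt(g[b]) * y0s[[b]])
  list(t = ts, gamma = g, eps = eps, yts = yts)
}

#' One stochastic training step of the denoising objective
#'
#' Draws a timestep uniformly per batch element, forms \eqn{y_t} through
#' the forward marginal, and evaluates the epsilon-prediction objective
#' \eqn{\|f_\theta(x, y_t, \gamma_t) - \varepsilon\|_2^2} averaged over
#' pixels and batch (the unbiased stochastic version of the sum over all
#' timesteps). For a trainable \code{\linkS4class{UNetDenoiser}} one Adam
#' update with global-norm gradient clipping is applied in place; for a
#' plain-function stub only the loss is computed.
#'
#' @param denoiser a \code{UNetDenoiser} or a stub function.
#' @param batch \code{list(xup = , y0 = )}: lists of aligned HxW matrices
#'   on the model scale (the condition already upsampled to the HR grid).
#' @param schedule a \code{\linkS4class{NoiseSchedule}}.
#' @param rng an \code{\link{rngSource}} (or integer seed).
#' @param lr Adam learning rate (default 1e-4); \code{lr = 0} leaves the
#'   parameters unchanged.
#' @param clip global gradient-norm clip (default 1).
#' @param eps optional list of forced noise fields (deterministic
#'   variant for oracles); implies \code{t} must also be given.
#' @param t optional vector of forced timesteps.
#' @return \code{list(loss, t, gradNorm, step)}.
#' @export
trainingStep <- function(denoiser, batch, schedule, rng = NULL, lr = 1e-4,
                         clip = 1.0, eps = NULL, t = NULL) {
  xups <- lapply(batch$xup, px)
  y0s <- lapply(batch$y0, px)
  stopifnot(length(xups) == length(y0s), length(y0s) >= 1L)
  if (is.null(eps)) {
    nb <- noiseBatch(y0s, schedule, asRNG(rng))
  } else {
    stopifnot(!is.null(t), length(eps) == length(y0s))
    g <- schedule@gamma[t]
    nb <- list(t = t, gamma = g, eps = lapply(eps, px),
               yts = lapply(seq_along(y0s), function(b)
                 sqrt(1 - g[b]) * px(eps[[b]]) + sqrt(g[b]) * y0s[[b]]))
  }
  epsLabel <- unlist(nb$eps, use.names = FALSE)
  if (is.function(denoiser)) {
    pred <- lapply(seq_along(y0s), function(b)
      denoiser(xups[[b]], nb$yts[[b]], nb$gamma[b]))
    loss <- mean((unlist(pred, use.names = FALSE) - epsLabel)^2)
    return(list(loss = loss, t = nb$t, gradNorm = NA_real_, step = NA_integer_))
  }
  pb <- predictBatch(denoiser, xups, nb$yts, nb$gamma, withCache = TRUE)
  resid <- pb$fw$out[, 1L] - epsLabel
  loss <- mean(resid^2)
  if (!is.finite(loss))
    stop(sprintf("non-finite loss at step %d (t drawn: %s; |y0| max %g)",
                 denoiser@state$opt$step + 1L,
                 paste(nb$t, collapse = ","),
                 max(abs(unlist(y0s)))))
  gn <- NA_real_
  if (lr > 0) {
    dOut <- matrix(2 * resid / length(resid), ncol = 1L)
    G <- unetBackward(denoiser@state$P, dOut, pb$fw$cache, pb$gm,
                      denoiser@config)
    gn <- adamUpdate(denoiser@state, flattenParams(G), lr = lr, clip = clip)
  }
  list(loss = loss, t = nb$t, gradNorm = gn, step = denoiser@state$opt$step)
}

# Convert a makeDataset()-style pair into model-scale (xup, y0) matrices.
preparePair <- function(pair, targetShape = NULL) {
  if (!is.null(pair$xup) && !is.null(pair$y0))
    return(list(xup = px(pair$xup), y0 = px(pair$y0)))
  hr <- pair$hr; lr <- pair$lr
  shape <- if (is.null(targetShape)) dim(px(hr)) else targetShape
  xup <- toModelScale(upsampleCondition(lr, shape))
  list(xup = px(xup), y0 = px(toModelScale(hr)))
}

#' Train the conditional denoiser
#'
#' Loops \code{\link{trainingStep}} over shuffled mini-batches. The
#' dataset may contain either raw pairs (\code{hr}, \code{lr}; conditions
#' are bicubic-upsampled to the HR grid and mapped to the model scale
#' internally) or prepared pairs (\code{xup}, \code{y0} matrices already
#' on the model scale).
#'
#' @param denoiser an initialized \code{\linkS4class{UNetDenoiser}}
#'   (updated in place and returned).
#' @param dataset non-empty list of pairs.
#' @param schedule a \code{\linkS4class{NoiseSchedule}}.
#' @param epochs number of passes over the dataset.
#' @param batchSize mini-batch size.
#' @param lr,clip optimizer settings (see \code{\link{trainingStep}}).
#' @param rng an \code{\link{rngSource}} or integer seed; the full run is
#'   reproducible from it.
#' @param checkpointPath optional file; the denoiser is serialized there
#'   every \code{checkpointEvery} epochs and at the end.
#' @param checkpointEvery interval in epochs.
#' @param verbose print per-epoch mean loss.
#' @return \code{list(denoiser, log)} where \code{log} is a data.frame
#'   with per-epoch mean training loss.
#' @export
trainDenoiser <- function(denoiser, dataset, schedule, epochs = 10L,
                          batchSize = 8L, lr = 1e-4, clip = 1.0, rng = 1L,
                          checkpointPath = NULL, checkpointEvery = Inf,
                          verbose = FALSE) {
  if (length(dataset) == 0L) stop("empty dataset")
  rng <- asRNG(rng)
  pairs <- lapply(dataset, preparePair)
  shp <- dim(pairs[[1L]]$y0)
  ok <- vapply(pairs, function(p)
    all(dim(p$y0) == shp) && all(dim(p$xup) == shp), logical(1))
  if (!all(ok)) stop("inconsistent image shapes across the dataset")
  n <- length(pairs)
  log <- data.frame(epoch = integer(0), meanLoss = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- withRNG(rng, sample.int(n))
    losses <- c()
    for (start in seq(1L, n, by = batchSize)) {
      sel <- ord[start:min(start + batchSize - 1L, n)]
      batch <- list(xup = lapply(pairs[sel], `[[`, "xup"),
                    y0 = lapply(pairs[sel], `[[`, "y0"))
      st <- trainingStep(denoiser, batch, schedule, rng, lr = lr,
                         clip = clip)
      losses <- c(losses, st$loss)
    }
    log <- rbind(log, data.frame(epoch = ep, meanLoss = mean(losses)))
    if (verbose)
      message(sprintf("epoch %d/%d: mean loss %.5f", ep, epochs,
                      mean(losses)))
    if (!is.null(checkpointPath) &&
        (ep %% checkpointEvery == 0L || ep == epochs))
      writeCheckpoint(denoiser, checkpointPath, schedule = schedule)
  }
  list(denoiser = denoiser, log = log)
}

#' Serialize / restore a denoiser checkpoint
#'
#' The checkpoint carries the parameters, the configuration, the schedule
#' specification and the initialization seed, so sampling from a restored
#' checkpoint is bit-for-bit reproducible.
#'
#' @param denoiser a \code{\linkS4class{UNetDenoiser}}.
#' @param path file path (RDS).
#' @param schedule optional \code{NoiseSchedule} stored alongside.
#' @return \code{readCheckpoint} returns \code{list(denoiser, schedule)}.
#' @export
writeCheckpoint <- function(denoiser, path, schedule = NULL) {
  obj <- list(config = denoiser@config, P = denoiser@state$P,
              opt = denoiser@state$opt, seed = denoiser@seed,
              schedule = if (!is.null(schedule))
                list(kind = schedule@kind, T = length(schedule@alpha),
                     params = schedule@params))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  obj <- readRDS(path)
  den <- buildDenoiser(obj$config, seed = obj$seed)
  den@state$P <- obj$P
  den@state$Pflat <- flattenParams(obj$P)
  den@state$opt <- obj$opt
  sch <- NULL
  if (!is.null(obj$schedule)) {
    ss <- obj$schedule
    sch <- do.call(buildSchedule,
                   c(list(T = ss$T, kind = ss$kind), ss$params))
  }
  list(denoiser = den, schedule = sch)
}
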