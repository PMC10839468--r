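#' Generate an anatomy-like phantom image
#'
#' Produces a piecewise-smooth 2-D phantom standing in for an anatomical
#' slice: overlapping ellipses at tissue-like intensity plateaus on a dark
#' background, boundary smoothing, a low-frequency intra-structure
#' texture, and optional additive i.i.d. Gaussian noise. Phantoms are
#' statistical stand-ins for MR slices, not physics simulations: they
#' reproduce the features the framework exercises (sharp boundaries,
#' smooth plateaus, known noise), nothing scanner-specific.
#'
#' @param shape integer (height, width), default \code{c(256, 256)}.
#' @param nStructures number of ellipse structures (default 6).
#' @param intensityLevels tissue-like intensity plateaus to draw from
#'   (storage units, default \code{c(60, 100, 140, 180, 220)}).
#' @param edgeSharpness Gaussian blur sigma (pixels) applied at structure
#'   boundaries; default 1.5.
#' @param textureAmp amplitude (storage units) of the smooth
#'   intra-structure texture; default 6.
#' @param noiseStd optional additive Gaussian noise standard deviation in
#'   storage units (default 0 = noiseless). Noise is added after the
#'   composition is clipped into the storage range, and is not re-clipped,
#'   so the injected standard deviation is exact.
#' @param background background intensity (default 25).
#' @param rng an \code{\link{rngSource}} or integer seed.
#' @return An \code{\linkS4class{ImageGrid}} on the storage scale
#'   \code{c(0, 255)}.
#' @examples
#' ph <- makePhantom(shape = c(64, 64), rng = 1)
#' @export
makePhantom <- function(shape = c(256L, 256L), nStructures = 6L,
                        intensityLevels = c(60, 100, 140, 180, 220),
                        edgeSharpness = 1.5, textureAmp = 6,
                        noiseStd = 0, background = 25, rng = 1L) {
  if (length(shape) != 2L || any(shape < 4))
    stop("degenerate phantom shape")
  rng <- asRNG(rng)
  H <- shape[1L]; W <- shape[2L]
  m <- matrix(background, H, W)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  if (nStructures > 0) {
    draws <- withRNG(rng, list(
      cy  = stats::runif(nStructures, 0.18, 0.82) * H,
      cx  = stats::runif(nStructures, 0.18, 0.82) * W,
      ry  = stats::runif(nStructures, 0.10, 0.32) * min(H, W),
      rx  = stats::runif(nStructures, 0.10, 0.32) * min(H, W),
      ang = stats::runif(nStructures, 0, pi),
      lev = sample(intensityLevels, nStructures, replace = TRUE)))
    for (i in seq_len(nStructures)) {
      ca <- cos(draws$ang[i]); sa <- sin(draws$ang[i])
      u <- (yy - draws$cy[i]) * ca + (xx - draws$cx[i]) * sa
      v <- -(yy - draws$cy[i]) * sa + (xx - draws$cx[i]) * ca
      inside <- (u / draws$ry[i])^2 + (v / draws$rx[i])^2 <= 1
      m[inside] <- draws$lev[i]
    }
  }
  if (edgeSharpness > 0) m <- gaussianBlur(m, edgeSharpness)
  if (textureAmp > 0 && nStructures > 0) {
    coarse <- c(max(2L, ceiling(H / 8)), max(2L, ceiling(W / 8)))
    field <- withRNG(rng, matrix(stats::rnorm(prod(coarse)),
                                 coarse[1L], coarse[2L]))
    tex <- resampleImage(field, c(H, W), kernel = "bicubic",
                         antialias = FALSE)
    m <- m + textureAmp * tex
  }
  m <- pmin(pmax(m, 0), 255)
  if (noiseStd > 0)
    m <- m + withRNG(rng, matrix(stats::rnorm(H * W, sd = noiseStd), H, W))
  ImageGrid(m, valueRange = c(0, 255))
}

#' Generate a paired high/low-resolution phantom dataset
#'
#' Builds \code{nTrain + nTest} phantoms from per-image seeds derived from
#' one master random source, degrades each to the low-resolution geometry,
#' and performs a disjoint random train/test split. When \code{outDir} is
#' given, HR and LR images are written as PNG files along with a
#' \code{manifest.csv}; the in-memory pairs are returned either way.
#'
#' @param nTrain,nTest number of training and test pairs (each >= 1).
#' @param shape high-resolution phantom shape, default \code{c(256, 256)}.
#' @param lrShape low-resolution target shape, default \code{c(86, 128)}.
#' @param phantomArgs list of extra arguments passed to
#'   \code{\link{makePhantom}} (e.g. \code{noiseStd}).
#' @param degradeMethod kernel passed to \code{\link{degradeImage}}.
#' @param rng an \code{\link{rngSource}} or integer master seed; the whole
#'   dataset is reproducible from it.
#' @param outDir optional output directory for PNG pairs and manifest.
#' @return \code{list(train = , test = , manifest = data.frame)}; each
#'   element of \code{train}/\code{test} is \code{list(id, hr, lr, seed)}.
#' @export
makeDataset <- function(nTrain, nTest, shape = c(256L, 256L),
                        lrShape = c(86L, 128L), phantomArgs = list(),
                        degradeMethod = "bicubic", rng = 1L,
                        outDir = NULL) {
  if (nTrain < 1 || nTest < 1) stop("nTrain and nTest must be >= 1")
  rng <- asRNG(rng)
  n <- nTrain + nTest
  seeds <- withRNG(rng, sample.int(.Machine$integer.max - 1L, n))
  ids <- sprintf("phantom-%04d", seq_len(n))
  testIdx <- sort(withRNG(rng, sample.int(n, nTest)))
  make1 <- function(i) {
    hr <- do.call(makePhantom,
                  c(list(shape = shape, rng = seeds[i]), phantomArgs))
    lr <- degradeImage(hr, lrShape, method = degradeMethod)
    list(id = ids[i], hr = hr, lr = lr, seed = seeds[i])
  }
  pairs <- lapply(seq_len(n), make1)
  split <- ifelse(seq_len(n) %in% testIdx, "test", "train")
  manifest <- data.frame(id = ids, seed = seeds, split = split,
                         hrHeight = shape[1L], hrWidth = shape[2L],
                         lrHeight = lrShape[1L], lrWidth = lrShape[2L],
                         stringsAsFactors = FALSE)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (p in pairs) {
      writeImageGrid(p$hr, file.path(outDir, paste0(p$id, "_hr.png")))
      writeImageGrid(p$lr, file.path(outDir, paste0(p$id, "_lr.png")))
    }
    utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(train = pairs[split == "train"], test = pairs[split == "test"],
       manifest = manifest)
}
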