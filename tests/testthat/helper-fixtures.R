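# Shared builders for desk-scale fixtures and denoiser stubs.

# Tiny U-Net configuration used across tests.
tinyConfig <- function(base = 8L, mult = c(1L, 2L)) {
  denoiserConfig(baseChannels = base, depthMultipliers = mult,
                 embDim = 8L, embHidden = 16L)
}

# Desk-scale training profile shared by the end-to-end checks: 32x32
# phantoms degraded to 11x16 (the pixel-count ratio of the full-scale
# 256x256 -> 86x128 geometry), T = 100 slow-start schedule.
deskSchedule <- function() buildSchedule(100L, betaStart = 0.02,
                                         betaEnd = 0.15)

deskDataset <- function(nTrain, nTest, rng = 11L)
  makeDataset(nTrain, nTest, shape = c(32L, 32L), lrShape = c(11L, 16L),
              phantomArgs = list(edgeSharpness = 1.0, textureAmp = 4),
              rng = rng)

# A stub sampler factory: returns a sampler emitting predetermined
# images in sequence (cycling), ignoring the denoiser and schedule.
stubSampler <- function(images) {
  i <- 0L
  function(denoiser, lr, schedule, rng, targetShape = NULL) {
    i <<- i %% length(images) + 1L
    images[[i]]
  }
}

# Clean phantom plus i.i.d. noise of a chosen sd, as an ImageGrid.
noisyImage <- function(clean, sd, seed) {
  m <- px_(clean)
  ImageGrid(m + withRNG(rngSource(seed),
                        matrix(stats::rnorm(length(m), sd = sd),
                               nrow(m), ncol(m))))
}

px_ <- function(img) if (is(img, "ImageGrid")) pixels(img) else img
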