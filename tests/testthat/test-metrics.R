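test_that("MAE matches closed forms and a brute-force loop", {
  expect_equal(imageMAE(matrix(1:4, 2), matrix(1:4, 2)), 0)
  expect_equal(imageMAE(matrix(c(0, 2), 1), matrix(c(1, 3), 1)), 1)
  set.seed(3)
  a <- matrix(rnorm(30), 5, 6); b <- matrix(rnorm(30), 5, 6)
  acc <- 0
  for (i in 1:5) for (j in 1:6) acc <- acc + abs(a[i, j] - b[i, j])
  expect_equal(imageMAE(a, b), acc / 30, tolerance = 1e-12)
  expect_error(imageMAE(a, matrix(0, 2, 2)), "mismatch")
})

test_that("PSNR matches its closed form and is scale invariant", {
  ref <- matrix(0, 10, 10); test <- matrix(5, 10, 10)   # MSE 25
  expect_equal(imagePSNR(ref, test, peak = 255), 10 * log10(255^2 / 25),
               tolerance = 1e-12)
  expect_equal(imagePSNR(matrix(0, 4, 4), matrix(255, 4, 4)), 0)
  expect_identical(imagePSNR(ref, ref), Inf)
  set.seed(4)
  a <- matrix(runif(64, 0, 255), 8, 8); b <- a + rnorm(64, sd = 3)
  expect_equal(imagePSNR(a, b, peak = 255),
               imagePSNR(a / 2, b / 2, peak = 127.5), tolerance = 1e-10)
})

test_that("MS-SSIM is 1 on identity, collapses on inversion, and degrades
           with noise", {
  ph <- makePhantom(c(176L, 176L), rng = 5)
  expect_equal(imageMSSIM(ph, ph), 1, tolerance = 1e-12)
  expect_lt(imageMSSIM(ph, ImageGrid(255 - pixels(ph))), 0.2)
  set.seed(6)
  vals <- sapply(c(0, 10, 30), function(sd0)
    imageMSSIM(ph, ImageGrid(pixels(ph) +
                               matrix(rnorm(176^2, sd = sd0), 176, 176))))
  expect_true(all(diff(vals) < 0))
  expect_error(imageMSSIM(matrix(0, 32, 32), matrix(0, 32, 32)),
               "levels")
  expect_equal(imageMSSIM(matrix(5, 32, 32), matrix(5, 32, 32),
                          levels = 2), 1)
})

test_that("NQM is capped on identity and monotone in degradation", {
  ph <- makePhantom(c(64L, 64L), rng = 7)
  expect_identical(imageNQM(ph, ph), Inf)
  n5 <- noisyImage(ph, 5, 21); n20 <- noisyImage(ph, 20, 22)
  expect_gt(imageNQM(ph, n5), imageNQM(ph, n20))
  # documented argument order: the metric is not symmetric
  expect_false(isTRUE(all.equal(imageNQM(ph, n20), imageNQM(n20, ph))))
})

test_that("NQM reproduces the frozen reference values on fixture pairs", {
  # regression values computed once with an independently written
  # implementation of the same degradation model (numpy port)
  frozen <- c(36.767301, 27.866598, 20.593018, 14.269347, 10.804781)
  sds <- c(2, 5, 10, 20, 40)
  for (k in 1:5) {
    ref <- makePhantom(c(64L, 64L), edgeSharpness = 1.2, textureAmp = 5,
                       rng = 100 + k)
    noise <- withRNG(rngSource(200 + k),
                     matrix(rnorm(64 * 64, sd = sds[k]), 64, 64))
    expect_equal(imageNQM(ref, ImageGrid(pixels(ref) + noise)), frozen[k],
                 tolerance = 0.1 / frozen[k])
  }
})

test_that("enhancement percentages follow the declared direction", {
  expect_equal(enhancementPct(20, 15, "lower-better"), 25)
  expect_equal(enhancementPct(10, 11, "higher-better"), 10)
  expect_equal(enhancementPct(10, 10, "higher-better"), 0)
  expect_error(enhancementPct(0, 5, "higher-better"), "zero")
})

test_that("paired comparison matches the exact signed-rank distribution", {
  expect_equal(pairedCompare(1:10, 1:10), 1)
  a <- rnorm(20); expect_lt(pairedCompare(a, a + 10), 0.01)
  expect_error(pairedCompare(1:4, 2:5), "at least 5")
  expect_error(pairedCompare(1:6, 1:5), "mismatch")
  # enumeration oracle at n = 8: all 2^8 sign assignments of the ranks
  set.seed(11)
  x <- rnorm(8); y <- x + rnorm(8, mean = 0.4)
  d <- x - y
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
  Wall <- as.vector(signs %*% rk)
  pOracle <- min(1, 2 * min(mean(Wall <= W), mean(Wall >= W)))
  expect_equal(pairedCompare(x, y), pOracle, tolerance = 1e-10)
})

test_that("aggregate report rows are recomputable from per-image records", {
  set.seed(9)
  per <- expand.grid(id = sprintf("i%02d", 1:8),
                     method = c("bicubic", "ddpm"),
                     stringsAsFactors = FALSE)
  per$psnr <- rnorm(16, 25, 2)
  per$mae <- rnorm(16, 15, 2)
  rep <- summarizeMetrics(per, baseline = "bicubic")
  agg <- aggregateMetrics(rep)
  for (r in seq_len(nrow(agg))) {
    v <- per[per$method == agg$method[r], agg$metric[r]]
    expect_equal(agg$mean[r], mean(v), tolerance = 1e-10)
    expect_equal(agg$sd[r], sd(v), tolerance = 1e-10)
  }
  dd <- agg[agg$method == "ddpm", ]
  b <- agg[agg$method == "bicubic", ]
  expect_equal(dd$enhancementPct[dd$metric == "psnr"],
               100 * (dd$mean[dd$metric == "psnr"] -
                        b$mean[b$metric == "psnr"]) /
                 b$mean[b$metric == "psnr"], tolerance = 1e-10)
  # per-image mode averages the per-image percentages instead
  rep2 <- summarizeMetrics(per, baseline = "bicubic",
                           enhancementMode = "per-image")
  agg2 <- aggregateMetrics(rep2)
  pi <- per[order(per$method, per$id), ]
  bvals <- pi$mae[pi$method == "bicubic"]
  dvals <- pi$mae[pi$method == "ddpm"]
  expect_equal(agg2$enhancementPct[agg2$method == "ddpm" &
                                     agg2$metric == "mae"],
               mean(100 * (bvals - dvals) / bvals), tolerance = 1e-10)
})
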