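test_that("explicit schedules reproduce hand-computed cumulative products", {
  sch <- buildSchedule(3, kind = "explicit", alpha = c(0.9, 0.9, 0.9))
  expect_equal(gammas(sch), c(0.9, 0.81, 0.729), tolerance = 1e-12)
  one <- buildSchedule(1, kind = "explicit", alpha = 0.5)
  expect_equal(gammas(one), 0.5)
  expect_equal(DiffuseSR:::gammaAt(one, 0L), 1)
})

test_that("cumulative-product identity holds across families and sizes", {
  for (T in c(1L, 3L, 100L, 5000L)) {
    for (kind in c("linear-beta", "linear-gamma")) {
      sch <- buildSchedule(T, kind = kind)
      a <- alphas(sch)
      expect_true(all(a > 0 & a < 1))
      expect_lt(max(abs(gammas(sch) - cumprod(a))), 1e-12)
      expect_true(all(diff(c(1, gammas(sch))) < 0))
    }
  }
})

test_that("the default full-scale schedule decays to a tiny signal fraction", {
  sch <- buildSchedule(5000)
  g <- gammas(sch)
  expect_true(all(diff(g) < 0))
  expect_lt(g[5000], 1e-3)
})

test_that("schedule construction rejects invalid inputs by step", {
  expect_error(buildSchedule(0), "positive integer")
  expect_error(buildSchedule(2, kind = "explicit", alpha = c(0.5, 1.2)),
               "step 2")
  expect_error(buildSchedule(2, kind = "explicit", alpha = c(0.5)),
               "length")
})

test_that("forward samples follow the closed-form marginal", {
  sch <- buildSchedule(1, kind = "explicit", alpha = 0.25)  # gamma = 0.25
  y0 <- matrix(1, 4, 4)
  z <- forwardSample(y0, 1, sch, eps = matrix(0, 4, 4))
  expect_equal(z$yt, matrix(0.5, 4, 4))
  z1 <- forwardSample(y0, 1, sch, eps = matrix(1, 4, 4))
  expect_equal(z1$yt, matrix(sqrt(0.75) + 0.5, 4, 4), tolerance = 1e-12)
})

test_that("forward marginal moments match Monte-Carlo sampling", {
  sch <- buildSchedule(1, kind = "explicit", alpha = 0.5)   # gamma = 0.5
  y0 <- matrix(0, 100, 100)
  z <- forwardSample(y0, 1, sch, rng = rngSource(4))
  n <- length(z$yt)
  # mean se = sqrt(0.5/n); var se ~ sqrt(2/n) * 0.5
  expect_lt(abs(mean(z$yt)), 3 * sqrt(0.5 / n))
  expect_lt(abs(var(as.vector(z$yt)) - 0.5), 3 * sqrt(2 / n) * 0.5)
})

test_that("stepwise composition matches the one-shot marginal", {
  a <- c(0.8, 0.7)
  sch <- buildSchedule(2, kind = "explicit", alpha = a)
  rng <- rngSource(9)
  n <- 200 * 200
  y0 <- matrix(0.4, 200, 200)
  # two applications of the one-step kernel
  y1 <- withRNG(rng, sqrt(a[1]) * y0 +
                  sqrt(1 - a[1]) * matrix(rnorm(n), 200, 200))
  y2 <- withRNG(rng, sqrt(a[2]) * y1 +
                  sqrt(1 - a[2]) * matrix(rnorm(n), 200, 200))
  g2 <- gammas(sch)[2]
  expect_lt(abs(mean(y2) - sqrt(g2) * 0.4), 3 * sqrt((1 - g2) / n))
  expect_lt(abs(var(as.vector(y2)) - (1 - g2)),
            3 * sqrt(2 / n) * (1 - g2))
})

test_that("posterior degenerates to (y0, 0) at t = 1", {
  sch <- buildSchedule(3, kind = "explicit", alpha = c(0.9, 0.8, 0.7))
  y0 <- matrix(rnorm(16), 4, 4)
  yt <- matrix(rnorm(16), 4, 4)
  post <- posteriorParams(y0, yt, 1, sch)
  expect_identical(post$mu, y0)
  expect_identical(post$sigma2, 0)
})

test_that("posterior mean and variance match direct substitution", {
  sch <- buildSchedule(2, kind = "explicit", alpha = c(0.9, 0.9))
  y0 <- matrix(1, 3, 3); y2 <- matrix(0.9, 3, 3)
  post <- posteriorParams(y0, y2, 2, sch)
  expect_equal(post$mu, matrix(0.948683, 3, 3), tolerance = 1e-6)
  expect_equal(post$sigma2, 0.1 * 0.1 / 0.19, tolerance = 1e-12)
})

test_that("the posterior mean is an affine combination of its inputs", {
  sch <- buildSchedule(3, kind = "explicit", alpha = c(0.9, 0.8, 0.7))
  y0 <- matrix(rnorm(25), 5, 5); yt <- matrix(rnorm(25), 5, 5)
  for (t in 2:3) {
    p1 <- posteriorParams(y0, yt, t, sch)
    p2 <- posteriorParams(3 * y0, 3 * yt, t, sch)
    expect_equal(p2$mu, 3 * p1$mu, tolerance = 1e-12)
    expect_identical(p1$sigma2, p2$sigma2)
  }
})

test_that("timestep range errors are informative", {
  sch <- buildSchedule(2, kind = "explicit", alpha = c(0.9, 0.9))
  y <- matrix(0, 2, 2)
  expect_error(forwardSample(y, 3, sch, rng = 1), "out of range")
  expect_error(posteriorParams(y, matrix(0, 3, 3), 1, sch), "match")
})
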