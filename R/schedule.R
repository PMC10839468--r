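#' Build a diffusion noise schedule
#'
#' Constructs the per-step signal-retention coefficients \eqn{\alpha_t} and
#' cumulative products \eqn{\gamma_t = \prod_{i=1}^{t}\alpha_i} of the
#' forward Gaussian diffusion process. Three families are available:
#' \describe{
#'   \item{\code{"linear-beta"} (default)}{classic linear schedule on
#'     \eqn{\beta_t = 1 - \alpha_t} between \code{betaStart} and
#'     \code{betaEnd}. Its slow start (\eqn{\alpha_t \to 1} as
#'     \eqn{t \to 1}) keeps the constant reverse variance
#'     \eqn{1 - \alpha_t} close to the true posterior variance near the
#'     end of the reverse chain, which the ancestral sampler relies on.}
#'   \item{\code{"linear-gamma"}}{\eqn{\gamma_t} interpolated
#'     geometrically between \code{gammaStart} and \code{gammaEnd}, with
#'     \eqn{\alpha_t = \gamma_t / \gamma_{t-1}}. Useful for forward-process
#'     experiments; its large first \eqn{\alpha} gap makes the
#'     constant-variance reverse sampler over-inject noise near
#'     \eqn{t = 2}, so it is not the sampling default.}
#'   \item{\code{"explicit"}}{caller-supplied \code{alpha} vector.}
#' }
#'
#' @param T number of timesteps (positive integer). The full-scale default
#'   in this framework is 5000; any \code{T >= 1} is accepted for
#'   desk-scale runs.
#' @param kind schedule family, see Details.
#' @param gammaStart,gammaEnd endpoints of the geometric gamma
#'   interpolation (defaults \code{1 - 1e-4} and \code{5e-4}).
#' @param betaStart,betaEnd endpoints for \code{"linear-beta"}.
#' @param alpha explicit \eqn{\alpha} vector for \code{"explicit"}
#'   (must have length \code{T} and lie in (0, 1)).
#' @return A \code{\linkS4class{NoiseSchedule}}.
#' @examples
#' sch <- buildSchedule(3, kind = "explicit", alpha = c(0.9, 0.9, 0.9))
#' gammas(sch)   # 0.9 0.81 0.729
#' @export
buildSchedule <- function(T = 5000L,
                          kind = c("linear-beta", "linear-gamma", "explicit"),
                          gammaStart = 1 - 1e-4, gammaEnd = 5e-4,
                          betaStart = 1e-4, betaEnd = 2e-2,
                          alpha = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T < 1 ||
      T != round(T))
    stop("T must be a positive integer")
  T <- as.integer(T)
  params <- list()
  a <- switch(kind,
    "linear-gamma" = {
      if (!(gammaStart > 0 && gammaStart < 1) || !(gammaEnd > 0) ||
          gammaEnd >= gammaStart)
        stop("need 0 < gammaEnd < gammaStart < 1")
      params <- list(gammaStart = gammaStart, gammaEnd = gammaEnd)
      g <- if (T == 1L) gammaEnd else
        exp(seq(log(gammaStart), log(gammaEnd), length.out = T))
      g / c(1, g[-T])
    },
    "linear-beta" = {
      if (!(betaStart > 0 && betaEnd < 1) || betaEnd < betaStart)
        stop("need 0 < betaStart <= betaEnd < 1")
      params <- list(betaStart = betaStart, betaEnd = betaEnd)
      1 - seq(betaStart, betaEnd, length.out = T)
    },
    "explicit" = {
      if (is.null(alpha)) stop("kind = 'explicit' requires an alpha vector")
      if (length(alpha) != T)
        stop(sprintf("alpha has length %d but T = %d", length(alpha), T))
      params <- list(alpha = alpha)
      as.numeric(alpha)
    })
  bad <- which(!(a > 0 & a < 1))
  if (length(bad))
    stop(sprintf("schedule construction produced alpha = %g outside (0,1) at step %d",
                 a[bad[1L]], bad[1L]))
  new("NoiseSchedule", alpha = a, gamma = cumprod(a), kind = kind,
      params = params)
}

#' @rdname NoiseSchedule-class
#' @export
setMethod("alphas", "NoiseSchedule", function(x) x@alpha)

#' @rdname NoiseSchedule-class
#' @export
setMethod("gammas", "NoiseSchedule", function(x) x@gamma)

#' @rdname NoiseSchedule-class
#' @export
setMethod("numSteps", "NoiseSchedule", function(x) length(x@alpha))

# gamma_t with the gamma_0 = 1 boundary convention.
gammaAt <- function(schedule, t) {
  if (t == 0L) 1 else schedule@gamma[t]
}

checkStep <- function(schedule, t) {
  T <- length(schedule@alpha)
  if (!is.numeric(t) || length(t) != 1L || t != round(t) || t < 1 || t > T)
    stop(sprintf("timestep t = %s out of range 1..%d", format(t), T))
  as.integer(t)
}

#' Sample the forward diffusion marginal
#'
#' Draws \eqn{y_t = \sqrt{1-\gamma_t}\,\varepsilon + \sqrt{\gamma_t}\,y_0}
#' with \eqn{\varepsilon \sim N(0, I)}, the closed-form marginal of the
#' stepwise Gaussian noising chain. The drawn \eqn{\varepsilon} is returned
#' alongside because it is the training label for the
#' \eqn{\varepsilon}-predicting denoiser.
#'
#' @param y0 clean image on the model scale (\code{ImageGrid} with
#'   \code{modelScale = TRUE}, or a bare matrix taken as model scale).
#' @param t timestep, \code{1 <= t <= numSteps(schedule)}.
#' @param schedule a \code{\linkS4class{NoiseSchedule}}.
#' @param rng an \code{\link{rngSource}} (or integer seed).
#' @param eps optional matrix: force the noise field instead of drawing it
#'   (deterministic variant used in tests and stubs).
#' @return \code{list(yt = matrix, eps = matrix)} on the model scale.
#' @export
forwardSample <- function(y0, t, schedule, rng = NULL, eps = NULL) {
  y0m <- modelPx(y0, "y0")
  t <- checkStep(schedule, t)
  g <- schedule@gamma[t]
  if (is.null(eps)) {
    if (is.null(rng)) stop("either rng or eps must be supplied")
    rng <- asRNG(rng)
    eps <- withRNG(rng, matrix(stats::rnorm(length(y0m)), nrow(y0m), ncol(y0m)))
  } else {
    eps <- px(eps)
    if (!all(dim(eps) == dim(y0m))) stop("eps shape must match y0")
  }
  list(yt = sqrt(1 - g) * eps + sqrt(g) * y0m, eps = eps)
}

#' Closed-form posterior of the forward process
#'
#' Mean and variance of \eqn{q(y_{t-1} \mid y_0, y_t)}:
#' \deqn{\mu = (1-\gamma_t)^{-1}\left[\sqrt{\gamma_{t-1}}(1-\alpha_t)y_0 +
#'   \sqrt{\alpha_t}(1-\gamma_{t-1})y_t\right]}
#' \deqn{\sigma^2 = (1-\gamma_t)^{-1}(1-\gamma_{t-1})(1-\alpha_t)}
#' with the convention \eqn{\gamma_0 = 1}, so that at \eqn{t = 1} the
#' posterior degenerates to \eqn{(y_0, 0)} exactly.
#'
#' @param y0,yt images of identical shape (model scale).
#' @param t timestep.
#' @param schedule a \code{\linkS4class{NoiseSchedule}}.
#' @return \code{list(mu = matrix, sigma2 = scalar)}.
#' @export
posteriorParams <- function(y0, yt, t, schedule) {
  y0m <- px(y0); ytm <- px(yt)
  if (!all(dim(y0m) == dim(ytm))) stop("y0 and yt shapes must match")
  t <- checkStep(schedule, t)
  a  <- schedule@alpha[t]
  g  <- schedule@gamma[t]
  gp <- gammaAt(schedule, t - 1L)
  if (t == 1L) return(list(mu = y0m, sigma2 = 0))
  mu <- (sqrt(gp) * (1 - a) * y0m + sqrt(a) * (1 - gp) * ytm) / (1 - g)
  list(mu = mu, sigma2 = (1 - gp) * (1 - a) / (1 - g))
}
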