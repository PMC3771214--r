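#' @include AllClasses.R
NULL

#' Default weakly informative priors
#'
#' @param VVariance prior variance of mean image values, s^2 (default 0.01,
#'   i.e. a 100 ms s.d., far wider than observed image values).
#' @param sigmaBounds uniform bounds on the session-to-session value s.d.,
#'   seconds.
#' @param logOmegaBounds uniform bounds on log overdispersion (logit units).
#' @param tauLocationBounds,tauScaleBounds,tauDfBounds uniform bounds on the
#'   location, scale, and degrees of freedom of the positively-truncated t
#'   prior on the session utility scale tau.
#' @param alphaVariance prior variance of time-trend slopes, s^2 per
#'   standardized-rank unit squared.
#' @return a [PriorConfig-class].
#' @export
priorConfig <- function(VVariance = 0.01,
                        sigmaBounds = c(1e-6, 1),
                        logOmegaBounds = c(-6, 2),
                        tauLocationBounds = c(0, 0.5),
                        tauScaleBounds = c(1e-4, 0.1),
                        tauDfBounds = c(0.1, 50),
                        alphaVariance = 0.01) {
  new("PriorConfig", VVariance = VVariance, sigmaBounds = sigmaBounds,
      logOmegaBounds = logOmegaBounds, tauLocationBounds = tauLocationBounds,
      tauScaleBounds = tauScaleBounds, tauDfBounds = tauDfBounds,
      alphaVariance = alphaVariance)
}

#' Positively-truncated location-scale t distribution
#'
#' Density (`dtplus`) and random draws (`rtplus`) for the t distribution
#' with location `location`, scale `scale`, and `df` degrees of freedom,
#' truncated and renormalized to the positive half-line. Used as the prior
#' for the session utility scale tau: heavier-tailed than a truncated
#' normal, approaching one as `df` grows.
#'
#' `rtplus` samples by rejection: location-scale t draws are taken until
#' positive, which is exact and efficient for non-negative locations
#' (acceptance probability >= 1/2).
#'
#' @param x quantiles (positive; density is 0 below the truncation point).
#' @param n number of draws.
#' @param location,scale,df t parameters; `scale > 0`, `df > 0`.
#' @param log if `TRUE` return the log density.
#' @return `dtplus`: (log) density values; `rtplus`: positive draws.
#' @export
dtplus <- function(x, location, scale, df, log = FALSE) {
  stopifnot(scale > 0, df > 0)
  # upper-tail mass above 0 of the untruncated distribution
  logZ <- stats::pt((0 - location) / scale, df, lower.tail = FALSE,
                    log.p = TRUE)
  ld <- stats::dt((x - location) / scale, df, log = TRUE) - log(scale) - logZ
  ld[x <= 0] <- -Inf
  if (log) ld else exp(ld)
}

#' @rdname dtplus
#' @export
rtplus <- function(n, location, scale, df) {
  stopifnot(scale > 0, df > 0)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    draw <- location + scale * stats::rt(2L * m, df)
    out <- c(out, draw[draw > 0])
  }
  out[seq_len(n)]
}
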