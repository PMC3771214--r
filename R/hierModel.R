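#' @include modelSpec.R choiceData.R
NULL

# Index structure tying a ModelSpec to a dataset: which subject/category
# groups exist, which (session, category-group) value cells exist, and how
# each block maps into them. Everything downstream (R densities, the JAGS
# code generator, reports) shares this one mapping.
.modelIndex <- function(spec, dataset) {
  b <- choiceBlocks(dataset)
  if (!nrow(b)) stop("dataset is empty")
  sess <- unique(b$session)
  subj <- unique(b$subject)
  subjOfSess <- sessionSubjects(dataset)[sess]

  gLevels <- if (spec@subjectPooling == "none") subj else "all"
  gOfSubject <- if (spec@subjectPooling == "none")
    stats::setNames(subj, subj) else stats::setNames(rep("all", length(subj)), subj)
  cats <- imageCategories()[imageCategories() %in% unique(b$category)]
  cgLevels <- if (spec@categoryPooling == "none") cats else "all"
  cgOfCat <- if (spec@categoryPooling == "none")
    stats::setNames(cats, cats) else stats::setNames(rep("all", length(cats)), cats)

  VMap <- NULL
  if (spec@sessionPooling != "none") {
    VMap <- expand.grid(catGroup = cgLevels, subjGroup = gLevels,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    VMap <- data.frame(k = seq_len(nrow(VMap)), subjGroup = VMap$subjGroup,
                       catGroup = VMap$catGroup, stringsAsFactors = FALSE)
  }
  kOf <- function(subjGroup, catGroup) {
    if (is.null(VMap)) return(rep(NA_integer_, length(subjGroup)))
    match(paste(subjGroup, catGroup), paste(VMap$subjGroup, VMap$catGroup))
  }

  vMap <- NULL
  if (spec@sessionPooling != "complete") {
    key <- paste(b$session, cgOfCat[b$category])
    first <- !duplicated(key)
    vMap <- data.frame(j = seq_len(sum(first)),
                       session = b$session[first],
                       catGroup = unname(cgOfCat[b$category[first]]),
                       stringsAsFactors = FALSE)
    vMap$subjGroup <- unname(gOfSubject[subjOfSess[vMap$session]])
    vMap$k <- kOf(vMap$subjGroup, vMap$catGroup)
    jOfBlock <- match(key, key[first])
  } else {
    jOfBlock <- rep(NA_integer_, nrow(b))
  }

  tcov <- if (spec@timeTrend) sessionTimeCovariate(dataset) else NULL

  list(blocks = b, B = nrow(b),
       sessions = sess, S = length(sess), subjOfSess = subjOfSess,
       subjects = subj,
       gLevels = gLevels, G = length(gLevels), gOfSubject = gOfSubject,
       cgLevels = cgLevels, cgOfCat = cgOfCat,
       VMap = VMap, K = if (is.null(VMap)) 0L else nrow(VMap),
       vMap = vMap, J = if (is.null(vMap)) 0L else nrow(vMap),
       sOfBlock = match(b$session, sess),
       gOfBlock = match(gOfSubject[b$subject], gLevels),
       kOfBlock = kOf(gOfSubject[b$subject], cgOfCat[b$category]),
       jOfBlock = jOfBlock,
       tcov = tcov)
}

.checkParams <- function(params, idx, spec) {
  need <- c("omega", "tau", "ell", "sca", "nu", "logitp")
  if (spec@sessionPooling != "none") need <- c(need, "V")
  if (spec@sessionPooling != "complete") need <- c(need, "v")
  if (spec@sessionPooling == "partial") need <- c(need, "sigma")
  if (spec@timeTrend) need <- c(need, "alpha")
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop("ParameterSet missing: ", paste(missing, collapse = ", "))
  lens <- c(V = idx$K, v = idx$J, sigma = idx$G, omega = idx$G,
            tau = idx$S, alpha = idx$K, logitp = idx$B)
  for (nm in intersect(names(lens), need)) {
    if (length(params[[nm]]) != lens[[nm]])
      stop(sprintf("parameter %s has length %d, expected %d", nm,
                   length(params[[nm]]), lens[[nm]]))
  }
  invisible(TRUE)
}

# prior mean of the session-value cells: V (+ alpha * t under a time trend),
# or 0 for the no-hierarchy variant
.cellMean <- function(params, idx, spec) {
  if (spec@sessionPooling == "none")
    return(rep(0, idx$J))
  mu <- params$V[idx$vMap$k]
  if (spec@timeTrend)
    mu <- mu + params$alpha[idx$vMap$k] * idx$tcov[idx$vMap$session]
  mu
}

#' Log prior density of a parameter set
#'
#' Sums the log densities of the stated priors: Normal on mean values V,
#' Uniform on sigma, Uniform on log(omega), positively-truncated t on each
#' session's tau with Uniform hyperpriors on its location/scale/df, Normal
#' on time-trend slopes, and the hierarchical Normal on session values v
#' (around V, or around 0 with the V prior's variance for the
#' no-session-pooling variant). The truncated-t term is normalized over the
#' positive half-line. Out-of-support values give `-Inf`. Overdispersion is
#' parameterized on the log scale (the density is with respect to
#' d log(omega)), matching the sampler's parameterization.
#'
#' The per-block latent choice probabilities (Eq.-4-style logit-normal
#' layer) belong to [logLikelihood()], not the prior.
#'
#' @param params named list (a ParameterSet): numeric vectors `V`, `v`,
#'   `sigma`, `omega`, `tau`, `ell`, `sca`, `nu`, `alpha`, `logitp`, as
#'   required by the spec (see [modelSpec()]).
#' @param spec a [ModelSpec-class].
#' @param dataset the [ChoiceDataset-class] the parameters refer to.
#' @return scalar log density.
#' @export
logPrior <- function(params, spec, dataset) {
  idx <- .modelIndex(spec, dataset)
  .checkParams(params, idx, spec)
  p <- spec@priors
  dunifLog <- function(x, b) {
    ifelse(x >= b[1] & x <= b[2], -log(b[2] - b[1]), -Inf)
  }
  lp <- 0
  if (spec@sessionPooling != "none")
    lp <- lp + sum(stats::dnorm(params$V, 0, sqrt(p@VVariance), log = TRUE))
  if (spec@sessionPooling == "partial")
    lp <- lp + sum(dunifLog(params$sigma, p@sigmaBounds))
  lp <- lp + sum(dunifLog(log(params$omega), p@logOmegaBounds))
  lp <- lp + dunifLog(params$ell, p@tauLocationBounds) +
    dunifLog(params$sca, p@tauScaleBounds) +
    dunifLog(params$nu, p@tauDfBounds)
  if (!is.finite(lp)) return(-Inf)
  if (any(params$tau < 1e-6)) return(-Inf)
  lp <- lp + sum(dtplus(params$tau, params$ell, params$sca, params$nu,
                        log = TRUE))
  if (spec@timeTrend)
    lp <- lp + sum(stats::dnorm(params$alpha, 0, sqrt(p@alphaVariance),
                                log = TRUE))
  if (spec@sessionPooling != "complete") {
    mu <- .cellMean(params, idx, spec)
    sdv <- if (spec@sessionPooling == "partial")
      params$sigma[match(idx$vMap$subjGroup, idx$gLevels)]
    else sqrt(p@VVariance)
    lp <- lp + sum(stats::dnorm(params$v, mu, sdv, log = TRUE))
  }
  lp
}

# utility eta per block for a parameter set
.blockEta <- function(params, idx, spec) {
  value <- if (spec@sessionPooling == "complete")
    params$V[idx$kOfBlock] else params$v[idx$jOfBlock]
  (idx$blocks$dv + value) / params$tau[idx$sOfBlock]
}

#' Log likelihood of a parameter set
#'
#' Sum over blocks of the logit-normal layer (Normal log density of the
#' latent `logit p` at the utility `eta = (dv + v) / tau`, s.d. omega) plus
#' the Binomial log pmf of the observed image-option count given
#' `p = plogis(logit p)`. Under complete session pooling the group mean
#' value stands in for `v`. Non-finite utilities (tau underflow) give
#' `-Inf`.
#'
#' @inheritParams logPrior
#' @return scalar log likelihood.
#' @export
logLikelihood <- function(params, spec, dataset) {
  idx <- .modelIndex(spec, dataset)
  .checkParams(params, idx, spec)
  eta <- .blockEta(params, idx, spec)
  if (!all(is.finite(eta))) {
    warning("non-finite utility eta (tau underflow?)")
    return(-Inf)
  }
  omega <- params$omega[idx$gOfBlock]
  sum(stats::dnorm(params$logitp, eta, omega, log = TRUE)) +
    sum(stats::dbinom(idx$blocks$n, idx$blocks$N,
                      stats::plogis(params$logitp), log = TRUE))
}

#' Deviance of a parameter set
#'
#' `-2` times the sum of the observation-level Binomial log pmf terms only,
#' conditional on each block's latent choice probability — the focus used
#' for DIC. Prior hyperparameters never enter.
#'
#' @inheritParams logPrior
#' @return scalar deviance.
#' @export
choiceDeviance <- function(params, spec, dataset) {
  idx <- .modelIndex(spec, dataset)
  if (length(params$logitp) != idx$B)
    stop(sprintf("logitp has length %d, expected %d", length(params$logitp),
                 idx$B))
  .devianceFromLogitp(params$logitp, idx$blocks$n, idx$blocks$N)
}

.devianceFromLogitp <- function(logitp, n, N) {
  -2 * sum(stats::dbinom(n, N, stats::plogis(logitp), log = TRUE))
}

#' Point of subjective equality
#'
#' The juice differential at which the two options are chosen equally
#' often: equal in magnitude and opposite in sign to the image value,
#' `dv* = -v`.
#'
#' @param v image value in seconds of juice access.
#' @param units `"s"` (default) or `"ms"` for the reported scale.
#' @return the indifference differential, same length as `v`.
#' @examples
#' indifferencePoint(0.025, units = "ms")  # -25 ms
#' @export
indifferencePoint <- function(v, units = c("s", "ms")) {
  units <- match.arg(units)
  stopifnot(all(is.finite(v)))
  out <- -v
  if (units == "ms") out <- out * 1000
  out
}
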