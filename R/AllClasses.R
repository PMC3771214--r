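#' @import methods
NULL

#' The four image categories
#'
#' Category levels used throughout the package: a non-social gray-square
#' control, female perinea, dominant-male faces, and subordinate-male faces.
#'
#' @export
imageCategories <- function() {
  c("control", "female", "dominant_male", "subordinate_male")
}

.checkBlocks <- function(blocks) {
  required <- c("subject", "session", "category", "dv", "n", "N")
  if (!is.data.frame(blocks) || !all(required %in% names(blocks)))
    return(sprintf("blocks must be a data.frame with columns %s",
                   paste(required, collapse = ", ")))
  msgs <- character()
  if (nrow(blocks)) {
    if (!all(blocks$category %in% imageCategories()))
      msgs <- c(msgs, "category outside the four-level set")
    if (!all(is.finite(blocks$dv)))
      msgs <- c(msgs, "dv must be finite")
    if (!all(blocks$N >= 1))
      msgs <- c(msgs, "N must be >= 1")
    if (!all(blocks$n >= 0 & blocks$n <= blocks$N))
      msgs <- c(msgs, "n must satisfy 0 <= n <= N")
    key <- paste(blocks$session, blocks$category, signif(blocks$dv, 12))
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate (session, category, dv) block")
  }
  if (length(msgs)) msgs else TRUE
}

#' ChoiceDataset: aggregated choice counts with session metadata
#'
#' One row of `blocks` is an aggregated observation: for a given subject,
#' session, and image category, `n` of `N` choices went to the image-plus-juice
#' option at juice differential `dv` (seconds of juice access; image-option
#' juice minus blank-option juice). `sessionDates` and `sessionSubjects` map
#' each session id to its calendar date and subject.
#'
#' @slot blocks data.frame with columns subject, session, category, dv (s),
#'   n, N.
#' @slot sessionDates named `Date` vector, one entry per session id.
#' @slot sessionSubjects named character vector, session id -> subject id.
#'
#' @export
setClass("ChoiceDataset",
  representation(blocks = "data.frame",
                 sessionDates = "Date",
                 sessionSubjects = "character"),
  validity = function(object) {
    msgs <- character()
    chk <- .checkBlocks(object@blocks)
    if (!isTRUE(chk)) msgs <- c(msgs, chk)
    sess <- unique(object@blocks$session)
    if (!all(sess %in% names(object@sessionDates)))
      msgs <- c(msgs, "every session in blocks needs a date")
    if (!all(sess %in% names(object@sessionSubjects)))
      msgs <- c(msgs, "every session in blocks needs a subject")
    if (nrow(object@blocks)) {
      mapped <- object@sessionSubjects[object@blocks$session]
      if (!all(mapped == object@blocks$subject))
        msgs <- c(msgs, "block subject disagrees with sessionSubjects map")
    }
    if (length(msgs)) msgs else TRUE
  })

#' StudyDesign: layout of a simulated study
#'
#' Describes the skeleton of a study: which subjects run how many sessions,
#' on which dates, with which juice-differential grid and how many choices
#' per block. All four image categories are presented in every session.
#'
#' @slot sessions character vector of session ids (all subjects, in order).
#' @slot sessionSubjects named character, session id -> subject id.
#' @slot sessionDates named `Date`, session id -> date.
#' @slot categories character, the four image categories.
#' @slot dvGrid named list, session id -> numeric vector of juice
#'   differentials in seconds (>= 1 value; real sessions can have as few
#'   as 3).
#' @slot nPerBlock integer, total choices per block.
#'
#' @export
setClass("StudyDesign",
  representation(sessions = "character",
                 sessionSubjects = "character",
                 sessionDates = "Date",
                 categories = "character",
                 dvGrid = "list",
                 nPerBlock = "integer"),
  validity = function(object) {
    msgs <- character()
    if (!length(object@sessions))
      msgs <- c(msgs, "need at least one session")
    if (!setequal(object@categories, imageCategories()))
      msgs <- c(msgs, "categories must be the four-level set")
    for (nm in c("sessionSubjects", "sessionDates", "dvGrid")) {
      if (!all(object@sessions %in% names(slot(object, nm))))
        msgs <- c(msgs, sprintf("%s must cover every session", nm))
    }
    if (any(lengths(object@dvGrid) < 1))
      msgs <- c(msgs, "dvGrid entries must be non-empty")
    if (length(object@nPerBlock) != 1 || object@nPerBlock < 1)
      msgs <- c(msgs, "nPerBlock must be a single count >= 1")
    if (length(msgs)) msgs else TRUE
  })

#' PriorConfig: hyperparameters of the weakly informative priors
#'
#' Mean image values V are Normal(0, `VVariance`) in squared seconds
#' (the default 0.01 s^2 is a 100 ms standard deviation); session-to-session
#' value s.d. sigma is Uniform over `sigmaBounds`; log overdispersion
#' log(omega) is Uniform over `logOmegaBounds`; the session utility scale tau
#' follows a positively-truncated t whose location, scale, and degrees of
#' freedom are themselves Uniform over the three `tau*Bounds`; time-trend
#' slopes alpha are Normal(0, `alphaVariance`).
#'
#' @export
setClass("PriorConfig",
  representation(VVariance = "numeric",
                 sigmaBounds = "numeric",
                 logOmegaBounds = "numeric",
                 tauLocationBounds = "numeric",
                 tauScaleBounds = "numeric",
                 tauDfBounds = "numeric",
                 alphaVariance = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (object@VVariance <= 0 || object@alphaVariance <= 0)
      msgs <- c(msgs, "variances must be positive")
    for (nm in c("sigmaBounds", "logOmegaBounds", "tauLocationBounds",
                 "tauScaleBounds", "tauDfBounds")) {
      b <- slot(object, nm)
      if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2])
        msgs <- c(msgs, sprintf("%s must be an ordered pair", nm))
    }
    if (object@sigmaBounds[1] <= 0 || object@tauScaleBounds[1] <= 0 ||
        object@tauDfBounds[1] <= 0)
      msgs <- c(msgs, "scale/df bounds must be positive")
    if (length(msgs)) msgs else TRUE
  })

#' ModelSpec: a pooling variant of the hierarchical model
#'
#' The model lattice is spanned by the degree of pooling applied to each
#' factor. Sessions: "none" (an independent value per session-by-category
#' cell), "partial" (the hierarchy: session values drawn around a group
#' mean), or "complete" (a single value shared by all of a group's
#' sessions). Category and subject: "none" (separate parameters per level)
#' or "complete" (levels collapsed into one group). `timeTrend` adds a
#' linear drift of mean value in standardized session rank and requires
#' partial session pooling.
#'
#' @export
setClass("ModelSpec",
  representation(label = "character",
                 description = "character",
                 sessionPooling = "character",
                 categoryPooling = "character",
                 subjectPooling = "character",
                 timeTrend = "logical",
                 priors = "PriorConfig"),
  validity = function(object) {
    msgs <- character()
    if (!object@sessionPooling %in% c("none", "partial", "complete"))
      msgs <- c(msgs, "sessionPooling must be none/partial/complete")
    if (!object@categoryPooling %in% c("none", "complete"))
      msgs <- c(msgs, "categoryPooling must be none/complete")
    if (!object@subjectPooling %in% c("none", "complete"))
      msgs <- c(msgs, "subjectPooling must be none/complete")
    if (object@timeTrend && object@sessionPooling != "partial")
      msgs <- c(msgs, "timeTrend requires partial session pooling")
    if (length(msgs)) msgs else TRUE
  })

#' GroundTruth: latent parameters of a simulated study
#'
#' Holds every latent quantity of a forward simulation: mean image values
#' `V` (subject x category, seconds), per-subject session-to-session s.d.
#' `sigma`, per-subject choice overdispersion `omega` (logit units),
#' per-session utility scale `tau`, optional per-subject-by-category drift
#' slopes `alpha` (seconds per standardized session-rank unit), and — once a
#' dataset has been simulated — the realized session values and block-level
#' choice probabilities.
#'
#' @export
setClass("GroundTruth",
  representation(V = "matrix",
                 sigma = "numeric",
                 omega = "numeric",
                 tau = "numeric",
                 alpha = "matrix",
                 timeTrend = "logical",
                 sessionValues = "data.frame",
                 blockLatents = "data.frame"),
  validity = function(object) {
    msgs <- character()
    if (any(object@sigma <= 0)) msgs <- c(msgs, "sigma must be > 0")
    if (any(object@omega <= 0)) msgs <- c(msgs, "omega must be > 0")
    if (any(object@tau <= 0)) msgs <- c(msgs, "tau must be > 0")
    if (nrow(object@blockLatents) &&
        !all(object@blockLatents$p > 0 & object@blockLatents$p < 1))
      msgs <- c(msgs, "realized p must lie strictly in (0, 1)")
    if (length(msgs)) msgs else TRUE
  })

#' ChainConfig: MCMC protocol
#'
#' Defaults follow the reference protocol: five chains, 1000 adaptation
#' iterations, 10,000 burn-in iterations, 20,000 post-burn iterations
#' thinned by 20, retaining 1000 draws per chain (5000 total).
#'
#' @export
setClass("ChainConfig",
  representation(nChains = "integer",
                 nAdapt = "integer",
                 nBurn = "integer",
                 nIter = "integer",
                 thin = "integer",
                 seed = "integer"),
  validity = function(object) {
    msgs <- character()
    for (nm in c("nChains", "nAdapt", "nBurn", "nIter", "thin")) {
      if (slot(object, nm) < 1L)
        msgs <- c(msgs, sprintf("%s must be >= 1", nm))
    }
    if (object@nIter %% object@thin != 0L)
      msgs <- c(msgs, "thin must divide nIter evenly")
    if (length(msgs)) msgs else TRUE
  })

#' PosteriorSamples: retained MCMC draws plus provenance
#'
#' @slot draws 3-d numeric array indexed (iteration, chain, variable); the
#'   variable dimension carries JAGS-style names such as `V[2]` or `v[17]`.
#' @slot varMap list of data.frames mapping flat variable indices back to
#'   subjects, categories, sessions.
#' @slot spec the [ModelSpec-class] that was fitted.
#' @slot config the [ChainConfig-class] used.
#' @slot fingerprint short digest of the fitted dataset.
#'
#' @export
setClass("PosteriorSamples",
  representation(draws = "array",
                 varMap = "list",
                 spec = "ModelSpec",
                 config = "ChainConfig",
                 fingerprint = "character"),
  validity = function(object) {
    if (length(dim(object@draws)) != 3)
      return("draws must be (iteration, chain, variable)")
    TRUE
  })

#' DicReport: Deviance Information Criterion summary for one model
#'
#' `Dbar` is the posterior-mean deviance, `pD = Dbar - D(posterior mean)` the
#' effective number of parameters (Spiegelhalter plug-in form), and
#' `DIC = Dbar + pD`. `DbarMCSE` is a Monte-Carlo standard error for `Dbar`
#' based on the effective sample size of the deviance trace.
#'
#' @export
setClass("DicReport",
  representation(label = "character",
                 Dbar = "numeric",
                 pD = "numeric",
                 DIC = "numeric",
                 DbarMCSE = "numeric",
                 nDraws = "integer",
                 nNonFinite = "integer",
                 maxRhat = "numeric",
                 converged = "logical"),
  validity = function(object) {
    if (is.finite(object@DIC) &&
        abs(object@DIC - (object@Dbar + object@pD)) > 1e-8 * max(1, abs(object@DIC)))
      return("DIC must equal Dbar + pD")
    TRUE
  })

#' PoolingReport: level-wise variance explained and pooling fractions
#'
#' One row of `levels` per model level (session, utility, counts) with the
#' fraction of variance explained R^2 = 1 - var(eps)/var(x) and the pooling
#' fraction lambda = 1 - var(E_u[eps])/var(eps); `residuals` retains the
#' per-unit residuals behind each row for audit.
#'
#' @export
setClass("PoolingReport",
  representation(levels = "data.frame",
                 residuals = "list"),
  validity = function(object) {
    lam <- object@levels$lambda
    ok <- is.na(lam) | (lam >= -1e-12 & lam <= 1 + 1e-12)
    if (!all(ok)) return("lambda must lie in [0, 1]")
    TRUE
  })
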