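#' @include choiceData.R priors.R
NULL

#' Construct a study design
#'
#' Builds the session layout for a simulated study. Session ids are
#' `<subject>_s<k>`; dates are weekly per subject with a per-subject day
#' offset, so subjects' sessions interleave in calendar time.
#'
#' @param sessionsPerSubject named integer vector, subject id -> number of
#'   sessions.
#' @param dvGrid numeric vector of juice differentials in seconds (recycled
#'   to every session), or a named list keyed by session id.
#' @param nPerBlock total choices per block.
#' @param startDate first session date (ISO-8601).
#' @return a [StudyDesign-class].
#' @export
studyDesign <- function(sessionsPerSubject,
                        dvGrid = c(-0.08, -0.04, 0, 0.04, 0.08),
                        nPerBlock = 30L,
                        startDate = "2008-01-01") {
  stopifnot(length(sessionsPerSubject) >= 1, all(sessionsPerSubject >= 1),
            !is.null(names(sessionsPerSubject)))
  subjectsIds <- names(sessionsPerSubject)
  sessions <- character(); sessSubj <- character(); dates <- as.Date(character())
  start <- as.Date(startDate)
  for (i in seq_along(subjectsIds)) {
    m <- subjectsIds[i]
    k <- seq_len(sessionsPerSubject[[i]])
    ids <- sprintf("%s_s%d", m, k)
    sessions <- c(sessions, ids)
    sessSubj <- c(sessSubj, structure(rep(m, length(k)), names = ids))
    dates <- c(dates, structure(start + (k - 1) * 7 + (i - 1), names = ids))
  }
  if (!is.list(dvGrid)) {
    dvGrid <- stats::setNames(rep(list(as.numeric(dvGrid)), length(sessions)),
                              sessions)
  }
  new("StudyDesign", sessions = sessions, sessionSubjects = sessSubj,
      sessionDates = dates, categories = imageCategories(),
      dvGrid = dvGrid, nPerBlock = as.integer(nPerBlock))
}

#' @rdname choiceDataset-accessors
setMethod("subjects", "StudyDesign",
          function(x) unique(unname(x@sessionSubjects)))

#' @rdname choiceDataset-accessors
setMethod("sessions", "StudyDesign", function(x) x@sessions)

#' @rdname choiceDataset-accessors
setMethod("sessionDates", "StudyDesign", function(x) x@sessionDates)

#' @rdname choiceDataset-accessors
setMethod("sessionSubjects", "StudyDesign", function(x) x@sessionSubjects)

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf("StudyDesign: %d subjects | %d sessions | N per block = %d\n",
              length(subjects(object)), length(object@sessions),
              object@nPerBlock))
  invisible(object)
})

#' Canonical desk-scale fixture design
#'
#' Four subjects with 10 sessions each, four categories, a five-point
#' juice-differential grid (+/- 80 ms), and 30 choices per block — the
#' standard size for parameter-recovery experiments.
#'
#' @return a [StudyDesign-class].
#' @export
canonicalDesign <- function() {
  studyDesign(c(A = 10L, B = 10L, C = 10L, D = 10L))
}

#' Reference study layout
#'
#' The eight-subject layout of the motivating study: subjects E, Os, Ot, D,
#' S, C, B, and N with 60, 32, 51, 23, 14, 10, 8, and 8 sessions
#' respectively (206 sessions in total).
#'
#' @param nPerBlock choices per block (default 50).
#' @return a [StudyDesign-class].
#' @export
referenceDesign <- function(nPerBlock = 50L) {
  studyDesign(c(E = 60L, Os = 32L, Ot = 51L, D = 23L, S = 14L, C = 10L,
                B = 8L, N = 8L),
              nPerBlock = nPerBlock)
}

#' Draw study-level parameters
#'
#' Draws ground-truth parameters from the model priors: mean image values
#' `V ~ Normal(0, VVariance)` per subject x category, session s.d.
#' `sigma ~ Uniform(sigmaBounds)` per subject, overdispersion
#' `log(omega) ~ Uniform(logOmegaBounds)` per subject, utility scales
#' `tau` per session from a positively-truncated t whose location/scale/df
#' are drawn uniformly from their bounds, and (when `timeTrend`) slopes
#' `alpha ~ Normal(0, alphaVariance)`. Any parameter can instead be fixed
#' via `fixed`, e.g. `fixed = list(sigma = 0.02)`; fixed values are
#' recycled to the required dimension and validated. Overdispersion values
#' are floored at 1e-8 logit units so the no-overdispersion limit stays
#' non-degenerate.
#'
#' @param design a [StudyDesign-class].
#' @param priors a [PriorConfig-class].
#' @param timeTrend if `TRUE`, draw drift slopes `alpha` (and simulation
#'   will use the time-trend value model).
#' @param fixed named list overriding any of V, sigma, omega, tau, alpha.
#' @param seed optional integer seed.
#' @return a [GroundTruth-class] (realized latents filled in by
#'   [simulateDataset()]).
#' @export
drawParameters <- function(design, priors = priorConfig(),
                           timeTrend = FALSE, fixed = list(),
                           seed = NULL) {
  stopifnot(is(design, "StudyDesign"), is(priors, "PriorConfig"))
  if (!is.null(seed)) set.seed(seed)
  bad <- setdiff(names(fixed), c("V", "sigma", "omega", "tau", "alpha"))
  if (length(bad))
    stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
  subj <- subjects(design)
  M <- length(subj); C <- length(design@categories)
  S <- length(design@sessions)

  take <- function(name, draw, dims, check = function(x) TRUE) {
    if (!is.null(fixed[[name]])) {
      x <- fixed[[name]]
      if (length(x) == 1) x <- rep(as.numeric(x), prod(dims))
      if (length(x) != prod(dims))
        stop(sprintf("fixed %s has length %d, need %d", name, length(fixed[[name]]),
                     prod(dims)))
      x <- as.numeric(x)
    } else {
      x <- draw()
    }
    if (!isTRUE(check(x))) stop(sprintf("invalid fixed value for %s", name))
    x
  }
  V <- take("V", function() stats::rnorm(M * C, 0, sqrt(priors@VVariance)),
            c(M, C), function(x) all(is.finite(x)))
  sigma <- take("sigma",
                function() stats::runif(M, priors@sigmaBounds[1], priors@sigmaBounds[2]),
                M, function(x) all(x > 0))
  omega <- take("omega",
                function() exp(stats::runif(M, priors@logOmegaBounds[1],
                                            priors@logOmegaBounds[2])),
                M, function(x) all(x >= 0))
  omega <- pmax(omega, 1e-8)
  tau <- if (!is.null(fixed$tau)) {
    take("tau", NULL, S, function(x) all(x > 0))
  } else {
    ell <- stats::runif(1, priors@tauLocationBounds[1], priors@tauLocationBounds[2])
    sca <- stats::runif(1, priors@tauScaleBounds[1], priors@tauScaleBounds[2])
    nu <- stats::runif(1, priors@tauDfBounds[1], priors@tauDfBounds[2])
    rtplus(S, ell, sca, nu)
  }
  alpha <- if (timeTrend) {
    take("alpha", function() stats::rnorm(M * C, 0, sqrt(priors@alphaVariance)),
         c(M, C), function(x) all(is.finite(x)))
  } else rep(0, M * C)

  new("GroundTruth",
      V = matrix(V, M, C, dimnames = list(subj, design@categories)),
      sigma = stats::setNames(sigma, subj),
      omega = stats::setNames(omega, subj),
      tau = stats::setNames(tau, design@sessions),
      alpha = matrix(alpha, M, C, dimnames = list(subj, design@categories)),
      timeTrend = timeTrend,
      sessionValues = data.frame(), blockLatents = data.frame())
}

#' Forward-simulate a complete study
#'
#' For every session x category cell, draws the realized session value
#' `v ~ Normal(V + alpha t, sigma^2)` (the `alpha t` term only under a time
#' trend, with `t` the standardized session rank from
#' [sessionTimeCovariate()]); then for every block forms the utility
#' `eta = (dv + v) / tau`, draws `logit p ~ Normal(eta, omega^2)`, and
#' draws `n ~ Binomial(N, p)`.
#'
#' @param truth a [GroundTruth-class] from [drawParameters()].
#' @param design the matching [StudyDesign-class].
#' @param seed optional integer seed; the same seed yields a bit-identical
#'   dataset.
#' @return list with elements `dataset` (a [ChoiceDataset-class]) and
#'   `truth` (the input with realized `sessionValues` and `blockLatents`
#'   filled in).
#' @export
simulateDataset <- function(truth, design, seed = NULL) {
  stopifnot(is(truth, "GroundTruth"), is(design, "StudyDesign"))
  if (!identical(sort(rownames(truth@V)), sort(subjects(design))) ||
      !identical(names(truth@tau), design@sessions))
    stop("truth dimensions do not match design")
  if (!is.null(seed)) set.seed(seed)
  tcov <- if (truth@timeTrend) sessionTimeCovariate(design) else
    stats::setNames(rep(0, length(design@sessions)), design@sessions)

  cells <- expand.grid(category = design@categories,
                       session = design@sessions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[, c("session", "category")]
  subjOf <- design@sessionSubjects[cells$session]
  mu <- truth@V[cbind(subjOf, cells$category)] +
    truth@alpha[cbind(subjOf, cells$category)] * tcov[cells$session]
  v <- stats::rnorm(nrow(cells), mu, truth@sigma[subjOf])
  cells$value <- v

  blockList <- vector("list", nrow(cells))
  for (j in seq_len(nrow(cells))) {
    dv <- design@dvGrid[[cells$session[j]]]
    blockList[[j]] <- data.frame(subject = unname(subjOf[j]),
                                 session = cells$session[j],
                                 category = cells$category[j],
                                 dv = dv, stringsAsFactors = FALSE)
  }
  blocks <- do.call(rbind, blockList)
  cellOf <- rep(seq_len(nrow(cells)), vapply(blockList, nrow, 1L))
  eta <- (blocks$dv + v[cellOf]) / truth@tau[blocks$session]
  logitp <- stats::rnorm(nrow(blocks), eta,
                         truth@omega[design@sessionSubjects[blocks$session]])
  p <- stats::plogis(logitp)
  blocks$n <- stats::rbinom(nrow(blocks), design@nPerBlock, p)
  blocks$N <- design@nPerBlock

  truth@sessionValues <- cells
  truth@blockLatents <- data.frame(session = blocks$session,
                                   category = blocks$category,
                                   dv = blocks$dv, eta = eta,
                                   logitp = logitp, p = p)
  dataset <- ChoiceDataset(blocks,
                           sessionDates = design@sessionDates,
                           sessionSubjects = design@sessionSubjects)
  list(dataset = dataset, truth = truth)
}

#' Realistic desk-scale ground truth
#'
#' Fixed parameter values on the scale of the reported behavior (image
#' values of 0 to tens of ms, choice-curve widths of tens of ms, moderate
#' overdispersion), used as the canonical recovery fixture: `V` drawn once
#' from Normal(0, 30 ms s.d.), `sigma` 15-30 ms, `omega` 0.2-0.5 logit
#' units, `tau` 30-70 ms.
#'
#' @param design a [StudyDesign-class].
#' @param seed integer seed controlling the draw.
#' @param timeTrend if `TRUE`, include drift slopes of +/- 0-10 ms per
#'   standardized-rank unit.
#' @return a [GroundTruth-class].
#' @export
realisticTruth <- function(design, seed = 1L, timeTrend = FALSE) {
  set.seed(seed)
  M <- length(subjects(design)); C <- length(design@categories)
  S <- length(sessions(design))
  drawParameters(design, timeTrend = timeTrend, fixed = list(
    V = stats::rnorm(M * C, 0, 0.03),
    sigma = stats::runif(M, 0.015, 0.03),
    omega = stats::runif(M, 0.2, 0.5),
    tau = stats::runif(S, 0.03, 0.07),
    alpha = if (timeTrend) stats::rnorm(M * C, 0, 0.008) else NULL))
}

#' Write / read a ground-truth sidecar
#'
#' JSON serialization of a [GroundTruth-class] (including realized latents
#' if present) for parameter-recovery bookkeeping alongside a simulated
#' choice table.
#'
#' @param truth a [GroundTruth-class].
#' @param path file path (JSON).
#' @export
writeGroundTruth <- function(truth, path) {
  obj <- list(V = truth@V, sigma = as.list(truth@sigma),
              omega = as.list(truth@omega), tau = as.list(truth@tau),
              alpha = truth@alpha, timeTrend = truth@timeTrend,
              sessionValues = truth@sessionValues,
              blockLatents = truth@blockLatents,
              subjects = rownames(truth@V), categories = colnames(truth@V))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mat <- function(x) matrix(as.numeric(x), nrow = length(obj$subjects),
                            dimnames = list(obj$subjects, obj$categories))
  asdf <- function(x) if (is.data.frame(x)) x else data.frame()
  new("GroundTruth", V = mat(obj$V),
      sigma = unlist(obj$sigma), omega = unlist(obj$omega),
      tau = unlist(obj$tau), alpha = mat(obj$alpha),
      timeTrend = obj$timeTrend,
      sessionValues = asdf(obj$sessionValues),
      blockLatents = asdf(obj$blockLatents))
}
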