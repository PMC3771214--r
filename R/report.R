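#' @include diagnostics.R
NULL

.requireFullModel <- function(samples) {
  spec <- samples@spec
  if (spec@sessionPooling != "partial" || spec@subjectPooling != "none" ||
      spec@categoryPooling != "none")
    stop("this summary needs the full subject-and-category-resolved model")
  invisible(spec)
}

# central 95% interval, type-7 quantiles (R default linear interpolation)
.q95 <- function(x) stats::quantile(x, c(0.025, 0.5, 0.975), type = 7,
                                    names = FALSE)

#' Subject-level image value summaries
#'
#' Posterior medians and central 95% credible intervals of the mean image
#' values `V` (per subject and category) and of the across-session value
#' s.d. `sigma` (per subject, repeated across that subject's rows), all
#' converted to milliseconds of juice access. Negative values are reported
#' as-is. Quantiles use type-7 linear interpolation.
#'
#' @param samples converged [PosteriorSamples-class] of the full model
#'   (with or without time trend).
#' @return data.frame: subject, category, median, lo, hi, sdMedian, sdLo,
#'   sdHi (all ms).
#' @export
valueSummaries <- function(samples) {
  .requireFullModel(samples)
  vm <- samples@varMap
  K <- nrow(vm$VMap)
  Vd <- .flatDraws(samples, .familyVars(samples, "V", K)) * 1000
  sigd <- .flatDraws(samples, .familyVars(samples, "sigma",
                                          length(vm$gLevels))) * 1000
  rows <- lapply(seq_len(K), function(k) {
    q <- .q95(Vd[, k])
    g <- match(vm$VMap$subjGroup[k], vm$gLevels)
    qs <- .q95(sigd[, g])
    data.frame(subject = vm$VMap$subjGroup[k],
               category = vm$VMap$catGroup[k],
               median = q[2], lo = q[1], hi = q[3],
               sdMedian = qs[2], sdLo = qs[1], sdHi = qs[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Time-trend slope summaries
#'
#' Posterior medians and 95% credible intervals of the drift slopes
#' `alpha`, one per subject and category, in ms of juice per
#' standardized-session-rank unit. `msPerSession` columns rescale by each
#' subject's rank step (1 / population s.d. of its session ranks), giving
#' an approximate ms-per-session reading.
#'
#' @param samples converged [PosteriorSamples-class] of the time-trend
#'   model.
#' @return data.frame: subject, category, slopeMedian, slopeLo, slopeHi
#'   (ms per rank unit), perSessionFactor, msPerSessionMedian.
#' @export
trendSummaries <- function(samples) {
  spec <- .requireFullModel(samples)
  if (!spec@timeTrend)
    stop("trend summaries need a model fitted with a time trend")
  vm <- samples@varMap
  K <- nrow(vm$VMap)
  Ad <- .flatDraws(samples, .familyVars(samples, "alpha", K)) * 1000
  nSess <- table(vm$sessions$subject)
  rows <- lapply(seq_len(K), function(k) {
    q <- .q95(Ad[, k])
    m <- vm$VMap$subjGroup[k]
    ns <- as.integer(nSess[[m]])
    r <- seq_len(ns)
    step <- if (ns > 1) 1 / sqrt(mean((r - mean(r))^2)) else NA_real_
    data.frame(subject = m, category = vm$VMap$catGroup[k],
               slopeMedian = q[2], slopeLo = q[1], slopeHi = q[3],
               perSessionFactor = step,
               msPerSessionMedian = q[2] * step,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Joint posterior samples of category values for one subject
#'
#' Draws `nPoints` joint vectors of session values: each point selects one
#' of the subject's sessions and one retained posterior draw uniformly at
#' random (with replacement) and emits that draw's values for all four
#' categories together, preserving the within-draw correlation structure of
#' the joint posterior. Intended for cross-category scatter plots.
#'
#' @param samples converged [PosteriorSamples-class] of the full model.
#' @param subject subject id.
#' @param nPoints number of joint vectors (default 1000).
#' @param seed optional integer seed.
#' @return matrix `nPoints` x categories of values in ms, with the sampled
#'   session ids as attribute `"session"`.
#' @export
categoryCorrelationSamples <- function(samples, subject, nPoints = 1000L,
                                       seed = NULL) {
  .requireFullModel(samples)
  if (!is.null(seed)) set.seed(seed)
  vm <- samples@varMap
  if (!subject %in% vm$gLevels)
    stop(sprintf("subject '%s' not present in samples", subject))
  cats <- vm$cgLevels
  sessIds <- vm$sessions$session[vm$sessions$subject == subject]
  J <- nrow(vm$vMap)
  vVars <- .familyVars(samples, "v", J)
  d <- dim(samples@draws)
  out <- matrix(NA_real_, nPoints, length(cats),
                dimnames = list(NULL, cats))
  pickedSess <- character(nPoints)
  sessPick <- sample(sessIds, nPoints, replace = TRUE)
  itPick <- sample.int(d[1], nPoints, replace = TRUE)
  chPick <- sample.int(d[2], nPoints, replace = TRUE)
  for (i in seq_len(nPoints)) {
    js <- which(vm$vMap$session == sessPick[i])
    js <- js[match(cats, vm$vMap$catGroup[js])]
    out[i, ] <- samples@draws[itPick[i], chPick[i], vVars[js]] * 1000
    pickedSess[i] <- sessPick[i]
  }
  attr(out, "session") <- pickedSess
  out
}

#' Write the delimited report files
#'
#' CSV emitters for the value, trend, and pooling reports (subject-level
#' medians and interval bounds in ms; pooling levels with R^2 and lambda).
#'
#' @param x the report object (data.frame or [PoolingReport-class]).
#' @param path output path.
#' @name report-io
#' @export
writeReportTable <- function(x, path) {
  if (is(x, "PoolingReport")) x <- x@levels
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
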