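#' @include sampler.R syntheticData.R
NULL

# resolve the draw variable names of an indexed family, tolerating JAGS's
# habit of dropping the bracket for length-1 arrays
.familyVars <- function(samples, fam, len) {
  vn <- dimnames(samples@draws)[[3]]
  want <- sprintf("%s[%d]", fam, seq_len(len))
  if (all(want %in% vn)) return(want)
  if (len == 1L && fam %in% vn) return(fam)
  stop(sprintf("samples do not contain %d '%s' variables", len, fam))
}

# flatten draws of a variable set to (total draws) x (variables)
.flatDraws <- function(samples, vars) {
  d <- dim(samples@draws)
  out <- matrix(NA_real_, d[1] * d[2], length(vars))
  for (i in seq_along(vars))
    out[, i] <- as.vector(samples@draws[, , vars[i]])
  colnames(out) <- vars
  out
}

.familyMeans <- function(samples, fam, len) {
  colMeans(.flatDraws(samples, .familyVars(samples, fam, len)))
}

# posterior-mean ParameterSet (latent probabilities averaged on the logit
# scale), the plug-in point for pD
.posteriorMeanParams <- function(samples, spec, dataset) {
  idx <- .modelIndex(spec, dataset)
  par <- list(
    omega = unname(.familyMeans(samples, "omega", idx$G)),
    tau = unname(.familyMeans(samples, "tau", idx$S)),
    ell = mean(.flatDraws(samples, "ell")),
    sca = mean(.flatDraws(samples, "sca")),
    nu = mean(.flatDraws(samples, "nu")),
    logitp = unname(.familyMeans(samples, "logitp", idx$B)))
  if (spec@sessionPooling != "none")
    par$V <- unname(.familyMeans(samples, "V", idx$K))
  if (spec@sessionPooling != "complete")
    par$v <- unname(.familyMeans(samples, "v", idx$J))
  if (spec@sessionPooling == "partial")
    par$sigma <- unname(.familyMeans(samples, "sigma", idx$G))
  if (spec@timeTrend)
    par$alpha <- unname(.familyMeans(samples, "alpha", idx$K))
  par
}

#' DIC arithmetic from a deviance trace
#'
#' Given per-draw deviances and the deviance at the posterior-mean
#' parameters, computes the posterior mean deviance `Dbar`, the effective
#' parameter count `pD = Dbar - D(theta-bar)` (Spiegelhalter plug-in form),
#' `DIC = Dbar + pD`, and a Monte-Carlo standard error for `Dbar` from the
#' effective sample size of the deviance trace.
#'
#' @param devDraws matrix of deviances, (retained iteration, chain).
#' @param devAtMean deviance at the posterior-mean parameters.
#' @param label model label carried into the report.
#' @param maxRhat,converged convergence annotation to carry along.
#' @return a [DicReport-class].
#' @export
dicFromDeviance <- function(devDraws, devAtMean, label = "model",
                            maxRhat = NA_real_, converged = NA) {
  devDraws <- as.matrix(devDraws)
  finite <- is.finite(devDraws)
  nBad <- sum(!finite)
  if (nBad > 0.01 * length(devDraws))
    stop(sprintf("%d of %d deviance draws non-finite", nBad,
                 length(devDraws)))
  Dbar <- mean(devDraws[finite])
  pD <- Dbar - devAtMean
  mcl <- coda::as.mcmc.list(lapply(seq_len(ncol(devDraws)), function(ch) {
    x <- devDraws[, ch]
    coda::mcmc(ifelse(is.finite(x), x, Dbar))
  }))
  ess <- max(1, unname(coda::effectiveSize(mcl)))
  new("DicReport", label = label, Dbar = Dbar, pD = pD, DIC = Dbar + pD,
      DbarMCSE = stats::sd(devDraws[finite]) / sqrt(ess),
      nDraws = as.integer(sum(finite)), nNonFinite = as.integer(nBad),
      maxRhat = maxRhat, converged = converged)
}

setMethod("show", "DicReport", function(object) {
  cat(sprintf("DicReport <%s>: Dbar = %.1f, pD = %.1f, DIC = %.1f (MCSE %.2f)%s\n",
              object@label, object@Dbar, object@pD, object@DIC,
              object@DbarMCSE,
              if (isFALSE(object@converged)) " [NOT CONVERGED]" else ""))
  invisible(object)
})

#' Deviance Information Criterion for a fitted model
#'
#' Recomputes the per-draw deviance (the binomial focus: observed counts
#' given each block's latent choice probability) from the retained latent
#' draws, evaluates the deviance at the posterior-mean latent
#' probabilities (averaged on the logit scale), and assembles the DIC
#' report. Deviance excludes all prior terms, so the result is invariant
#' to prior hyperparameters.
#'
#' @param samples a [PosteriorSamples-class] fitted with
#'   `monitorLatent = TRUE`.
#' @param dataset the fitted [ChoiceDataset-class].
#' @param spec the model; defaults to the one stored in `samples`.
#' @return a [DicReport-class].
#' @export
dic <- function(samples, dataset, spec = samples@spec) {
  idx <- .modelIndex(spec, dataset)
  vars <- .familyVars(samples, "logitp", idx$B)
  L <- .flatDraws(samples, vars)           # draws x blocks
  P <- stats::plogis(t(L))                 # blocks x draws
  ll <- stats::dbinom(idx$blocks$n, idx$blocks$N, P, log = TRUE)
  devDraws <- matrix(-2 * colSums(ll), nrow = dim(samples@draws)[1])
  devAtMean <- .devianceFromLogitp(colMeans(L), idx$blocks$n, idx$blocks$N)
  conv <- convergenceTable(samples)
  maxRhat <- suppressWarnings(max(conv$rhat, na.rm = TRUE))
  dicFromDeviance(devDraws, devAtMean, label = spec@label,
                  maxRhat = maxRhat, converged = maxRhat < 1.1)
}

#' Fit and compare pooling variants by DIC
#'
#' Fits each model to the dataset with the same chain protocol, computes
#' its DIC report, and returns the table sorted by ascending DIC (ties
#' keep their input order). Fits whose monitored parameters have
#' split R-hat >= 1.1 are flagged, not dropped.
#'
#' @param dataset a [ChoiceDataset-class].
#' @param specs list of [ModelSpec-class] (or integers 0-7).
#' @param config a [ChainConfig-class] used for every fit.
#' @param quiet suppress progress output.
#' @return data.frame with one row per model: label, description, pooling
#'   triple, Dbar, pD, DIC, DbarMCSE, maxRhat, converged.
#' @export
compareModels <- function(dataset, specs, config = chainConfig(),
                          quiet = TRUE) {
  specs <- lapply(specs, function(s) if (is(s, "ModelSpec")) s else modelSpec(s))
  rows <- lapply(specs, function(sp) {
    fit <- runMCMC(sp, dataset, config, monitorLatent = TRUE, quiet = quiet)
    rep <- dic(fit, dataset, sp)
    data.frame(label = sp@label, description = sp@description,
               session = sp@sessionPooling, category = sp@categoryPooling,
               subject = sp@subjectPooling, timeTrend = sp@timeTrend,
               Dbar = rep@Dbar, pD = rep@pD, DIC = rep@DIC,
               DbarMCSE = rep@DbarMCSE, maxRhat = rep@maxRhat,
               converged = rep@converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$DIC), , drop = FALSE]
}

# population variance
.varPop <- function(x) mean((x - mean(x))^2)

#' R^2 and pooling fraction from residual draws
#'
#' Arithmetic core of the level-wise pooling diagnostics. `eps` (and `x`)
#' are matrices with one row per unit and one column per posterior draw
#' (a single column means plug-in values). Variance explained is
#' `R^2 = 1 - var(eps)/var(x)` and the pooling fraction
#' `lambda = 1 - var(E_u[eps]) / var(eps)`, where `E_u` is the within-unit
#' expectation (the row mean over draws), `var(.)` the population variance
#' pooled over all entries (units x draws), and `var(E_u[eps])` the
#' across-unit variance of the within-unit expectations. `lambda` is 1
#' under complete pooling (unit-level residual expectations all shrunk
#' together) and 0 under no pooling; it lies in [0, 1] because the
#' between-unit variance of the expectations never exceeds the total by
#' the law of total variance.
#'
#' @param x matrix (units x draws) of the modeled quantity.
#' @param eps matrix (units x draws) of residuals.
#' @return named vector with elements `R2` and `lambda` (`NA` where a
#'   variance in a denominator is zero).
#' @export
poolingFractions <- function(x, eps) {
  x <- as.matrix(x); eps <- as.matrix(eps)
  vxTot <- .varPop(as.vector(x))
  veTot <- .varPop(as.vector(eps))
  R2 <- if (vxTot > 0) 1 - veTot / vxTot else NA_real_
  lambda <- if (veTot > 0) 1 - .varPop(rowMeans(eps)) / veTot else NA_real_
  c(R2 = R2, lambda = lambda)
}

#' Level-wise variance explained and pooling fractions
#'
#' For each level of the hierarchy carrying variance — session values,
#' scaled utilities, and choice counts — computes `R^2 = 1 -
#' var(eps)/var(x)` and the pooling fraction `lambda = 1 -
#' var(E_u[eps])/var(eps)` via [poolingFractions()], with residuals taken
#' over the posterior draws: session level `eps = v - (V + alpha t)`
#' (units: session-by-category cells), utility level `eps = logit p - eta`
#' (units: blocks), counts level `eps = n/N - p` (units: blocks).
#' `lambda = 1` means a level's unit residuals are completely pooled
#' toward their group structure, `lambda = 0` none.
#'
#' @param samples converged [PosteriorSamples-class] of a partial-pooling
#'   model fitted with `monitorLatent = TRUE`.
#' @param dataset the fitted [ChoiceDataset-class].
#' @param spec the model; defaults to the one stored in `samples`.
#' @return a [PoolingReport-class]; the `residuals` slot retains per-unit
#'   posterior-mean residuals for audit.
#' @export
poolingMetrics <- function(samples, dataset, spec = samples@spec) {
  if (spec@sessionPooling != "partial")
    stop("pooling metrics require a partial-pooling model")
  idx <- .modelIndex(spec, dataset)
  b <- idx$blocks
  nd <- dim(samples@draws)[1] * dim(samples@draws)[2]

  # draws x units matrices for every ingredient
  L <- .flatDraws(samples, .familyVars(samples, "logitp", idx$B))
  P <- stats::plogis(L)
  vD <- .flatDraws(samples, .familyVars(samples, "v", idx$J))
  tauD <- .flatDraws(samples, .familyVars(samples, "tau", idx$S))
  VD <- .flatDraws(samples, .familyVars(samples, "V", idx$K))
  muD <- VD[, idx$vMap$k, drop = FALSE]
  if (spec@timeTrend) {
    aD <- .flatDraws(samples, .familyVars(samples, "alpha", idx$K))
    muD <- muD + aD[, idx$vMap$k, drop = FALSE] *
      rep(idx$tcov[idx$vMap$session], each = nd)
  }

  epsV <- t(vD - muD)                                   # cells x draws
  sessionRow <- poolingFractions(t(vD), epsV)

  etaD <- (rep(b$dv, each = nd) + vD[, idx$jOfBlock, drop = FALSE]) /
    tauD[, idx$sOfBlock, drop = FALSE]
  epsEta <- t(L - etaD)                                 # blocks x draws
  utilityRow <- poolingFractions(t(L), epsEta)

  epsN <- t(rep(b$n / b$N, each = nd) - P)              # blocks x draws
  countsRow <- poolingFractions(matrix(b$n / b$N, idx$B, 1), epsN)

  levels <- data.frame(
    level = c("session", "utility", "counts"),
    R2 = c(sessionRow["R2"], utilityRow["R2"], countsRow["R2"]),
    lambda = c(sessionRow["lambda"], utilityRow["lambda"], countsRow["lambda"]),
    row.names = NULL, stringsAsFactors = FALSE)
  new("PoolingReport", levels = levels,
      residuals = list(
        session = data.frame(unit = paste(idx$vMap$session, idx$vMap$catGroup),
                             residual = rowMeans(epsV),
                             stringsAsFactors = FALSE),
        utility = data.frame(unit = paste(b$session, b$category, b$dv),
                             residual = rowMeans(epsEta),
                             stringsAsFactors = FALSE),
        counts = data.frame(unit = paste(b$session, b$category, b$dv),
                            residual = rowMeans(epsN),
                            stringsAsFactors = FALSE)))
}

setMethod("show", "PoolingReport", function(object) {
  cat("PoolingReport (R^2 = variance explained, lambda = pooling fraction)\n")
  print(object@levels, row.names = FALSE)
  invisible(object)
})

#' Simulate fictitious sessions from the fitted posterior
#'
#' Posterior predictive simulation: for each fictitious session, one
#' retained posterior draw is selected at random; the session's utility
#' scale is drawn from the truncated-t layer at that draw's
#' hyperparameters, session values from the value hierarchy, and counts
#' through the overdispersed binomial observation layer (via
#' [simulateDataset()] at the selected parameters). Subjects are cycled
#' round-robin across the fictitious sessions.
#'
#' @param samples converged [PosteriorSamples-class] of a full
#'   (subject-and-category resolved, partial-pooling) model.
#' @param nSessions number of fictitious sessions.
#' @param dvGrid juice-differential grid (s) per fictitious session.
#' @param nPerBlock choices per block.
#' @param seed optional integer seed.
#' @return a [ChoiceDataset-class] of fictitious sessions.
#' @export
posteriorPredictiveSessions <- function(samples, nSessions,
                                        dvGrid = c(-0.08, -0.04, 0, 0.04, 0.08),
                                        nPerBlock = 30L, seed = NULL) {
  spec <- samples@spec
  if (spec@sessionPooling != "partial" || spec@subjectPooling != "none" ||
      spec@categoryPooling != "none")
    stop("posterior predictive simulation needs the full hierarchical model")
  if (!is.null(seed)) set.seed(seed)
  vm <- samples@varMap
  subj <- vm$gLevels
  cats <- vm$cgLevels
  K <- nrow(vm$VMap)
  Vd <- .flatDraws(samples, .familyVars(samples, "V", K))
  Gn <- length(subj)
  sigd <- .flatDraws(samples, .familyVars(samples, "sigma", Gn))
  omd <- .flatDraws(samples, .familyVars(samples, "omega", Gn))
  elld <- .flatDraws(samples, "ell")
  scad <- .flatDraws(samples, "sca")
  nud <- .flatDraws(samples, "nu")
  nDraws <- nrow(Vd)

  pieces <- vector("list", nSessions)
  for (i in seq_len(nSessions)) {
    m <- subj[(i - 1L) %% length(subj) + 1L]
    dr <- sample.int(nDraws, 1)
    kRows <- which(vm$VMap$subjGroup == m)
    Vrow <- Vd[dr, kRows[match(cats, vm$VMap$catGroup[kRows])]]
    g <- match(m, subj)
    tau1 <- rtplus(1, elld[dr], scad[dr], nud[dr])
    design1 <- studyDesign(stats::setNames(1L, m), dvGrid = dvGrid,
                           nPerBlock = nPerBlock)
    truth1 <- drawParameters(design1, priors = spec@priors, fixed = list(
      V = Vrow, sigma = sigd[dr, g], omega = omd[dr, g], tau = tau1))
    sim <- simulateDataset(truth1, design1)
    bl <- choiceBlocks(sim$dataset)
    bl$session <- sprintf("ppc_%s_%d", m, i)
    pieces[[i]] <- bl
  }
  blocks <- do.call(rbind, pieces)
  first <- !duplicated(blocks$session)
  ChoiceDataset(blocks,
                sessionDates = stats::setNames(
                  rep(as.Date("2100-01-01"), sum(first)) + seq_len(sum(first)),
                  blocks$session[first]),
                sessionSubjects = stats::setNames(blocks$subject[first],
                                                  blocks$session[first]))
}

#' Fit a logistic choice curve to one session-by-category cell
#'
#' Maximum-likelihood logistic regression of choice counts on the juice
#' differential: `logit p = beta0 + beta1 dv`. The curve width is
#' `1/beta1` (seconds of juice per logit) and the point of subjective
#' equality `pse = -beta0/beta1`; the image value estimate is `-pse`.
#' Complete separation is flagged (`separable = TRUE`) and the diverging
#' estimates reported as-is rather than replaced.
#'
#' @param blocks data.frame with columns dv (s), n, N for a single
#'   session-by-category cell; needs >= 2 distinct dv values.
#' @return one-row data.frame: beta0, beta1, width, pse, separable.
#' @export
fitChoiceCurve <- function(blocks) {
  stopifnot(all(c("dv", "n", "N") %in% names(blocks)))
  if (length(unique(blocks$dv)) < 2)
    stop("need >= 2 distinct dv values to fit a choice curve")
  separable <- FALSE
  fit <- withCallingHandlers(
    stats::glm(cbind(n, N - n) ~ dv, family = stats::binomial(),
               data = blocks),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        separable <<- TRUE
      invokeRestart("muffleWarning")
    })
  mu <- stats::fitted(fit)
  if (!fit$converged || any(mu < 1e-8 | mu > 1 - 1e-8)) separable <- TRUE
  beta0 <- unname(stats::coef(fit)[1])
  beta1 <- unname(stats::coef(fit)[2])
  data.frame(beta0 = beta0, beta1 = beta1, width = 1 / beta1,
             pse = -beta0 / beta1, separable = separable)
}

#' Refit choice curves for every session-by-category cell
#'
#' Applies [fitChoiceCurve()] across a dataset; cells with fewer than two
#' distinct dv values are skipped.
#'
#' @param dataset a [ChoiceDataset-class].
#' @return data.frame: subject, session, category, beta0, beta1, width,
#'   pse, value (`-pse`), separable.
#' @export
refitChoiceCurves <- function(dataset) {
  b <- choiceBlocks(dataset)
  key <- paste(b$session, b$category)
  rows <- lapply(unique(key), function(k) {
    cell <- b[key == k, ]
    if (length(unique(cell$dv)) < 2) return(NULL)
    fit <- fitChoiceCurve(cell)
    cbind(data.frame(subject = cell$subject[1], session = cell$session[1],
                     category = cell$category[1], stringsAsFactors = FALSE),
          fit, data.frame(value = -fit$pse))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior predictive check on choice-curve summaries
#'
#' Refits logistic choice curves to the observed and the posterior
#' predictive datasets through the identical code path and compares the
#' distributions of fitted image values and curve widths with two-sample
#' Kolmogorov-Smirnov tests. Diverging (separable) fits and non-positive
#' slopes are excluded from both sides.
#'
#' @param dataset the observed [ChoiceDataset-class].
#' @param ppcDataset fictitious sessions from
#'   [posteriorPredictiveSessions()].
#' @return list with `valueP` and `widthP` (KS p-values), plus the two
#'   refit tables.
#' @export
ppcKsCheck <- function(dataset, ppcDataset) {
  keep <- function(df) df[!df$separable & df$beta1 > 0, , drop = FALSE]
  real <- keep(refitChoiceCurves(dataset))
  sim <- keep(refitChoiceCurves(ppcDataset))
  ksp <- function(a, b) suppressWarnings(stats::ks.test(a, b)$p.value)
  list(valueP = ksp(real$value, sim$value),
       widthP = ksp(real$width, sim$width),
       realFits = real, ppcFits = sim)
}
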