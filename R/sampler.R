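#' @include jagsCode.R
NULL

#' Construct an MCMC protocol
#'
#' @param nChains number of independent chains (default 5).
#' @param nAdapt adaptation iterations (default 1000).
#' @param nBurn burn-in iterations, discarded (default 10000).
#' @param nIter post-burn iterations per chain (default 20000).
#' @param thin keep every `thin`-th draw (default 20); must divide `nIter`.
#' @param seed master seed; per-chain RNG seeds are derived from it by a
#'   fixed splitting rule, so the same seed reproduces draws bit-for-bit.
#' @return a [ChainConfig-class]. The default protocol retains
#'   `nIter/thin = 1000` draws per chain, 5000 in total.
#' @export
chainConfig <- function(nChains = 5L, nAdapt = 1000L, nBurn = 10000L,
                        nIter = 20000L, thin = 20L, seed = 1L) {
  new("ChainConfig", nChains = as.integer(nChains),
      nAdapt = as.integer(nAdapt), nBurn = as.integer(nBurn),
      nIter = as.integer(nIter), thin = as.integer(thin),
      seed = as.integer(seed))
}

#' @rdname retainedDraws
setMethod("retainedDraws", "ChainConfig", function(x, perChain = FALSE) {
  per <- x@nIter %/% x@thin
  if (perChain) per else per * x@nChains
})

#' @rdname retainedDraws
setMethod("retainedDraws", "PosteriorSamples", function(x, perChain = FALSE) {
  d <- dim(x@draws)
  if (perChain) d[1] else d[1] * d[2]
})

setMethod("show", "ChainConfig", function(object) {
  cat(sprintf("ChainConfig: %d chains x (%d adapt + %d burn + %d iter, thin %d) -> %d retained\n",
              object@nChains, object@nAdapt, object@nBurn, object@nIter,
              object@thin, retainedDraws(object)))
  invisible(object)
})

setMethod("show", "PosteriorSamples", function(object) {
  d <- dim(object@draws)
  cat(sprintf("PosteriorSamples <%s>: %d chains x %d draws, %d variables\n",
              object@spec@label, d[2], d[1], d[3]))
  invisible(object)
})

.fingerprint <- function(dataset) {
  b <- choiceBlocks(dataset)
  sprintf("b%d-n%d-N%d-dv%d", nrow(b), sum(b$n), sum(b$N),
          as.integer(sum(abs(b$dv)) * 1e6) %% 1000000L)
}

# mcmc.list -> array (iteration, chain, variable)
.codaToArray <- function(mcl) {
  vn <- colnames(mcl[[1]])
  arr <- array(NA_real_, c(nrow(mcl[[1]]), length(mcl), length(vn)),
               dimnames = list(NULL, NULL, vn))
  for (ch in seq_along(mcl)) arr[, ch, ] <- as.matrix(mcl[[ch]])
  arr
}

#' Low-level JAGS runner
#'
#' Runs an arbitrary JAGS model text through the package's chain protocol
#' (adaptation, burn-in, thinned sampling, per-chain derived seeds) and
#' returns the retained draws as an (iteration, chain, variable) array.
#' [runMCMC()] builds on this; it is exported so that simple reference
#' models (e.g. conjugate checks) can exercise the identical chain
#' management.
#'
#' @param code JAGS model code as a single string.
#' @param data named list of data values.
#' @param monitor character vector of variables to record.
#' @param config a [ChainConfig-class].
#' @param inits optional list (one per chain) of initial values; RNG name
#'   and seed entries are added per chain if absent.
#' @param quiet suppress JAGS progress output.
#' @return array (iteration, chain, variable).
#' @export
runJagsTextModel <- function(code, data, monitor, config, inits = NULL,
                             quiet = TRUE) {
  stopifnot(is(config, "ChainConfig"))
  if (is.null(inits)) inits <- rep(list(list()), config@nChains)
  for (ch in seq_len(config@nChains)) {
    if (is.null(inits[[ch]]$.RNG.name)) {
      inits[[ch]]$.RNG.name <- "base::Mersenne-Twister"
      inits[[ch]]$.RNG.seed <- (config@seed * 1009L + 7919L * ch) %%
        2147483546L + 1L
    }
  }
  jm <- rjags::jags.model(textConnection(code), data = data, inits = inits,
                          n.chains = config@nChains, n.adapt = config@nAdapt,
                          quiet = quiet)
  if (config@nBurn > 0)
    update(jm, config@nBurn, progress.bar = "none")
  mcl <- rjags::coda.samples(jm, variable.names = monitor,
                             n.iter = config@nIter, thin = config@thin,
                             progress.bar = "none")
  .codaToArray(mcl)
}

#' Sample the posterior of a pooling variant
#'
#' Generates the JAGS program for `spec`, initializes `config@nChains`
#' dispersed chains (group means from the prior, session values at jittered
#' no-pooling estimates, utility scales near 50 ms), runs
#' adaptation/burn-in/thinned sampling, and returns the retained draws.
#' The monitored set covers the group means V, session values v, sigma,
#' omega, tau and its hyperparameters, slopes alpha when present, and
#' (by default) the per-block latent logit p needed for deviance-based
#' diagnostics.
#'
#' If the initial state has non-finite density, initialization is retried
#' with re-drawn starting points up to `maxRetries` times.
#'
#' @param spec a [ModelSpec-class].
#' @param dataset a [ChoiceDataset-class].
#' @param config a [ChainConfig-class]; the same seed gives bit-identical
#'   draws.
#' @param monitorLatent record the per-block latent `logitp` (needed by
#'   [dic()] and [poolingMetrics()]; adds volume).
#' @param maxRetries bounded re-initialization attempts.
#' @param quiet suppress JAGS progress output.
#' @return a [PosteriorSamples-class].
#' @export
runMCMC <- function(spec, dataset, config = chainConfig(),
                    monitorLatent = TRUE, maxRetries = 3L, quiet = TRUE) {
  stopifnot(is(spec, "ModelSpec"), is(dataset, "ChoiceDataset"),
            is(config, "ChainConfig"))
  idx <- .modelIndex(spec, dataset)
  code <- .jagsCode(spec)
  data <- .jagsData(spec, idx)
  monitor <- c(if (spec@sessionPooling != "none") "V",
               if (spec@sessionPooling != "complete") "v",
               if (spec@sessionPooling == "partial") "sigma",
               "omega", "tau", "ell", "sca", "nu",
               if (spec@timeTrend) "alpha",
               if (monitorLatent) "logitp")
  arr <- NULL
  for (attempt in 0:maxRetries) {
    set.seed(config@seed + attempt)
    inits <- .jagsInits(spec, idx, config, attempt = attempt)
    arr <- tryCatch(
      runJagsTextModel(code, data, monitor, config, inits = inits,
                       quiet = quiet),
      error = function(e) e)
    if (!inherits(arr, "error")) break
  }
  if (inherits(arr, "error"))
    stop("MCMC initialization failed after ", maxRetries + 1, " attempts: ",
         conditionMessage(arr))
  varMap <- list(VMap = idx$VMap, vMap = idx$vMap,
                 sessions = data.frame(s = seq_len(idx$S),
                                       session = idx$sessions,
                                       subject = unname(idx$subjOfSess),
                                       stringsAsFactors = FALSE),
                 gLevels = idx$gLevels, cgLevels = idx$cgLevels,
                 tcov = idx$tcov)
  new("PosteriorSamples", draws = arr, varMap = varMap, spec = spec,
      config = config, fingerprint = .fingerprint(dataset))
}

#' Extract draws for one parameter family
#'
#' @param samples a [PosteriorSamples-class].
#' @param param a family name (`"V"`, `"v"`, `"tau"`, ...) or an exact
#'   variable name (`"V[2]"`).
#' @return array (iteration, chain, element) for a family; matrix
#'   (iteration, chain) for an exact name.
#' @export
extractDraws <- function(samples, param) {
  vn <- dimnames(samples@draws)[[3]]
  if (param %in% vn) return(samples@draws[, , param])
  hits <- grep(paste0("^", param, "\\["), vn)
  if (!length(hits))
    stop(sprintf("parameter '%s' not found in samples", param))
  samples@draws[, , hits, drop = FALSE]
}

# draws for an exact variable as (iteration, chain) matrix
.varMatrix <- function(samples, var) {
  vn <- dimnames(samples@draws)[[3]]
  if (!var %in% vn) stop(sprintf("variable '%s' not found", var))
  samples@draws[, , var]
}

# split-R-hat on an (iteration, chain) matrix
.splitRhat <- function(mat) {
  niter <- nrow(mat)
  half <- niter %/% 2
  splits <- cbind(mat[seq_len(half), , drop = FALSE],
                  mat[(niter - half + 1):niter, , drop = FALSE])
  n <- nrow(splits); m <- ncol(splits)
  means <- colMeans(splits)
  W <- mean(apply(splits, 2, stats::var))
  if (!is.finite(W) || W <= 0) return(NA_real_)
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Split R-hat convergence diagnostic
#'
#' Potential scale reduction computed after splitting each chain in half:
#' the ratio of pooled within+between variance to within-chain variance.
#' Values near 1 indicate that chains agree; the conventional convergence
#' criterion is R-hat < 1.1. Returns `NA` with a warning when the draws are
#' (numerically) constant.
#'
#' @param samples a [PosteriorSamples-class] with >= 2 chains and >= 10
#'   retained draws per chain.
#' @param param exact variable name (e.g. `"V[1]"`) or family name, in
#'   which case a named vector over the family's elements is returned.
#' @return R-hat value(s), >= 1 up to floating-point error.
#' @export
rhat <- function(samples, param) {
  d <- dim(samples@draws)
  if (d[2] < 2)
    stop("R-hat needs >= 2 chains; use effectiveSampleSize() for one chain")
  if (d[1] < 10) stop("R-hat needs >= 10 retained draws per chain")
  vn <- dimnames(samples@draws)[[3]]
  vars <- if (param %in% vn) param else
    vn[grepl(paste0("^", param, "\\["), vn)]
  if (!length(vars)) stop(sprintf("parameter '%s' not found", param))
  out <- vapply(vars, function(v) .splitRhat(.varMatrix(samples, v)), 0)
  if (anyNA(out))
    warning("zero within-chain variance; R-hat undefined for some variables")
  if (length(out) == 1L) unname(out) else out
}

#' Effective sample size
#'
#' Autocorrelation-adjusted number of independent draws, via the spectral
#' estimator of `coda::effectiveSize`, capped at the total number of
#' retained draws. Degenerate (constant) chains give `NA` with a warning.
#'
#' @inheritParams rhat
#' @return effective sample size value(s).
#' @export
effectiveSampleSize <- function(samples, param) {
  d <- dim(samples@draws)
  if (d[1] < 10) stop("ESS needs >= 10 retained draws per chain")
  vn <- dimnames(samples@draws)[[3]]
  vars <- if (param %in% vn) param else
    vn[grepl(paste0("^", param, "\\["), vn)]
  if (!length(vars)) stop(sprintf("parameter '%s' not found", param))
  total <- d[1] * d[2]
  out <- vapply(vars, function(v) {
    mat <- .varMatrix(samples, v)
    if (stats::sd(as.vector(mat)) == 0) return(NA_real_)
    mcl <- coda::as.mcmc.list(lapply(seq_len(ncol(mat)),
                                     function(ch) coda::mcmc(mat[, ch])))
    min(unname(coda::effectiveSize(mcl)), total)
  }, 0)
  if (anyNA(out)) warning("constant chain; effective sample size undefined")
  if (length(out) == 1L) unname(out) else out
}

#' Convergence table over the monitored set
#'
#' Split R-hat and effective sample size for every non-latent monitored
#' variable (latent per-block `logitp` entries are excluded by default).
#'
#' @param samples a [PosteriorSamples-class].
#' @param includeLatent include per-block `logitp` variables.
#' @return data.frame with columns variable, rhat, ess.
#' @export
convergenceTable <- function(samples, includeLatent = FALSE) {
  vn <- dimnames(samples@draws)[[3]]
  if (!includeLatent) vn <- vn[!grepl("^logitp", vn)]
  data.frame(variable = vn,
             rhat = vapply(vn, function(v)
               .splitRhat(.varMatrix(samples, v)), 0),
             ess = suppressWarnings(vapply(vn, function(v)
               effectiveSampleSize(samples, v), 0)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Persist / reload posterior samples
#'
#' `savePosterior` writes a columnar on-disk layout: one CSV of draws per
#' chain (variables as columns), a JSON manifest (variable names, shapes,
#' chain protocol, dataset fingerprint, index maps), and the model
#' configuration; `loadPosterior` reconstructs the
#' [PosteriorSamples-class] without refitting.
#'
#' @param samples a [PosteriorSamples-class].
#' @param dir directory to create/use.
#' @export
savePosterior <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(samples@draws)
  for (ch in seq_len(d[2])) {
    mat <- samples@draws[, ch, , drop = FALSE]
    dim(mat) <- d[c(1, 3)]
    colnames(mat) <- dimnames(samples@draws)[[3]]
    utils::write.csv(as.data.frame(mat),
                     file.path(dir, sprintf("chain%d.csv", ch)),
                     row.names = FALSE)
  }
  writeModelSpec(samples@spec, file.path(dir, "modelspec.dcf"))
  cfg <- samples@config
  manifest <- list(
    variables = dimnames(samples@draws)[[3]],
    nIterRetained = d[1], nChains = d[2],
    config = list(nChains = cfg@nChains, nAdapt = cfg@nAdapt,
                  nBurn = cfg@nBurn, nIter = cfg@nIter, thin = cfg@thin,
                  seed = cfg@seed),
    fingerprint = samples@fingerprint,
    varMap = samples@varMap)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' @rdname savePosterior
#' @export
loadPosterior <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  spec <- readModelSpec(file.path(dir, "modelspec.dcf"))
  arr <- array(NA_real_, c(man$nIterRetained, man$nChains,
                           length(man$variables)),
               dimnames = list(NULL, NULL, man$variables))
  for (ch in seq_len(man$nChains)) {
    tab <- utils::read.csv(file.path(dir, sprintf("chain%d.csv", ch)),
                           check.names = FALSE)
    arr[, ch, ] <- as.matrix(tab)
  }
  cfg <- chainConfig(nChains = man$config$nChains, nAdapt = man$config$nAdapt,
                     nBurn = man$config$nBurn, nIter = man$config$nIter,
                     thin = man$config$thin, seed = man$config$seed)
  vm <- man$varMap
  for (nm in c("VMap", "vMap", "sessions"))
    if (!is.null(vm[[nm]])) vm[[nm]] <- as.data.frame(vm[[nm]])
  if (!is.null(vm$tcov)) vm$tcov <- unlist(vm$tcov)
  new("PosteriorSamples", draws = arr, varMap = vm, spec = spec,
      config = cfg, fingerprint = man$fingerprint)
}
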