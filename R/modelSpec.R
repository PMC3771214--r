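#' @include AllClasses.R priors.R
NULL

# the model lattice: pooling triples per model number
.modelLattice <- data.frame(
  model = 0:7,
  description = c("All sessions independent",
                  "One model per (category, subject)",
                  "One model per subject",
                  "Only session variation",
                  "Collapse category, model session",
                  "Collapse subject, model session",
                  "Model session per (category, subject)",
                  "Session model plus time trend"),
  session = c("none", "complete", "complete", "partial", "partial",
              "partial", "partial", "partial"),
  category = c("none", "none", "complete", "complete", "complete",
               "none", "none", "none"),
  subject = c("none", "none", "none", "complete", "none", "complete",
              "none", "none"),
  timeTrend = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
  stringsAsFactors = FALSE)

#' Construct a pooling variant of the hierarchical model
#'
#' Either give a model number 0-7 selecting a variant from the standard
#' lattice (see [modelLattice()]), or specify the pooling of each factor
#' explicitly. Model 6 is the full hierarchical model (partial session
#' pooling, separate parameters per category and subject); Model 7 adds
#' the time trend; Models 0-2 are the non-hierarchical comparison fits.
#'
#' @param model integer 0-7, or `NULL` to use the explicit pooling
#'   arguments.
#' @param sessionPooling "none", "partial", or "complete".
#' @param categoryPooling,subjectPooling "none" or "complete".
#' @param timeTrend logical; requires `sessionPooling = "partial"`.
#' @param priors a [PriorConfig-class]; the same defaults are used for all
#'   variants.
#' @return a [ModelSpec-class].
#' @examples
#' modelSpec(6)
#' modelSpec(sessionPooling = "partial", timeTrend = TRUE)
#' @export
modelSpec <- function(model = NULL,
                      sessionPooling = "partial",
                      categoryPooling = "none",
                      subjectPooling = "none",
                      timeTrend = FALSE,
                      priors = priorConfig()) {
  if (!is.null(model)) {
    stopifnot(length(model) == 1, model %in% 0:7)
    row <- .modelLattice[.modelLattice$model == model, ]
    return(new("ModelSpec", label = paste0("model", model),
               description = row$description,
               sessionPooling = row$session, categoryPooling = row$category,
               subjectPooling = row$subject, timeTrend = row$timeTrend,
               priors = priors))
  }
  lab <- .matchLatticeLabel(sessionPooling, categoryPooling, subjectPooling,
                            timeTrend)
  new("ModelSpec", label = lab$label, description = lab$description,
      sessionPooling = sessionPooling, categoryPooling = categoryPooling,
      subjectPooling = subjectPooling, timeTrend = timeTrend,
      priors = priors)
}

.matchLatticeLabel <- function(sessionPooling, categoryPooling,
                               subjectPooling, timeTrend) {
  hit <- which(.modelLattice$session == sessionPooling &
               .modelLattice$category == categoryPooling &
               .modelLattice$subject == subjectPooling &
               .modelLattice$timeTrend == timeTrend)
  if (length(hit) == 1)
    list(label = paste0("model", .modelLattice$model[hit]),
         description = .modelLattice$description[hit])
  else
    list(label = "custom", description = "custom pooling combination")
}

#' The standard model lattice
#'
#' The eight pooling variants: per-model degree of pooling over sessions,
#' categories, and subjects, plus the time-trend flag.
#'
#' @return data.frame with columns model, description, session, category,
#'   subject, timeTrend.
#' @export
modelLattice <- function() .modelLattice

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec <%s>: %s\n", object@label, object@description))
  cat(sprintf("  pooling: session=%s category=%s subject=%s; timeTrend=%s\n",
              object@sessionPooling, object@categoryPooling,
              object@subjectPooling, object@timeTrend))
  invisible(object)
})

#' Serialize / restore a ModelSpec configuration
#'
#' Writes a key/value text file (DCF) naming the lattice variant and its
#' pooling flags and prior hyperparameters; `readModelSpec` reconstructs an
#' equivalent [ModelSpec-class].
#'
#' @param spec a [ModelSpec-class].
#' @param path file path.
#' @export
writeModelSpec <- function(spec, path) {
  p <- spec@priors
  df <- data.frame(
    label = spec@label,
    sessionPooling = spec@sessionPooling,
    categoryPooling = spec@categoryPooling,
    subjectPooling = spec@subjectPooling,
    timeTrend = spec@timeTrend,
    VVariance = p@VVariance,
    sigmaBounds = paste(p@sigmaBounds, collapse = " "),
    logOmegaBounds = paste(p@logOmegaBounds, collapse = " "),
    tauLocationBounds = paste(p@tauLocationBounds, collapse = " "),
    tauScaleBounds = paste(p@tauScaleBounds, collapse = " "),
    tauDfBounds = paste(p@tauDfBounds, collapse = " "),
    alphaVariance = p@alphaVariance)
  write.dcf(df, path)
  invisible(path)
}

#' @rdname writeModelSpec
#' @export
readModelSpec <- function(path) {
  d <- as.data.frame(read.dcf(path), stringsAsFactors = FALSE)
  pair <- function(nm) as.numeric(strsplit(d[[nm]], " +")[[1]])
  priors <- priorConfig(VVariance = as.numeric(d$VVariance),
                        sigmaBounds = pair("sigmaBounds"),
                        logOmegaBounds = pair("logOmegaBounds"),
                        tauLocationBounds = pair("tauLocationBounds"),
                        tauScaleBounds = pair("tauScaleBounds"),
                        tauDfBounds = pair("tauDfBounds"),
                        alphaVariance = as.numeric(d$alphaVariance))
  modelSpec(model = NULL,
            sessionPooling = d$sessionPooling,
            categoryPooling = d$categoryPooling,
            subjectPooling = d$subjectPooling,
            timeTrend = as.logical(d$timeTrend),
            priors = priors)
}
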