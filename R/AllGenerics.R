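#' @include AllClasses.R
NULL

#' Accessors for ChoiceDataset
#'
#' `choiceBlocks` returns the block table (one aggregated observation per
#' row), `sessionDates` the session id -> date map, `sessionSubjects` the
#' session id -> subject map, `subjects` and `sessions` the unique labels.
#'
#' @param x a [ChoiceDataset-class] (or [StudyDesign-class] where noted).
#' @return `choiceBlocks`: data.frame; the others: named vectors or
#'   character vectors of labels.
#' @name choiceDataset-accessors
#' @aliases choiceBlocks sessionDates sessionSubjects subjects sessions
#' @export
setGeneric("choiceBlocks", function(x) standardGeneric("choiceBlocks"))

#' @rdname choiceDataset-accessors
#' @export
setGeneric("sessionDates", function(x) standardGeneric("sessionDates"))

#' @rdname choiceDataset-accessors
#' @export
setGeneric("sessionSubjects", function(x) standardGeneric("sessionSubjects"))

#' @rdname choiceDataset-accessors
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname choiceDataset-accessors
#' @export
setGeneric("sessions", function(x) standardGeneric("sessions"))

#' Standardized session-rank time covariate
#'
#' Within each subject, sessions are rank-ordered by date (midranks for
#' ties) and the ranks are z-scored with the population (divide-by-n)
#' standard deviation, so each subject's covariate vector has mean 0 and
#' unit variance. A subject with a single session gets covariate 0 with a
#' warning, its variance being undefined.
#'
#' @param x a [ChoiceDataset-class] or [StudyDesign-class].
#' @return named numeric vector, session id -> standardized rank.
#' @export
setGeneric("sessionTimeCovariate",
           function(x) standardGeneric("sessionTimeCovariate"))

#' Number of retained draws implied by a chain configuration
#'
#' @param x a [ChainConfig-class] or [PosteriorSamples-class].
#' @param perChain if `TRUE`, draws per chain; otherwise the total across
#'   chains.
#' @export
setGeneric("retainedDraws",
           function(x, perChain = FALSE) standardGeneric("retainedDraws"))
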