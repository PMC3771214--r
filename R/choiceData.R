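#' @include AllGenerics.R
NULL

#' Construct a ChoiceDataset
#'
#' @param blocks data.frame with columns subject, session, category,
#'   dv (seconds), n, N.
#' @param sessionDates named `Date` (or ISO-8601 character) vector keyed by
#'   session id.
#' @param sessionSubjects named character vector, session id -> subject id.
#'   Defaults to the map implied by `blocks`.
#' @return a validated [ChoiceDataset-class].
#' @examples
#' blocks <- data.frame(subject = "E", session = "s1", category = "female",
#'                      dv = c(-0.05, 0, 0.05), n = c(4, 11, 18), N = 20)
#' ds <- ChoiceDataset(blocks, c(s1 = "2008-01-01"))
#' choiceBlocks(ds)
#' @export
ChoiceDataset <- function(blocks, sessionDates,
                          sessionSubjects = NULL) {
  blocks <- as.data.frame(blocks)
  blocks$subject <- as.character(blocks$subject)
  blocks$session <- as.character(blocks$session)
  blocks$category <- as.character(blocks$category)
  blocks$dv <- as.numeric(blocks$dv)
  blocks$n <- as.integer(blocks$n)
  blocks$N <- as.integer(blocks$N)
  rownames(blocks) <- NULL
  if (is.null(sessionSubjects)) {
    first <- !duplicated(blocks$session)
    sessionSubjects <- structure(blocks$subject[first], names = blocks$session[first])
  }
  new("ChoiceDataset", blocks = blocks,
      sessionDates = as.Date(sessionDates),
      sessionSubjects = sessionSubjects)
}

#' @rdname choiceDataset-accessors
setMethod("choiceBlocks", "ChoiceDataset", function(x) x@blocks)

#' @rdname choiceDataset-accessors
setMethod("sessionDates", "ChoiceDataset", function(x) x@sessionDates)

#' @rdname choiceDataset-accessors
setMethod("sessionSubjects", "ChoiceDataset", function(x) x@sessionSubjects)

#' @rdname choiceDataset-accessors
setMethod("subjects", "ChoiceDataset",
          function(x) unique(x@blocks$subject))

#' @rdname choiceDataset-accessors
setMethod("sessions", "ChoiceDataset",
          function(x) unique(x@blocks$session))

setMethod("show", "ChoiceDataset", function(object) {
  b <- object@blocks
  cat(sprintf("ChoiceDataset: %d blocks | %d subjects | %d sessions | %d categories\n",
              nrow(b), length(unique(b$subject)), length(unique(b$session)),
              length(unique(b$category))))
  if (nrow(b)) {
    cat(sprintf("  dv range [%g, %g] ms; choices per block %d-%d\n",
                1000 * min(b$dv), 1000 * max(b$dv), min(b$N), max(b$N)))
  }
  invisible(object)
})

.requiredCols <- c("subject", "session", "date", "category", "dv_ms", "n", "N")

#' Read an aggregated choice-count table
#'
#' Reads the package's CSV schema (header columns `subject, session, date,
#' category, dv_ms, n, N`; dates ISO-8601; `dv_ms` in milliseconds of juice
#' access) and returns a validated dataset with `dv` converted to seconds,
#' the internal unit.
#'
#' @param path file path to a CSV file.
#' @return a [ChoiceDataset-class].
#' @seealso [writeChoiceTable()]
#' @export
readChoiceTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(.requiredCols, names(tab))
  if (length(missing))
    stop("choice table is missing columns: ", paste(missing, collapse = ", "))
  num <- function(col) {
    x <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(x) & nzchar(tab[[col]]))
    if (any(is.na(x)))
      stop(sprintf("malformed value in column '%s' (row %d)", col,
                   if (length(bad)) bad[1] else which(is.na(x))[1]))
    x
  }
  dv_ms <- num("dv_ms"); n <- num("n"); N <- num("N")
  badCat <- which(!tab$category %in% imageCategories())
  if (length(badCat))
    stop(sprintf("unknown category '%s' (row %d)", tab$category[badCat[1]],
                 badCat[1]))
  badN <- which(n > N | n < 0 | N < 1)
  if (length(badN))
    stop(sprintf("invalid counts n=%g, N=%g (row %d)", n[badN[1]], N[badN[1]],
                 badN[1]))
  key <- paste(tab$session, tab$category, signif(dv_ms, 12))
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate (session, category, dv) block (row %d)", dup[1]))
  dates <- as.Date(tab$date)
  if (anyNA(dates) && nrow(tab))
    stop(sprintf("unparseable date (row %d)", which(is.na(dates))[1]))
  consolidate <- function(val, by) {
    first <- !duplicated(by)
    map <- structure(val[first], names = by[first])
    conflict <- which(val != map[by])
    if (length(conflict))
      stop(sprintf("session metadata conflict (row %d)", conflict[1]))
    map
  }
  blocks <- data.frame(subject = tab$subject, session = tab$session,
                       category = tab$category, dv = dv_ms / 1000,
                       n = as.integer(n), N = as.integer(N),
                       stringsAsFactors = FALSE)
  if (!nrow(tab)) {
    return(ChoiceDataset(blocks, sessionDates = as.Date(character()),
                         sessionSubjects = character()))
  }
  ChoiceDataset(blocks,
                sessionDates = as.Date(consolidate(as.character(dates), tab$session)),
                sessionSubjects = consolidate(tab$subject, tab$session))
}

#' Write an aggregated choice-count table
#'
#' Emits the same CSV schema [readChoiceTable()] accepts, with `dv`
#' converted back to milliseconds.
#'
#' @param dataset a [ChoiceDataset-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeChoiceTable <- function(dataset, path) {
  stopifnot(is(dataset, "ChoiceDataset"))
  b <- choiceBlocks(dataset)
  out <- data.frame(subject = b$subject, session = b$session,
                    date = as.character(sessionDates(dataset)[b$session]),
                    category = b$category, dv_ms = b$dv * 1000,
                    n = b$n, N = b$N, stringsAsFactors = FALSE)
  if (!nrow(out)) {
    # preserve header for empty datasets
    out <- out[0, .requiredCols, drop = FALSE]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# midrank z-scoring with population (divide-by-n) sd; the workhorse behind
# sessionTimeCovariate for both datasets and designs
.zrank <- function(dates, sessIds, subjectOf) {
  out <- numeric(length(sessIds))
  names(out) <- sessIds
  for (m in unique(subjectOf)) {
    idx <- which(subjectOf == m)
    if (length(idx) == 1L) {
      warning(sprintf("subject '%s' has a single session; covariate set to 0", m))
      out[idx] <- 0
      next
    }
    r <- rank(dates[idx], ties.method = "average")
    sdPop <- sqrt(mean((r - mean(r))^2))
    out[idx] <- if (sdPop > 0) (r - mean(r)) / sdPop else 0
  }
  out
}

#' @rdname sessionTimeCovariate
setMethod("sessionTimeCovariate", "ChoiceDataset", function(x) {
  sess <- sessions(x)
  .zrank(sessionDates(x)[sess], sess, sessionSubjects(x)[sess])
})

#' @rdname sessionTimeCovariate
setMethod("sessionTimeCovariate", "StudyDesign", function(x) {
  .zrank(x@sessionDates[x@sessions], x@sessions,
         x@sessionSubjects[x@sessions])
})
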