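#' Default function-word stoplist
#'
#' Articles, determiners, pronouns, auxiliaries, prepositions, conjunctions
#' and interjections/fillers shipped with the package. Content words
#' (nouns, verbs, adjectives, adverbs) are what remains after removal and
#' are what contributes to response vectors.
#'
#' @param path optional path to a custom stoplist (one word per line, '#'
#'   comments allowed); defaults to the packaged list.
#' @return character vector of lowercase words, with attribute
#'   \code{"md5"} (hash of the source file, logged for reproducibility).
#' @export
defaultStoplist <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "function_words.txt", package = "cohmap")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words <- tolower(trimws(lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]))
  structure(unique(words), md5 = unname(tools::md5sum(path)))
}

#' Tokenize a transcript into content tokens
#'
#' Lowercases, splits on non-alphabetic characters (intra-word apostrophes
#' are kept, so "don't" survives tokenization and can be stoplisted as a
#' unit), drops numerals and punctuation-only tokens, and removes every
#' stoplist word. Token order is preserved for auditability even though
#' the downstream vector composition is order-invariant.
#'
#' @param rawText character(1), the transcript (empty text gives an empty
#'   token vector).
#' @param stoplist character vector of function words to remove; defaults
#'   to [defaultStoplist()].
#' @return character vector of content tokens
#' @examples
#' preprocess("The boy is stealing the cookies.")
#' @export
preprocess <- function(rawText, stoplist = defaultStoplist()) {
  if (length(rawText) == 0L || is.na(rawText) || !nzchar(rawText))
    return(character(0))
  x <- tolower(rawText)
  x <- gsub("[^a-z']+", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks <- gsub("^'+|'+$", "", toks)
  toks <- toks[nzchar(toks) & grepl("[a-z]", toks)]
  toks[!toks %in% stoplist]
}

#' Compose a response vector from content tokens
#'
#' The unweighted mean of the word vectors of all in-vocabulary tokens.
#' By default token instances count (a word occurring twice contributes
#' twice); \code{mode = "type"} averages over distinct words instead.
#' Out-of-vocabulary tokens are skipped silently but counted.
#'
#' @param tokens character vector of content tokens
#' @param space a \linkS4class{SemanticSpace}
#' @param mode "instance" (default) or "type"
#' @return numeric vector of dimension k with attribute \code{"n_oov"}, or
#'   \code{NULL} when no token is in vocabulary.
#' @export
composeResponseVector <- function(space, tokens, mode = c("instance", "type")) {
  mode <- match.arg(mode)
  if (mode == "type") tokens <- unique(tokens)
  idx <- match(tolower(tokens), rownames(space@vectors))
  oov <- sum(is.na(idx))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) return(NULL)
  v <- colMeans(space@vectors[idx, , drop = FALSE])
  attr(v, "n_oov") <- oov
  v
}

#' Construct a ResponseRecord
#'
#' Tokenizes the transcript and composes its response vector in one step.
#'
#' @param participantId,group,task,rawText record fields
#' @param space a \linkS4class{SemanticSpace}
#' @param stoplist function-word list, see [defaultStoplist()]
#' @param mode vector composition mode, see [composeResponseVector()]
#' @return a \linkS4class{ResponseRecord}
#' @export
responseRecord <- function(participantId, group, task, rawText, space,
                           stoplist = defaultStoplist(),
                           mode = c("instance", "type")) {
  toks <- preprocess(rawText, stoplist)
  v <- composeResponseVector(space, toks, match.arg(mode))
  new("ResponseRecord", participantId = as.character(participantId),
      group = group, task = task, rawText = rawText,
      contentTokens = toks,
      responseVector = if (is.null(v)) numeric(0) else as.numeric(v),
      nOov = if (is.null(v)) length(toks) else attr(v, "n_oov"))
}

.hasVector <- function(rec) length(rec@responseVector) > 0L

#' Composite prototype vector for one discourse task
#'
#' The element-wise mean of control participants' response vectors for one
#' task: the prototypical semantic content healthy speakers produce for
#' that stimulus. When scoring a control participant, that participant's
#' own response is excluded (leave-one-out) to keep the prototype
#' independent of the response being scored.
#'
#' @param records list of \linkS4class{ResponseRecord}s (only control
#'   records for the given task with a present vector contribute)
#' @param task character(1), the task
#' @param excludeId participant to exclude, or NULL
#' @return a \linkS4class{PrototypeVector}
#' @export
compositePrototype <- function(records, task, excludeId = NULL) {
  keep <- Filter(function(r)
    r@task == task && r@group == "control" && .hasVector(r) &&
      (is.null(excludeId) || r@participantId != excludeId), records)
  if (length(keep) == 0L)
    stop("no prototype contributors for task '", task, "'")
  m <- do.call(rbind, lapply(keep, function(r) r@responseVector))
  new("PrototypeVector", task = task, vector = colMeans(m),
      nContributors = length(keep),
      excludedId = if (is.null(excludeId)) NA_character_ else excludeId)
}

#' Global coherence: cosine between a response and the prototype
#'
#' The degree to which a response's semantic content conforms to the
#' expected topic, measured as the cosine of the angle between the response
#' vector and the control-derived composite vector. Symmetric in its
#' arguments and invariant to positive rescaling of either vector.
#'
#' @param responseVector numeric vector
#' @param prototype a \linkS4class{PrototypeVector} or numeric vector of
#'   the same dimension
#' @return numeric(1) in [-1, 1]
#' @examples
#' globalCoherence(c(1, 1, 0), c(1, 0, 0))  # 1/sqrt(2)
#' @export
globalCoherence <- function(responseVector, prototype) {
  p <- if (is(prototype, "PrototypeVector")) prototype@vector else prototype
  if (length(responseVector) != length(p))
    stop("vector dimensions differ: ", length(responseVector), " vs ", length(p))
  na <- sqrt(sum(responseVector^2)); nb <- sqrt(sum(p^2))
  if (na == 0 || nb == 0) stop("degenerate vector: zero norm")
  max(-1, min(1, sum(responseVector * p) / (na * nb)))
}

#' Score a cohort of discourse responses
#'
#' Patients are scored against the all-controls prototype for each task;
#' each control is scored against the prototype excluding itself. The
#' per-participant composite is the mean of that participant's present
#' per-task scores. Deficit flags mark scores more than 1.5 SD below the
#' control mean for the task (see [flagDeficit()]); controls' leave-one-out
#' scores define the reference distribution. Participants with no scorable
#' response in any task are dropped with a warning.
#'
#' @param records list of \linkS4class{ResponseRecord}s
#' @return a \linkS4class{CoherenceTable}
#' @export
scoreCohort <- function(records) {
  stopifnot(length(records) > 0L)
  tasks <- unique(vapply(records, function(r) r@task, character(1)))
  ids <- unique(vapply(records, function(r) r@participantId, character(1)))
  grp <- vapply(ids, function(id) {
    g <- unique(vapply(Filter(function(r) r@participantId == id, records),
                       function(r) r@group, character(1)))
    if (length(g) != 1L) stop("participant ", id, " appears in both groups")
    g
  }, character(1))

  for (tk in tasks) {
    nc <- sum(vapply(records, function(r)
      r@task == tk && r@group == "control" && .hasVector(r), logical(1)))
    if (nc < 2L)
      stop("task '", tk, "' has ", nc,
           " scorable control response(s); at least 2 required")
  }

  rows <- do.call(rbind, lapply(tasks, function(tk) {
    proto_all <- compositePrototype(records, tk)
    do.call(rbind, lapply(ids, function(id) {
      rec <- Filter(function(r) r@participantId == id && r@task == tk, records)
      score <- NA_real_
      if (length(rec) == 1L && .hasVector(rec[[1]])) {
        proto <- if (grp[[id]] == "control")
          compositePrototype(records, tk, excludeId = id) else proto_all
        score <- globalCoherence(rec[[1]]@responseVector, proto)
      }
      data.frame(participant_id = id, group = grp[[id]], task = tk,
                 global_coherence = score, stringsAsFactors = FALSE)
    }))
  }))

  # deficit flags against the control score distribution per task
  rows$deficit <- NA
  for (tk in tasks) {
    ctl <- rows$global_coherence[rows$task == tk & rows$group == "control"]
    ctl <- ctl[!is.na(ctl)]
    sel <- rows$task == tk & !is.na(rows$global_coherence)
    if (length(ctl) >= 2L)
      rows$deficit[sel] <- vapply(rows$global_coherence[sel], flagDeficit,
                                  logical(1), controlScores = ctl)
  }

  comp <- do.call(rbind, lapply(ids, function(id) {
    s <- rows$global_coherence[rows$participant_id == id]
    data.frame(participant_id = id, group = grp[[id]],
               composite_coherence = if (all(is.na(s))) NA_real_
                                     else mean(s, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))

  drop <- comp$participant_id[is.na(comp$composite_coherence)]
  if (length(drop)) {
    warning("dropped ", length(drop),
            " participant(s) with no scorable response in any task: ",
            paste(drop, collapse = ", "))
    rows <- rows[!rows$participant_id %in% drop, , drop = FALSE]
    comp <- comp[!comp$participant_id %in% drop, , drop = FALSE]
  }
  rownames(rows) <- rownames(comp) <- NULL
  new("CoherenceTable", scores = rows, composite = comp)
}

#' Flag a coherence deficit
#'
#' A score is a deficit when it falls strictly more than 1.5 sample
#' standard deviations below the control-group mean for the task:
#' \code{score < mean(controls) - 1.5 * sd(controls)}. A score exactly at
#' the cutoff is not flagged.
#'
#' @param score numeric(1)
#' @param controlScores numeric vector of control scores for the same task
#'   (length >= 2 so the SD is defined; n-1 denominator)
#' @return logical(1)
#' @examples
#' flagDeficit(0.65, controlScores = c(0.80, 0.86, 0.92))
#' @export
flagDeficit <- function(score, controlScores) {
  if (length(controlScores) < 2L)
    stop("SD undefined: need at least 2 control scores")
  score < mean(controlScores) - 1.5 * stats::sd(controlScores)
}

#' Deficit cutoff for a set of control scores
#'
#' @param controlScores numeric vector (length >= 2)
#' @return the cutoff \code{mean - 1.5 * sd}
#' @export
deficitCutoff <- function(controlScores) {
  if (length(controlScores) < 2L)
    stop("SD undefined: need at least 2 control scores")
  mean(controlScores) - 1.5 * stats::sd(controlScores)
}
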