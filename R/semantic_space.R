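#' Build a latent-semantic-analysis word-vector space
#'
#' Constructs a term-document matrix from a tokenized corpus, applies the
#' chosen weighting, factors it by truncated SVD and retains each term's
#' k-dimensional representation (rows of U scaled by the singular values,
#' then L2-normalized). The sign ambiguity of each singular vector is fixed
#' deterministically by making its largest-magnitude entry positive, so the
#' result is reproducible and invariant to document order.
#'
#' Weightings:
#' \describe{
#'   \item{log-entropy}{\code{log2(1 + tf) * (1 + sum_j p_ij log2 p_ij / log2 N)},
#'     the classical LSA weighting; down-weights terms spread evenly over
#'     documents.}
#'   \item{tf-idf}{\code{tf * log(N / df)}.}
#'   \item{raw}{untransformed counts.}
#' }
#'
#' Terms whose weighted row is identically zero (e.g. a term occurring
#' uniformly in every document under log-entropy) are dropped with a
#' warning, since a zero vector has no direction to compare.
#'
#' @param documents list of character vectors (one tokenized document each),
#'   or a character vector of file paths / a directory of UTF-8 .txt files
#'   (one document per file; tokenized with [preprocess()] using an empty
#'   stoplist).
#' @param k integer, dimensionality of the space (default 300; capped
#'   requests error with the attainable maximum).
#' @param weighting one of "log-entropy", "tf-idf", "raw".
#' @param minCount integer, minimum total corpus frequency for a term to
#'   enter the vocabulary (default 2).
#'
#' @return a \linkS4class{SemanticSpace}
#' @examples
#' docs <- list(c("tea", "kettle", "cup"), c("tea", "cup", "water"),
#'              c("boy", "cookie", "jar"), c("boy", "jar", "stool"))
#' sp <- buildSpace(docs, k = 2, weighting = "raw", minCount = 1)
#' getVector(sp, "tea")
#' @export
buildSpace <- function(documents, k = 300L,
                       weighting = c("log-entropy", "tf-idf", "raw"),
                       minCount = 2L) {
  weighting <- match.arg(weighting)
  if (is.character(documents)) documents <- readCorpusDir(documents)
  if (!is.list(documents) || length(documents) == 0L)
    stop("empty corpus")
  if (length(documents) < 2L)
    stop("need at least 2 documents, got ", length(documents))
  documents <- lapply(documents, function(d) tolower(as.character(d)))

  tdm <- .termDocumentMatrix(documents, minCount)
  if (nrow(tdm) == 0L)
    stop("empty corpus: no term passes minCount = ", minCount)
  w <- .weightTdm(tdm, weighting)
  zero <- rowSums(w != 0) == 0L
  if (any(zero)) {
    warning(sum(zero), " term(s) with all-zero weighted profile dropped")
    w <- w[!zero, , drop = FALSE]
  }
  kmax <- min(dim(w))
  if (k > kmax)
    stop("k = ", k, " exceeds the attainable maximum ", kmax,
         " (min of #documents and #vocabulary)")
  fac <- .lsaFactor(w, k)
  vec <- fac$u %*% diag(fac$d, nrow = k)
  vec <- vec / sqrt(rowSums(vec^2))
  rownames(vec) <- rownames(w)
  new("SemanticSpace", vectors = vec,
      provenance = sprintf("LSA: %d documents, %d terms, k=%d, %s weighting, minCount=%d",
                           ncol(w), nrow(w), k, weighting, minCount))
}

# terms x documents count matrix, vocabulary sorted for order invariance
.termDocumentMatrix <- function(documents, minCount) {
  all <- unlist(documents, use.names = FALSE)
  keep <- names(which(table(all) >= minCount))
  vocab <- sort(keep)
  m <- matrix(0, nrow = length(vocab), ncol = length(documents),
              dimnames = list(vocab, NULL))
  for (j in seq_along(documents)) {
    tab <- table(documents[[j]])
    tab <- tab[names(tab) %in% vocab]
    if (length(tab)) m[names(tab), j] <- as.numeric(tab)
  }
  m
}

.weightTdm <- function(tdm, weighting) {
  switch(weighting,
    raw = tdm,
    `tf-idf` = {
      df <- rowSums(tdm > 0)
      tdm * log(ncol(tdm) / df)
    },
    `log-entropy` = {
      n <- ncol(tdm)
      gf <- rowSums(tdm)
      p <- tdm / gf
      plogp <- ifelse(p > 0, p * log2(p), 0)
      gw <- 1 + rowSums(plogp) / log2(n)
      log2(1 + tdm) * gw
    })
}

# truncated SVD with deterministic sign convention: the largest-magnitude
# entry of each left singular vector is made positive (ties broken by the
# first such entry)
.lsaFactor <- function(w, k) {
  s <- svd(w, nu = k, nv = k)
  for (j in seq_len(k)) {
    i <- which.max(abs(s$u[, j]))
    if (s$u[i, j] < 0) {
      s$u[, j] <- -s$u[, j]
      s$v[, j] <- -s$v[, j]
    }
  }
  list(u = s$u, d = s$d[seq_len(k)], v = s$v)
}

#' Read a corpus directory
#'
#' @param path directory of UTF-8 .txt files (one document each) or a
#'   character vector of file paths.
#' @return list of token vectors
#' @export
readCorpusDir <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path))
    list.files(path, pattern = "\\.txt$", full.names = TRUE) else path
  if (length(files) == 0L) stop("empty corpus")
  lapply(files, function(f)
    preprocess(paste(readLines(f, encoding = "UTF-8", warn = FALSE),
                     collapse = " "), stoplist = character(0)))
}

#' Save / load a semantic space as TSV
#'
#' The format is a header line \code{#k=<int>} followed by one row per word:
#' the word, then k floats at full precision (17 significant digits), tab
#' separated. \code{loadSpace(saveSpace(x))} reproduces the vectors
#' bit-exactly.
#'
#' @param space a \linkS4class{SemanticSpace}
#' @param path file path
#' @return \code{saveSpace} returns \code{path} invisibly; \code{loadSpace}
#'   returns a \linkS4class{SemanticSpace}.
#' @export
saveSpace <- function(space, path) {
  stopifnot(is(space, "SemanticSpace"))
  v <- space@vectors
  rows <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(sprintf("#k=%d", ncol(v)), rows), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname saveSpace
#' @export
loadSpace <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no vocabulary: file is empty")
  header <- lines[[1]]
  if (!grepl("^#k=[0-9]+$", header))
    stop("malformed header at line 1: expected '#k=<int>', got '", header, "'")
  k <- as.integer(sub("^#k=", "", header))
  body <- lines[-1]
  if (length(body) == 0L) stop("no vocabulary: file has a header but no rows")
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != k + 1L)
  if (length(bad))
    stop("malformed row at line ", bad[1] + 1L, ": expected ", k + 1L,
         " fields, got ", nf[bad[1]])
  words <- vapply(parts, `[[`, character(1), 1L)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(k)))
  if (k == 1L) vec <- matrix(vec, ncol = 1L)
  if (any(is.na(vec))) stop("non-numeric vector entries in space file")
  rownames(vec) <- words
  new("SemanticSpace", vectors = vec,
      provenance = sprintf("loaded from %s", path))
}

#' Look up a word vector
#'
#' Case-insensitive lookup: the query is lowercased before matching. Unknown
#' words return \code{NULL} (the missing-marker) and never raise.
#'
#' @param space a \linkS4class{SemanticSpace}
#' @param word character(1)
#' @return numeric vector of length k, or \code{NULL} if the word is out of
#'   vocabulary.
#' @export
getVector <- function(space, word) {
  stopifnot(is(space, "SemanticSpace"))
  w <- tolower(word)
  i <- match(w, rownames(space@vectors))
  if (is.na(i)) NULL else space@vectors[i, ]
}
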