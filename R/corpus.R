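# Corpus measurement, the affine time-vs-size workload model, and the
# synthetic corpus generator.

#' Measure a corpus
#'
#' Builds a \code{\link{Corpus}} from PubTator files or in-memory documents.
#' The workload proxy of a file is the exact character count of the
#' composite text of every document it contains (a multi-document file
#' contributes the sum). Input order is preserved.
#'
#' @param x a character vector of PubTator file paths, or a list of
#'   \code{Document} / \code{AnnotatedDocument} objects.
#' @return A \code{Corpus}; file ids are the paths (for path input) or the
#'   document ids (for document input).
#' @export
measureCorpus <- function(x) {
  if (is.character(x)) {
    missing <- x[!file.exists(x)]
    if (length(missing))
      stop("cannot read corpus file ", dQuote(missing[1L], FALSE),
           call. = FALSE)
    sizes <- vapply(x, function(p) {
      docs <- readPubTator(p)
      sum(vapply(docs, function(d) nchar(compositeText(d)), numeric(1)))
    }, numeric(1))
    return(Corpus(x, unname(sizes)))
  }
  if (is.list(x)) {
    ids <- vapply(x, docId, character(1))
    sizes <- vapply(x, function(d) nchar(compositeText(d)), numeric(1))
    return(Corpus(ids, sizes))
  }
  stop("x must be a character vector of paths or a list of documents")
}

#' Read and write corpus manifests
#'
#' A manifest is a two-column tab-separated file, one line per corpus file:
#' file id, size in characters. Lines starting with \code{#} are comments.
#'
#' @param path manifest file path.
#' @return \code{readManifest} returns a \code{Corpus};
#'   \code{writeManifest} invisibly returns \code{path}.
#' @export
readManifest <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#",
                          col.names = c("file_id", "size"),
                          colClasses = c("character", "numeric"))
  Corpus(df$file_id, df$size)
}

#' @rdname readManifest
#' @param corpus a \code{Corpus} to serialise.
#' @export
writeManifest <- function(corpus, path) {
  utils::write.table(
    data.frame(file_id = fileIds(corpus), size = unname(sizeChars(corpus))),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Fit the affine time-versus-size workload model
#'
#' Ordinary (unweighted) least squares of observed processing seconds on
#' input size. Document-level NER cost is empirically close to proportional
#' to input length; the intercept absorbs fixed per-run overhead such as
#' model loading.
#'
#' @param points a data.frame (or 2-column matrix) with columns
#'   \code{size} and \code{seconds}; at least two points with at least two
#'   distinct sizes.
#' @param sizeUnit unit of the \code{size} column, \code{"chars"} or
#'   \code{"MB"}; recorded in the returned model so that predictions on
#'   character counts convert correctly (1 MB = 10^6 characters).
#' @return A \code{\link{WorkloadModel}}.
#' @examples
#' m <- fitTimeModel(data.frame(size = c(1, 2), seconds = c(10, 20)))
#' modelSlope(m)
#' @export
fitTimeModel <- function(points, sizeUnit = "chars") {
  points <- as.data.frame(points)
  if (ncol(points) < 2L) stop("points must have columns size and seconds")
  if (!all(c("size", "seconds") %in% names(points)))
    names(points)[1:2] <- c("size", "seconds")
  if (nrow(points) < 2L)
    stop("need at least two timing points to fit the model", call. = FALSE)
  if (length(unique(points$size)) < 2L)
    stop("degenerate fit: all sizes are equal", call. = FALSE)
  fit <- stats::lm(seconds ~ size, data = points)
  co <- stats::coef(fit)
  WorkloadModel(intercept = unname(co[1L]), slope = unname(co[2L]),
                sizeUnit = sizeUnit)
}

#' Read timing points from a delimited file
#'
#' Two whitespace- or tab-separated columns per line: size, seconds.
#' \code{#} comments allowed.
#'
#' @param path file path.
#' @return A data.frame with columns \code{size} and \code{seconds}.
#' @export
readTimingPoints <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("size", "seconds"),
                          colClasses = "numeric")
  df
}

#' Predict per-file processing cost
#'
#' \code{intercept + slope * size} in the model's size unit; sizes are
#' always supplied in characters and converted when the model was fitted on
#' megabytes (1 MB = 10^6 characters). Strictly increasing in size.
#'
#' @param model a \code{\link{WorkloadModel}}.
#' @param size size(s) in characters: a numeric vector, a
#'   \code{\link{Corpus}} (all its files), or a single \code{Document}.
#' @return Predicted seconds, named by file id when a corpus is given.
#' @export
predictCost <- function(model, size) {
  if (is(size, "Corpus")) size <- sizeChars(size)
  else if (is(size, "Document")) size <- nchar(compositeText(size))
  u <- if (sizeUnit(model) == "MB") size / 1e6 else size
  modelIntercept(model) + modelSlope(model) * u
}

#' Serialise a workload model
#'
#' Plain-text key=value file with keys \code{intercept}, \code{slope},
#' \code{size_unit}.
#'
#' @param model a \code{WorkloadModel}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeWorkloadModel <- function(model, path) {
  writeLines(c(sprintf("intercept=%.10g", modelIntercept(model)),
               sprintf("slope=%.10g", modelSlope(model)),
               sprintf("size_unit=%s", sizeUnit(model))), path)
  invisible(path)
}

#' @rdname writeWorkloadModel
#' @export
readWorkloadModel <- function(path) {
  kv <- readKeyValue(path)
  WorkloadModel(intercept = as.numeric(kv[["intercept"]]),
                slope = as.numeric(kv[["slope"]]),
                sizeUnit = kv[["size_unit"]])
}

# ---- synthetic corpora ---------------------------------------------------

.defaultParams <- list(
  uniform = list(min = 100, max = 10000),
  lognormal = list(meanlog = log(5000), sdlog = 1),
  pareto = list(xmin = 1000, alpha = 1.5),
  twopoint = list(small = 500, large = 50000, pLarge = 0.05))

#' Generate a synthetic corpus
#'
#' Draws per-file sizes i.i.d. from a chosen distribution and rounds them to
#' positive integers. The heavy-tailed settings (\code{pareto},
#' \code{twopoint}) emulate real literature corpora in which a few full-text
#' articles are extremely long while most are short — the regime in which
#' naive schedulers lose efficiency.
#'
#' Defaults: uniform on [100, 10000]; lognormal with meanlog log(5000),
#' sdlog 1; Pareto with scale 1000 and tail index 1.5; two-point with sizes
#' 500/50000 and 5\% large files.
#'
#' @param nFiles number of files, >= 0.
#' @param distribution one of \code{"uniform"}, \code{"lognormal"},
#'   \code{"pareto"}, \code{"twopoint"}.
#' @param params named list overriding the distribution's default
#'   parameters (see Details).
#' @param seed integer seed; the same seed always yields the same corpus.
#' @return A \code{\link{Corpus}} with file ids \code{doc00001, ...}.
#' @examples
#' generateCorpus(5, "uniform", seed = 1)
#' @export
generateCorpus <- function(nFiles,
                           distribution = c("pareto", "uniform",
                                            "lognormal", "twopoint"),
                           params = list(), seed) {
  distribution <- match.arg(distribution)
  if (missing(seed)) stop("a seed is required for reproducibility")
  if (nFiles < 0) stop("nFiles must be >= 0")
  p <- utils::modifyList(.defaultParams[[distribution]], params)
  bad <- switch(distribution,
    uniform = !(p$min > 0 && p$max >= p$min),
    lognormal = !(is.finite(p$meanlog) && p$sdlog > 0),
    pareto = !(p$xmin > 0 && p$alpha > 0),
    twopoint = !(p$small > 0 && p$large > 0 &&
                   p$pLarge >= 0 && p$pLarge <= 1))
  if (bad) stop("invalid parameters for the ", distribution,
                " distribution", call. = FALSE)
  if (nFiles == 0) return(Corpus())
  sizes <- withSeed(seed, switch(distribution,
    uniform = stats::runif(nFiles, p$min, p$max),
    lognormal = stats::rlnorm(nFiles, p$meanlog, p$sdlog),
    pareto = p$xmin * (1 - stats::runif(nFiles))^(-1 / p$alpha),
    twopoint = ifelse(stats::runif(nFiles) < p$pLarge, p$large, p$small)))
  Corpus(sprintf("doc%05d", seq_len(nFiles)), pmax(1, round(sizes)))
}

.fillerWords <- c("the", "of", "in", "and", "with", "we", "report", "a",
                  "novel", "variant", "patients", "tumor", "samples",
                  "expression", "analysis", "observed", "cohort", "cells",
                  "pathway", "signaling", "treatment", "response", "study")

.entityWords <- c("BRAF", "KRAS", "EGFR", "TP53", "BRCA1", "PTEN", "MYC",
                  "melanoma", "leukemia", "lymphoma", "glioblastoma",
                  "sarcoma", "breast cancer", "lung cancer",
                  "V600E", "G12D", "T790M", "R175H", "c.123A>G", "c.35G>T")

#' Materialise a synthetic corpus as PubTator files
#'
#' Writes one single-document PubTator file per corpus entry into
#' \code{dir}, with random text whose composite length (title + one space +
#' body) is exactly the recorded size. With \code{vocabulary = "alnum"} the
#' text is featureless alphanumeric noise; with \code{"biomedical"} it is
#' built from a small word pool salted with gene, disease and mutation
#' mentions, so that demonstration annotators produce non-empty output on
#' synthetic corpora.
#'
#' @param corpus a \code{\link{Corpus}} (typically from
#'   \code{\link{generateCorpus}}).
#' @param dir output directory (created if absent).
#' @param seed integer seed for the random text.
#' @param vocabulary \code{"alnum"} or \code{"biomedical"}.
#' @return Character vector of the written file paths, named by file id.
#' @export
materializeCorpus <- function(corpus, dir, seed,
                              vocabulary = c("alnum", "biomedical")) {
  vocabulary <- match.arg(vocabulary)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  alphabet <- c(letters, LETTERS, 0:9)
  randText <- function(len) {
    if (len <= 0) return("")
    if (vocabulary == "alnum")
      return(paste(sample(alphabet, len, replace = TRUE), collapse = ""))
    pool <- c(.fillerWords, sample(.entityWords, 8))
    words <- sample(pool, ceiling(len / 3), replace = TRUE)
    out <- paste(words, collapse = " ")
    while (nchar(out) < len)
      out <- paste(out, paste(sample(pool, 10, replace = TRUE),
                              collapse = " "))
    substr(out, 1L, len)
  }
  withSeed(seed, {
    paths <- vapply(seq_len(nFiles(corpus)), function(k) {
      id <- fileIds(corpus)[k]
      s <- unname(sizeChars(corpus))[k]
      if (s <= 2) {
        title <- randText(s); body <- ""
      } else {
        tl <- min(30L, floor(s / 2))
        title <- randText(tl)
        body <- randText(s - tl - 1L)  # one composite-text separator char
      }
      path <- file.path(dir, paste0(id, ".txt"))
      writePubTator(list(Document(id, title, body)), path)
      path
    }, character(1))
    stats::setNames(paths, fileIds(corpus))
  })
}
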