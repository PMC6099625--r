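#' @import methods
NULL

# ---- annotation table ----------------------------------------------------

.annotationColumns <- c("doc_id", "start", "end", "mention", "type", "concept")

#' Construct an annotation table
#'
#' Annotations are kept as an ordinary data.frame with one row per entity
#' mention and a fixed column set: \code{doc_id}, \code{start} (0-based,
#' inclusive), \code{end} (0-based, exclusive), \code{mention}, \code{type}
#' and \code{concept} (empty string when the mention is not normalised to a
#' concept identifier). Offsets index the composite text of the document,
#' i.e. title, one space, body (see \code{\link{compositeText}}).
#'
#' @param doc_id,mention,type,concept character vectors (recycled to a common
#'   length); \code{concept} defaults to empty strings.
#' @param start,end integer vectors of 0-based character offsets,
#'   end-exclusive.
#' @return A data.frame with the six annotation columns, sorted by
#'   \code{(start, end, type)}.
#' @export
annotationTable <- function(doc_id = character(), start = integer(),
                            end = integer(), mention = character(),
                            type = character(), concept = "") {
  n <- max(length(doc_id), length(start), length(end),
           length(mention), length(type))
  if (n == 0L) {
    return(data.frame(doc_id = character(), start = integer(),
                      end = integer(), mention = character(),
                      type = character(), concept = character(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(doc_id = rep_len(as.character(doc_id), n),
                   start = rep_len(as.integer(start), n),
                   end = rep_len(as.integer(end), n),
                   mention = rep_len(as.character(mention), n),
                   type = rep_len(as.character(type), n),
                   concept = rep_len(as.character(concept), n),
                   stringsAsFactors = FALSE)
  df <- df[order(df$start, df$end, df$type, df$concept), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.checkAnnotationTable <- function(ann) {
  if (!is.data.frame(ann)) return("annotations must be a data.frame")
  if (!identical(names(ann), .annotationColumns))
    return(sprintf("annotation columns must be %s",
                   paste(.annotationColumns, collapse = ", ")))
  if (nrow(ann) == 0L) return(TRUE)
  if (any(is.na(ann$start)) || any(is.na(ann$end)))
    return("annotation offsets must not be NA")
  if (any(ann$start < 0L) || any(ann$end <= ann$start))
    return("annotation offsets must satisfy 0 <= start < end")
  if (any(!nzchar(ann$type))) return("entity type must be non-empty")
  TRUE
}

# ---- documents -----------------------------------------------------------

#' @rdname Document
#' @export
setClass("Document",
         representation(docId = "character", title = "character",
                        body = "character"),
         prototype(docId = NA_character_, title = "", body = ""))

setValidity("Document", function(object) {
  msgs <- character()
  if (length(object@docId) != 1L || is.na(object@docId) ||
      !nzchar(object@docId))
    msgs <- c(msgs, "docId must be a single non-empty string")
  else if (grepl("[|\t\r\n]", object@docId))
    msgs <- c(msgs, "docId must not contain '|', tab or newline")
  if (length(object@title) != 1L || is.na(object@title))
    msgs <- c(msgs, "title must be a single string")
  if (length(object@body) != 1L || is.na(object@body))
    msgs <- c(msgs, "body must be a single string")
  if (length(msgs) == 0L &&
      any(grepl("[\r\n]", c(object@title, object@body))))
    msgs <- c(msgs, "title/body must not contain newlines")
  if (length(msgs)) msgs else TRUE
})

.flattenLine <- function(x) {
  # the line-oriented exchange format cannot represent newlines
  gsub("[\r\n]+", " ", x)
}

#' Document: one article
#'
#' A \code{Document} holds one article: an identifier (a PMID or a synthetic
#' id), its title, and its body (the abstract, or the abstract followed by
#' the full text). Newlines in title or body are replaced by single spaces
#' at construction, because the PubTator exchange format is line-oriented.
#'
#' @param docId single non-empty string without \code{"|"}, tab or newline.
#' @param title,body single strings; \code{body} may be empty.
#' @return A \code{Document} object.
#' @examples
#' d <- Document("26094", "BRAF V600E in melanoma.",
#'               "We report the V600E mutation.")
#' compositeText(d)
#' @export
Document <- function(docId, title, body = "") {
  new("Document", docId = as.character(docId),
      title = .flattenLine(as.character(title)),
      body = .flattenLine(as.character(body)))
}

#' @rdname AnnotatedDocument
#' @export
setClass("AnnotatedDocument",
         representation(document = "Document", annotations = "data.frame"),
         prototype(annotations = annotationTable()))

setValidity("AnnotatedDocument", function(object) {
  chk <- .checkAnnotationTable(object@annotations)
  if (!isTRUE(chk)) return(chk)
  ann <- object@annotations
  if (nrow(ann) == 0L) return(TRUE)
  if (!all(ann$doc_id == object@document@docId))
    return("all annotation doc_ids must equal the document id")
  comp <- compositeText(object@document)
  bad <- which(ann$end > nchar(comp) |
                 substring(comp, ann$start + 1L, ann$end) != ann$mention)
  if (length(bad))
    return(sprintf(
      "annotation %d: mention %s does not match composite text at [%d,%d)",
      bad[1L], dQuote(ann$mention[bad[1L]], FALSE),
      ann$start[bad[1L]], ann$end[bad[1L]]))
  TRUE
})

#' AnnotatedDocument: a document plus its entity annotations
#'
#' Couples a \code{\link{Document}} with an annotation table (see
#' \code{\link{annotationTable}}). Every annotation is validated against the
#' document's composite text: the \code{mention} string must equal the
#' substring its offsets index.
#'
#' @param document a \code{Document}.
#' @param annotations annotation data.frame; defaults to none.
#' @return An \code{AnnotatedDocument}.
#' @export
AnnotatedDocument <- function(document, annotations = annotationTable()) {
  if (nrow(annotations)) {
    annotations <- annotations[order(annotations$start, annotations$end,
                                     annotations$type, annotations$concept),
                               , drop = FALSE]
    rownames(annotations) <- NULL
  }
  new("AnnotatedDocument", document = document, annotations = annotations)
}

# ---- corpus --------------------------------------------------------------

#' @rdname Corpus
#' @export
setClass("Corpus",
         representation(fileId = "character", sizeChars = "numeric"))

setValidity("Corpus", function(object) {
  if (length(object@fileId) != length(object@sizeChars))
    return("fileId and sizeChars must have equal length")
  if (anyDuplicated(object@fileId))
    return("file ids must be unique within a corpus")
  if (length(object@sizeChars) &&
      (any(is.na(object@sizeChars)) || any(object@sizeChars < 0)))
    return("sizes must be non-negative")
  TRUE
})

#' Corpus: an ordered set of files to be scheduled
#'
#' A \code{Corpus} records, for each input file, its identifier (typically a
#' path or document id) and its workload proxy: the character count of its
#' composite text. Character count, not byte count, is the proxy because the
#' processing time of document-level NER tools grows with text length.
#'
#' @param fileId character vector of unique file identifiers.
#' @param sizeChars non-negative numeric vector of character counts.
#' @return A \code{Corpus}.
#' @export
Corpus <- function(fileId = character(), sizeChars = numeric()) {
  new("Corpus", fileId = as.character(fileId),
      sizeChars = as.numeric(sizeChars))
}

# ---- workload model ------------------------------------------------------

#' @rdname WorkloadModel
#' @export
setClass("WorkloadModel",
         representation(intercept = "numeric", slope = "numeric",
                        sizeUnit = "character"),
         prototype(intercept = 0, slope = 1, sizeUnit = "chars"))

setValidity("WorkloadModel", function(object) {
  if (length(object@slope) != 1L || is.na(object@slope) ||
      object@slope <= 0)
    return("slope must be a single positive number")
  if (length(object@intercept) != 1L || is.na(object@intercept))
    return("intercept must be a single number")
  if (!object@sizeUnit %in% c("chars", "MB"))
    return("sizeUnit must be 'chars' or 'MB'")
  TRUE
})

#' WorkloadModel: affine time-versus-size model
#'
#' Predicted processing time of a file is
#' \code{intercept + slope * size}, where \code{size} is measured in the
#' model's own unit (\code{"chars"} or \code{"MB"}; 1 MB is taken as 10^6
#' characters for conversion). The affine form reflects the empirical
#' observation that document-level NER cost is approximately proportional to
#' input length, with a per-file overhead absorbed by the intercept.
#'
#' @param intercept seconds at zero size (per-file overhead); normally
#'   non-negative. A negative value (possible when fitted to noisy data) is
#'   accepted with a warning.
#' @param slope seconds per size unit; must be positive.
#' @param sizeUnit \code{"chars"} or \code{"MB"}.
#' @return A \code{WorkloadModel}.
#' @export
WorkloadModel <- function(intercept = 0, slope = 1, sizeUnit = "chars") {
  if (!is.na(intercept) && intercept < 0)
    warning("negative intercept: predicted costs of small files may be ",
            "negative", call. = FALSE)
  new("WorkloadModel", intercept = as.numeric(intercept),
      slope = as.numeric(slope), sizeUnit = sizeUnit)
}

#' Identity workload model
#'
#' The default cost model used by the schedulers when no timing data is
#' available: cost equals raw character count (slope 1, intercept 0).
#' Scheduling decisions are invariant to a uniform positive scaling of
#' costs, so this model yields the same assignments as any zero-intercept
#' model.
#'
#' @return A \code{WorkloadModel} with intercept 0, slope 1, unit "chars".
#' @export
identityModel <- function() WorkloadModel(0, 1, "chars")

# ---- assignment ----------------------------------------------------------

#' @rdname Assignment
#' @export
setClass("Assignment",
         representation(nProcs = "integer", groups = "list"))

setValidity("Assignment", function(object) {
  if (length(object@nProcs) != 1L || is.na(object@nProcs) ||
      object@nProcs < 1L)
    return("nProcs must be a single integer >= 1")
  if (length(object@groups) != object@nProcs)
    return("groups must have length nProcs")
  if (!all(vapply(object@groups, is.character, logical(1))))
    return("each group must be a character vector of file ids")
  ids <- unlist(object@groups, use.names = FALSE)
  if (anyDuplicated(ids))
    return("a file id appears in more than one group")
  TRUE
})

#' Assignment: a partition of corpus files across worker ranks
#'
#' Group \code{i} (1-based list position) holds the file ids assigned to
#' worker rank \code{i - 1}. Every corpus file appears in exactly one group;
#' empty groups are permitted (more ranks than files).
#'
#' @param nProcs integer number of worker ranks, >= 1.
#' @param groups list of \code{nProcs} character vectors of file ids.
#' @return An \code{Assignment}.
#' @export
Assignment <- function(nProcs, groups) {
  new("Assignment", nProcs = as.integer(nProcs), groups = groups)
}

# ---- run metrics ---------------------------------------------------------

#' @rdname RunMetrics
#' @export
setClass("RunMetrics",
         representation(perProcSeconds = "numeric", maxSeconds = "numeric",
                        meanSeconds = "numeric", lbeRatio = "numeric"))

setValidity("RunMetrics", function(object) {
  p <- object@perProcSeconds
  if (!length(p) || any(is.na(p)) || any(p < 0))
    return("per-process times must be non-negative and non-empty")
  if (!isTRUE(all.equal(object@maxSeconds, max(p))))
    return("maxSeconds must equal max(perProcSeconds)")
  if (!isTRUE(all.equal(object@meanSeconds, mean(p))))
    return("meanSeconds must equal mean(perProcSeconds)")
  if (object@lbeRatio > 1 + 1e-12 || object@lbeRatio <= 0)
    return("LBE must lie in (0, 1]")
  TRUE
})

# ---- plugins -------------------------------------------------------------

#' @rdname PluginSpec
#' @export
setClass("PluginSpec",
         representation(name = "character", initCostHint = "numeric",
                        maxProcsPerNode = "integer",
                        entityTypes = "character"),
         prototype(initCostHint = 0, maxProcsPerNode = 1L))

setValidity("PluginSpec", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("plugin name must be a single non-empty string")
  if (object@initCostHint < 0) return("initCostHint must be >= 0")
  if (object@maxProcsPerNode < 1L) return("maxProcsPerNode must be >= 1")
  TRUE
})

#' PluginSpec: metadata describing an annotator plugin
#'
#' \code{maxProcsPerNode} records how many concurrent instances of the
#' plugin one compute node can host; memory-hungry NER tools (which load
#' multi-gigabyte dictionaries at startup) cap this well below the node's
#' core count. The cap is advisory here: the engine warns when a run exceeds
#' it but cannot observe physical node placement portably.
#'
#' @param name unique plugin name.
#' @param initCostHint expected one-time initialisation cost per worker, in
#'   seconds.
#' @param maxProcsPerNode advisory concurrency cap per node.
#' @param entityTypes entity types the plugin emits.
#' @return A \code{PluginSpec}.
#' @export
PluginSpec <- function(name, initCostHint = 0, maxProcsPerNode = 1L,
                       entityTypes = character()) {
  new("PluginSpec", name = as.character(name),
      initCostHint = as.numeric(initCostHint),
      maxProcsPerNode = as.integer(maxProcsPerNode),
      entityTypes = as.character(entityTypes))
}

#' @rdname Plugin
#' @export
setClass("Plugin",
         representation(spec = "PluginSpec", init = "function",
                        annotate = "function"))

#' Plugin: an annotator with per-worker initialisation
#'
#' The annotator contract has two steps: \code{init()}, invoked exactly once
#' per worker before any document and returning an opaque state object, and
#' \code{annotate(doc, state)}, mapping a \code{\link{Document}} plus that
#' state to an annotation table. Annotators must be pure with respect to
#' documents: the same document always yields the same annotations.
#'
#' @param spec a \code{\link{PluginSpec}}.
#' @param annotate function of \code{(doc, state)} returning an annotation
#'   data.frame.
#' @param init function of no arguments returning the per-worker state;
#'   defaults to returning \code{NULL}.
#' @return A \code{Plugin}.
#' @export
Plugin <- function(spec, annotate, init = function() NULL) {
  new("Plugin", spec = spec, init = init, annotate = annotate)
}

# ---- time log ------------------------------------------------------------

#' @rdname TimeLog
#' @export
setClass("TimeLog",
         representation(perFile = "data.frame", perRankInit = "data.frame",
                        failures = "data.frame"))

setValidity("TimeLog", function(object) {
  pf <- object@perFile
  if (!all(c("file_id", "rank", "plugin", "seconds") %in% names(pf)))
    return("perFile must have columns file_id, rank, plugin, seconds")
  if (!all(c("rank", "plugin", "seconds") %in% names(object@perRankInit)))
    return("perRankInit must have columns rank, plugin, seconds")
  if (nrow(pf) && anyDuplicated(pf[, c("file_id", "plugin")]))
    return("each (file, plugin) pair may appear at most once")
  if ((nrow(pf) && any(pf$seconds < 0)) ||
      (nrow(object@perRankInit) && any(object@perRankInit$seconds < 0)))
    return("logged seconds must be non-negative")
  TRUE
})

#' TimeLog: per-file and per-rank execution times
#'
#' Produced by \code{\link{runEngine}}: one \code{perFile} row per executed
#' (file, plugin) pair, one \code{perRankInit} row per (rank, plugin)
#' initialisation, and one \code{failures} row per file that could not be
#' processed.
#'
#' @param perFile data.frame with columns file_id, rank, plugin, seconds.
#' @param perRankInit data.frame with columns rank, plugin, seconds.
#' @param failures data.frame with columns file_id, rank, message.
#' @return A \code{TimeLog}.
#' @export
TimeLog <- function(perFile = data.frame(file_id = character(),
                                         rank = integer(),
                                         plugin = character(),
                                         seconds = numeric(),
                                         stringsAsFactors = FALSE),
                    perRankInit = data.frame(rank = integer(),
                                             plugin = character(),
                                             seconds = numeric(),
                                             stringsAsFactors = FALSE),
                    failures = data.frame(file_id = character(),
                                          rank = integer(),
                                          message = character(),
                                          stringsAsFactors = FALSE)) {
  new("TimeLog", perFile = perFile, perRankInit = perRankInit,
      failures = failures)
}

# ---- lexicon -------------------------------------------------------------

#' @rdname Lexicon
#' @export
setClass("Lexicon",
         representation(entries = "character", entityType = "character"))

setValidity("Lexicon", function(object) {
  surf <- names(object@entries)
  if (is.null(surf) || any(!nzchar(surf)))
    return("entries must be a named character vector with non-empty names")
  if (any(surf != trimws(surf)))
    return("surface forms must have no leading/trailing whitespace")
  if (length(object@entityType) != 1L || !nzchar(object@entityType))
    return("entityType must be a single non-empty string")
  TRUE
})

#' Lexicon: a dictionary of surface forms for a single entity type
#'
#' Maps case-folded surface forms to concept identifiers. Used by the
#' demonstration dictionary tagger; surface forms are matched
#' case-insensitively at word boundaries, longest match wins.
#'
#' @param entries named character vector: names are surface forms (stored
#'   case-folded), values concept ids.
#' @param entityType entity type carried by every emitted annotation.
#' @return A \code{Lexicon}.
#' @export
Lexicon <- function(entries, entityType) {
  names(entries) <- tolower(trimws(names(entries)))
  new("Lexicon", entries = entries, entityType = as.character(entityType))
}
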