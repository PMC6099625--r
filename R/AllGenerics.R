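# Accessor generics. Slots are never accessed with @ outside the package.

#' @rdname Document
#' @param x,object an object of the documented class.
#' @export
setGeneric("docId", function(x) standardGeneric("docId"))
#' @rdname Document
#' @export
setGeneric("docTitle", function(x) standardGeneric("docTitle"))
#' @rdname Document
#' @export
setGeneric("docBody", function(x) standardGeneric("docBody"))
#' @rdname Document
#' @export
setGeneric("compositeText", function(x) standardGeneric("compositeText"))
#' @rdname AnnotatedDocument
#' @param x an \code{AnnotatedDocument}.
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname AnnotatedDocument
#' @export
setGeneric("document", function(x) standardGeneric("document"))
#' @rdname Corpus
#' @param x a \code{Corpus}.
#' @export
setGeneric("fileIds", function(x) standardGeneric("fileIds"))
#' @rdname Corpus
#' @export
setGeneric("sizeChars", function(x) standardGeneric("sizeChars"))
#' @rdname Corpus
#' @export
setGeneric("nFiles", function(x) standardGeneric("nFiles"))
#' @rdname Assignment
#' @param x an \code{Assignment}.
#' @export
setGeneric("nProcs", function(x) standardGeneric("nProcs"))
#' @rdname Assignment
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))
#' @rdname RunMetrics
#' @param x a \code{RunMetrics}.
#' @export
setGeneric("perProcSeconds", function(x) standardGeneric("perProcSeconds"))
#' @rdname RunMetrics
#' @export
setGeneric("maxSeconds", function(x) standardGeneric("maxSeconds"))
#' @rdname RunMetrics
#' @export
setGeneric("meanSeconds", function(x) standardGeneric("meanSeconds"))
#' @rdname RunMetrics
#' @export
setGeneric("lbeRatio", function(x) standardGeneric("lbeRatio"))
#' @rdname WorkloadModel
#' @param x,model a \code{WorkloadModel}.
#' @export
setGeneric("modelIntercept", function(x) standardGeneric("modelIntercept"))
#' @rdname WorkloadModel
#' @export
setGeneric("modelSlope", function(x) standardGeneric("modelSlope"))
#' @rdname WorkloadModel
#' @export
setGeneric("sizeUnit", function(x) standardGeneric("sizeUnit"))
#' @rdname Plugin
#' @param x a \code{Plugin} or \code{PluginSpec}.
#' @export
setGeneric("pluginName", function(x) standardGeneric("pluginName"))
#' @rdname TimeLog
#' @param x a \code{TimeLog}.
#' @export
setGeneric("perFileTimes", function(x) standardGeneric("perFileTimes"))
#' @rdname TimeLog
#' @export
setGeneric("perRankInitTimes", function(x) standardGeneric("perRankInitTimes"))
#' @rdname TimeLog
#' @export
setGeneric("failures", function(x) standardGeneric("failures"))

#' @rdname Document
#' @export
setMethod("docId", "Document", function(x) x@docId)
#' @rdname Document
#' @export
setMethod("docTitle", "Document", function(x) x@title)
#' @rdname Document
#' @export
setMethod("docBody", "Document", function(x) x@body)

#' @describeIn Document Composite text over which annotation offsets are
#'   counted: title, then exactly one space, then body; a document with an
#'   empty body contributes the title alone (no trailing separator).
#' @export
setMethod("compositeText", "Document", function(x) {
  if (nzchar(x@body)) paste(x@title, x@body) else x@title
})

#' @rdname AnnotatedDocument
#' @export
setMethod("annotations", "AnnotatedDocument", function(x) x@annotations)
#' @rdname AnnotatedDocument
#' @export
setMethod("document", "AnnotatedDocument", function(x) x@document)
#' @rdname AnnotatedDocument
#' @export
setMethod("docId", "AnnotatedDocument", function(x) x@document@docId)
#' @rdname AnnotatedDocument
#' @export
setMethod("compositeText", "AnnotatedDocument",
          function(x) compositeText(x@document))

#' @rdname Corpus
#' @export
setMethod("fileIds", "Corpus", function(x) x@fileId)
#' @rdname Corpus
#' @export
setMethod("sizeChars", "Corpus", function(x) {
  stats::setNames(x@sizeChars, x@fileId)
})
#' @rdname Corpus
#' @export
setMethod("nFiles", "Corpus", function(x) length(x@fileId))

#' @rdname Assignment
#' @export
setMethod("nProcs", "Assignment", function(x) x@nProcs)
#' @rdname Assignment
#' @export
setMethod("groups", "Assignment", function(x) x@groups)

#' @rdname RunMetrics
#' @export
setMethod("perProcSeconds", "RunMetrics", function(x) x@perProcSeconds)
#' @rdname RunMetrics
#' @export
setMethod("maxSeconds", "RunMetrics", function(x) x@maxSeconds)
#' @rdname RunMetrics
#' @export
setMethod("meanSeconds", "RunMetrics", function(x) x@meanSeconds)
#' @rdname RunMetrics
#' @export
setMethod("lbeRatio", "RunMetrics", function(x) x@lbeRatio)

#' @rdname WorkloadModel
#' @export
setMethod("modelIntercept", "WorkloadModel", function(x) x@intercept)
#' @rdname WorkloadModel
#' @export
setMethod("modelSlope", "WorkloadModel", function(x) x@slope)
#' @rdname WorkloadModel
#' @export
setMethod("sizeUnit", "WorkloadModel", function(x) x@sizeUnit)

#' @rdname Plugin
#' @export
setMethod("pluginName", "PluginSpec", function(x) x@name)
#' @rdname Plugin
#' @export
setMethod("pluginName", "Plugin", function(x) x@spec@name)

#' @rdname TimeLog
#' @export
setMethod("perFileTimes", "TimeLog", function(x) x@perFile)
#' @rdname TimeLog
#' @export
setMethod("perRankInitTimes", "TimeLog", function(x) x@perRankInit)
#' @rdname TimeLog
#' @export
setMethod("failures", "TimeLog", function(x) x@failures)

# ---- show methods --------------------------------------------------------

setMethod("show", "Document", function(object) {
  cat(sprintf("Document %s: %s (%d chars)\n", object@docId,
              .ellipsize(object@title, 50), nchar(compositeText(object))))
})

setMethod("show", "AnnotatedDocument", function(object) {
  show(object@document)
  cat(sprintf("  %d annotation(s)", nrow(object@annotations)))
  if (nrow(object@annotations))
    cat(": ", paste(unique(object@annotations$type), collapse = ", "),
        sep = "")
  cat("\n")
})

setMethod("show", "Corpus", function(object) {
  n <- length(object@fileId)
  cat(sprintf("Corpus with %d file(s), %.0f characters total\n",
              n, sum(object@sizeChars)))
  if (n)
    cat(sprintf("  sizes: min %.0f / median %.0f / max %.0f\n",
                min(object@sizeChars), stats::median(object@sizeChars),
                max(object@sizeChars)))
})

setMethod("show", "WorkloadModel", function(object) {
  cat(sprintf("WorkloadModel: seconds = %.4g + %.4g * size [%s]\n",
              object@intercept, object@slope, object@sizeUnit))
})

setMethod("show", "Assignment", function(object) {
  sizes <- lengths(object@groups)
  cat(sprintf("Assignment of %d file(s) across %d rank(s)\n",
              sum(sizes), object@nProcs))
  cat(sprintf("  files per rank: %s\n", paste(sizes, collapse = " ")))
})

setMethod("show", "RunMetrics", function(object) {
  cat(sprintf("RunMetrics over %d process(es)\n",
              length(object@perProcSeconds)))
  cat(sprintf("  MET %.2f s, AET %.2f s, LBE %.2f\n",
              object@maxSeconds, object@meanSeconds, object@lbeRatio))
})

setMethod("show", "PluginSpec", function(object) {
  cat(sprintf("PluginSpec %s (types: %s; <= %d procs/node)\n", object@name,
              paste(object@entityTypes, collapse = ", "),
              object@maxProcsPerNode))
})

setMethod("show", "Plugin", function(object) show(object@spec))

setMethod("show", "TimeLog", function(object) {
  cat(sprintf("TimeLog: %d file timing(s), %d init record(s), %d failure(s)\n",
              nrow(object@perFile), nrow(object@perRankInit),
              nrow(object@failures)))
})

setMethod("show", "Lexicon", function(object) {
  cat(sprintf("Lexicon (%s) with %d entries\n", object@entityType,
              length(object@entries)))
})

.ellipsize <- function(x, n) {
  ifelse(nchar(x) > n, paste0(substr(x, 1L, n - 3L), "..."), x)
}
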