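# PubTator exchange format: line-oriented blocks separated by blank lines.
#
#   <id>|t|<title>
#   <id>|a|<abstract / body>
#   <id>\t<start>\t<end>\t<mention>\t<type>[\t<concept>]
#
# Offsets are 0-based, end-exclusive, counted in decoded characters over the
# composite text (title + one space + body).

#' Read a PubTator-format corpus
#'
#' Parses zero or more document blocks from a file, connection or character
#' vector of lines. Each block starts with a \code{<id>|t|} title line,
#' optionally followed by an \code{<id>|a|} abstract line, then zero or more
#' tab-separated annotation lines with 5 or 6 fields (doc id, start, end,
#' mention, entity type, optional concept id). Annotation offsets are
#' validated against the composite text; the mention must equal the
#' substring it indexes.
#'
#' @param input a file path, a connection, or a character vector of lines.
#' @param strict logical; in strict mode (the default) any malformed line
#'   aborts with an error naming the line number. In lenient mode the
#'   offending record is skipped with a warning and parsing continues.
#'   Strict is the default because downstream scheduling relies on
#'   trustworthy document sizes.
#' @return A list of \code{\link{AnnotatedDocument}} objects in stream
#'   order. Documents without an abstract line get an empty body.
#' @examples
#' lines <- c("26094|t|BRAF V600E in melanoma.",
#'            "26094|a|We report the V600E mutation.",
#'            "26094\t5\t10\tV600E\tMutation")
#' docs <- readPubTator(lines)
#' annotations(docs[[1]])
#' @export
readPubTator <- function(input, strict = TRUE) {
  if (inherits(input, "connection")) {
    lines <- readLines(input, warn = FALSE)
  } else if (is.character(input) && length(input) == 1L &&
             !grepl("[\n|]", input) && file.exists(input)) {
    lines <- readLines(input, warn = FALSE)
  } else {
    lines <- as.character(input)
  }

  complain <- function(lineno, msg) {
    full <- sprintf("line %d: %s", lineno, msg)
    if (strict) stop(full, call. = FALSE)
    warning(full, " (record skipped)", call. = FALSE)
    NULL
  }

  blank <- !nzchar(trimws(lines))
  docs <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (blank[i]) { i <- i + 1L; next }
    # block start: title line
    tm <- regmatches(lines[i], regexec("^([^|\t]+)\\|t\\|(.*)$", lines[i]))[[1]]
    if (length(tm) != 3L) {
      complain(i, sprintf("expected '<id>|t|' title line, got %s",
                          dQuote(.ellipsize(lines[i], 40), FALSE)))
      # lenient: skip to end of block
      while (i <= n && !blank[i]) i <- i + 1L
      next
    }
    id <- tm[2L]
    title <- tm[3L]
    i <- i + 1L
    body <- ""
    if (i <= n && !blank[i]) {
      am <- regmatches(lines[i], regexec("^([^|\t]+)\\|a\\|(.*)$", lines[i]))[[1]]
      if (length(am) == 3L) {
        if (am[2L] != id)
          complain(i, sprintf("abstract line id %s differs from block id %s",
                              dQuote(am[2L], FALSE), dQuote(id, FALSE)))
        else body <- am[3L]
        i <- i + 1L
      }
    }
    doc <- Document(id, title, body)
    comp <- compositeText(doc)
    ann <- list()
    while (i <= n && !blank[i]) {
      fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      ok <- TRUE
      if (length(fields) < 5L || length(fields) > 6L) {
        complain(i, sprintf("annotation line has %d tab-separated fields, expected 5 or 6",
                            length(fields)))
        ok <- FALSE
      } else {
        start <- suppressWarnings(as.integer(fields[2L]))
        end <- suppressWarnings(as.integer(fields[3L]))
        if (fields[1L] != id) {
          complain(i, sprintf("annotation doc id %s differs from block id %s",
                              dQuote(fields[1L], FALSE), dQuote(id, FALSE)))
          ok <- FALSE
        } else if (is.na(start) || is.na(end)) {
          complain(i, "non-integer annotation offsets")
          ok <- FALSE
        } else if (start < 0L || end <= start || end > nchar(comp)) {
          complain(i, sprintf("offsets [%d,%d) out of range for a %d-character composite text",
                              start, end, nchar(comp)))
          ok <- FALSE
        } else if (substring(comp, start + 1L, end) != fields[4L]) {
          complain(i, sprintf("mention %s does not match composite text %s at [%d,%d)",
                              dQuote(fields[4L], FALSE),
                              dQuote(substring(comp, start + 1L, end), FALSE),
                              start, end))
          ok <- FALSE
        } else if (!nzchar(fields[5L])) {
          complain(i, "empty entity type")
          ok <- FALSE
        }
      }
      if (ok) {
        ann[[length(ann) + 1L]] <- data.frame(
          doc_id = fields[1L], start = start, end = end,
          mention = fields[4L], type = fields[5L],
          concept = if (length(fields) == 6L) fields[6L] else "",
          stringsAsFactors = FALSE)
      }
      i <- i + 1L
    }
    annDf <- if (length(ann)) do.call(rbind, ann) else annotationTable()
    docs[[length(docs) + 1L]] <- AnnotatedDocument(doc, annDf)
  }
  docs
}

#' Write a PubTator-format corpus
#'
#' Emits one block per document in input order: the title line, the abstract
#' line (always emitted, empty body allowed), then one tab-separated line
#' per annotation sorted by \code{(start, end)}, and a blank line after each
#' block. Annotation lines always carry 6 fields (an empty concept id is
#' written as an empty final field) for uniformity. Every annotation is
#' re-validated against its document's composite text before anything is
#' written; a failing annotation aborts the whole write.
#'
#' \code{readPubTator(writePubTator(x))} reproduces \code{x} field by field.
#'
#' @param docs list of \code{\link{AnnotatedDocument}} objects (bare
#'   \code{Document}s are accepted and wrapped).
#' @param path output file path or connection. Omit to return the lines
#'   invisibly without writing.
#' @return Invisibly, the character vector of emitted lines.
#' @export
writePubTator <- function(docs, path = NULL) {
  if (is(docs, "AnnotatedDocument") || is(docs, "Document")) docs <- list(docs)
  docs <- lapply(docs, function(d) {
    if (is(d, "Document")) AnnotatedDocument(d) else d
  })
  for (d in docs) validObject(d)  # offset validation before any output
  out <- unlist(lapply(docs, function(d) {
    doc <- document(d)
    ann <- annotations(d)
    lines <- c(paste0(docId(doc), "|t|", docTitle(doc)),
               paste0(docId(doc), "|a|", docBody(doc)))
    if (nrow(ann)) {
      ord <- order(ann$start, ann$end, ann$type, ann$concept)
      ann <- ann[ord, , drop = FALSE]
      lines <- c(lines, paste(ann$doc_id, ann$start, ann$end, ann$mention,
                              ann$type, ann$concept, sep = "\t"))
    }
    c(lines, "")
  }), use.names = FALSE)
  if (!is.null(path)) writeLines(out, path, useBytes = FALSE)
  invisible(out)
}

#' Extract a document from a JATS/NXML article
#'
#' Flattens the title, abstract and (optionally) body paragraphs of a
#' full-text article in the NCBI JATS/NXML format into a plain-text
#' \code{\link{Document}}: all XML markup is stripped and whitespace runs
#' are collapsed to single spaces, so the output never contains angle
#' brackets, tabs or newlines.
#'
#' @param nxml a file path, a connection, a raw XML string, or a parsed
#'   \code{xml2} document.
#' @param includeFullText logical; when \code{TRUE} the body is the abstract
#'   followed by the body paragraph texts joined with single spaces, when
#'   \code{FALSE} (default) the abstract alone.
#' @param fallbackId document id to use when the article carries no
#'   \code{article-id} of type \code{pmid}.
#' @return A \code{Document}; the id is the article's PMID when present,
#'   otherwise \code{fallbackId}.
#' @export
nxmlToDocument <- function(nxml, includeFullText = FALSE, fallbackId = NULL) {
  doc <- if (inherits(nxml, "xml_document")) nxml else
    tryCatch(xml2::read_xml(nxml),
             error = function(e) stop("cannot parse NXML input ",
                                      if (is.character(nxml) && length(nxml) == 1L &&
                                          !grepl("<", nxml)) dQuote(nxml, FALSE) else "",
                                      ": ", conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)

  titleNode <- xml2::xml_find_first(doc, ".//article-title")
  if (is.na(titleNode) || inherits(titleNode, "xml_missing"))
    stop("NXML article has no article-title element", call. = FALSE)
  title <- squish(xml2::xml_text(titleNode))

  pmid <- xml2::xml_find_first(doc, ".//article-id[@pub-id-type='pmid']")
  id <- if (!inherits(pmid, "xml_missing") && !is.na(pmid))
    squish(xml2::xml_text(pmid)) else NULL
  if (is.null(id) || !nzchar(id)) {
    if (is.null(fallbackId))
      stop("NXML article has no pmid article-id and no fallbackId was given",
           call. = FALSE)
    id <- fallbackId
  }

  abstractNode <- xml2::xml_find_first(doc, ".//abstract")
  abstract <- if (!inherits(abstractNode, "xml_missing") && !is.na(abstractNode))
    squish(xml2::xml_text(abstractNode)) else ""

  body <- abstract
  if (includeFullText) {
    paras <- xml2::xml_find_all(doc, ".//body//p")
    paraText <- squish(vapply(paras, xml2::xml_text, character(1)))
    paraText <- paraText[nzchar(paraText)]
    body <- squish(paste(c(abstract, paraText), collapse = " "))
  }
  Document(id, title, body)
}

#' Merge per-plugin annotation sets for one document
#'
#' Combines the annotation tables produced by several annotators over the
#' same document into one validated \code{\link{AnnotatedDocument}}: the
#' union of all annotations, sorted by \code{(start, end, type)}, with exact
#' duplicates (same span, type and concept) collapsed to a single row.
#' Overlapping spans of different types are all kept.
#'
#' @param doc the \code{\link{Document}} the annotations refer to.
#' @param perPlugin a list of annotation data.frames (one per annotator).
#' @return An \code{AnnotatedDocument}.
#' @export
mergeAnnotations <- function(doc, perPlugin) {
  if (is.data.frame(perPlugin)) perPlugin <- list(perPlugin)
  all <- do.call(rbind, c(list(annotationTable()), perPlugin))
  if (nrow(all)) {
    if (any(all$doc_id != docId(doc)))
      stop("annotation for document ",
           dQuote(all$doc_id[all$doc_id != docId(doc)][1L], FALSE),
           " cannot be merged into document ", dQuote(docId(doc), FALSE),
           call. = FALSE)
    all <- all[!duplicated(all[, c("start", "end", "type", "concept")]), ,
               drop = FALSE]
    all <- all[order(all$start, all$end, all$type, all$concept), ,
               drop = FALSE]
    rownames(all) <- NULL
  }
  AnnotatedDocument(doc, all)
}

#' Compare two annotated corpora field by field
#'
#' Structural equality helper used in round-trip checks: two lists of
#' \code{\link{AnnotatedDocument}}s are equal when they have the same length
#' and every position agrees on id, title, body and the full annotation
#' table.
#'
#' @param a,b lists of \code{AnnotatedDocument}s.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
sameCorpus <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  for (k in seq_along(a)) {
    da <- document(a[[k]]); db <- document(b[[k]])
    if (docId(da) != docId(db) || docTitle(da) != docTitle(db) ||
        docBody(da) != docBody(db)) return(FALSE)
    aa <- annotations(a[[k]]); ab <- annotations(b[[k]])
    rownames(aa) <- NULL; rownames(ab) <- NULL
    if (!identical(aa, ab)) return(FALSE)
  }
  TRUE
}
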