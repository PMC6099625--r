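# Lightweight demonstration annotators. They stand in for heavyweight NER
# tools so the pipeline can be exercised end to end; recognition quality is
# explicitly not a goal.

# Resolve overlapping candidate spans: longest first, then leftmost.
.resolveOverlaps <- function(cand) {
  if (nrow(cand) <= 1L) return(cand)
  ord <- order(-(cand$end - cand$start), cand$start)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  taken <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(nrow(cand))) {
    s <- cand$start[k]; e <- cand$end[k]
    if (!nrow(taken) || all(e <= taken[, 1] | s >= taken[, 2])) {
      keep[k] <- TRUE
      taken <- rbind(taken, c(s, e))
    }
  }
  cand[keep, , drop = FALSE]
}

# All matches of one regex over text, as 0-based [start, end) offsets.
.regexSpans <- function(text, pattern, ignoreCase = FALSE) {
  m <- gregexpr(pattern, text, perl = TRUE, ignore.case = ignoreCase)[[1]]
  if (m[1L] == -1L) return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

#' Pattern-based mutation mention tagger
#'
#' Matches two mutation nomenclature patterns over the document's composite
#' text: protein substitutions in the one-letter convention (an uppercase
#' letter, 1–5 digits, an uppercase letter, at word boundaries, e.g.
#' \code{V600E}) and HGVS-like coding changes (\code{c.} digits, reference
#' base, \code{>}, alternate base, e.g. \code{c.123A>G}). Overlapping
#' matches are resolved longest-first, then leftmost. Emitted annotations
#' have entity type \code{"Mutation"} and no concept id.
#'
#' @param doc a \code{\link{Document}}.
#' @return An annotation data.frame (see \code{\link{annotationTable}}).
#' @examples
#' d <- Document("1", "BRAF V600E in melanoma.")
#' regexMutationTagger(d)
#' @export
regexMutationTagger <- function(doc) {
  comp <- compositeText(doc)
  cand <- rbind(
    .regexSpans(comp, "(?<![A-Za-z0-9])[A-Z][0-9]{1,5}[A-Z](?![A-Za-z0-9])"),
    .regexSpans(comp, "(?<![A-Za-z0-9.])c\\.[0-9]+[ACGT]>[ACGT](?![A-Za-z0-9])"))
  if (!nrow(cand)) return(annotationTable())
  hit <- .resolveOverlaps(cand)
  annotationTable(doc_id = docId(doc), start = hit$start, end = hit$end,
                  mention = substring(comp, hit$start + 1L, hit$end),
                  type = "Mutation", concept = "")
}

#' Dictionary-based entity tagger
#'
#' Case-insensitive scan of the composite text for the lexicon's surface
#' forms, matching only at word boundaries (transitions between
#' alphanumeric and non-alphanumeric characters). When entries overlap
#' ("breast cancer" vs "cancer") the longest match wins and the output is
#' non-overlapping. Each annotation carries the lexicon's entity type and
#' the matched entry's concept id.
#'
#' @param doc a \code{\link{Document}}.
#' @param lexicon a \code{\link{Lexicon}}.
#' @return An annotation data.frame.
#' @export
lexiconTagger <- function(doc, lexicon) {
  entries <- lexicon@entries
  if (!length(entries)) stop("lexicon is empty", call. = FALSE)
  comp <- compositeText(doc)
  cand <- do.call(rbind, lapply(names(entries), function(surface) {
    pat <- paste0("(?<![A-Za-z0-9])",
                  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", surface),
                  "(?![A-Za-z0-9])")
    sp <- .regexSpans(comp, pat, ignoreCase = TRUE)
    if (nrow(sp)) sp$concept <- entries[[surface]]
    sp
  }))
  if (is.null(cand) || !nrow(cand)) return(annotationTable())
  hit <- .resolveOverlaps(cand)
  annotationTable(doc_id = docId(doc), start = hit$start, end = hit$end,
                  mention = substring(comp, hit$start + 1L, hit$end),
                  type = lexicon@entityType, concept = hit$concept)
}

#' Read a lexicon file
#'
#' Two tab-separated columns per line: surface form, concept id. Lines
#' starting with \code{#} are comments.
#'
#' @param path lexicon file path.
#' @param entityType entity type the lexicon represents.
#' @return A \code{\link{Lexicon}}.
#' @export
readLexicon <- function(path, entityType) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", quote = "",
                          col.names = c("surface", "concept"),
                          colClasses = "character")
  Lexicon(stats::setNames(df$concept, df$surface), entityType)
}

.bundledLexicon <- function(which, entityType) {
  readLexicon(system.file("extdata", which, package = "corpusBalance",
                          mustWork = TRUE), entityType)
}

#' Demonstration plugins
#'
#' Three ready-made \code{\link{Plugin}} objects mirroring the classic NER
#' trio — a pattern-based mutation tagger and two dictionary taggers for
#' genes and diseases (built on small bundled demonstration lexicons).
#' The \code{initCostHint} and \code{maxProcsPerNode} metadata mimic
#' memory-hungry real tools: dictionary taggers get a lower per-node cap
#' than the pattern tagger.
#'
#' @return A single \code{Plugin} (\code{demoMutationPlugin} etc.) or a
#'   named list of all three (\code{demoPlugins}).
#' @export
demoMutationPlugin <- function() {
  Plugin(PluginSpec("mutation", initCostHint = 0, maxProcsPerNode = 10L,
                    entityTypes = "Mutation"),
         annotate = function(doc, state) regexMutationTagger(doc))
}

#' @rdname demoMutationPlugin
#' @export
demoGenePlugin <- function() {
  Plugin(PluginSpec("gene", initCostHint = 0, maxProcsPerNode = 5L,
                    entityTypes = "Gene"),
         init = function() .bundledLexicon("gene_lexicon.tsv", "Gene"),
         annotate = function(doc, state) lexiconTagger(doc, state))
}

#' @rdname demoMutationPlugin
#' @export
demoDiseasePlugin <- function() {
  Plugin(PluginSpec("disease", initCostHint = 0, maxProcsPerNode = 5L,
                    entityTypes = "Disease"),
         init = function() .bundledLexicon("disease_lexicon.tsv", "Disease"),
         annotate = function(doc, state) lexiconTagger(doc, state))
}

#' @rdname demoMutationPlugin
#' @export
demoPlugins <- function() {
  list(mutation = demoMutationPlugin(), gene = demoGenePlugin(),
       disease = demoDiseasePlugin())
}
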