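# Fixture builders shared across test files. Everything is generated in
# code; no stored corpora.

# A random document whose title/body are words over a safe alphabet
# (no tabs or newlines; pipes allowed in titles on purpose).
randomDocument <- function(id) {
  word <- function() paste(sample(c(letters, LETTERS, 0:9), sample(1:8, 1),
                                  replace = TRUE), collapse = "")
  words <- function(n) paste(replicate(n, word()), collapse = " ")
  title <- words(sample(2:6, 1))
  body <- if (runif(1) < 0.15) "" else words(sample(5:40, 1))
  Document(id, title, body)
}

# A random annotated document: spans are random substrings of the
# composite text, so offset validation holds by construction.
randomAnnotatedDocument <- function(id) {
  doc <- randomDocument(id)
  comp <- compositeText(doc)
  nAnn <- sample(0:5, 1)
  if (nAnn == 0 || nchar(comp) < 3)
    return(AnnotatedDocument(doc))
  start <- sample.int(nchar(comp) - 1L, nAnn, replace = TRUE) - 1L
  len <- pmin(sample(1:10, nAnn, replace = TRUE), nchar(comp) - start)
  types <- sample(c("Gene", "Disease", "Mutation"), nAnn, replace = TRUE)
  concepts <- ifelse(runif(nAnn) < 0.5, "",
                     as.character(sample(1000:9999, nAnn, replace = TRUE)))
  AnnotatedDocument(doc, annotationTable(
    doc_id = docId(doc), start = start, end = start + len,
    mention = substring(comp, start + 1L, start + len),
    type = types, concept = concepts))
}

randomCorpusDocs <- function(n, prefix = "pt") {
  lapply(seq_len(n), function(k) randomAnnotatedDocument(paste0(prefix, k)))
}

# The five-file worked scheduling instance used throughout.
fixtureCorpus5 <- function() Corpus(paste0("f", 0:4), c(7, 5, 4, 3, 2))

# Write a small annotated corpus of PubTator files with entity mentions the
# demo plugins can find; returns the file paths.
writeDemoCorpus <- function(dir, nFiles, seed) {
  corpus <- generateCorpus(nFiles, "lognormal",
                           params = list(meanlog = log(400), sdlog = 0.8),
                           seed = seed)
  materializeCorpus(corpus, dir, seed = seed, vocabulary = "biomedical")
}

# Minimal JATS/NXML article as a string.
nxmlArticle <- function(title, abstract = NULL, paragraphs = character(),
                        pmid = NULL) {
  paste0(
    "<article><front><article-meta>",
    if (!is.null(pmid))
      paste0("<article-id pub-id-type=\"pmid\">", pmid, "</article-id>"),
    "<title-group><article-title>", title, "</article-title></title-group>",
    if (!is.null(abstract)) paste0("<abstract><p>", abstract,
                                   "</p></abstract>"),
    "</article-meta></front>",
    if (length(paragraphs))
      paste0("<body>", paste0("<p>", paragraphs, "</p>", collapse = ""),
             "</body>"),
    "</article>")
}
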