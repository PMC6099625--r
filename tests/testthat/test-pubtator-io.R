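block <- c("26094|t|BRAF V600E in melanoma.",
           "26094|a|We report the V600E mutation.",
           "26094\t5\t10\tV600E\tMutation")

test_that("a PubTator block parses with validated offsets", {
  docs <- readPubTator(block)
  expect_length(docs, 1)
  d <- docs[[1]]
  expect_equal(docId(d), "26094")
  expect_equal(docTitle(document(d)), "BRAF V600E in melanoma.")
  expect_equal(docBody(document(d)), "We report the V600E mutation.")
  ann <- annotations(d)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$start, 5L)
  expect_equal(ann$end, 10L)
  expect_equal(ann$mention, "V600E")
  expect_equal(ann$concept, "")
})

test_that("offsets are counted over title + one space + body", {
  # oracle: locate the second V600E occurrence in the composite string
  docs <- readPubTator(block[1:2])
  comp <- compositeText(docs[[1]])
  hits <- gregexpr("V600E", comp, fixed = TRUE)[[1]]
  second <- as.integer(hits[2]) - 1L
  expect_equal(second, 38L)  # title (23) + separator (1) + 14 chars in
  withAbstractAnn <- c(block[1:2], "26094\t38\t43\tV600E\tMutation")
  ann <- annotations(readPubTator(withAbstractAnn)[[1]])
  expect_equal(ann$start, 38L)
  expect_equal(ann$mention, substring(comp, 39, 43))
})

test_that("empty input and bodiless documents are handled", {
  expect_identical(readPubTator(character()), list())
  docs <- readPubTator("99|t|Only a title")
  expect_equal(docBody(document(docs[[1]])), "")
  expect_equal(compositeText(docs[[1]]), "Only a title")
})

test_that("malformed records are errors in strict mode, skipped in lenient", {
  noTitle <- c("26094 no title marker", "26094|a|abstract")
  expect_error(readPubTator(noTitle), "line 1")
  expect_warning(out <- readPubTator(noTitle, strict = FALSE), "line 1")
  expect_length(out, 0)

  badOffset <- c(block[1:2], "26094\tfive\t10\tV600E\tMutation")
  expect_error(readPubTator(badOffset), "non-integer")

  mismatch <- c(block[1:2], "26094\t0\t4\tKRAS\tGene")
  expect_error(readPubTator(mismatch), "does not match")
  expect_warning(out <- readPubTator(mismatch, strict = FALSE), "line 3")
  expect_equal(nrow(annotations(out[[1]])), 0)

  alienId <- c(block[1:2], "777\t5\t10\tV600E\tMutation")
  expect_error(readPubTator(alienId), "differs from block id")
})

test_that("writing emits sorted six-field annotation lines per block", {
  d <- readPubTator(block)[[1]]
  lines <- writePubTator(list(d))
  expect_equal(lines[3], "26094\t5\t10\tV600E\tMutation\t")
  expect_equal(length(strsplit(lines[3], "\t")[[1]]), 5)  # empty 6th field
  expect_equal(lines[4], "")

  # a bare document writes two lines plus the blank separator
  plain <- writePubTator(list(Document("1", "T", "")))
  expect_equal(plain, c("1|t|T", "1|a|", ""))

  # six-field annotation with a concept id survives
  withConcept <- c(block[1:2], "26094\t5\t10\tV600E\tMutation\tp.V600E")
  out <- writePubTator(readPubTator(withConcept))
  expect_equal(out[3], "26094\t5\t10\tV600E\tMutation\tp.V600E")
})

test_that("write validates offsets before emitting anything", {
  d <- AnnotatedDocument(Document("1", "abcdef"))
  # corrupt the annotation table behind the constructor's back
  bad <- d
  bad@annotations <- data.frame(doc_id = "1", start = 0L, end = 3L,
                                mention = "zzz", type = "Gene",
                                concept = "", stringsAsFactors = FALSE)
  expect_error(writePubTator(list(bad)), "does not match")
})

test_that("read/write round-trips property-generated corpora", {
  set.seed(101)
  for (rep in 1:25) {
    docs <- randomCorpusDocs(sample(1:4, 1), prefix = sprintf("r%d_", rep))
    path <- withr::local_tempfile(fileext = ".txt")
    writePubTator(docs, path)
    back <- readPubTator(path)
    expect_true(sameCorpus(docs, back))
  }
})

test_that("NXML extraction flattens markup and collapses whitespace", {
  x <- nxmlArticle("A <italic>BRAF</italic>  study", abstract = "An abstract.",
                   pmid = "123")
  d <- nxmlToDocument(x)
  expect_equal(docId(d), "123")
  expect_equal(docTitle(d), "A BRAF study")
  expect_equal(docBody(d), "An abstract.")
  expect_false(grepl("[<>\t\n]", paste(docTitle(d), docBody(d))))
})

test_that("full-text extraction appends body paragraphs to the abstract", {
  x <- nxmlArticle("T", abstract = "A.", paragraphs = c("P one.", "P two."),
                   pmid = "5")
  expect_equal(docBody(nxmlToDocument(x, includeFullText = TRUE)),
               "A. P one. P two.")  # oracle: manual concatenation
  expect_equal(docBody(nxmlToDocument(x)), "A.")
})

test_that("NXML edge cases error informatively", {
  expect_error(nxmlToDocument("<article><front/></article>"),
               "article-title")
  expect_error(nxmlToDocument(nxmlArticle("T")), "fallbackId")
  expect_equal(docId(nxmlToDocument(nxmlArticle("T"), fallbackId = "fb1")),
               "fb1")
  expect_error(nxmlToDocument("<article><unclosed></article>"),
               "cannot parse")
})

test_that("merging plugin outputs unions, sorts and deduplicates", {
  doc <- Document("1", "BRAF V600E in melanoma.")
  a1 <- annotationTable("1", 5, 10, "V600E", "Mutation")
  a2 <- annotationTable("1", 0, 4, "BRAF", "Gene", "673")
  merged <- mergeAnnotations(doc, list(a1, a2))
  expect_equal(annotations(merged)$mention, c("BRAF", "V600E"))

  # identical annotation from two plugins appears once
  dup <- mergeAnnotations(doc, list(a1, a1))
  expect_equal(nrow(annotations(dup)), 1)

  # overlapping spans of different types are both kept
  overlap <- annotationTable("1", 5, 10, "V600E", "Variant")
  both <- mergeAnnotations(doc, list(a1, overlap))
  expect_equal(nrow(annotations(both)), 2)

  # oracle: union over (start, end, type, concept) tuples
  u <- unique(rbind(a1, a1, a2, overlap)[, c("start", "end", "type",
                                             "concept")])
  expect_equal(nrow(annotations(mergeAnnotations(doc, list(a1, a1, a2,
                                                           overlap)))),
               nrow(u))

  alien <- annotationTable("2", 0, 4, "BRAF", "Gene")
  expect_error(mergeAnnotations(doc, list(alien)), "cannot be merged")
})

test_that("document invariants reject ids and text the format cannot carry", {
  expect_error(Document("a|b", "t"), "docId")
  expect_error(Document("", "t"), "docId")
  expect_equal(docTitle(Document("1", "two\nlines")), "two lines")
  expect_equal(docBody(Document("1", "t", "a\r\nb")), "a b")
})
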