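test_that("JATS parsing extracts body, headings, captions and metadata", {
  a <- parse_article(jats_fixture(), "jats_xml", doc_id = "fix1")
  expect_equal(nrow(a$heading_spans), 2L)
  expect_equal(a$heading_spans$text, c("Introduction", "Methods"))
  expect_length(a$captions, 1L)
  expect_equal(a$captions, "A plot made with ImageJ.")  # markup stripped
  expect_equal(a$journal, "Fixture J Biol")
  expect_equal(a$year, 2007L)
  # heading offsets index into the body exactly
  for (i in seq_len(nrow(a$heading_spans))) {
    expect_equal(substring(a$body, a$heading_spans$start[i] + 1,
                           a$heading_spans$end[i]),
                 a$heading_spans$text[i])
  }
  # caption text never appears in the body stream
  expect_false(grepl("ImageJ", a$body, fixed = TRUE))
})

test_that("plain text and degenerate inputs parse", {
  a <- parse_article("just some words\nover two lines", "plain_text",
                     doc_id = "p1")
  expect_equal(nrow(a$heading_spans), 0L)
  expect_length(a$captions, 0L)
  b <- parse_article("<article><body></body></article>", "jats_xml",
                     doc_id = "e1")
  expect_equal(b$body, "")
  expect_equal(nrow(b$heading_spans), 0L)
  expect_error(parse_article("<article><body>", "jats_xml", doc_id = "bad"),
               "malformed")
  # missing year is flagged, not fatal
  c0 <- parse_article("<article><body><p>x</p></body></article>", "jats_xml",
                      doc_id = "noyear")
  expect_true(is.na(c0$year))
})

test_that("extract_captions returns captions in document order", {
  two <- paste0("<article><body>",
                "<fig><caption><p>first cap</p></caption></fig>",
                "<p>body text</p>",
                "<fig><caption><p>second <bold>cap</bold></p></caption></fig>",
                "</body></article>")
  expect_equal(extract_captions(two, "jats_xml"),
               c("first cap", "second cap"))
  expect_equal(extract_captions("<article><body><p>x</p></body></article>",
                                "jats_xml"), character())
})

test_that("serialisation round-trips generated articles losslessly", {
  corp <- small_corpus()
  for (a in corp$articles[1:8]) {
    b <- parse_article(serialize_article(a), "jats_xml", doc_id = a$doc_id)
    expect_identical(b$body, a$body)
    expect_identical(b$captions, a$captions)
    expect_identical(as.data.frame(b$heading_spans),
                     as.data.frame(a$heading_spans[, c("text", "start", "end")]))
    expect_identical(b$journal, a$journal)
    expect_identical(b$year, a$year)
  }
})

test_that("read_corpus skips unparseable documents and counts them", {
  files <- c(good = jats_fixture(), bad = "<article><body>",
             good2 = jats_fixture())
  rc <- read_corpus(files, "jats_xml")
  expect_length(rc$articles, 2L)
  expect_equal(rc$n_skipped, 1L)
})

test_that("partitioning follows the subject-code hierarchy", {
  mk <- function(id, journal) new_article(doc_id = id, journal = journal,
                                          year = 2005L, body = "x")
  arts <- list(mk("d1", "JBioinf"), mk("d2", "JBiol"), mk("d3", "JMed"),
               mk("d4", "JNowhere"))
  catalog <- tibble::tibble(
    journal = c("JBioinf", "JBiol", "JMed"),
    codes = list("H01.158.273.180", "H01.158.273", "H02.403"))
  parts <- partition_corpus(arts, catalog)
  # bioinformatics journal is in bioinformatics AND biology
  expect_true("d1" %in% parts$bioinformatics$doc_ids)
  expect_true("d1" %in% parts$biology$doc_ids)
  expect_false("d1" %in% parts$medicine$doc_ids)
  # uncatalogued journal only in full
  expect_true("d4" %in% parts$full$doc_ids)
  expect_false("d4" %in% parts$biology$doc_ids)
  # sizes 1/1/1 for the sub-partitions (biology additionally holds d1)
  expect_equal(length(parts$medicine$doc_ids), 1L)
  expect_equal(length(parts$bioinformatics$doc_ids), 1L)
  expect_equal(length(parts$biology$doc_ids), 2L)
  expect_equal(length(parts$full$doc_ids), 4L)
  # summaries
  expect_equal(corpus_summary(parts$full), list(n_journals = 4L, n_docs = 4L))
  expect_equal(corpus_summary(list(journal_names = character(),
                                   doc_ids = character())),
               list(n_journals = 0L, n_docs = 0L))
})

test_that("partition subset chain holds on generated corpora", {
  corp <- small_corpus()
  parts <- partition_corpus(corp$articles, corp$catalog)
  expect_true(all(parts$bioinformatics$doc_ids %in% parts$biology$doc_ids))
  expect_true(all(parts$biology$doc_ids %in% parts$full$doc_ids))
  expect_true(all(parts$medicine$doc_ids %in% parts$full$doc_ids))
})
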