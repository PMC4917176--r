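fixture_article <- function(headings = c("Introduction",
                                         "Materials and Methods",
                                         "Results and Discussion",
                                         "Conclusions"),
                            lead = NULL) {
  segs <- character(); hs <- list()
  if (!is.null(lead)) segs <- lead
  for (h in headings) {
    segs <- c(segs, h, paste("Text under", h, "with several words."))
    hs[[h]] <- length(segs) - 1L  # line index of the heading
  }
  starts <- c(0L, cumsum(nchar(segs) + 1L))
  body <- paste(segs, collapse = "\n")
  new_article(doc_id = "z1", body = body,
              heading_spans = tibble::tibble(
                text = headings,
                start = starts[unlist(hs)],
                end = starts[unlist(hs)] + nchar(headings)))
}

test_that("heading patterns map sections, merging results and discussion", {
  a <- fixture_article()
  spans <- label_sections(a)
  expect_equal(spans$label, c("introduction", "methods",
                              "results_discussion", "conclusion"))
  # spans are sorted, disjoint, and cover the body exactly
  expect_true(all(diff(spans$start) > 0))
  expect_equal(spans$start[-1], spans$end[-nrow(spans)])
  expect_equal(spans$start[1], 0L)
  expect_equal(spans$end[nrow(spans)], nchar(a$body))
  # leading text before the first heading is "other"
  b <- fixture_article(lead = "Some preamble text.")
  sp2 <- label_sections(b)
  expect_equal(sp2$label[1], "other")
  expect_equal(sp2$start[1], 0L)
})

test_that("unrecognised headings and headingless bodies fall back to other", {
  a <- fixture_article(headings = c("Weird Section Name"))
  expect_equal(label_sections(a)$label, "other")
  noh <- new_article(doc_id = "n", body = "plain text only")
  sp <- label_sections(noh)
  expect_equal(sp$label, "other")
  expect_equal(c(sp$start, sp$end), c(0L, nchar(noh$body)))
  empty <- new_article(doc_id = "e", body = "")
  expect_equal(nrow(label_sections(empty)), 0L)
})

test_that("mentions take the section of their start offset; captions are never zoned", {
  a <- fixture_article()
  spans <- label_sections(a)
  meth <- spans[spans$label == "methods", ]
  m <- tibble::tibble(doc_id = "z1", stream = c("body", "body", "caption"),
                      caption_idx = c(NA, NA, 1L),
                      start = c(meth$start + 2L, meth$end - 1L, 3L),
                      end = c(meth$start + 6L, meth$end + 4L, 8L))
  out <- assign_section(m, spans)
  expect_equal(out$section[1], "methods")
  expect_equal(out$section[2], "methods")  # straddles: start offset decides
  expect_equal(out$section[3], "caption")
  bad <- tibble::tibble(doc_id = "z1", stream = "body", caption_idx = NA,
                        start = nchar(a$body) + 5L, end = nchar(a$body) + 9L)
  expect_error(assign_section(bad, spans), "outside")
})

test_that("span coverage and heading quality hold on generated articles", {
  corp <- small_corpus()
  pats <- read_heading_patterns()
  n_true <- 0L; n_detected <- 0L; n_correct <- 0L
  for (a in corp$articles[1:60]) {
    spans <- label_sections(a, pats)
    expect_equal(spans$start[1], 0L)
    expect_equal(spans$end[nrow(spans)], nchar(a$body))
    expect_true(all(spans$start[-1] == spans$end[-nrow(spans)]))
    truth <- attr(a, "section_truth")
    truth_label <- c(intro = "introduction", methods = "methods",
                     results = "results_discussion",
                     concl = "conclusion")[truth$section]
    got <- spans[match(truth$text, spans$heading), ]
    detected <- got$label != "other"
    n_true <- n_true + nrow(truth)
    n_detected <- n_detected + sum(detected)
    n_correct <- n_correct + sum(got$label[detected] ==
                                   truth_label[detected])
  }
  expect_gte(n_detected / n_true, 0.75)       # heading recall
  expect_gte(n_correct / n_detected, 0.85)    # heading precision
})

test_that("per-section top-N table ranks by document fraction", {
  part <- list(name = "p", doc_ids = c("d1", "d2", "d3", "d4"))
  m <- tibble::tibble(
    doc_id = c("d1", "d1", "d2", "d3"),
    canonical = c("ToolA", "ToolA", "ToolA", "ToolB"),
    section = c("methods", "methods", "methods", "methods"))
  tab <- section_usage_table(m, part)
  expect_equal(tab$doc_count[tab$canonical == "ToolA"], 2L)
  expect_equal(tab$fraction[tab$canonical == "ToolA"], 0.5)
  expect_equal(tab$fraction[tab$canonical == "ToolB"], 0.25)
  # single doc, single methods mention -> one row at 1/N
  tab1 <- section_usage_table(m[4, ], part)
  expect_equal(nrow(tab1), 1L)
  expect_equal(tab1$fraction, 1 / 4)
  # empty corpus
  expect_equal(nrow(section_usage_table(m[0, ], part)), 0L)
  # per-section doc count never exceeds whole-document count
  corp <- small_corpus()
  mm <- zone_corpus(small_mentions(), corp$articles)
  whole <- dplyr::count(dplyr::distinct(mm, doc_id, canonical),
                        canonical, name = "whole")
  parts <- partition_corpus(corp$articles, corp$catalog)
  st <- section_usage_table(mm, parts$full, n = 10000L)
  j <- dplyr::left_join(st, whole, by = "canonical")
  expect_true(all(j$doc_count <= j$whole))
})
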