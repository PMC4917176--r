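mini_dict <- function() {
  new_dictionary(tibble::tibble(
    canonical = c("BLAST", "ClustalW", "GenBank", "GO", "clustering",
                  "Cluster"),
    rtype = c("SW", "SW", "DB", "ONT", "SW", "SW"),
    source = "test",
    expansion = c(NA, NA, NA, "Gene Ontology", NA, NA)))
}

test_that("preprocessing is total, tagged and deterministic", {
  p <- preprocess("We used BLAST.")
  expect_equal(p$n_sentences, 1L)
  expect_equal(nrow(p$tokens), 4L)
  expect_equal(p$tokens$pos[p$tokens$text == "BLAST"], "NNP")
  expect_equal(preprocess("")$n_sentences, 0L)
  # verbless sentence still has exactly one root
  q <- preprocess("The large genome database.")
  expect_equal(sum(q$tokens$is_root), 1L)
  expect_true(all(!is.na(q$tokens$head) | q$tokens$is_root))
  expect_identical(preprocess("We used BLAST."), preprocess("We used BLAST."))
})

test_that("rules fire on dictionary, version, keyword and negative contexts", {
  d <- mini_dict()
  txt <- "Sequences were aligned with the ClustalW software (version 2.0)."
  cands <- apply_rules(preprocess(txt), txt, d)
  cw <- cands[cands$surface == "ClustalW", ]
  expect_equal(nrow(cw), 1L)
  expect_true(all(c(1L, 2L, 5L) %in% cw$rules[[1]]))  # dict, version, keyword
  expect_true(9L %in% cw$rules[[1]])                  # head association

  txt2 <- "Our novel clustering algorithm performed well."
  c2 <- apply_rules(preprocess(txt2), txt2, d)
  cl <- c2[c2$surface == "clustering", ]
  expect_true(6L %in% cl$rules[[1]])                  # negative keyword
  expect_lt(cl$raw_score, 0)

  txt3 <- "Nothing notable happens in this sentence."
  expect_equal(nrow(apply_rules(preprocess(txt3), txt3, d)), 0L)
})

test_that("document adjustment rewards repeated weak evidence and never lowers scores", {
  d <- mini_dict()
  # five weak occurrences vs a lone one
  weak5 <- paste(rep("GenBank holds the records.", 5), collapse = " ")
  c5 <- adjust_document_scores(apply_rules(preprocess(weak5), weak5, d))
  expect_true(all(c5$adjusted_score > c5$raw_score))
  lone <- "GenBank holds the records."
  c1 <- adjust_document_scores(apply_rules(preprocess(lone), lone, d))
  expect_equal(c1$adjusted_score, c1$raw_score)  # singleton: zero bonus
  # all-negative cohort floors at zero bonus
  neg <- paste(rep("Our clustering algorithm failed.", 3), collapse = " ")
  cn <- adjust_document_scores(apply_rules(preprocess(neg), neg, d))
  expect_true(all(cn$adjusted_score == cn$raw_score))
  expect_true(all(cn$adjusted_score >= cn$raw_score))
})

test_that("propagation promotes bare occurrences and never invents surfaces", {
  d <- mini_dict()
  cfg <- ner_config()
  # the seed occurrence crosses tau via keyword context; the later bare
  # occurrence of this non-dictionary name attracts no rule at all and only
  # becomes a mention through propagation
  txt <- paste("We analysed the samples with the Meridian pipeline.",
               "Meridian crashed repeatedly on malformed input.")
  cands <- adjust_document_scores(apply_rules(preprocess(txt), txt, d), cfg)
  expect_equal(sum(cands$surface == "Meridian"), 1L)
  out <- propagate_document_matches(cands, txt, cfg)
  expect_gte(nrow(out), nrow(cands))
  prop <- out[vapply(out$rules, function(r) 11L %in% r, logical(1)), ]
  expect_gt(nrow(prop), 0L)
  expect_equal(sum(out$surface == "Meridian"), 2L)
  for (i in seq_len(nrow(out))) {
    expect_equal(substring(txt, out$start[i] + 1, out$end[i]),
                 out$surface[i])
  }
  # nothing crosses threshold -> unchanged
  weaktxt <- "Our clustering algorithm is novel."
  weak <- adjust_document_scores(apply_rules(preprocess(weaktxt), weaktxt, d),
                                 cfg)
  expect_identical(propagate_document_matches(weak, weaktxt, cfg), weak)
})

test_that("acronym filter accepts matching long forms and rejects collisions", {
  d <- mini_dict()
  cfg <- ner_config()
  ok <- "Terms came from the Gene Ontology (GO). GO was browsed daily."
  cands <- adjust_document_scores(apply_rules(preprocess(ok), ok, d), cfg)
  res <- resolve_acronyms(cands, ok, d, cfg)
  go <- res[res$surface == "GO", ]
  expect_gt(nrow(go), 0L)
  expect_true(all(vapply(go$rules, function(r) 15L %in% r, logical(1))))

  bad <- "Activity of glucose oxidase (GO) was measured. GO was elevated."
  cb <- adjust_document_scores(apply_rules(preprocess(bad), bad, d), cfg)
  rb <- resolve_acronyms(cb, bad, d, cfg)
  expect_equal(nrow(rb[rb$surface == "GO", ]), 0L)

  nodef <- "GO was used to annotate genes."
  cn <- adjust_document_scores(apply_rules(preprocess(nodef), nodef, d), cfg)
  rn <- resolve_acronyms(cn, nodef, d, cfg)
  expect_identical(rn, cn)  # pass through unchanged
})

test_that("case/length adjustment follows the documented piecewise rule", {
  cw <- ner_config()$common_words
  s <- 2
  expect_gte(adjust_case_length(s, "BLAST", cw), s)
  expect_lt(adjust_case_length(s, "analysis", cw), s)
  expect_equal(adjust_case_length(s, "VeryLongMixedName", cw), s)
  # monotone in the underlying score
  grid <- seq(-2, 6, by = 0.5)
  for (sf in c("BLAST", "analysis", "ClustalW", "VeryLongMixedName")) {
    expect_true(all(diff(adjust_case_length(grid, sf, cw)) >= 0))
  }
})

test_that("thresholding is monotone and sorted by span", {
  d <- mini_dict()
  cfg <- ner_config()
  txt <- paste("We used the BLAST software. GenBank was queried.",
               "Our clustering algorithm ran. ClustalW v2.1 aligned reads.")
  cands <- adjust_document_scores(apply_rules(preprocess(txt), txt, d), cfg)
  all_in <- threshold_mentions(cands, tau = -Inf, config = cfg)
  expect_equal(nrow(all_in), nrow(cands))
  expect_true(all(diff(all_in$start) >= 0))
  none <- threshold_mentions(cands, tau = max(cands$adjusted_score) + 10,
                             config = cfg)
  expect_equal(nrow(none), 0L)
  taus <- sort(stats::runif(10, -3, 8))
  sizes <- vapply(taus, function(t)
    nrow(threshold_mentions(cands, tau = t, config = cfg)), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("recognition is deterministic and reaches strict F >= 0.6 pre-filter", {
  corp <- small_corpus()
  m1 <- small_mentions()
  m2 <- recognize_corpus(corp$articles[1:10], corp$dictionary)
  m1_sub <- m1[m1$doc_id %in% m2$doc_id, ]
  expect_equal(as.data.frame(m1_sub[order(m1_sub$doc_id, m1_sub$stream,
                                          m1_sub$start), ]),
               as.data.frame(m2[order(m2$doc_id, m2$stream, m2$start), ]))
  ev <- evaluate_mentions(m1, corp$gold)
  expect_gte(ev$f1[ev$mode == "strict"], 0.6)
})
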