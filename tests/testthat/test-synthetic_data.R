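test_that("dictionary generation is deterministic with exact ambiguity counts", {
  g1 <- generate_dictionary(100, ambiguity_rate = 0.2, seed = 5)
  g2 <- generate_dictionary(100, ambiguity_rate = 0.2, seed = 5)
  expect_identical(g1$truth, g2$truth)
  expect_equal(sum(g1$truth$ambiguous), 20L)
  g0 <- generate_dictionary(50, ambiguity_rate = 0, seed = 5)
  expect_equal(sum(g0$truth$ambiguous), 0L)
  # canonical names are unique under normalisation
  expect_equal(anyDuplicated(normalise_name(g1$truth$canonical)), 0L)
  # acronym entries carry expansions
  expect_true(all(!is.na(g1$truth$expansion[g1$truth$is_acronym])))
})

test_that("corpus generation aligns gold spans with emitted text exactly", {
  corp <- small_corpus()
  arts <- corp$articles
  names(arts) <- vapply(arts, `[[`, character(1), "doc_id")
  g <- corp$gold
  for (i in seq_len(nrow(g))) {
    a <- arts[[g$doc_id[i]]]
    s <- if (g$stream[i] == "body") a$body else a$captions[[g$caption_idx[i]]]
    expect_identical(substring(s, g$start[i] + 1, g$end[i]), g$surface[i])
  }
})

test_that("the truth table is the recount of the gold annotations", {
  corp <- small_corpus()
  dm <- corpus_meta(corp$articles)
  recount <- dplyr::summarise(
    dplyr::group_by(dplyr::left_join(corp$gold, dm, by = "doc_id"),
                    canonical, year, journal),
    mention_count = dplyr::n(),
    doc_count = dplyr::n_distinct(doc_id), .groups = "drop")
  key <- function(df) {
    df <- as.data.frame(df[order(df$canonical, df$year, df$journal), ])
    rownames(df) <- NULL
    df
  }
  expect_equal(key(recount),
               key(corp$truth)[, colnames(recount)], ignore_attr = TRUE)
})

test_that("generation is deterministic and degenerate sizes work", {
  c1 <- generate_corpus(generator_config(n_articles = 12, seed = 3))
  c2 <- generate_corpus(generator_config(n_articles = 12, seed = 3))
  expect_identical(lapply(c1$articles, `[[`, "body"),
                   lapply(c2$articles, `[[`, "body"))
  expect_identical(c1$gold, c2$gold)
  c0 <- generate_corpus(generator_config(n_articles = 0, seed = 3))
  expect_length(c0$articles, 0L)
  expect_equal(nrow(c0$gold), 0L)
})

test_that("written corpora are readable standoff + XML", {
  corp <- generate_corpus(generator_config(n_articles = 5, seed = 9))
  dir <- withr::local_tempdir()
  write_corpus(corp, dir)
  xmls <- list.files(dir, pattern = "\\.xml$", full.names = TRUE)
  expect_length(xmls, 5L)
  rc <- read_corpus(xmls, "jats_xml")
  expect_equal(rc$n_skipped, 0L)
  bodies_in <- sort(vapply(corp$articles, `[[`, character(1), "body"))
  bodies_out <- sort(vapply(rc$articles, `[[`, character(1), "body"))
  expect_identical(bodies_out, bodies_in)
})

test_that("usage frequencies follow the configured Zipf law", {
  s <- sample_truth_usage(generator_config(n_articles = 2000L, seed = 41))
  cnt <- tapply(s$truth$mention_count, s$truth$canonical, sum)
  expect_lt(abs(estimate_zipf_exponent(cnt) - 1.1), 0.1)
})

test_that("labelled candidate profiles have the advertised Bayes AUC", {
  # identical profiles: chance
  expect_equal(bayes_auc(rep(0.3, 17), rep(0.3, 17)), 0.5)
  # fully disjoint supports: perfect
  tp <- rep(0, 17); tp[1] <- 1
  fp <- rep(0, 17)
  expect_equal(bayes_auc(tp, fp), 1.0)
  # single informative rule, hand-computed:
  # AUC = P(T=1)P(F=0) + 0.5 * (P(1,1) + P(0,0))
  #     = .8*.8 + .5*(.8*.2 + .2*.8) = 0.80
  tp2 <- rep(0.3, 17); fp2 <- rep(0.3, 17)
  tp2[4] <- 0.8; fp2[4] <- 0.2
  expect_equal(bayes_auc(tp2, fp2), 0.80)
  # generated labels are balanced-ish and deterministic under seed
  l1 <- generate_labeled_candidates(500, seed = 6)
  l2 <- generate_labeled_candidates(500, seed = 6)
  expect_identical(l1, l2)
  expect_true(all(c("true_positive", "false_positive") %in% l1$label))
})

test_that("captions prefer visualisation tools when flagged", {
  corp <- main_corpus()
  vis <- corp$dict_truth$canonical[corp$dict_truth$vis]
  capg <- corp$gold[corp$gold$stream == "caption", ]
  # visualisation tools are a small minority of the dictionary but a large
  # share of caption mentions
  vis_rate_dict <- mean(corp$dict_truth$vis)
  vis_rate_caps <- mean(capg$canonical %in% vis)
  expect_gt(vis_rate_caps, 5 * vis_rate_dict)
})
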