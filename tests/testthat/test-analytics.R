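toy_usage <- function() {
  # hand-built 3-partition usage table
  mk <- function(id, j, y) new_article(doc_id = id, journal = j, year = y,
                                       body = "x")
  arts <- list(mk("d1", "JBio", 2005L), mk("d2", "JBio", 2006L),
               mk("d3", "JMed", 2005L), mk("d4", "JFree", 2006L))
  catalog <- tibble::tibble(journal = c("JBio", "JMed"),
                            codes = list("H01.158.273", "H02.403"))
  parts <- partition_corpus(arts, catalog)
  mentions <- tibble::tibble(
    doc_id = c("d1", "d1", "d1", "d2", "d3", "d4"),
    canonical = c("ToolA", "ToolA", "ToolA", "ToolA", "ToolB", "ToolC"))
  u <- aggregate_usage(mentions, parts, corpus_meta(arts))
  list(u = u, parts = parts, arts = arts, mentions = mentions)
}

test_that("usage aggregation counts both levels and matches a naive recount", {
  t <- toy_usage()
  full <- t$u$cells[t$u$cells$partition == "full", ]
  a_d1 <- full[full$canonical == "ToolA" & full$year == 2005, ]
  expect_equal(a_d1$mention_count, 3L)  # 3 mentions in one doc
  expect_equal(a_d1$doc_count, 1L)
  # empty mention stream
  e <- aggregate_usage(t$mentions[0, ], t$parts, corpus_meta(t$arts))
  expect_equal(nrow(e$cells), 0L)
  # brute-force oracle on a generated corpus
  corp <- small_corpus()
  parts <- partition_corpus(corp$articles, corp$catalog)
  m <- small_mentions()
  u <- aggregate_usage(m, parts, corpus_meta(corp$articles))
  for (p in c("full", "bioinformatics")) {
    naive <- naive_usage_count(
      dplyr::left_join(m[, c("doc_id", "canonical")],
                       corpus_meta(corp$articles), by = "doc_id"),
      parts[[p]]$doc_ids)
    got <- as.data.frame(u$cells[u$cells$partition == p,
                                 c("canonical", "year", "journal",
                                   "mention_count", "doc_count")])
    key <- function(df) df[order(df$canonical, df$year, df$journal), ]
    expect_equal(key(got), key(naive), ignore_attr = TRUE)
  }
})

test_that("mean mentions per document reproduces printed arithmetic", {
  expect_equal(mean_mentions_per_document(797501, 25851), 30.8)
  expect_equal(mean_mentions_per_document(3926176, 713634), 5.5)
  expect_equal(mean_mentions_per_document(0, 100), 0.0)
  expect_error(mean_mentions_per_document(10, 0), "positive")
})

test_that("top resources rank correctly with alphabetical tie-breaks", {
  t <- toy_usage()
  top <- top_resources(t$u, "full", "document", n = 10)
  expect_equal(top$canonical[1], "ToolA")
  expect_equal(top$value[1], 2 / 4)  # 2 of 4 docs
  # ties broken alphabetically: ToolB and ToolC both in 1 doc
  expect_equal(top$canonical[2:3], c("ToolB", "ToolC"))
  # n larger than distinct resources returns everything
  expect_equal(nrow(top), 3L)
  expect_error(top_resources(t$u, "nope", "document"), "unknown partition")
  # mention level: average mentions per document
  topm <- top_resources(t$u, "full", "mention")
  expect_equal(topm$value[topm$canonical == "ToolA"], 4 / 4)
})

test_that("journal proportions reproduce printed arithmetic and thresholds", {
  counts <- tibble::tibble(
    journal = c("BMC Bioinformatics", "Tiny J", "Silent J"),
    articles = c(6033L, 999L, 2000L),
    mentions = c(203882L, 5000L, 0L))
  jp <- journal_proportions_from_counts(counts, min_articles = 1000L)
  expect_equal(jp$proportion[jp$journal == "BMC Bioinformatics"], 33.8)
  expect_false("Tiny J" %in% jp$journal)       # 999 articles: excluded
  expect_equal(jp$proportion[jp$journal == "Silent J"], 0.0)
  # usage-table route agrees with the counts route
  t <- toy_usage()
  jpu <- journal_proportions(t$u, min_articles = 1L)
  expect_equal(jpu$mentions[jpu$journal == "JBio"], 4L)
  expect_equal(jpu$proportion[jpu$journal == "JBio"], 2.0)
})

test_that("relative usage pools normalise to one and match a brute-force recount", {
  set.seed(5)
  cells <- expand.grid(canonical = paste0("Res", 1:20), year = 2001:2005,
                       journal = "J1", stringsAsFactors = FALSE)
  cells$mention_count <- rpois(nrow(cells), 4) + 1L
  cells$doc_count <- pmax(1L, cells$mention_count - 1L)
  dm <- tibble::tibble(doc_id = paste0("d", 1:50), journal = "J1",
                       year = rep(2001:2005, 10))
  parts <- list(full = list(name = "full", journal_names = "J1",
                            doc_ids = dm$doc_id))
  u <- usage_from_cells(tibble::as_tibble(cells), parts, dm)
  ser <- relative_usage_series(u, "full", 2001:2005, pool = 10)
  sums <- tapply(ser$x, ser$year, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # brute-force recomputation for one year
  y <- 2003
  yc <- cells[cells$year == y, ]
  yc <- yc[order(-yc$doc_count, yc$canonical), ]
  cutoff <- yc$doc_count[10]
  pool <- yc[yc$doc_count >= cutoff, ]
  sy <- ser[ser$year == y, ]
  expect_setequal(sy$canonical, pool$canonical)
  expect_equal(sy$x[match(pool$canonical, sy$canonical)],
               pool$doc_count / sum(pool$doc_count))
  # single-resource corpus: x = 1 every year
  one <- usage_from_cells(tibble::as_tibble(cells[cells$canonical == "Res1", ]),
                          parts, dm)
  s1 <- relative_usage_series(one, "full", 2001:2005)
  expect_true(all(s1$x == 1))
})

test_that("Year0 normalisation starts every series at exactly one", {
  ser <- tibble::tibble(canonical = c("A", "A", "B"),
                        year = c(2001L, 2002L, 2003L),
                        x = c(0.02, 0.04, 0.5))
  norm <- normalize_to_year0(ser)
  expect_equal(norm$value[norm$canonical == "A"], c(1.0, 2.0))
  expect_equal(norm$value[norm$canonical == "B"], 1.0)
  const <- normalize_to_year0(tibble::tibble(canonical = "C",
                                             year = 2001:2004,
                                             x = rep(0.3, 4)))
  expect_true(all(const$value == 1))
})

test_that("random-walk envelope has sqrt-t width and nominal null coverage", {
  # constant series: degenerate bounds collapse to the baseline
  const <- normalize_to_year0(tibble::tibble(
    canonical = rep(c("A", "B"), each = 4), year = rep(2001:2004, 2),
    x = rep(0.25, 8)))
  rw0 <- random_walk_bounds(const, horizon = 4)
  expect_true(rw0$degenerate)
  expect_true(all(rw0$bounds$lower == 1 & rw0$bounds$upper == 1))
  # width scaling: width(4) = 2 * width(1)
  set.seed(42)
  walks <- lapply(1:400, function(i) 1 + cumsum(rnorm(12, 0, 0.3)))
  norm <- dplyr::bind_rows(lapply(seq_along(walks), function(i)
    tibble::tibble(canonical = paste0("w", i), year = 2000 + 0:12,
                   offset = 0:12, value = c(1, walks[[i]]))))
  rw <- random_walk_bounds(norm, horizon = 12)
  width <- rw$bounds$upper - rw$bounds$lower
  expect_equal(width[4] / width[1], 2, tolerance = 1e-9)
  # null coverage at each offset near the nominal level (n = 400 here;
  # the acceptance suite re-checks at 1000 replicates)
  cov <- vapply(1:12, function(t) {
    v <- vapply(walks, `[`, numeric(1), t)
    mean(v >= rw$bounds$lower[t] & v <= rw$bounds$upper[t])
  }, numeric(1))
  expect_true(all(abs(cov - 0.95) <= 0.03))
  expect_error(random_walk_bounds(const[1, ]), "steps")
})

test_that("change score sums absolute consecutive differences", {
  expect_equal(delta_sigma(c(0.1, 0.3, 0.2)), 0.3)
  expect_equal(delta_sigma(rep(0.4, 5)), 0)
  expect_equal(delta_sigma(0.7), 0)
  # >= 0, zero iff constant, invariant under constant shifts
  set.seed(1)
  for (i in 1:20) {
    x <- runif(sample(2:8, 1))
    expect_gte(delta_sigma(x), 0)
    expect_equal(delta_sigma(x), delta_sigma(x + 3.7))
    if (delta_sigma(x) == 0) expect_true(all(x == x[1]))
  }
  tab <- delta_sigma_table(tibble::tibble(
    canonical = c("A", "A", "A", "B"), year = c(2001:2003, 2005),
    x = c(0.1, 0.3, 0.2, 0.9)))
  expect_equal(tab$delta_sigma[tab$canonical == "A"], 0.3)
  expect_false("B" %in% tab$canonical)  # single-year resources dropped
})

test_that("persistence selects unbroken runs outside year zero", {
  mkcells <- function(name, years) tibble::tibble(
    canonical = name, year = years, journal = "J",
    mention_count = 1L, doc_count = 1L)
  cells <- dplyr::bind_rows(
    mkcells("Steady", 2003:2013),
    mkcells("Gappy", c(2003:2008, 2010:2013)),
    mkcells("Ancient", c(2000, 2001:2013)),
    mkcells("Gone", 2004:2009))
  dm <- tibble::tibble(doc_id = "d1", journal = "J", year = 2005L)
  parts <- list(full = list(name = "full", journal_names = "J",
                            doc_ids = "d1"))
  u <- usage_from_cells(cells, parts, dm)
  ps <- persistence_set(u, "full", start_year = 2000L, end_year = 2013L)
  expect_true("Steady" %in% ps$canonical)
  expect_true(ps$current[ps$canonical == "Steady"])
  expect_false("Gappy" %in% ps$canonical)    # gap in 2009
  expect_false("Ancient" %in% ps$canonical)  # mentioned in year zero
  expect_true("Gone" %in% ps$canonical)
  expect_false(ps$current[ps$canonical == "Gone"])
})

test_that("long-tail summary matches hand-computed shares", {
  zipf <- tibble::tibble(
    canonical = paste0("R", 1:10), year = 2005L, journal = "J",
    mention_count = c(100L, 50L, 33L, 25L, 20L, 17L, 14L, 13L, 11L, 10L),
    doc_count = c(100L, 50L, 33L, 25L, 20L, 17L, 14L, 13L, 11L, 10L))
  dm <- tibble::tibble(doc_id = "d1", journal = "J", year = 2005L)
  parts <- list(full = list(name = "full", journal_names = "J",
                            doc_ids = "d1"))
  u <- usage_from_cells(zipf, parts, dm)
  lt <- long_tail_summary(u, "full")
  total <- 293
  expect_equal(lt$n_resources, 10L)
  expect_equal(lt$singleton_fraction, 0)
  expect_equal(lt$top_1_share, 100 / total)
  expect_equal(lt$top_10_share, 1)
  expect_equal(lt$top_5pct_share, 100 / total)  # ceil(0.5) = 1 name
  # all singletons
  ones <- zipf; ones$mention_count <- 1L; ones$doc_count <- 1L
  u1 <- usage_from_cells(ones, parts, dm)
  lt1 <- long_tail_summary(u1, "full")
  expect_equal(lt1$singleton_fraction, 1)
  expect_equal(lt1$singleton_mention_share, 1)
  # top-5% share >= 0.05 whenever n >= 20
  set.seed(8)
  for (i in 1:15) {
    n <- sample(20:120, 1)
    rnd <- tibble::tibble(canonical = paste0("X", 1:n), year = 2005L,
                          journal = "J",
                          mention_count = rpois(n, 3) + 1L,
                          doc_count = rpois(n, 3) + 1L)
    lt2 <- long_tail_summary(usage_from_cells(rnd, parts, dm), "full")
    expect_gte(lt2$top_5pct_share, 0.05)
  }
  expect_error(long_tail_summary(usage_from_cells(zipf[0, ], parts, dm),
                                 "full"), "empty")
})

test_that("name overlap catches disjoint, nested and hand-counted cases", {
  dm <- tibble::tibble(doc_id = c("d1", "d2", "d3"),
                       journal = c("J1", "J2", "J3"),
                       year = 2005L)
  parts <- list(
    full = list(name = "full", journal_names = c("J1", "J2", "J3"),
                doc_ids = c("d1", "d2", "d3")),
    medicine = list(name = "medicine", journal_names = "J1", doc_ids = "d1"),
    biology = list(name = "biology", journal_names = c("J2", "J3"),
                   doc_ids = c("d2", "d3")),
    bioinformatics = list(name = "bioinformatics", journal_names = "J3",
                          doc_ids = "d3"))
  cells <- tibble::tibble(
    canonical = c("MedOnly", "Shared", "BioOnly", "Shared", "DeepTool"),
    year = 2005L,
    journal = c("J1", "J1", "J2", "J2", "J3"),
    mention_count = 1L, doc_count = 1L)
  u <- usage_from_cells(cells, parts, dm)
  ov <- name_overlap(u)
  per <- ov$per_partition
  # bioinformatics is nested in biology: nothing is unique to it
  expect_equal(per$pct_unique[per$partition == "bioinformatics"], 0)
  expect_equal(per$n_unique[per$partition == "medicine"], 1L)  # MedOnly
  expect_equal(per$pct_unique[per$partition == "medicine"], 50)
  inter <- ov$intersections
  expect_equal(inter$n_shared[inter$a == "medicine" & inter$b == "biology"],
               1L)  # Shared
  # disjoint vocabularies are 100% unique
  cells2 <- tibble::tibble(canonical = c("A", "B"), year = 2005L,
                           journal = c("J1", "J2"),
                           mention_count = 1L, doc_count = 1L)
  ov2 <- name_overlap(usage_from_cells(cells2, parts, dm),
                      c("medicine", "biology"))
  expect_true(all(ov2$per_partition$pct_unique == 100))
})

test_that("Zipf exponent estimation recovers a planted law", {
  s <- sample_truth_usage(generator_config(n_articles = 2000L, seed = 33))
  cnt <- tapply(s$truth$mention_count, s$truth$canonical, sum)
  est <- estimate_zipf_exponent(cnt)
  expect_lt(abs(est - 1.1), 0.1)
})
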