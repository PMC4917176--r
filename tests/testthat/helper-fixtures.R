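# shared fixtures, memoised so expensive corpora are built once per session

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures, inherits = FALSE)
}

fixture_dict <- function() {
  memo("dict", load_dictionary(
    system.file("extdata", "resource_dictionary.tsv", package = "resmine")))
}

# small gold corpus for recogniser/zoner unit tests
small_corpus <- function() {
  memo("corp_small", generate_corpus(
    generator_config(n_articles = 120, seed = 11)))
}

small_mentions <- function() {
  memo("m_small", {
    corp <- small_corpus()
    recognize_corpus(corp$articles, corp$dictionary)
  })
}

# full-size study corpus shared by the acceptance checks
main_corpus <- function() {
  memo("corp_main", generate_corpus(generator_config(seed = 101)))
}

main_mentions <- function() {
  memo("m_main", {
    corp <- main_corpus()
    recognize_corpus(corp$articles, corp$dictionary)
  })
}

main_filtered <- function() {
  memo("m_main_filtered", {
    corp <- main_corpus()
    m <- main_mentions()
    lab <- label_mentions(m, corp$gold, "lenient")
    model <- train_filter(lab, "random_forest", seed = 7)
    list(model = model,
         kept = apply_filter(m, model, confidence = 0.80),
         labelled = lab)
  })
}

jats_fixture <- function() {
  paste0(
    "<article><front>",
    "<journal-meta><journal-title>Fixture J Biol</journal-title></journal-meta>",
    "<article-meta><title-group><article-title>A fixture</article-title>",
    "</title-group><pub-date><year>2007</year></pub-date></article-meta>",
    "</front><body>",
    "<sec><title>Introduction</title><p>We searched many resources.</p></sec>",
    "<sec><title>Methods</title><p>We used the BLAST software.</p>",
    "<p>Counts were computed in R.</p></sec>",
    "<fig><caption><p>A plot made with <italic>ImageJ</italic>.</p></caption></fig>",
    "</body></article>")
}

# independent naive usage counter: plain loops, no dplyr, for oracle checks
naive_usage_count <- function(mentions, doc_ids) {
  mm <- mentions[mentions$doc_id %in% doc_ids, , drop = FALSE]
  cells <- list()
  for (i in seq_len(nrow(mm))) {
    key <- paste(mm$canonical[i], mm$year[i], mm$journal[i], sep = "\r")
    if (is.null(cells[[key]])) cells[[key]] <- list(n = 0L, docs = character())
    cells[[key]]$n <- cells[[key]]$n + 1L
    cells[[key]]$docs <- union(cells[[key]]$docs, mm$doc_id[i])
  }
  out <- data.frame(key = names(cells),
                    mention_count = vapply(cells, `[[`, integer(1), "n"),
                    doc_count = vapply(cells, function(c) length(c$docs),
                                       integer(1)))
  parts <- do.call(rbind, strsplit(out$key, "\r", fixed = TRUE))
  data.frame(canonical = parts[, 1], year = as.integer(parts[, 2]),
             journal = parts[, 3], mention_count = out$mention_count,
             doc_count = out$doc_count, row.names = NULL)
}

# exhaustive maximum-cardinality bipartite span matching for <= 8 spans
exhaustive_match <- function(gold, system, mode) {
  ng <- nrow(gold); ns <- nrow(system)
  if (ng == 0 || ns == 0) return(0L)
  ok <- matrix(FALSE, ng, ns)
  for (i in seq_len(ng)) for (j in seq_len(ns)) {
    ok[i, j] <- if (mode == "strict") {
      gold$start[i] == system$start[j] && gold$end[i] == system$end[j]
    } else {
      min(gold$end[i], system$end[j]) > max(gold$start[i], system$start[j])
    }
  }
  best <- 0L
  rec <- function(i, used) {
    if (i > ng) return(0L)
    b <- rec(i + 1L, used)  # leave gold i unmatched
    for (j in seq_len(ns)) {
      if (!used[j] && ok[i, j]) {
        used2 <- used; used2[j] <- TRUE
        b <- max(b, 1L + rec(i + 1L, used2))
      }
    }
    b
  }
  rec(1L, rep(FALSE, ns))
}

# random disjoint spans within [0, width)
random_disjoint_spans <- function(n, width = 200L) {
  starts <- sort(sample.int(width - 6L, n))
  out_s <- integer(); out_e <- integer(); last_end <- 0L
  for (s in starts) {
    if (s < last_end) next
    e <- min(s + sample(1:5, 1), width)
    out_s <- c(out_s, s); out_e <- c(out_e, e)
    last_end <- e
  }
  data.frame(start = out_s, end = out_e)
}
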