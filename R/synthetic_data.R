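#' Synthetic corpora with gold annotations
#'
#' Generates corpora with known ground truth so every pipeline stage can be
#' evaluated without external downloads: multi-section articles with
#' captions and journal/year metadata, resource mentions drawn from a
#' Zipfian usage law with journal-domain preferences, planted temporal
#' growth/decline trends, ambiguous common-word resource names that also
#' occur as ordinary words, acronym definitions (correct and colliding),
#' and gold standoff annotations whose spans slice the emitted text
#' exactly. Sentence templates embed mentions in the contextual frames the
#' recognition rules target (keyword-adjacent, versioned, URL-adjacent,
#' Hearst, citation-adjacent, bare) with configurable mixture weights.
#'
#' @name synthetic_data
NULL

.SYLLABLES <- c("Gen", "Seq", "Prot", "Bio", "Map", "Net", "Path", "Chem",
                "Trans", "Meta", "Omni", "Align", "Fold", "Dock", "Var",
                "Phylo", "Reg", "Exo", "Iso", "Glyco", "Micro", "Macro",
                "Chromo", "Lig", "Nucleo", "Ribo", "Stat", "Quant")
.SUFFIXES <- c("DB", "Base", "Bank", "Tool", "Viewer", "Finder", "Aligner",
               "Scan", "Explorer", "Atlas", "Miner", "Press", "Works")
.ACRO_WORDS <- c("Gene", "Genome", "Protein", "Sequence", "Expression",
                 "Atlas", "Ontology", "Alignment", "Network", "Resource",
                 "Repository", "Analysis", "Mapping", "Annotation",
                 "Archive", "Index", "Catalog", "Browser", "Registry",
                 "Knowledgebase", "Variation", "Pathway", "Structure",
                 "Interaction", "Phenotype")
.FAKE_NAMES <- c("Horizon", "Aurora", "Meridian", "Cascade", "Lattice",
                 "Beacon", "Vertex", "Quartz", "Summit", "Pinnacle")

#' Generate a synthetic resource dictionary
#'
#' `n` entries with types in DB/SW/PK/ONT. Exactly `round(n *
#' ambiguity_rate)` names are ambiguous common English words (lower-case,
#' drawn from the recogniser's common-word list) to exercise the
#' false-positive machinery; roughly a quarter of the remaining names are
#' acronyms carrying expected expansions; a subset of software names is
#' flagged as visualisation tools (upweighted in captions).
#'
#' @param n number of entries (>= 1).
#' @param ambiguity_rate fraction of ambiguous common-word names.
#' @param seed integer seed (mandatory; same seed gives an identical
#'   dictionary).
#' @return list with `dictionary` (`resmine_dictionary`) and `truth`
#'   (tibble: canonical, rtype, ambiguous, is_acronym, expansion, vis).
#' @export
generate_dictionary <- function(n, ambiguity_rate = 0.1, seed) {
  stopifnot(n >= 1, ambiguity_rate >= 0, ambiguity_rate <= 1)
  set.seed(seed)
  n_amb <- round(n * ambiguity_rate)
  common <- ner_config()$common_words
  amb <- if (n_amb > 0) {
    base <- rep_len(common, n_amb)
    dup <- duplicated(base)
    base[dup] <- paste0(base[dup], seq_len(sum(dup)))
    base
  } else character()

  n_rest <- n - n_amb
  names_out <- character(0)
  expans <- character(0)
  used <- tolower(amb)
  mk_unique <- function(nm) {
    key <- tolower(normalise_name(nm))
    while (key %in% used) {
      nm <- paste0(nm, sample(c("X", "Z", "Q", "Pro", "Plus", "Lite", "Max",
                                "Neo", "Ultra", "II", "XL"), 1))
      key <- tolower(normalise_name(nm))
    }
    used <<- c(used, key)
    nm
  }
  styles <- sample(c("camel", "suffix", "acronym", "word"), n_rest,
                   replace = TRUE, prob = c(0.35, 0.25, 0.25, 0.15))
  for (st in styles) {
    if (st == "camel") {
      nm <- mk_unique(paste0(sample(.SYLLABLES, 1), tolower(sample(.SYLLABLES, 1))))
      ex <- NA_character_
    } else if (st == "suffix") {
      nm <- mk_unique(paste0(sample(.SYLLABLES, 1), sample(.SUFFIXES, 1)))
      ex <- NA_character_
    } else if (st == "acronym") {
      w <- sample(.ACRO_WORDS, sample(2:4, 1))
      nm <- mk_unique(paste(substr(w, 1, 1), collapse = ""))
      ex <- paste(w, collapse = " ")
    } else {
      nm <- mk_unique(paste0(sample(.SYLLABLES, 1), sample(c("on", "ix", "ar", "us", "ea"), 1)))
      ex <- NA_character_
    }
    names_out <- c(names_out, nm)
    expans <- c(expans, ex)
  }
  canonical <- c(amb, names_out)
  expansion <- c(rep(NA_character_, n_amb), expans)
  rtype <- sample(c("DB", "SW", "PK", "ONT"), n, replace = TRUE,
                  prob = c(0.35, 0.4, 0.15, 0.1))
  truth <- tibble::tibble(
    canonical = canonical, rtype = rtype,
    ambiguous = c(rep(TRUE, n_amb), rep(FALSE, n_rest)),
    is_acronym = !is.na(expansion), expansion = expansion,
    vis = rtype == "SW" & stats::runif(n) < 0.15)
  entries <- tibble::tibble(canonical = canonical, rtype = rtype,
                            source = "synthetic", expansion = expansion)
  d <- new_dictionary(entries)
  list(dictionary = d, truth = truth)
}

#' Default journal profiles for the generator
#'
#' Seven synthetic journals spanning the subject hierarchy: two
#' bioinformatics journals (code under biology, making bioinformatics a
#' strict subset of biology), two biology, two medicine, and one
#' uncatalogued multidisciplinary journal that belongs only to the full
#' corpus.
#'
#' @return tibble: journal, code, weight, and domain weights (bioinf, bio,
#'   med).
#' @export
default_journal_profiles <- function() {
  tibble::tibble(
    journal = c("Synth J Bioinformatics", "Synth Comput Biol",
                "Synth Genome Res", "Synth Mol Cell Biol",
                "Synth Clin Med", "Synth Intern Med Rep",
                "Synth Multidiscip Sci"),
    code = c("H01.158.273.180", "H01.158.273.180",
             "H01.158.273", "H01.158.273",
             "H02.403", "H02.403", ""),
    weight = c(0.14, 0.10, 0.16, 0.14, 0.16, 0.10, 0.20),
    w_bioinf = c(3, 3, 1.5, 1.2, 0.5, 0.5, 1),
    w_bio = c(1.5, 1.5, 3, 3, 0.8, 0.8, 1),
    w_med = c(0.4, 0.4, 0.8, 0.8, 3, 3, 1))
}

#' Generator configuration
#'
#' Defaults define the study conditions emulated throughout the package: a
#' 2,000-article corpus over publication years 2000-2013, a 3,000-name
#' dictionary with 1% ambiguous common-word names, Zipf exponent 1.1 for
#' resource usage (yielding a pronounced long tail: roughly half the
#' mentioned names occur once), about six mentions per article, a planted
#' strongly growing resource and a planted declining resource, and
#' distractor sentences that use ambiguous names as ordinary words.
#'
#' @param n_articles number of articles.
#' @param years publication-year span.
#' @param n_resources dictionary size.
#' @param ambiguity_rate fraction of common-word names.
#' @param zipf_exponent exponent of the rank-frequency usage law.
#' @param mention_rate Poisson mean of mention instances per article.
#' @param distractor_rate Poisson mean of ambiguous-word distractor
#'   sentences per article.
#' @param noise_rate Poisson mean of fake-proper-name resource-frame
#'   sentences per article.
#' @param caption_prob probability an article carries captions.
#' @param caption_mention_prob probability a caption mentions a resource.
#' @param frame_weights mixture over mention frames (keyword, versioned,
#'   url, hearst, reference, bare).
#' @param trend_grow,trend_decline yearly slopes of the two planted trend
#'   resources (sampling-weight multiplier `1 + slope * (year - year0)`,
#'   floored at 0.05).
#' @param trend_grow_rank,trend_decline_rank Zipf ranks the planted trend
#'   resources are assigned to.
#' @param acronym_definition_prob probability the first mention of an
#'   acronym resource in an article is introduced as "Long Form (ACR)".
#' @param acronym_mismatch_prob probability an article defines a colliding
#'   (non-resource) long form for some acronym and uses it.
#' @param seed integer seed (mandatory).
#' @return config list.
#' @export
generator_config <- function(n_articles = 2000L, years = 2000:2013,
                             n_resources = 3000L, ambiguity_rate = 0.01,
                             zipf_exponent = 1.1, mention_rate = 6,
                             distractor_rate = 1.2, noise_rate = 0.5,
                             caption_prob = 0.6, caption_mention_prob = 0.7,
                             frame_weights = c(keyword = 0.30,
                                               versioned = 0.20, url = 0.10,
                                               hearst = 0.05,
                                               reference = 0.05, bare = 0.30),
                             trend_grow = 0.35, trend_decline = -0.06,
                             trend_grow_rank = 25L, trend_decline_rank = 8L,
                             acronym_definition_prob = 0.5,
                             acronym_mismatch_prob = 0.05,
                             seed) {
  stopifnot(!missing(seed))
  as.list(environment())
}

# sentence with one embedded mention; returns text + local (0-based) span
mk_sent <- function(prefix, name, suffix) {
  list(text = paste0(prefix, name, suffix),
       start = nchar(prefix), end = nchar(prefix) + nchar(name))
}

.FILLERS <- c(
  "This method improves on previous approaches in several respects.",
  "The patients were recruited between 2004 and 2009 at two centres.",
  "Our approach follows established statistical procedures.",
  "Transcript abundance was measured for each biological sample.",
  "The algorithm converged after a small number of iterations.",
  "Samples were collected under an approved study protocol.",
  "Each measurement was repeated three times for consistency.",
  "These findings agree with earlier reports in the field.",
  "Further work is needed to confirm these observations.",
  "The remaining parameters were left at their default values.")

.FRAME_TEMPLATES <- list(
  keyword = list(
    c("We used the ", " software to process the raw samples."),
    c("All variants were stored in the ", " database for later use."),
    c("Counts were normalised with the ", " package before testing."),
    c("Annotations were retrieved from the ", " database in batch mode.")),
  versioned = list(
    c("Sequences were aligned with ", " (version %s) under default settings."),
    c("Reads were mapped using ", " v%s with standard parameters.")),
  url = list(
    c("Data were downloaded from ", " (http://www.%s.org) as flat files."),
    c("Records were obtained through ", " (http://%s.example.org) in 2013.")),
  hearst = list(
    c("Public databases such as ", " were searched for each candidate locus."),
    c("Analysis tools such as ", " have become widespread in recent years.")),
  reference = list(
    c("", " [12] was used for the normalisation step."),
    c("", " [3] produced the final consensus calls.")),
  bare = list(
    c("", " was run on each sample separately."),
    c("The output of ", " was converted to a standard format."),
    c("Results produced by ", " were summarised for all cohorts.")))

.DISTRACTOR_PLAIN <- list(
  c("The ", " of samples showed a consistent expression pattern."),
  c("A clear ", " emerged when comparing the two cohorts."),
  c("Differences in ", " were observed between groups."))
.DISTRACTOR_RESOURCEY <- list(
  c("Records were organised in a custom ", " database maintained locally."),
  c("We built an in-house ", " tool for routine checks."),
  c("Output was loaded into the local ", " database each week."))
.NOISE_TEMPLATES <- list(
  c("The ", " pipeline produced consistent estimates across runs."),
  c("Estimates from the ", " toolkit were broadly similar."))

.CAPTION_TEMPLATES <- list(
  c("Heatmap generated with ", " showing expression profiles across samples."),
  c("Distribution of quality scores as rendered by ", " for the full cohort."),
  c("Overview of the workflow; plots were produced with ", "."))

realize_mention_sentence <- function(frame, surface, slug) {
  tpl <- .FRAME_TEMPLATES[[frame]]
  t <- tpl[[sample.int(length(tpl), 1)]]
  suffix <- t[2]
  if (frame == "versioned") {
    suffix <- sprintf(suffix, paste0(sample(1:9, 1), ".", sample(0:9, 1)))
  } else if (frame == "url") {
    suffix <- sprintf(suffix, slug)
  }
  mk_sent(t[1], surface, suffix)
}

#' Generate a synthetic corpus
#'
#' See [generator_config()] for the knobs. Resource usage follows a Zipf
#' law with the configured exponent (modulated by journal-domain
#' preferences and the planted trends); gold spans align exactly with the
#' emitted text; the returned truth table is the recount of the gold
#' annotations.
#'
#' @param config list from [generator_config()].
#' @return list with `articles` (list of `resmine_article`), `gold` (tibble:
#'   doc_id, stream, caption_idx, start, end, canonical, surface), `truth`
#'   (tibble: canonical, year, journal, mention_count, doc_count),
#'   `dictionary`, `dict_truth`, `catalog` (journal catalog tibble) and
#'   `config`.
#' @export
generate_corpus <- function(config) {
  dict <- generate_dictionary(config$n_resources, config$ambiguity_rate,
                              seed = config$seed)
  d <- dict$dictionary
  dtruth <- dict$truth
  set.seed(config$seed + 1L)
  nres <- nrow(dtruth)

  # Zipf base weights over a random rank assignment
  rank_of <- sample.int(nres)
  base_w <- rank_of^(-config$zipf_exponent)
  domain <- sample(c("bioinf", "bio", "med"), nres, replace = TRUE,
                   prob = c(0.5, 0.3, 0.2))
  trend_slope <- rep(0, nres)
  gi <- which(rank_of == min(config$trend_grow_rank, nres))
  di <- which(rank_of == min(config$trend_decline_rank, nres))
  trend_slope[gi] <- config$trend_grow
  trend_slope[di] <- config$trend_decline
  vis_idx <- which(dtruth$vis)
  acro_idx <- which(dtruth$is_acronym)

  profiles <- default_journal_profiles()
  catalog <- tibble::tibble(
    journal = profiles$journal[nzchar(profiles$code)],
    codes = as.list(profiles$code[nzchar(profiles$code)]))

  slug_of <- tolower(gsub("[^A-Za-z0-9]", "-", dtruth$canonical))

  articles <- vector("list", config$n_articles)
  gold_rows <- list()
  truth_rows <- list()

  for (ai in seq_len(config$n_articles)) {
    doc_id <- sprintf("SYN%05d", ai)
    jrow <- sample.int(nrow(profiles), 1, prob = profiles$weight)
    journal <- profiles$journal[jrow]
    year <- sample(config$years, 1)
    dw <- c(bioinf = profiles$w_bioinf[jrow], bio = profiles$w_bio[jrow],
            med = profiles$w_med[jrow])
    w <- base_w * dw[domain] *
      pmax(0.05, 1 + trend_slope * (year - min(config$years)))

    n_m <- stats::rpois(1, config$mention_rate)
    picks <- if (n_m > 0) sample.int(nres, n_m, replace = TRUE, prob = w) else integer()

    # a mismatching acronym collision excludes genuine use of that acronym
    mismatch_res <- NA_integer_
    if (length(acro_idx) && stats::runif(1) < config$acronym_mismatch_prob) {
      cand <- setdiff(acro_idx, picks)
      if (length(cand)) mismatch_res <- cand[sample.int(length(cand), 1)]
    }

    # build sentences per section ------------------------------------------
    sec_names <- c("intro", "methods", "results", "concl")
    sec_probs <- c(intro = 0.10, methods = 0.60, results = 0.25, concl = 0.05)
    mention_sec <- sample(sec_names, length(picks), replace = TRUE,
                          prob = sec_probs)
    sents <- list(intro = list(), methods = list(), results = list(),
                  concl = list())
    for (s in sec_names) {
      for (k in seq_len(sample(2:3, 1))) {
        sents[[s]][[k]] <- list(text = sample(.FILLERS, 1), mentions = NULL)
      }
    }
    defined_acr <- character()
    for (mi in seq_along(picks)) {
      r <- picks[mi]
      cn <- dtruth$canonical[r]
      frame <- sample(names(config$frame_weights), 1,
                      prob = config$frame_weights)
      if (dtruth$is_acronym[r] && !cn %in% defined_acr &&
          stats::runif(1) < config$acronym_definition_prob) {
        # "Long Form (ACR)": gold annotates both spans
        lf <- dtruth$expansion[r]
        pre <- "The "
        mid <- " ("
        post <- ") was queried for all records."
        txt <- paste0(pre, lf, mid, cn, post)
        m <- tibble::tibble(
          start = c(nchar(pre), nchar(pre) + nchar(lf) + nchar(mid)),
          end = c(nchar(pre) + nchar(lf),
                  nchar(pre) + nchar(lf) + nchar(mid) + nchar(cn)),
          canonical = cn, surface = c(lf, cn))
        sent <- list(text = txt, mentions = m)
        defined_acr <- c(defined_acr, cn)
      } else {
        sm <- realize_mention_sentence(frame, cn, slug_of[r])
        sent <- list(text = sm$text,
                     mentions = tibble::tibble(start = sm$start, end = sm$end,
                                               canonical = cn, surface = cn))
      }
      s <- mention_sec[mi]
      sents[[s]][[length(sents[[s]]) + 1L]] <- sent
    }
    # distractors: ambiguous words in plain and resource-like frames
    amb_names <- dtruth$canonical[dtruth$ambiguous]
    n_d <- if (length(amb_names)) stats::rpois(1, config$distractor_rate) else 0L
    for (k in seq_len(n_d)) {
      wd <- sample(amb_names, 1)
      tplset <- if (stats::runif(1) < 0.5) .DISTRACTOR_PLAIN else
        .DISTRACTOR_RESOURCEY
      t <- tplset[[sample.int(length(tplset), 1)]]
      s <- sample(sec_names, 1, prob = sec_probs)
      sents[[s]][[length(sents[[s]]) + 1L]] <-
        list(text = paste0(t[1], wd, t[2]), mentions = NULL)
    }
    # fake-name resource-frame noise
    n_f <- stats::rpois(1, config$noise_rate)
    for (k in seq_len(n_f)) {
      t <- .NOISE_TEMPLATES[[sample.int(length(.NOISE_TEMPLATES), 1)]]
      s <- sample(sec_names, 1, prob = sec_probs)
      sents[[s]][[length(sents[[s]]) + 1L]] <-
        list(text = paste0(t[1], sample(.FAKE_NAMES, 1), t[2]),
             mentions = NULL)
    }
    # colliding acronym definition + bare later use (unannotated)
    if (!is.na(mismatch_res)) {
      acr <- dtruth$canonical[mismatch_res]
      wrong <- paste(sample(c("graded", "standard", "composite", "clinical",
                              "baseline"), 2), collapse = " ")
      wrong <- paste(wrong, sample(c("exercise assessment", "outcome score",
                                     "observation index"), 1))
      sents$methods[[length(sents$methods) + 1L]] <-
        list(text = paste0("Participants completed the ", wrong, " (", acr,
                           ") at enrolment."), mentions = NULL)
      sents$results[[length(sents$results) + 1L]] <-
        list(text = paste0(acr, " values were recorded for each participant."),
             mentions = NULL)
    }

    # assemble body: heading + one paragraph per section --------------------
    headings <- c(
      intro = sample(c("Introduction", "Background", "Study Overview"), 1,
                     prob = c(0.55, 0.35, 0.10)),
      methods = sample(c("Methods", "Materials and Methods",
                         "Experimental Workflow"), 1,
                       prob = c(0.5, 0.4, 0.10)),
      results = sample(c("Results", "Results and Discussion", "Discussion"),
                       1, prob = c(0.35, 0.5, 0.15)),
      concl = sample(c("Conclusions", "Conclusion", "Final Remarks"), 1,
                     prob = c(0.5, 0.4, 0.10)))
    segs <- character(); seg_mentions <- list()
    head_rows <- list()
    for (s in sec_names) {
      segs <- c(segs, headings[[s]])
      head_rows[[s]] <- list(text = headings[[s]], line = length(segs),
                             section = s)
      seg_mentions[[length(segs)]] <- NULL
      ord <- sample.int(length(sents[[s]]))  # shuffle sentences
      para <- ""
      pm <- list()
      for (si in ord) {
        sn <- sents[[s]][[si]]
        sep <- if (nzchar(para)) " " else ""
        off <- nchar(para) + nchar(sep)
        para <- paste0(para, sep, sn$text)
        if (!is.null(sn$mentions)) {
          m <- sn$mentions
          m$start <- m$start + off
          m$end <- m$end + off
          pm[[length(pm) + 1L]] <- m
        }
      }
      segs <- c(segs, para)
      seg_mentions[[length(segs)]] <- if (length(pm)) dplyr::bind_rows(pm) else NULL
    }
    seg_starts <- c(0L, cumsum(nchar(segs) + 1L))[seq_along(segs)]
    body <- paste(segs, collapse = "\n")
    hs <- tibble::tibble(
      text = vapply(head_rows, `[[`, character(1), "text"),
      start = seg_starts[vapply(head_rows, `[[`, integer(1), "line")],
      end = seg_starts[vapply(head_rows, `[[`, integer(1), "line")] +
        nchar(vapply(head_rows, `[[`, character(1), "text")),
      section = vapply(head_rows, `[[`, character(1), "section"))

    body_gold <- list()
    for (gi2 in seq_along(seg_mentions)) {
      m <- seg_mentions[[gi2]]
      if (is.null(m)) next
      m$start <- m$start + seg_starts[gi2]
      m$end <- m$end + seg_starts[gi2]
      body_gold[[length(body_gold) + 1L]] <- m
    }

    # captions ---------------------------------------------------------------
    captions <- character(); cap_gold <- list()
    if (stats::runif(1) < config$caption_prob) {
      for (ci in seq_len(sample(1:2, 1))) {
        cap_pre <- sprintf("Figure %d. ", ci)
        if (stats::runif(1) < config$caption_mention_prob) {
          r <- if (length(vis_idx) && stats::runif(1) < 0.6) {
            vis_idx[sample.int(length(vis_idx), 1, prob = w[vis_idx])]
          } else sample.int(nres, 1, prob = w)
          t <- .CAPTION_TEMPLATES[[sample.int(length(.CAPTION_TEMPLATES), 1)]]
          sm <- mk_sent(paste0(cap_pre, t[1]), dtruth$canonical[r], t[2])
          captions <- c(captions, sm$text)
          cap_gold[[length(cap_gold) + 1L]] <- tibble::tibble(
            stream = "caption", caption_idx = length(captions),
            start = sm$start, end = sm$end,
            canonical = dtruth$canonical[r],
            surface = dtruth$canonical[r])
        } else {
          captions <- c(captions,
                        paste0(cap_pre, "Summary of cohort characteristics."))
        }
      }
    }

    articles[[ai]] <- new_article(
      doc_id = doc_id, journal = journal, year = year,
      title = paste("Synthetic article", ai), body = body,
      captions = captions, heading_spans = hs[, c("text", "start", "end")])
    attr(articles[[ai]], "section_truth") <- hs

    g <- dplyr::bind_rows(
      if (length(body_gold)) {
        bg <- dplyr::bind_rows(body_gold)
        bg$stream <- "body"; bg$caption_idx <- NA_integer_
        bg
      },
      if (length(cap_gold)) dplyr::bind_rows(cap_gold))
    if (!is.null(g) && nrow(g)) {
      g$doc_id <- doc_id
      gold_rows[[length(gold_rows) + 1L]] <- g
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        doc_id = doc_id, journal = journal, year = year,
        canonical = g$canonical)
    }
  }

  gold <- if (length(gold_rows)) dplyr::bind_rows(gold_rows) else
    tibble::tibble(doc_id = character(), stream = character(),
                   caption_idx = integer(), start = integer(),
                   end = integer(), canonical = character(),
                   surface = character())
  gold <- dplyr::select(gold, "doc_id", "stream", "caption_idx", "start",
                        "end", "canonical", "surface")
  tr <- dplyr::bind_rows(truth_rows)
  truth <- if (nrow(tr)) {
    dplyr::summarise(
      dplyr::group_by(tr, .data$canonical, .data$year, .data$journal),
      mention_count = dplyr::n(),
      doc_count = dplyr::n_distinct(.data$doc_id), .groups = "drop")
  } else {
    tibble::tibble(canonical = character(), year = integer(),
                   journal = character(), mention_count = integer(),
                   doc_count = integer())
  }
  list(articles = articles, gold = gold, truth = truth, dictionary = d,
       dict_truth = dtruth,
       planted = list(grow = dtruth$canonical[gi], decline = dtruth$canonical[di]),
       catalog = catalog, config = config)
}

#' Sample a truth usage table without rendering text
#'
#' Draws journals, years and resource mentions from exactly the statistical
#' model of [generate_corpus()] (Zipf usage, journal-domain preferences,
#' planted trends) but skips article text, captions and gold spans. Used
#' for multi-seed studies of the temporal analytics, where only the usage
#' counts matter.
#'
#' @param config list from [generator_config()].
#' @return list with `truth` (tibble: canonical, year, journal,
#'   mention_count, doc_count), `doc_meta`, `catalog`, `planted`.
#' @export
sample_truth_usage <- function(config) {
  dict <- generate_dictionary(config$n_resources, config$ambiguity_rate,
                              seed = config$seed)
  dtruth <- dict$truth
  set.seed(config$seed + 1L)
  nres <- nrow(dtruth)
  rank_of <- sample.int(nres)
  base_w <- rank_of^(-config$zipf_exponent)
  domain <- sample(c("bioinf", "bio", "med"), nres, replace = TRUE,
                   prob = c(0.5, 0.3, 0.2))
  trend_slope <- rep(0, nres)
  gi <- which(rank_of == min(config$trend_grow_rank, nres))
  di <- which(rank_of == min(config$trend_decline_rank, nres))
  trend_slope[gi] <- config$trend_grow
  trend_slope[di] <- config$trend_decline
  profiles <- default_journal_profiles()

  n <- config$n_articles
  jrow <- sample.int(nrow(profiles), n, replace = TRUE,
                     prob = profiles$weight)
  year <- sample(config$years, n, replace = TRUE)
  n_m <- stats::rpois(n, config$mention_rate)
  # per (journal, year) weight vectors are shared; precompute them
  y0 <- min(config$years)
  wcache <- list()
  picks_list <- vector("list", n)
  for (ai in seq_len(n)) {
    if (n_m[ai] == 0L) next
    key <- paste0(jrow[ai], "_", year[ai])
    w <- wcache[[key]]
    if (is.null(w)) {
      dw <- c(bioinf = profiles$w_bioinf[jrow[ai]],
              bio = profiles$w_bio[jrow[ai]], med = profiles$w_med[jrow[ai]])
      w <- base_w * dw[domain] *
        pmax(0.05, 1 + trend_slope * (year[ai] - y0))
      wcache[[key]] <- w
    }
    picks_list[[ai]] <- sample.int(nres, n_m[ai], replace = TRUE, prob = w)
  }
  lens <- lengths(picks_list)
  tr <- tibble::tibble(
    doc_id = rep(sprintf("SYN%05d", seq_len(n)), lens),
    journal = rep(profiles$journal[jrow], lens),
    year = rep(year, lens),
    canonical = dtruth$canonical[unlist(picks_list, use.names = FALSE)])
  truth <- dplyr::summarise(
    dplyr::group_by(tr, .data$canonical, .data$year, .data$journal),
    mention_count = dplyr::n(),
    doc_count = dplyr::n_distinct(.data$doc_id), .groups = "drop")
  list(truth = truth,
       doc_meta = tibble::tibble(doc_id = sprintf("SYN%05d", seq_len(n)),
                                 journal = profiles$journal[jrow],
                                 year = year),
       catalog = tibble::tibble(
         journal = profiles$journal[nzchar(profiles$code)],
         codes = as.list(profiles$code[nzchar(profiles$code)])),
       planted = list(grow = dtruth$canonical[gi],
                      decline = dtruth$canonical[di]))
}

#' Conditions for the temporal trend sub-study
#'
#' The envelope analysis needs yearly document counts in the tens for the
#' resources whose series are analysed, so the temporal sub-study samples a
#' deeper corpus over a tighter dictionary than the survey-wide defaults:
#' 6,000 articles, 1,000 resources, with the planted growing resource at
#' Zipf rank 5 and the declining one at rank 3.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [generator_config()].
#' @return config list.
#' @export
temporal_study_config <- function(seed, ...) {
  generator_config(n_articles = 6000L, n_resources = 1000L,
                   trend_grow_rank = 5L, trend_decline_rank = 3L,
                   seed = seed, ...)
}

#' Write a synthetic corpus to disk
#'
#' One JATS-like XML file per article, one standoff `.ann` TSV per document
#' (stream, caption_idx, start, end, canonical, surface), the truth usage
#' table and the journal catalog as TSVs.
#'
#' @param corpus list from [generate_corpus()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (a in corpus$articles) {
    writeLines(serialize_article(a), file.path(dir, paste0(a$doc_id, ".xml")))
  }
  for (id in unique(corpus$gold$doc_id)) {
    g <- corpus$gold[corpus$gold$doc_id == id,
                     c("stream", "caption_idx", "start", "end",
                       "canonical", "surface")]
    utils::write.table(g, file.path(dir, paste0(id, ".ann")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(corpus$truth, file.path(dir, "truth_usage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(journal = corpus$catalog$journal,
               codes = vapply(corpus$catalog$codes, paste, character(1),
                              collapse = ",")),
    file.path(dir, "journal_catalog.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Generate labelled rule-profile candidates
#'
#' Draws feature vectors from two configured rule-profile distributions
#' (per-rule independent Bernoulli probabilities for true-positive-like and
#' false-positive-like mentions) with a known Bayes-optimal AUC, for
#' benchmarking the filter's cross-validation machinery.
#'
#' @param n number of candidates.
#' @param tp_prob,fp_prob length-17 vectors of per-rule firing
#'   probabilities.
#' @param prevalence P(true positive).
#' @param seed integer seed.
#' @return tibble with `rules` (list of integer vectors) and `label`.
#' @export
generate_labeled_candidates <- function(n,
                                        tp_prob = default_rule_profiles()$tp,
                                        fp_prob = default_rule_profiles()$fp,
                                        prevalence = 0.5, seed = 1L) {
  stopifnot(length(tp_prob) == N_RULES, length(fp_prob) == N_RULES)
  set.seed(seed)
  label <- ifelse(stats::runif(n) < prevalence, "true_positive",
                  "false_positive")
  rules <- lapply(label, function(l) {
    p <- if (l == "true_positive") tp_prob else fp_prob
    which(stats::runif(N_RULES) < p)
  })
  tibble::tibble(rules = rules, label = label)
}

#' Default rule profiles for the candidate generator
#'
#' Three informative rules (dictionary, positive keyword, version) separate
#' the classes; the remaining rules fire with equal probability under both,
#' carrying no signal.
#'
#' @return list with `tp` and `fp` probability vectors (length 17).
#' @export
default_rule_profiles <- function() {
  tp <- rep(0.2, N_RULES)
  fp <- rep(0.2, N_RULES)
  tp[c(1, 5, 2)] <- c(0.90, 0.70, 0.55)
  fp[c(1, 5, 2)] <- c(0.35, 0.30, 0.10)
  list(tp = tp, fp = fp)
}

#' Bayes-optimal AUC of a two-profile Bernoulli mixture
#'
#' Enumerates the joint distribution of the informative rules (those whose
#' probabilities differ between profiles), computes the likelihood ratio of
#' each outcome, and returns P(LLR_TP > LLR_FP) + 0.5 P(tie) -- the AUC of
#' the Bayes-optimal scorer.
#'
#' @param tp_prob,fp_prob per-rule firing probabilities.
#' @return AUC in \[0.5, 1\].
#' @export
bayes_auc <- function(tp_prob, fp_prob) {
  inf <- which(abs(tp_prob - fp_prob) > 1e-12)
  if (!length(inf)) return(0.5)
  if (length(inf) > 16L) stop("too many informative rules to enumerate")
  k <- length(inf)
  combos <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  p_t <- apply(combos, 1, function(z)
    prod(ifelse(z == 1, tp_prob[inf], 1 - tp_prob[inf])))
  p_f <- apply(combos, 1, function(z)
    prod(ifelse(z == 1, fp_prob[inf], 1 - fp_prob[inf])))
  llr <- log(pmax(p_t, 1e-300)) - log(pmax(p_f, 1e-300))
  key <- round(llr, 12)
  auc <- 0; cum_f <- 0
  for (v in sort(unique(key))) {
    g <- which(key == v)
    pt_g <- sum(p_t[g]); pf_g <- sum(p_f[g])
    auc <- auc + pt_g * cum_f + 0.5 * pt_g * pf_g
    cum_f <- cum_f + pf_g
  }
  auc
}
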