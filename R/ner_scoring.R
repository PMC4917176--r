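#' Document-level scoring, propagation, acronym filtering, thresholding
#'
#' After sentence-level rules fire, evidence is pooled across the document:
#' candidates sharing a (normalised) surface form reinforce each other so
#' that many weak clues can jointly cross the acceptance threshold; surface
#' forms with at least one accepted occurrence are propagated to their bare
#' occurrences elsewhere in the document; acronym candidates whose in-text
#' long form contradicts the dictionary's expected expansion are rejected;
#' and a final case/length-adjusted score is compared against `tau`.
#'
#' @name ner_scoring
NULL

#' Document-wide score adjustment
#'
#' Candidates are grouped into cohorts by normalised surface form. Each
#' cohort member receives a bonus `alpha * (n - 1) * mean(max(raw, 0))`
#' (capped at `cohort_cap`), i.e. proportional to both the cohort size and
#' its summed positive evidence. Singletons and all-negative cohorts get a
#' zero bonus; the adjustment never decreases a score.
#'
#' @param cands candidate tibble from [apply_rules()].
#' @param config list from [ner_config()].
#' @return the tibble with an `adjusted_score` column added.
#' @export
adjust_document_scores <- function(cands, config = ner_config()) {
  if (nrow(cands) == 0L) {
    cands$adjusted_score <- numeric()
    return(cands)
  }
  key <- normalise_name(cands$surface)
  pos_ev <- tapply(pmax(cands$raw_score, 0), key, mean)
  n_coh <- table(key)
  bonus <- pmin(config$cohort_alpha * (as.numeric(n_coh[key]) - 1) *
                  as.numeric(pos_ev[key]), config$cohort_cap)
  bonus <- pmax(bonus, 0)
  cands$adjusted_score <- cands$raw_score + bonus
  cands
}

# detect the long form defined in text for an acronym via the
# parenthesis pattern "Long Form (ACR)"; returns the best-matching
# normalised edit distance against `expected`, or NA if no definition
detect_long_form_distance <- function(body, acronym, expected,
                                      max_extra = 5L) {
  pat <- paste0("\\(\\s*", stringr::str_escape(acronym), "\\s*\\)")
  locs <- stringr::str_locate_all(body, pat)[[1]]
  if (nrow(locs) == 0L) return(NA_real_)
  best <- Inf
  for (r in seq_len(nrow(locs))) {
    pre <- substring(body, max(1L, locs[r, 1] - 100L), locs[r, 1] - 1L)
    words <- stringr::str_split_1(stringr::str_squish(
      stringr::str_remove_all(pre, "[^A-Za-z0-9' -]")), " ")
    words <- words[nzchar(words)]
    if (!length(words)) next
    kmax <- min(length(words), nchar(acronym) + max_extra)
    for (k in seq_len(kmax)) {
      lf <- paste(utils::tail(words, k), collapse = " ")
      best <- min(best, norm_edit_distance(lf, expected))
    }
  }
  if (is.infinite(best)) NA_real_ else best
}

#' Acronym expansion filtering
#'
#' For each candidate that looks like an acronym (all-caps, 2-6 characters)
#' and whose dictionary entry records an expected expansion: if the document
#' defines the acronym in parenthesis style ("Long Form (LF)"), the detected
#' long form is compared to the expected expansion by normalised edit
#' distance. A match within `tolerance` adds the acronym-verified rule (15);
#' a mismatch rejects the candidate (rule 16). Candidates with no in-text
#' definition pass through unchanged.
#'
#' @param cands candidate tibble (after [adjust_document_scores()]).
#' @param body document text.
#' @param d `resmine_dictionary`.
#' @param config list from [ner_config()]; `config$tolerance` is the maximum
#'   accepted normalised edit distance.
#' @return filtered candidate tibble.
#' @export
resolve_acronyms <- function(cands, body, d, config = ner_config()) {
  if (nrow(cands) == 0L) return(cands)
  has_exp <- !is.na(d$entries$expansion)
  acr_entries <- d$entries[has_exp, , drop = FALSE]
  if (nrow(acr_entries) == 0L) return(cands)
  is_acr <- grepl("^[A-Z0-9]{2,6}$", cands$surface) & cands$dictionary_hit
  keep <- rep(TRUE, nrow(cands))
  # one distance per distinct acronym surface in this document
  for (sf in unique(cands$surface[is_acr])) {
    m <- match(sf, acr_entries$canonical)
    if (is.na(m)) next
    dist <- detect_long_form_distance(body, sf, acr_entries$expansion[m])
    if (is.na(dist)) next
    if (dist <= config$tolerance) {
      # the verified definition vouches for the acronym and its long form
      idx <- which(cands$canonical == acr_entries$canonical[m])
      for (i in idx) {
        cands$rules[[i]] <- sort(unique(c(cands$rules[[i]], 15L)))
        cands$raw_score[i] <- cands$raw_score[i] + config$weights[["15"]]
        cands$adjusted_score[i] <- cands$adjusted_score[i] +
          config$weights[["15"]]
      }
    } else {
      keep[cands$surface == sf & is_acr] <- FALSE
    }
  }
  cands[keep, , drop = FALSE]
}

#' Propagate document-level matches to the mention level
#'
#' For every surface cohort whose best member's case/length-adjusted score
#' crosses `tau`, all other occurrences of that surface form in the body
#' are promoted to candidate mentions flagged with the propagation rule
#' (11) and inheriting the cohort's best adjusted score; existing
#' sub-threshold cohort members are raised the same way. Propagation never
#' removes candidates and never invents a surface form absent from the
#' document.
#'
#' @param cands candidate tibble with `adjusted_score`.
#' @param body document text.
#' @param config list from [ner_config()].
#' @return augmented candidate tibble.
#' @export
propagate_document_matches <- function(cands, body, config = ner_config()) {
  if (nrow(cands) == 0L) return(cands)
  final <- adjust_case_length(cands$adjusted_score, cands$surface,
                              config$common_words)
  key <- normalise_name(cands$surface)
  best <- tapply(final, key, max)
  best_adj <- tapply(cands$adjusted_score, key, max)
  accepted_keys <- names(best)[best >= config$tau]
  if (!length(accepted_keys)) return(cands)

  new_rows <- list()
  for (k in accepted_keys) {
    members <- which(key == k)
    seed_adj <- as.numeric(best_adj[[k]])
    seed <- members[which.max(cands$adjusted_score[members])]
    # raise existing sub-threshold members of the cohort
    for (i in members) {
      if (final[i] < config$tau) {
        cands$adjusted_score[i] <- seed_adj
        cands$rules[[i]] <- sort(unique(c(cands$rules[[i]], 11L)))
      }
    }
    # find bare occurrences of the cohort's surfaces not yet covered
    for (sf in unique(cands$surface[members])) {
      pat <- paste0("(?<![A-Za-z0-9])", stringr::str_escape(sf),
                    "(?![A-Za-z0-9])")
      locs <- stringr::str_locate_all(body, stringr::regex(pat))[[1]]
      for (r in seq_len(nrow(locs))) {
        s0 <- locs[r, 1] - 1L; e0 <- locs[r, 2]
        covered <- any(cands$start < e0 & cands$end > s0)
        if (covered) next
        new_rows[[length(new_rows) + 1L]] <- tibble::tibble(
          surface = sf, start = s0, end = e0,
          i1 = NA_integer_, i2 = NA_integer_, sent = NA_integer_,
          canonical = cands$canonical[seed],
          dictionary_hit = cands$dictionary_hit[seed],
          rules = list(sort(unique(c(cands$rules[[seed]], 11L)))),
          raw_score = cands$raw_score[seed],
          adjusted_score = seed_adj)
      }
    }
  }
  if (length(new_rows)) cands <- dplyr::bind_rows(cands, new_rows)
  cands
}

#' Threshold candidates into accepted mentions
#'
#' Applies the case/length adjustment and keeps candidates whose final score
#' reaches `tau`, sorted by span.
#'
#' @param cands candidate tibble with `adjusted_score`.
#' @param tau acceptance threshold (defaults to the config value).
#' @param config list from [ner_config()].
#' @return tibble of accepted mentions with a `final_score` column, ordered
#'   by `start`.
#' @export
threshold_mentions <- function(cands, tau = NULL, config = ner_config()) {
  if (is.null(tau)) tau <- config$tau
  if (nrow(cands) == 0L) {
    cands$final_score <- numeric()
    cands$accepted <- logical()
    return(cands)
  }
  cands$final_score <- adjust_case_length(cands$adjusted_score,
                                          cands$surface,
                                          config$common_words)
  cands$accepted <- cands$final_score >= tau
  out <- cands[cands$accepted, , drop = FALSE]
  out[order(out$start, out$end), , drop = FALSE]
}

ner_stream <- function(text, d, config) {
  prep <- preprocess(text)
  cands <- apply_rules(prep, text, d, config)
  cands <- adjust_document_scores(cands, config)
  cands <- resolve_acronyms(cands, text, d, config)
  cands <- propagate_document_matches(cands, text, config)
  threshold_mentions(cands, config = config)
}

#' Recognise resource mentions in an article
#'
#' Runs the full recogniser over the body stream and (optionally) each
#' caption stream: preprocessing, rule firing, document-wide score
#' adjustment, acronym resolution, propagation and thresholding.
#'
#' @param article `resmine_article`.
#' @param d `resmine_dictionary`.
#' @param config list from [ner_config()].
#' @param captions whether to also process the caption stream.
#' @return tibble of accepted mentions: doc_id, journal, year, stream
#'   ("body"/"caption"), caption_idx (NA for body), surface, canonical,
#'   start, end (offsets within their stream), rules (list), raw_score,
#'   adjusted_score, final_score.
#' @export
recognize_mentions <- function(article, d, config = ner_config(),
                               captions = TRUE) {
  stopifnot(inherits(article, "resmine_article"))
  res <- list()
  body_m <- ner_stream(article$body, d, config)
  if (nrow(body_m)) {
    body_m$stream <- "body"
    body_m$caption_idx <- NA_integer_
    res[[1]] <- body_m
  }
  if (captions && length(article$captions)) {
    for (ci in seq_along(article$captions)) {
      cm <- ner_stream(article$captions[[ci]], d, config)
      if (nrow(cm)) {
        cm$stream <- "caption"
        cm$caption_idx <- ci
        res[[length(res) + 1L]] <- cm
      }
    }
  }
  if (!length(res)) {
    return(tibble::tibble(
      doc_id = character(), journal = character(), year = integer(),
      stream = character(), caption_idx = integer(), surface = character(),
      canonical = character(), start = integer(), end = integer(),
      rules = list(), raw_score = numeric(), adjusted_score = numeric(),
      final_score = numeric()))
  }
  out <- dplyr::bind_rows(res)
  out$doc_id <- article$doc_id
  out$journal <- article$journal
  out$year <- article$year
  dplyr::select(out, "doc_id", "journal", "year", "stream", "caption_idx",
                "surface", "canonical", "start", "end", "rules",
                "raw_score", "adjusted_score", "final_score")
}

#' Recognise mentions across a corpus
#'
#' @param articles list of `resmine_article`.
#' @param d `resmine_dictionary`.
#' @param config list from [ner_config()].
#' @param captions whether to process caption streams.
#' @return a single mention tibble (see [recognize_mentions()]).
#' @export
recognize_corpus <- function(articles, d, config = ner_config(),
                             captions = TRUE) {
  dplyr::bind_rows(lapply(articles, recognize_mentions, d = d,
                          config = config, captions = captions))
}
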