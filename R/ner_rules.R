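#' Recognition rules
#'
#' The recogniser fires a fixed inventory of 17 positive and negative rules
#' around dictionary and pattern matches. Rule identifiers are stable (they
#' double as the machine-learning filter's feature ids):
#'
#' 1. dictionary: surface matches a dictionary name variant
#' 2. version: a version number follows the candidate
#' 3. url: a website URL is adjacent
#' 4. reference: an inline citation marker is adjacent
#' 5. positive-keyword: a category keyword (database, software, tool, ...)
#'    occurs in the candidate's sentence window
#' 6. negative-keyword: a negative keyword (algorithm, method, approach, ...)
#'    is adjacent
#' 7. Hearst "such as": category keyword *such as* candidate (or
#'    "candidate and other keyword")
#' 8. Hearst "including/like": category keyword *including* candidate
#' 9. head-association: the candidate's noun-phrase head is a category
#'    keyword ("the ClustalW software")
#' 10. restricted-head: as 9 for the ambiguous heads program/system/
#'     project/service; only fires when corroborated by a second positive
#'     contextual rule
#' 11. propagated: occurrence promoted by document-level propagation
#' 12. case-acronym: short all-caps surface (2-6 characters)
#' 13. case-mixed: mixed-case surface under 12 characters
#' 14. case-lowercase-common: all-lowercase common English word
#' 15. acronym-verified: in-text long form matches the expected expansion
#' 16. acronym-mismatch: in-text long form contradicts the expected
#'     expansion (the candidate is rejected)
#' 17. name-morphology: resource-like suffix (-DB, -Base, -seq, -omics, ...)
#'
#' Rules 12-14 are recorded as features but carry zero weight in the score:
#' their numeric effect is applied by [adjust_case_length()].
#'
#' @name ner_rules
NULL

N_RULES <- 17L
CONTEXT_POSITIVE_RULES <- c(2L, 3L, 5L, 7L, 8L, 9L)

#' Default recogniser configuration
#'
#' Loads the rule weights, acceptance threshold `tau`, keyword lists,
#' acronym fuzzy-match tolerance and document-adjustment parameters from
#' the configuration bundled with the package.
#'
#' @param path optional path to a JSON config overriding the bundled one.
#' @return list; see the bundled `rules_config.json` for the schema.
#' @export
ner_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rules_config.json", package = "resmine")
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$weights <- stats::setNames(as.numeric(cfg$weights),
                                 names(cfg$weights))
  stopifnot(length(cfg$weights) == N_RULES)
  cfg
}

surface_case_class <- function(surface) {
  dplyr::case_when(
    grepl("^[A-Z0-9.\\-]{2,6}$", surface) & grepl("[A-Z]", surface) ~ "acronym",
    grepl("[A-Z]", surface) & grepl("[a-z]", surface) ~ "mixed",
    surface == tolower(surface) ~ "lower",
    TRUE ~ "other"
  )
}

#' Case/length score adjustment
#'
#' Piecewise adjustment applied to each candidate's score just before
#' thresholding: short all-caps surfaces (likely acronyms of named tools)
#' gain +1; mixed-case surfaces under 12 characters gain +0.5; all-lowercase
#' surfaces under 10 characters that are common English words lose 1; all
#' other surfaces are unchanged. Monotone in the input score.
#'
#' @param score numeric vector of scores.
#' @param surface character vector of surface forms (recycled with score).
#' @param common_words character vector of common-word forms.
#' @return adjusted numeric vector.
#' @export
adjust_case_length <- function(score, surface,
                               common_words = ner_config()$common_words) {
  cls <- surface_case_class(surface)
  delta <- ifelse(cls == "acronym" & nchar(surface) <= 6, 1,
           ifelse(cls == "mixed" & nchar(surface) < 12, 0.5,
           ifelse(cls == "lower" & nchar(surface) < 10 &
                    tolower(surface) %in% common_words, -1, 0)))
  score + delta
}

# ---- candidate generation -------------------------------------------------

# greedy longest-match dictionary scan over token n-grams (n = 3, 2, 1);
# n-grams never end on a bare number so that "ClustalW 2.0" matches as
# "ClustalW" with the version left to rule 2
dict_candidates <- function(tokens, body, d) {
  n <- nrow(tokens)
  out <- list()
  if (n == 0L || nrow(d$entries) == 0L) return(out)
  wordish <- !tokens$pos %in% c("PUNCT", "URL")
  # token-join keys agree with normalise_name for n-grams that neither end
  # in a version token (excluded below) nor carry internal markup
  low <- tolower(tokens$text)
  i <- 1L
  while (i <= n) {
    if (!wordish[i]) { i <- i + 1L; next }
    hit <- NULL
    for (len in 4:1) {
      j <- i + len - 1L
      if (j > n || tokens$sent[j] != tokens$sent[i]) next
      if (any(!wordish[i:j])) next
      if (tokens$pos[j] == "CD") next
      surface <- span_text(body, tokens$start[i], tokens$end[j])
      eid <- dict_lookup(d, paste(low[i:j], collapse = " "), surface)
      if (!is.na(eid)) {
        hit <- list(i1 = i, i2 = j, surface = surface, entry_id = eid)
        break
      }
    }
    if (!is.null(hit)) {
      out[[length(out) + 1L]] <- hit
      i <- hit$i2 + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Fire recognition rules over a preprocessed document
#'
#' Generates mention candidates from dictionary matches (which always become
#' candidates, even with no contextual evidence) and from name-like tokens
#' (proper-noun or acronym-cased) that attract at least one contextual
#' positive rule. Each candidate records every rule it matched and its raw
#' score, the weighted sum over matched rules.
#'
#' @param prep result of [preprocess()].
#' @param body the text that was preprocessed.
#' @param d `resmine_dictionary`.
#' @param config list from [ner_config()].
#' @return tibble of candidates: surface, start, end, i1, i2, sent,
#'   canonical, dictionary_hit, rules (list of integer rule ids), raw_score.
#' @export
apply_rules <- function(prep, body, d, config = ner_config()) {
  tk <- prep$tokens
  empty <- tibble::tibble(surface = character(), start = integer(),
                          end = integer(), i1 = integer(), i2 = integer(),
                          sent = integer(), canonical = character(),
                          dictionary_hit = logical(), rules = list(),
                          raw_score = numeric())
  if (nrow(tk) == 0L) return(empty)

  low <- tolower(tk$text)
  pos_kw <- low %in% config$positive_keywords
  neg_kw <- low %in% config$negative_keywords
  res_kw <- low %in% config$restricted_heads
  cat_kw <- pos_kw | res_kw

  dcands <- dict_candidates(tk, body, d)
  dspans <- if (length(dcands)) {
    cbind(vapply(dcands, `[[`, integer(1), "i1"),
          vapply(dcands, `[[`, integer(1), "i2"))
  } else matrix(integer(), ncol = 2)

  # name-like singleton tokens not already inside a dictionary match
  in_dict_span <- rep(FALSE, nrow(tk))
  if (nrow(dspans)) for (r in seq_len(nrow(dspans))) {
    in_dict_span[dspans[r, 1]:dspans[r, 2]] <- TRUE
  }
  namelike <- which(
    !in_dict_span & !cat_kw & nchar(tk$text) >= 2 &
      (tk$pos == "NNP" | grepl("^[A-Z0-9.\\-]{2,6}$", tk$text) &
         grepl("[A-Z]", tk$text)) &
      !low %in% c(config$negative_keywords, "et", "al", "fig", "table"))

  cand <- c(dcands, lapply(namelike, function(i) {
    list(i1 = i, i2 = i, surface = tk$text[i], entry_id = NA_integer_)
  }))
  if (!length(cand)) return(empty)

  rows <- lapply(cand, function(cd) {
    i1 <- cd$i1; i2 <- cd$i2
    s <- tk$sent[i1]
    in_sent <- tk$sent == s
    win <- function(a, b) {
      idx <- seq(max(i1 + a, 1L), min(i2 + b, nrow(tk)))
      idx[in_sent[idx] & !(idx %in% i1:i2)]
    }
    after <- win(0, 4)[win(0, 4) > i2]
    before <- win(-6, 0)[win(-6, 0) < i1]
    rules <- integer()
    if (!is.na(cd$entry_id)) rules <- c(rules, 1L)
    # 2: version number in the next tokens
    nxt <- after[after <= i2 + 4]
    if (length(nxt) &&
        (any(tk$pos[nxt] == "CD" & grepl("\\.", tk$text[nxt])) ||
         any(low[nxt] %in% c("version", "release")) ||
         any(grepl("^v[0-9]", low[nxt])))) rules <- c(rules, 2L)
    # 3: URL adjacent
    if (any(tk$pos[nxt] == "URL")) rules <- c(rules, 3L)
    # 4: citation marker adjacent: "[ 12 ]" or "( Author et al"
    if (length(nxt)) {
      br <- nxt[tk$text[nxt] == "["]
      cite <- any(vapply(br, function(b) {
        b + 1 <= nrow(tk) && tk$pos[b + 1] == "CD"
      }, logical(1))) || any(low[nxt] == "et")
      if (cite) rules <- c(rules, 4L)
    }
    # 5: positive keyword in sentence window of 4
    if (any(pos_kw[win(-4, 4)])) rules <- c(rules, 5L)
    # 6: negative keyword adjacent (window 2)
    if (any(neg_kw[win(-2, 2)])) rules <- c(rules, 6L)
    # 7: "KW such as X" / "X and other KW"
    hearst7 <- FALSE
    for (j in before[cat_kw[before]]) {
      if (j + 2 < i1 + 1 && j + 2 <= nrow(tk) &&
          low[j + 1] == "such" && low[j + 2] == "as" &&
          i1 - j <= 8) hearst7 <- TRUE
    }
    if (i2 + 3 <= nrow(tk) && low[i2 + 1] == "and" &&
        low[i2 + 2] == "other" && cat_kw[i2 + 3]) hearst7 <- TRUE
    if (hearst7) rules <- c(rules, 7L)
    # 8: "KW including/like X"
    hearst8 <- any(vapply(before[cat_kw[before]], function(j) {
      j + 1 < i1 + 1 && low[j + 1] %in% c("including", "like") && i1 - j <= 7
    }, logical(1)))
    if (hearst8) rules <- c(rules, 8L)
    # 9 / 10: head-keyword association via the token head links
    h <- tk$head[i2]
    head_hit <- function(kwmask) {
      (!is.na(h) && kwmask[h] && h > i2 && h - i2 <= 3) ||
        (i2 + 1 <= nrow(tk) && in_sent[i2 + 1] && kwmask[i2 + 1])
    }
    if (head_hit(pos_kw)) rules <- c(rules, 9L)
    restricted <- head_hit(res_kw)
    if (restricted && length(intersect(rules, CONTEXT_POSITIVE_RULES)))
      rules <- c(rules, 10L)
    # 12-14: case classes (zero-weight features; see adjust_case_length)
    cls <- surface_case_class(cd$surface)
    if (cls == "acronym") rules <- c(rules, 12L)
    if (cls == "mixed" && nchar(cd$surface) < 12) rules <- c(rules, 13L)
    if (cls == "lower" && tolower(cd$surface) %in% config$common_words)
      rules <- c(rules, 14L)
    # 17: resource-like name morphology
    if (any(vapply(config$name_suffixes, function(sf)
      endsWith(tolower(cd$surface), sf), logical(1))) &&
      is.na(match(tolower(cd$surface), config$common_words)))
      rules <- c(rules, 17L)

    if (is.na(cd$entry_id) &&
        !length(intersect(rules, CONTEXT_POSITIVE_RULES))) return(NULL)
    rr <- sort(unique(rules))
    list(surface = cd$surface, start = tk$start[i1], end = tk$end[i2],
         i1 = i1, i2 = i2, sent = s,
         canonical = if (!is.na(cd$entry_id))
           d$entries$canonical[cd$entry_id] else cd$surface,
         dictionary_hit = !is.na(cd$entry_id),
         rules = rr,
         raw_score = sum(config$weights[as.character(rr)]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  tibble::tibble(
    surface = vapply(rows, `[[`, character(1), "surface"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    i1 = vapply(rows, `[[`, integer(1), "i1"),
    i2 = vapply(rows, `[[`, integer(1), "i2"),
    sent = vapply(rows, `[[`, integer(1), "sent"),
    canonical = vapply(rows, `[[`, character(1), "canonical"),
    dictionary_hit = vapply(rows, `[[`, logical(1), "dictionary_hit"),
    rules = lapply(rows, `[[`, "rules"),
    raw_score = vapply(rows, `[[`, numeric(1), "raw_score"))
}
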