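#' Text preprocessing for the recogniser
#'
#' Deterministic shallow linguistic analysis: offset-preserving
#' tokenisation, sentence splitting, a coarse part-of-speech tagger driven
#' by closed-class word lists and morphology, and a shallow head
#' assignment (noun-phrase chunking with a nearest-head heuristic) standing
#' in for full dependency parsing. Every token carries a tag and either a
#' head index or root status; identical input always yields identical
#' output.
#'
#' @name preprocess
NULL

.TOKEN_PATTERN <- paste0(
  "https?://[^\\s)\\]>]+|www\\.[^\\s)\\]>]+",  # URLs first
  "|[A-Za-z0-9][A-Za-z0-9.\\-_/:']*[A-Za-z0-9]|[A-Za-z0-9]",  # words/numbers
  "|[()\\[\\],.;:!?]"                           # punctuation
)

.POS_CLOSED <- list(
  DT = c("the", "a", "an", "this", "that", "these", "those", "each", "all",
         "some", "any", "no", "both", "other"),
  IN = c("of", "in", "on", "with", "within", "for", "from", "by", "to", "at",
         "as", "into", "via", "under", "over", "between", "against", "per",
         "through", "during", "than"),
  CC = c("and", "or", "but", "nor"),
  PRP = c("we", "it", "they", "i", "he", "she", "you", "our", "its", "their")
)

.POS_VERBS <- c(
  "used", "use", "uses", "using", "performed", "perform", "applied", "apply",
  "aligned", "align", "analysed", "analyzed", "analyse", "analyze",
  "computed", "compute", "ran", "run", "obtained", "obtain", "generated",
  "generate", "downloaded", "download", "implemented", "implement",
  "developed", "develop", "compared", "compare", "was", "were", "is", "are",
  "be", "been", "being", "has", "have", "had", "provides", "provide",
  "contains", "contain", "shows", "show", "queried", "query", "stored",
  "store", "processed", "process", "visualised", "visualized", "plotted",
  "plot", "built", "build", "calculated", "calculate", "retrieved",
  "retrieve", "mapped", "map", "assembled", "assemble", "annotated",
  "annotate", "clustered", "identified", "identify", "searched", "search",
  "extracted", "extract", "evaluated", "evaluate", "remained", "remains",
  "became", "required", "require", "can", "could", "may", "might", "will")

tag_pos <- function(tok) {
  low <- tolower(tok)
  n <- length(tok)
  pos <- rep("NN", n)
  pos[grepl("^[][(),.;:!?]$", tok)] <- "PUNCT"
  pos[grepl("^(https?://|www\\.)", tok)] <- "URL"
  pos[grepl("^v?[0-9][0-9.\\-_/:]*$", tok)] <- "CD"
  for (tg in names(.POS_CLOSED)) pos[low %in% .POS_CLOSED[[tg]] & pos == "NN"] <- tg
  pos[low %in% .POS_VERBS & pos == "NN"] <- "VB"
  morph_vb <- pos == "NN" & nchar(tok) > 5 & grepl("(ed|ing)$", low) &
    tok == low
  pos[morph_vb] <- "VB"
  cap <- pos == "NN" & grepl("^[A-Z]", tok)
  pos[cap] <- "NNP"
  pos
}

#' Preprocess a body of text
#'
#' @param body character string (may be empty).
#' @return list with `tokens`, a tibble with one row per token: `sent` (1-based
#'   sentence id), `text`, `start`/`end` (0-based half-open offsets into
#'   `body`), `pos` (coarse tag), `head` (row index of the token's head, NA
#'   for roots) and `is_root`; and `n_sentences`.
#' @export
preprocess <- function(body) {
  empty <- tibble::tibble(sent = integer(), text = character(),
                          start = integer(), end = integer(),
                          pos = character(), head = integer(),
                          is_root = logical())
  if (is.null(body) || !nzchar(body)) {
    return(list(tokens = empty, n_sentences = 0L))
  }
  loc <- stringr::str_locate_all(body, .TOKEN_PATTERN)[[1]]
  if (nrow(loc) == 0L) return(list(tokens = empty, n_sentences = 0L))
  text <- stringr::str_sub(body, loc[, 1], loc[, 2])
  start <- loc[, 1] - 1L
  end <- loc[, 2]
  pos <- tag_pos(text)

  # sentence split: break after . ! ? and at newlines (paragraph boundaries)
  n <- length(text)
  nl <- gregexpr("\n", body, fixed = TRUE)[[1]]
  if (length(nl) == 1L && nl == -1L) nl <- integer()
  gap_newline <- if (n > 1) {
    # newline strictly between token i's end and token i+1's start?
    c(findInterval(start[-1], nl) > findInterval(end[-n], nl), TRUE)
  } else TRUE
  is_break <- text %in% c(".", "!", "?") | gap_newline
  sent <- cumsum(c(1L, utils::head(is_break, -1)))

  # NP chunks: maximal runs of DT/JJ-like/NN/NNP/CD; head = last NN/NNP token
  chunky <- pos %in% c("DT", "NN", "NNP", "CD")
  run_id <- cumsum(c(TRUE, diff(as.integer(chunky)) != 0 |
                       diff(sent) != 0))
  head_idx <- rep(NA_integer_, n)
  is_root <- rep(FALSE, n)
  for (s in unique(sent)) {
    in_s <- which(sent == s)
    root <- in_s[which(pos[in_s] == "VB")[1]]
    if (is.na(root)) root <- in_s[1]
    for (r in unique(run_id[in_s])) {
      run <- in_s[run_id[in_s] == r]
      if (!chunky[run[1]]) next
      noms <- run[pos[run] %in% c("NN", "NNP")]
      h <- if (length(noms)) noms[length(noms)] else run[length(run)]
      head_idx[run] <- h
      head_idx[h] <- root
    }
    head_idx[in_s][is.na(head_idx[in_s])] <- root
    head_idx[root] <- NA_integer_
    is_root[root] <- TRUE
  }

  list(tokens = tibble::tibble(sent = sent, text = text, start = start,
                               end = end, pos = pos, head = head_idx,
                               is_root = is_root),
       n_sentences = length(unique(sent)))
}
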