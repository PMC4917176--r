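#' Document zoning
#'
#' Articles are zoned into introduction / methods / results-discussion /
#' conclusion spans from their section headings, using an editable table of
#' heading regular expressions. Results and discussion are combined into a
#' single category since journals frequently merge them. Text before the
#' first recognised heading (and any span opened by an unrecognised
#' heading) is labelled `other`. Caption-stream mentions are never zoned;
#' they carry the section label `"caption"`.
#'
#' @name zoning
NULL

SECTION_LABELS <- c("introduction", "methods", "results_discussion",
                    "conclusion", "other")

#' Load the heading-pattern table
#'
#' TSV with columns `pattern<TAB>label`; patterns are case-insensitive
#' regular expressions matched against whole heading texts.
#'
#' @param path TSV path; defaults to the table bundled with the package.
#' @return tibble with columns pattern, label.
#' @export
read_heading_patterns <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "heading_patterns.tsv", package = "resmine")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(df$label %in% SECTION_LABELS))
  tibble::as_tibble(df)
}

match_heading <- function(text, patterns) {
  for (i in seq_len(nrow(patterns))) {
    if (grepl(patterns$pattern[i], text, ignore.case = TRUE)) {
      return(patterns$label[i])
    }
  }
  NA_character_
}

#' Label section spans of an article
#'
#' Every heading opens a span running to the next heading (or document
#' end); recognised headings take their pattern's label, unrecognised ones
#' are `other`, and any text before the first heading is `other`. The
#' returned spans are disjoint, sorted, and jointly cover the body.
#'
#' @param a `resmine_article`.
#' @param patterns tibble from [read_heading_patterns()].
#' @return tibble with columns label, start, end (0-based half-open), plus
#'   `heading` (the heading text, NA for the leading span).
#' @export
label_sections <- function(a, patterns = read_heading_patterns()) {
  stopifnot(inherits(a, "resmine_article"))
  len <- nchar(a$body)
  hs <- a$heading_spans[order(a$heading_spans$start), , drop = FALSE]
  if (len == 0L) {
    return(tibble::tibble(label = character(), start = integer(),
                          end = integer(), heading = character()))
  }
  if (nrow(hs) == 0L) {
    return(tibble::tibble(label = "other", start = 0L, end = len,
                          heading = NA_character_))
  }
  starts <- c(if (hs$start[1] > 0L) 0L, hs$start)
  labels <- c(if (hs$start[1] > 0L) "other",
              vapply(hs$text, function(t) {
                l <- match_heading(t, patterns)
                if (is.na(l)) "other" else l
              }, character(1), USE.NAMES = FALSE))
  headings <- c(if (hs$start[1] > 0L) NA_character_, hs$text)
  ends <- c(starts[-1], len)
  keep <- ends > starts
  tibble::tibble(label = labels[keep], start = starts[keep],
                 end = ends[keep], heading = headings[keep])
}

#' Attach section labels to mentions
#'
#' Body mentions take the label of the unique span containing their start
#' offset (mentions straddling a boundary are labelled by where they
#' start); caption mentions are labelled `"caption"`.
#'
#' @param mentions mention tibble for one document.
#' @param spans tibble from [label_sections()].
#' @return the mention tibble with a `section` column.
#' @export
assign_section <- function(mentions, spans) {
  sec <- rep(NA_character_, nrow(mentions))
  is_cap <- mentions$stream == "caption"
  sec[is_cap] <- "caption"
  body_idx <- which(!is_cap)
  for (i in body_idx) {
    j <- which(spans$start <= mentions$start[i] &
                 mentions$start[i] < spans$end)
    if (length(j) != 1L)
      stop("mention at offset ", mentions$start[i],
           " outside body section cover")
    sec[i] <- spans$label[j]
  }
  mentions$section <- sec
  mentions
}

#' Zone a corpus of mentions
#'
#' @param mentions corpus mention tibble.
#' @param articles list of `resmine_article` (for heading spans).
#' @param patterns heading-pattern table.
#' @return mention tibble with a `section` column.
#' @export
zone_corpus <- function(mentions, articles,
                        patterns = read_heading_patterns()) {
  ids <- vapply(articles, `[[`, character(1), "doc_id")
  out <- lapply(split(mentions, mentions$doc_id), function(mm) {
    a <- articles[[match(mm$doc_id[1], ids)]]
    assign_section(mm, label_sections(a, patterns))
  })
  dplyr::bind_rows(out)
}

#' Per-section top-N document-level usage table
#'
#' Within each section label, resources are ranked by the fraction of the
#' partition's documents that contain at least one mention of the resource
#' in that section (ties broken alphabetically).
#'
#' @param mentions zoned mention tibble (with `section` and `canonical`).
#' @param partition partition list (uses `doc_ids` for the denominator).
#' @param n rows per section.
#' @return tibble: section, canonical, doc_count, fraction.
#' @export
section_usage_table <- function(mentions, partition, n = 10L) {
  n_docs <- length(unique(partition$doc_ids))
  mm <- mentions[mentions$doc_id %in% partition$doc_ids, , drop = FALSE]
  if (nrow(mm) == 0L || n_docs == 0L) {
    return(tibble::tibble(section = character(), canonical = character(),
                          doc_count = integer(), fraction = numeric()))
  }
  agg <- dplyr::summarise(
    dplyr::group_by(mm, .data$section, .data$canonical),
    doc_count = dplyr::n_distinct(.data$doc_id), .groups = "drop")
  agg$fraction <- agg$doc_count / n_docs
  agg <- dplyr::arrange(agg, .data$section, -.data$doc_count, .data$canonical)
  dplyr::slice_head(dplyr::group_by(agg, .data$section), n = n) |>
    dplyr::ungroup()
}
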