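#' Resource-name dictionary
#'
#' The recogniser is seeded by a dictionary of known database, software,
#' package and ontology names. Each entry carries a canonical name, a
#' resource type, a provenance tag for the source list it came from, and
#' (for acronym entries) the expected long-form expansion used by the
#' acronym filter. Name variants (case, hyphenation, camel-case splits,
#' version-stripped forms) are generated deterministically and indexed
#' under a shared normalisation so that surface forms in text can be
#' looked up directly.
#'
#' @name dictionary
NULL

DICT_RTYPES <- c("DB", "SW", "PK", "ONT", "unknown")

#' Generate name variants for a canonical resource name
#'
#' Deterministically enumerates the surface variants a resource name is
#' matched under: the name itself, lower-case, upper-case for short names,
#' hyphen/space alternations (both directions plus removal), and camel-case
#' splitting ("ClustalW" -> "Clustal W").
#'
#' @param canonical single non-empty string.
#' @return character vector of unique variants (always includes `canonical`).
#' @examples
#' expand_variants("SWISS-PROT") # includes "SWISS PROT" and "SWISSPROT"
#' @export
expand_variants <- function(canonical) {
  stopifnot(is.character(canonical), length(canonical) == 1L, nzchar(canonical))
  base <- c(
    canonical,
    gsub("-", " ", canonical, fixed = TRUE),
    gsub("-", "", canonical, fixed = TRUE),
    gsub(" ", "-", canonical, fixed = TRUE),
    gsub(" ", "", canonical, fixed = TRUE),
    gsub("([a-z])([A-Z])", "\\1 \\2", canonical)
  )
  out <- unique(base)
  # short all-caps forms (acronyms) are matched case-sensitively: their
  # lowercase spelling is ordinary text, not a name variant
  is_acro <- nchar(out) <= 6L & out == toupper(out) & grepl("[A-Z]", out)
  out <- unique(c(out, tolower(out[!is_acro]), toupper(out[nchar(out) <= 6L])))
  out[nzchar(out)]
}

#' Load the resource-name dictionary from TSV files
#'
#' Each row is `canonical<TAB>rtype<TAB>source[<TAB>expansion]`. Entries are
#' deduplicated per (canonical, source); unknown resource types are kept with
#' `rtype = "unknown"` and a warning. A variant index is built over the
#' normalised forms of every generated variant (see [expand_variants()] and
#' [normalise_name()]).
#'
#' @param files character vector of TSV paths (may be empty).
#' @return object of class `resmine_dictionary`: a list with `entries`
#'   (tibble: entry_id, canonical, rtype, source, expansion, variants
#'   list-column) and `index` (tibble: variant_norm, entry_id, canonical).
#' @export
load_dictionary <- function(files) {
  if (length(files) == 0L) {
    return(new_dictionary(tibble::tibble(
      canonical = character(), rtype = character(),
      source = character(), expansion = character()
    )))
  }
  rows <- lapply(files, function(f) {
    if (!file.exists(f)) stop("dictionary file not found: ", f)
    raw <- utils::read.delim(f, header = FALSE, sep = "\t", quote = "",
                             comment.char = "#", stringsAsFactors = FALSE,
                             col.names = c("canonical", "rtype", "source", "expansion")[
                               seq_len(max(count.fields(f, sep = "\t", quote = "",
                                                        comment.char = "#"), na.rm = TRUE))],
                             fill = TRUE)
    if (!"expansion" %in% names(raw)) raw$expansion <- NA_character_
    raw$expansion[!is.na(raw$expansion) & !nzchar(raw$expansion)] <- NA_character_
    raw
  })
  df <- do.call(rbind, rows)
  bad <- !df$rtype %in% DICT_RTYPES
  if (any(bad)) {
    warning(sum(bad), " entries with unknown rtype kept as 'unknown'")
    df$rtype[bad] <- "unknown"
  }
  df <- df[!duplicated(df[, c("canonical", "source")]), , drop = FALSE]
  new_dictionary(tibble::as_tibble(df))
}

#' Construct a dictionary from an entries table
#'
#' Programmatic counterpart of [load_dictionary()]; used by the synthetic
#' generator and tests.
#'
#' @param entries data frame with columns canonical, rtype, source and
#'   optionally expansion.
#' @return `resmine_dictionary` object.
#' @export
new_dictionary <- function(entries) {
  entries <- tibble::as_tibble(entries)
  if (!"expansion" %in% names(entries)) entries$expansion <- NA_character_
  entries$entry_id <- seq_len(nrow(entries))
  entries$variants <- lapply(entries$canonical, function(cn) {
    if (nzchar(cn)) expand_variants(cn) else character()
  })
  idx <- if (nrow(entries)) {
    tibble::tibble(
      entry_id = rep(entries$entry_id, lengths(entries$variants)),
      variant = unlist(entries$variants, use.names = FALSE)
    )
  } else {
    tibble::tibble(entry_id = integer(), variant = character())
  }
  idx$variant_norm <- normalise_name(idx$variant)
  # an entry's expected expansion (long form) is itself a name variant
  exp_rows <- which(!is.na(entries$expansion) & nzchar(entries$expansion))
  if (length(exp_rows)) {
    idx <- dplyr::bind_rows(idx, tibble::tibble(
      entry_id = entries$entry_id[exp_rows],
      variant = entries$expansion[exp_rows],
      variant_norm = normalise_name(entries$expansion[exp_rows])))
  }
  idx <- idx[!duplicated(idx[, c("entry_id", "variant_norm")]), , drop = FALSE]
  idx$canonical <- entries$canonical[idx$entry_id]
  # a folded key produced only by short all-caps variants ("GO", "IN") must
  # not fire on lowercase running text ("go", "in", sentence-initial "In")
  idx$needs_caps <- nchar(idx$variant) <= 6L &
    idx$variant == toupper(idx$variant) &
    grepl("[A-Z]", idx$variant)
  # O(1) lookup hash: first entry wins for variants shared across entries;
  # value is c(entry_id, needs_caps) with needs_caps ANDed over duplicates
  hash <- new.env(parent = emptyenv(), size = max(64L, nrow(idx)))
  caps_by_key <- tapply(idx$needs_caps, idx$variant_norm, all)
  for (i in rev(seq_len(nrow(idx)))) {
    assign(idx$variant_norm[i],
           c(idx$entry_id[i],
             as.integer(caps_by_key[[idx$variant_norm[i]]])),
           envir = hash)
  }
  structure(list(entries = entries, index = idx, hash = hash),
            class = "resmine_dictionary")
}

#' Dictionary accounting
#'
#' Totals used for dictionary audits: the number of entries, the number of
#' distinct normalised name variants across all entries, and a per-source
#' breakdown. The entry total is, by construction, the sum of the per-source
#' counts, which is how the published dictionary's size is audited from its
#' source-list breakdown.
#'
#' @param d `resmine_dictionary`.
#' @return list with `total_entries`, `unique_variants`, `per_source`
#'   (named integer vector).
#' @export
dictionary_stats <- function(d) {
  stopifnot(inherits(d, "resmine_dictionary"))
  per_source <- if (nrow(d$entries)) {
    tab <- table(d$entries$source)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(), character())
  }
  list(
    total_entries = nrow(d$entries),
    unique_variants = length(unique(d$index$variant_norm)),
    per_source = per_source
  )
}

#' @export
print.resmine_dictionary <- function(x, ...) {
  s <- dictionary_stats(x)
  cat("<resmine_dictionary> ", s$total_entries, " entries, ",
      s$unique_variants, " unique variants, ",
      length(s$per_source), " sources\n", sep = "")
  invisible(x)
}

# look up a normalised surface form; returns entry id or NA. When the key
# comes only from short all-caps variants, the surface itself must be
# all-caps for the match to count.
dict_lookup <- function(d, surface_norm, surface = NULL) {
  v <- get0(surface_norm, envir = d$hash, inherits = FALSE)
  if (is.null(v)) return(NA_integer_)
  if (!is.null(surface) && v[2] == 1L && surface != toupper(surface)) {
    return(NA_integer_)
  }
  v[1]
}
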