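#' Articles and corpora
#'
#' Full-text articles arrive either as JATS-like XML (`<article>` with
#' `<journal-title>`, `<pub-date><year>`, `<sec><title>`, `<caption>`) or as
#' plain UTF-8 text. Parsing produces a single stripped body string with
#' 0-based half-open heading offsets, plus a *separate* caption stream:
#' captions are analysed independently of the narrative text and never share
#' offsets with it.
#'
#' @name corpus_io
NULL

#' Construct an article object
#'
#' @param doc_id opaque identifier.
#' @param journal journal-name string (NA if unknown).
#' @param year publication year (integer; NA flags missing). Years before
#'   1900 are treated as missing.
#' @param title article title.
#' @param body stripped narrative text.
#' @param captions character vector of caption texts (separate stream).
#' @param heading_spans tibble with columns text, start, end (0-based,
#'   half-open offsets into `body`).
#' @return object of class `resmine_article`.
#' @export
new_article <- function(doc_id, journal = NA_character_, year = NA_integer_,
                        title = "", body = "", captions = character(),
                        heading_spans = NULL) {
  if (is.null(heading_spans)) {
    heading_spans <- tibble::tibble(text = character(), start = integer(),
                                    end = integer())
  }
  year <- suppressWarnings(as.integer(year))
  if (length(year) != 1L || is.na(year) || year < 1900L) year <- NA_integer_
  stopifnot(all(heading_spans$start >= 0L),
            all(heading_spans$end <= nchar(body)))
  structure(
    list(doc_id = doc_id, journal = journal, year = year, title = title,
         body = body, captions = captions,
         heading_spans = tibble::as_tibble(heading_spans)),
    class = "resmine_article"
  )
}

#' @export
print.resmine_article <- function(x, ...) {
  cat("<resmine_article> ", x$doc_id, " [", x$journal, ", ",
      ifelse(is.na(x$year), "year?", x$year), "] ",
      nchar(x$body), " chars, ", nrow(x$heading_spans), " headings, ",
      length(x$captions), " captions\n", sep = "")
  invisible(x)
}

# collapse the text of an XML node, dropping markup, squashing whitespace
xml_plain <- function(node) {
  stringr::str_squish(xml2::xml_text(node))
}

# walk <body> content: returns list(segments = chr of body lines,
# headings = tibble(text, line_index)) ; captions collected separately
walk_body <- function(node) {
  segs <- character()
  heads <- list()
  for (child in xml2::xml_children(node)) {
    nm <- xml2::xml_name(child)
    if (nm == "sec") {
      title <- xml2::xml_find_first(child, "./title")
      if (!inherits(title, "xml_missing")) {
        txt <- xml_plain(title)
        if (nzchar(txt)) {
          segs <- c(segs, txt)
          heads[[length(heads) + 1L]] <- list(text = txt,
                                              line = length(segs))
        }
      }
      sub <- walk_body(child)
      off <- length(segs)
      segs <- c(segs, sub$segments)
      for (h in sub$headings) {
        h$line <- h$line + off
        heads[[length(heads) + 1L]] <- h
      }
    } else if (nm == "p") {
      txt <- xml_plain(child)
      if (nzchar(txt)) segs <- c(segs, txt)
    } else if (nm %in% c("fig", "table-wrap", "supplementary-material",
                         "title", "caption")) {
      # captions handled globally; sec titles handled above
      next
    }
  }
  list(segments = segs, headings = heads)
}

#' Parse a full-text article
#'
#' For JATS-like XML the narrative body is the concatenation (newline-joined)
#' of section titles and paragraph texts in document order with all inline
#' markup stripped; `<caption>` content anywhere in the document goes to the
#' caption stream and is excluded from the body. For plain text the body is
#' the raw text and no headings or captions are detected.
#'
#' @param raw a string: XML markup / plain text content, or a path to a file
#'   holding it.
#' @param format `"jats_xml"` or `"plain_text"`.
#' @param doc_id identifier for the article; defaults to the file name or a
#'   hash-like placeholder.
#' @return `resmine_article`. A missing/absent `<year>` yields `year = NA`
#'   (flagged missing, not fatal); malformed XML is an error.
#' @export
parse_article <- function(raw, format = c("jats_xml", "plain_text"),
                          doc_id = NULL) {
  format <- match.arg(format)
  is_path <- length(raw) == 1L && !grepl("[<\n]", raw) && file.exists(raw)
  if (is.null(doc_id)) {
    doc_id <- if (is_path) basename(raw) else sprintf("doc-%08x",
      sum(utf8ToInt(substr(raw, 1, 64))) %% 0xffffffff)
  }
  if (format == "plain_text") {
    body <- if (is_path) paste(readLines(raw, warn = FALSE), collapse = "\n") else raw
    return(new_article(doc_id = doc_id, body = body))
  }
  doc <- tryCatch(xml2::read_xml(raw),
                  error = function(e) stop("malformed XML in '", doc_id,
                                           "': ", conditionMessage(e)))
  journal <- xml2::xml_find_first(doc, ".//journal-title")
  journal <- if (inherits(journal, "xml_missing")) NA_character_ else xml_plain(journal)
  year <- xml2::xml_find_first(doc, ".//pub-date/year")
  year <- if (inherits(year, "xml_missing")) NA_integer_ else
    suppressWarnings(as.integer(xml_plain(year)))
  title <- xml2::xml_find_first(doc, ".//article-title")
  title <- if (inherits(title, "xml_missing")) "" else xml_plain(title)

  caption_nodes <- xml2::xml_find_all(doc, ".//caption")
  captions <- vapply(caption_nodes, xml_plain, character(1))
  captions <- captions[nzchar(captions)]
  # captions are a separate stream: remove them before walking the body
  xml2::xml_remove(caption_nodes)

  bodynode <- xml2::xml_find_first(doc, ".//body")
  segs <- character(); heads <- list()
  if (!inherits(bodynode, "xml_missing")) {
    w <- walk_body(bodynode)
    segs <- w$segments
    heads <- w$headings
  }
  body <- paste(segs, collapse = "\n")
  hs <- if (length(heads)) {
    starts <- c(0L, cumsum(nchar(segs) + 1L))  # +1 for the newline joins
    tibble::tibble(
      text = vapply(heads, `[[`, character(1), "text"),
      start = starts[vapply(heads, `[[`, integer(1), "line")],
      end = starts[vapply(heads, `[[`, integer(1), "line")] +
        nchar(vapply(heads, `[[`, character(1), "text"))
    )
  } else NULL
  new_article(doc_id = doc_id, journal = journal, year = year, title = title,
              body = body, captions = as.character(captions),
              heading_spans = hs)
}

#' Extract caption texts from a raw document
#'
#' @inheritParams parse_article
#' @return character vector, one string per caption element, inner markup
#'   stripped, in document order.
#' @export
extract_captions <- function(raw, format = c("jats_xml", "plain_text")) {
  parse_article(raw, format)$captions
}

#' Serialise an article back to JATS-like XML
#'
#' Inverse of [parse_article()] for round-trip testing and for the synthetic
#' generator: `parse_article(serialize_article(a))` reproduces `a`'s body,
#' headings and captions exactly.
#'
#' @param a `resmine_article`.
#' @return single string of XML markup.
#' @export
serialize_article <- function(a) {
  stopifnot(inherits(a, "resmine_article"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  segs <- if (nzchar(a$body)) strsplit(a$body, "\n", fixed = TRUE)[[1]] else character()
  starts <- if (length(segs)) c(0L, cumsum(nchar(segs) + 1L))[seq_along(segs)] else integer()
  is_head <- starts %in% a$heading_spans$start &
    segs %in% a$heading_spans$text
  out <- c("<article><front>",
           if (!is.na(a$journal))
             paste0("<journal-meta><journal-title>", esc(a$journal),
                    "</journal-title></journal-meta>"),
           "<article-meta>",
           paste0("<title-group><article-title>", esc(a$title),
                  "</article-title></title-group>"),
           if (!is.na(a$year))
             paste0("<pub-date><year>", a$year, "</year></pub-date>"),
           "</article-meta></front><body>")
  open <- FALSE
  for (i in seq_along(segs)) {
    if (is_head[i]) {
      if (open) out <- c(out, "</sec>")
      out <- c(out, paste0("<sec><title>", esc(segs[i]), "</title>"))
      open <- TRUE
    } else {
      out <- c(out, paste0("<p>", esc(segs[i]), "</p>"))
    }
  }
  if (open) out <- c(out, "</sec>")
  for (cp in a$captions) {
    out <- c(out, paste0("<fig><caption><p>", esc(cp), "</p></caption></fig>"))
  }
  paste(c(out, "</body></article>"), collapse = "")
}

#' Read a corpus of article files
#'
#' Articles that fail to parse are skipped and counted rather than aborting
#' the pipeline (mirroring large-corpus processing where a small number of
#' documents cannot be handled).
#'
#' @param files character vector of paths, or a named character vector of raw
#'   document strings (names become doc ids).
#' @param format passed to [parse_article()].
#' @return list with `articles` (list of `resmine_article`) and `n_skipped`.
#' @export
read_corpus <- function(files, format = c("jats_xml", "plain_text")) {
  format <- match.arg(format)
  ids <- if (!is.null(names(files))) names(files) else rep(NA_character_, length(files))
  arts <- list(); skipped <- 0L
  for (i in seq_along(files)) {
    a <- tryCatch(
      parse_article(files[[i]], format,
                    doc_id = if (!is.na(ids[i])) ids[i] else NULL),
      error = function(e) NULL)
    if (is.null(a)) skipped <- skipped + 1L else arts[[length(arts) + 1L]] <- a
  }
  list(articles = arts, n_skipped = skipped)
}

#' Read a journal subject-term catalog
#'
#' TSV with columns `journal_name<TAB>code[,code...]`; codes are dot-delimited
#' hierarchical subject terms (e.g. "H01.158.273.180") where the prefix
#' relation defines subsumption.
#'
#' @param path TSV path.
#' @return tibble with columns `journal` and `codes` (list of character).
#' @export
read_journal_catalog <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("journal", "codes"))
  tibble::tibble(journal = df$journal,
                 codes = strsplit(df$codes, "[,;]\\s*"))
}

DEFAULT_PARTITION_RULES <- c(medicine = "H02.403",
                             biology = "H01.158.273",
                             bioinformatics = "H01.158.273.180")

# does any code match rule exactly or fall under it in the dot hierarchy?
code_under <- function(codes, rule) {
  any(codes == rule | startsWith(codes, paste0(rule, ".")))
}

#' Partition a corpus into subject sub-corpora
#'
#' An article belongs to a partition iff its journal carries a subject code
#' equal to, or hierarchically under, the partition's code. Journals with
#' several codes join every matching partition. The `full` partition always
#' contains every article; journals absent from the catalog fall only into
#' `full`. With the default rules the bioinformatics code is a descendant of
#' the biology code, so bioinformatics is a strict subset of biology.
#'
#' @param articles list of `resmine_article`.
#' @param catalog tibble from [read_journal_catalog()] (or equivalent).
#' @param rules named character vector partition-name -> subject code.
#' @return named list of partitions; each is a list with `name`,
#'   `journal_names` (character) and `doc_ids` (character).
#' @export
partition_corpus <- function(articles, catalog,
                             rules = DEFAULT_PARTITION_RULES) {
  journals <- vapply(articles, function(a) a$journal %||% NA_character_, character(1))
  ids <- vapply(articles, `[[`, character(1), "doc_id")
  parts <- list(full = list(name = "full",
                            journal_names = unique(journals[!is.na(journals)]),
                            doc_ids = ids))
  for (p in names(rules)) {
    member_journals <- catalog$journal[vapply(catalog$codes, code_under,
                                              logical(1), rule = rules[[p]])]
    sel <- !is.na(journals) & journals %in% member_journals
    parts[[p]] <- list(name = p,
                       journal_names = unique(journals[sel]),
                       doc_ids = ids[sel])
  }
  parts
}

#' Summarise a corpus partition
#'
#' @param partition one element of the list returned by [partition_corpus()].
#' @return list with `n_journals` and `n_docs`.
#' @export
corpus_summary <- function(partition) {
  list(n_journals = length(unique(partition$journal_names)),
       n_docs = length(unique(partition$doc_ids)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
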