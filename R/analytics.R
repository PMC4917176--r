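#' Usage analytics
#'
#' All survey statistics computed over extracted mentions: aggregation into
#' a (resource x partition x year x journal) usage table at both counting
#' levels (total mention occurrences, and document-level mentions counting
#' a resource once per document), top-N tables, journal proportions,
#' temporal relative usage within the yearly top-100 pool, Year0
#' normalisation with Gaussian random-walk significance envelopes, the
#' year-over-year change score (the sum of absolute differences in relative
#' usage), persistence runs, long-tail summaries and name-overlap analyses.
#'
#' @name analytics
NULL

#' Document metadata for a corpus
#'
#' @param articles list of `resmine_article`.
#' @return tibble: doc_id, journal, year.
#' @export
corpus_meta <- function(articles) {
  tibble::tibble(
    doc_id = vapply(articles, `[[`, character(1), "doc_id"),
    journal = vapply(articles, function(a) a$journal %||% NA_character_,
                     character(1)),
    year = vapply(articles, function(a) a$year %||% NA_integer_, integer(1)))
}

#' Aggregate mentions into a usage table
#'
#' For every (partition, resource, year, journal) cell, counts total mention
#' occurrences (`mention_count`) and documents with at least one mention
#' (`doc_count`). Canonical-name merging has already happened upstream (the
#' recogniser maps dictionary variants to one canonical form). Mentions
#' with a missing year keep `year = NA`: they are excluded from temporal
#' cells but still counted in all-years margins.
#'
#' @param mentions mention tibble (doc_id, canonical, and optionally journal
#'   and year; journal/year are filled from `doc_meta` when absent).
#' @param partitions named list from [partition_corpus()].
#' @param doc_meta tibble from [corpus_meta()] (for per-journal/-year
#'   document totals).
#' @return object of class `resmine_usage`: list with `cells` and `docs`
#'   tibbles.
#' @export
aggregate_usage <- function(mentions, partitions, doc_meta) {
  mm <- dplyr::select(mentions, "doc_id", "canonical")
  mm <- dplyr::left_join(mm, doc_meta, by = "doc_id")
  cells <- list(); docs <- list()
  for (p in names(partitions)) {
    ids <- partitions[[p]]$doc_ids
    sub <- mm[mm$doc_id %in% ids, , drop = FALSE]
    if (nrow(sub)) {
      agg <- dplyr::summarise(
        dplyr::group_by(sub, .data$canonical, .data$year, .data$journal),
        mention_count = dplyr::n(),
        doc_count = dplyr::n_distinct(.data$doc_id), .groups = "drop")
      agg$partition <- p
      cells[[p]] <- agg
    }
    dm <- doc_meta[doc_meta$doc_id %in% ids, , drop = FALSE]
    dm$partition <- p
    docs[[p]] <- dm
  }
  structure(list(
    cells = if (length(cells)) dplyr::bind_rows(cells) else
      tibble::tibble(canonical = character(), year = integer(),
                     journal = character(), mention_count = integer(),
                     doc_count = integer(), partition = character()),
    docs = dplyr::bind_rows(docs)),
    class = "resmine_usage")
}

#' Build a usage table from pre-aggregated cells
#'
#' Used for truth usage tables from the synthetic generator (already
#' aggregated per canonical x year x journal). Because every document
#' belongs to exactly one (journal, year), cell counts are additive and can
#' be filtered into partitions by journal membership.
#'
#' @param cells tibble: canonical, year, journal, mention_count, doc_count.
#' @param partitions named list from [partition_corpus()].
#' @param doc_meta tibble from [corpus_meta()].
#' @return `resmine_usage`.
#' @export
usage_from_cells <- function(cells, partitions, doc_meta) {
  out_cells <- list(); docs <- list()
  for (p in names(partitions)) {
    ids <- partitions[[p]]$doc_ids
    dm <- doc_meta[doc_meta$doc_id %in% ids, , drop = FALSE]
    sub <- cells[cells$journal %in% unique(dm$journal), , drop = FALSE]
    if (nrow(sub)) {
      sub$partition <- p
      out_cells[[p]] <- sub
    }
    dm$partition <- p
    docs[[p]] <- dm
  }
  empty_cells <- tibble::tibble(
    canonical = character(), year = integer(), journal = character(),
    mention_count = integer(), doc_count = integer(), partition = character())
  structure(list(cells = if (length(out_cells))
    dplyr::bind_rows(out_cells) else empty_cells,
    docs = dplyr::bind_rows(docs)),
    class = "resmine_usage")
}

#' @export
print.resmine_usage <- function(x, ...) {
  cat("<resmine_usage> ", nrow(x$cells), " cells over ",
      length(unique(x$cells$partition)), " partitions\n", sep = "")
  invisible(x)
}

part_cells <- function(u, partition) {
  stopifnot(inherits(u, "resmine_usage"))
  cells <- u$cells[u$cells$partition == partition, , drop = FALSE]
  if (!nrow(cells) && !partition %in% u$docs$partition)
    stop("unknown partition: ", partition)
  cells
}

part_ndocs <- function(u, partition) {
  length(unique(u$docs$doc_id[u$docs$partition == partition]))
}

#' Mean mentions per document
#'
#' @param total_mentions,n_docs corpus totals.
#' @return total/n rounded half-up to 1 decimal.
#' @export
mean_mentions_per_document <- function(total_mentions, n_docs) {
  if (any(n_docs == 0)) stop("n_docs must be positive")
  round_half_up(total_mentions / n_docs, 1)
}

#' Top-N resources within a partition
#'
#' Mention level reports average mentions per corpus document
#' (mention_count / document total); document level reports the fraction of
#' the corpus's documents containing at least one mention. Ties are broken
#' alphabetically.
#'
#' @param u `resmine_usage`.
#' @param partition partition name.
#' @param level `"mention"` or `"document"`.
#' @param n number of rows (all resources if fewer).
#' @return tibble: canonical, count, value.
#' @export
top_resources <- function(u, partition, level = c("mention", "document"),
                          n = 10L) {
  level <- match.arg(level)
  cells <- part_cells(u, partition)
  nd <- part_ndocs(u, partition)
  agg <- dplyr::summarise(
    dplyr::group_by(cells, .data$canonical),
    count = if (level == "mention") sum(.data$mention_count) else
      sum(.data$doc_count), .groups = "drop")
  agg$value <- if (nd > 0) agg$count / nd else NA_real_
  agg <- dplyr::arrange(agg, -.data$count, .data$canonical)
  utils::head(agg, n)
}

#' Journal resource-mention proportions from count rows
#'
#' @param counts tibble with columns journal, articles, mentions.
#' @param min_articles journals with fewer articles are excluded.
#' @return tibble sorted by decreasing proportion
#'   (mentions/articles, rounded half-up to 1 decimal).
#' @export
journal_proportions_from_counts <- function(counts, min_articles = 1000L) {
  out <- counts[counts$articles >= min_articles, , drop = FALSE]
  out$proportion <- round_half_up(out$mentions / out$articles, 1)
  dplyr::arrange(out, -.data$proportion, .data$journal)
}

#' Journal resource-mention proportions
#'
#' @param u `resmine_usage`.
#' @param min_articles minimum article count for inclusion.
#' @param level `"mention"` (total occurrences) or `"document"`.
#' @param partition partition over which to count (default full).
#' @return tibble: journal, articles, mentions, proportion.
#' @export
journal_proportions <- function(u, min_articles = 1000L,
                                level = c("mention", "document"),
                                partition = "full") {
  level <- match.arg(level)
  cells <- part_cells(u, partition)
  docs <- u$docs[u$docs$partition == partition, , drop = FALSE]
  arts <- dplyr::summarise(dplyr::group_by(docs, .data$journal),
                           articles = dplyr::n_distinct(.data$doc_id),
                           .groups = "drop")
  men <- dplyr::summarise(
    dplyr::group_by(cells, .data$journal),
    mentions = if (level == "mention") sum(.data$mention_count) else
      sum(.data$doc_count), .groups = "drop")
  counts <- dplyr::left_join(arts, men, by = "journal")
  counts$mentions[is.na(counts$mentions)] <- 0L
  journal_proportions_from_counts(counts, min_articles)
}

#' Relative usage within the yearly top-100 pool
#'
#' For each year, takes the `pool` resources with the highest document-level
#' counts (ties at the boundary are all included) and expresses each pool
#' member's count as a fraction of the pool total, so the fractions sum to
#' one within each year. Resources outside a year's pool have no value for
#' that year.
#'
#' @param u `resmine_usage`.
#' @param partition partition name.
#' @param years integer vector of contiguous years.
#' @param pool nominal pool size (shrinks to all resources when fewer).
#' @return tibble: canonical, year, count, x (relative frequency).
#' @export
relative_usage_series <- function(u, partition, years, pool = 100L) {
  cells <- part_cells(u, partition)
  cells <- cells[!is.na(cells$year) & cells$year %in% years, , drop = FALSE]
  out <- list()
  for (y in sort(years)) {
    yc <- cells[cells$year == y, , drop = FALSE]
    if (!nrow(yc)) next
    agg <- dplyr::summarise(dplyr::group_by(yc, .data$canonical),
                            count = sum(.data$doc_count), .groups = "drop")
    agg <- dplyr::arrange(agg, -.data$count, .data$canonical)
    if (nrow(agg) > pool) {
      cutoff <- agg$count[pool]
      agg <- agg[agg$count >= cutoff, , drop = FALSE]  # keep boundary ties
    }
    agg$x <- agg$count / sum(agg$count)
    agg$year <- y
    out[[as.character(y)]] <- agg
  }
  if (!length(out)) {
    return(tibble::tibble(canonical = character(), count = integer(),
                          x = numeric(), year = integer()))
  }
  dplyr::bind_rows(out)
}

#' Year0 normalisation of usage series
#'
#' Each resource's trajectory is divided by its value in the first year it
#' appears in the pool, so every series starts at exactly 1; later values
#' are ratios to that baseline.
#'
#' @param series tibble from [relative_usage_series()] (canonical, year, x).
#' @return tibble: canonical, year, offset (years since Year0), value.
#' @export
normalize_to_year0 <- function(series) {
  stopifnot(nrow(series) > 0)
  out <- lapply(split(series, series$canonical), function(s) {
    s <- s[order(s$year), , drop = FALSE]
    tibble::tibble(canonical = s$canonical, year = s$year,
                   offset = s$year - s$year[1], value = s$x / s$x[1])
  })
  dplyr::bind_rows(out)
}

#' Random-walk significance envelope
#'
#' Models normalised usage change as a Gaussian random walk: the step
#' spread sigma is estimated as the standard deviation of the pooled
#' year-over-year changes of all Year0-normalised series, and the bounds at
#' offset t are `1 +/- z(confidence) * sigma * sqrt(t)`, so the envelope
#' widens as the square root of the horizon. Divergence outside the 95%
#' envelope marks a significant usage change.
#'
#' @param normalized tibble from [normalize_to_year0()].
#' @param confidence two-sided coverage level.
#' @param horizon number of offsets to produce bounds for.
#' @return list with `sigma`, `degenerate` (TRUE when the pooled variance is
#'   zero) and `bounds`, a tibble (offset, lower, upper).
#' @export
random_walk_bounds <- function(normalized, confidence = 0.95, horizon = 13L) {
  steps <- unlist(lapply(split(normalized$value, normalized$canonical),
                         function(v) if (length(v) >= 2) diff(v) else NULL),
                  use.names = FALSE)
  if (length(steps) < 2L)
    stop("need at least 2 pooled year-over-year steps")
  sigma <- stats::sd(steps)
  degenerate <- !is.finite(sigma) || sigma == 0
  if (degenerate) sigma <- 0
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  t <- seq_len(horizon)
  list(sigma = sigma, degenerate = degenerate,
       bounds = tibble::tibble(offset = t,
                               lower = 1 - z * sigma * sqrt(t),
                               upper = 1 + z * sigma * sqrt(t)))
}

#' Flag significant usage trends against the random-walk envelope
#'
#' Builds the yearly relative-usage series for a partition, normalises each
#' resource to its Year0, estimates the random-walk envelope from the
#' Year0-normalised series of the partition's `top_n` document-level
#' resources (established resources with stable yearly counts), and flags
#' every resource whose trajectory leaves the envelope.
#'
#' @param u `resmine_usage`.
#' @param partition partition name.
#' @param years contiguous study years.
#' @param top_n number of established resources used for the spread
#'   estimate.
#' @param confidence envelope coverage level.
#' @return list with `series` (normalised trajectories), `envelope` (from
#'   [random_walk_bounds()]) and `flags` (tibble: canonical, exits_upper,
#'   exits_lower, max_value).
#' @export
trend_significance <- function(u, partition, years, top_n = 20L,
                               confidence = 0.95) {
  ser <- relative_usage_series(u, partition, years)
  norm <- normalize_to_year0(ser)
  topn <- top_resources(u, partition, "document", top_n)$canonical
  est <- normalize_to_year0(ser[ser$canonical %in% topn, , drop = FALSE])
  rw <- random_walk_bounds(est, confidence,
                           horizon = max(1L, length(years) - 1L))
  j <- dplyr::left_join(norm, rw$bounds, by = "offset")
  j$lower[j$offset == 0L] <- 1
  j$upper[j$offset == 0L] <- 1
  flags <- dplyr::summarise(
    dplyr::group_by(j, .data$canonical),
    exits_upper = any(.data$value > .data$upper),
    exits_lower = any(.data$value < .data$lower),
    max_value = max(.data$value), .groups = "drop")
  list(series = norm, envelope = rw, flags = flags)
}

#' Year-over-year change score of a usage series
#'
#' The sum of absolute differences in relative usage between consecutive
#' observed years. Constant series score 0; resources observed in a single
#' year have an empty sum and also score 0 (such resources are excluded
#' from change-score plots).
#'
#' @param x numeric vector of relative usage values in year order.
#' @return non-negative number.
#' @export
delta_sigma <- function(x) {
  if (length(x) <= 1L) return(0)
  sum(abs(diff(x)))
}

#' Change-score table for all resources
#'
#' @param series tibble from [relative_usage_series()].
#' @param drop_single drop resources observed in only one year.
#' @return tibble: canonical, n_years, total_usage (sum of x over years),
#'   delta_sigma.
#' @export
delta_sigma_table <- function(series, drop_single = TRUE) {
  out <- dplyr::summarise(
    dplyr::group_by(series[order(series$year), ], .data$canonical),
    n_years = dplyr::n(),
    total_usage = sum(.data$x),
    delta_sigma = delta_sigma(.data$x), .groups = "drop")
  if (drop_single) out <- out[out$n_years > 1L, , drop = FALSE]
  out
}

#' Persistent "medium-usage" resources
#'
#' Selects resources with at least one document-level mention every year
#' from their first observed year through their last, with no gaps, within
#' `[start_year, end_year]`; resources mentioned in `start_year` itself are
#' excluded (they have "always existed"). `current` records whether the run
#' reaches `end_year`.
#'
#' @param u `resmine_usage`.
#' @param partition partition name.
#' @param start_year,end_year study window.
#' @return tibble: canonical, first_year, last_year, run_length, unbroken,
#'   current — one row per resource passing the filters.
#' @export
persistence_set <- function(u, partition, start_year = 2000L,
                            end_year = 2013L) {
  cells <- part_cells(u, partition)
  cells <- cells[!is.na(cells$year) & cells$year >= start_year &
                   cells$year <= end_year & cells$doc_count > 0, ,
                 drop = FALSE]
  yrs <- lapply(split(cells$year, cells$canonical), function(y)
    sort(unique(y)))
  rows <- lapply(names(yrs), function(nm) {
    y <- yrs[[nm]]
    if (start_year %in% y) return(NULL)           # "always existed"
    unbroken <- length(y) == max(y) - min(y) + 1  # sorted unique years
    if (!unbroken) return(NULL)
    tibble::tibble(canonical = nm, first_year = min(y), last_year = max(y),
                   run_length = max(y) - min(y) + 1L, unbroken = TRUE,
                   current = max(y) == end_year)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(tibble::tibble(canonical = character(), first_year = integer(),
                          last_year = integer(), run_length = integer(),
                          unbroken = logical(), current = logical()))
  }
  dplyr::bind_rows(rows)
}

#' Long-tail summary of resource usage
#'
#' @param u `resmine_usage`.
#' @param partition partition name.
#' @param level `"document"` (default) or `"mention"`.
#' @return list: n_resources, singleton_fraction (names with count 1 over
#'   all names), singleton_mention_share (their share of total counts),
#'   top_1_share, top_10_share, top_5pct_share (over ceil(0.05 n) names),
#'   top_5pct_names.
#' @export
long_tail_summary <- function(u, partition, level = c("document", "mention")) {
  level <- match.arg(level)
  cells <- part_cells(u, partition)
  if (nrow(cells) == 0L) stop("empty usage table for partition ", partition)
  agg <- dplyr::summarise(
    dplyr::group_by(cells, .data$canonical),
    count = if (level == "document") sum(.data$doc_count) else
      sum(.data$mention_count), .groups = "drop")
  cnt <- sort(agg$count, decreasing = TRUE)
  total <- sum(cnt)
  n <- length(cnt)
  k5 <- ceiling(0.05 * n)
  list(n_resources = n,
       singleton_fraction = mean(cnt == 1),
       singleton_mention_share = sum(cnt[cnt == 1]) / total,
       top_1_share = cnt[1] / total,
       top_10_share = sum(utils::head(cnt, 10)) / total,
       top_5pct_share = sum(utils::head(cnt, k5)) / total,
       top_5pct_names = k5)
}

#' Name overlap between partitions
#'
#' For each sub-partition, the percentage of its unique canonical names
#' found in no other sub-partition, plus pairwise intersection counts. A
#' partition that is a strict subset of another (bioinformatics within
#' biology) necessarily has a zero unique share.
#'
#' @param u `resmine_usage`.
#' @param partitions partition names to compare (>= 2); defaults to all
#'   except `full`.
#' @return list with `per_partition` tibble (partition, n_names, n_unique,
#'   pct_unique) and `intersections` tibble (a, b, n_shared).
#' @export
name_overlap <- function(u, partitions = NULL) {
  if (is.null(partitions)) {
    partitions <- setdiff(unique(u$cells$partition), "full")
  }
  stopifnot(length(partitions) >= 2L)
  sets <- lapply(partitions, function(p) unique(part_cells(u, p)$canonical))
  names(sets) <- partitions
  per <- dplyr::bind_rows(lapply(partitions, function(p) {
    others <- unique(unlist(sets[setdiff(partitions, p)]))
    uniq <- setdiff(sets[[p]], others)
    tibble::tibble(partition = p, n_names = length(sets[[p]]),
                   n_unique = length(uniq),
                   pct_unique = if (length(sets[[p]]))
                     100 * length(uniq) / length(sets[[p]]) else NA_real_)
  }))
  pairs <- utils::combn(partitions, 2)
  inter <- dplyr::bind_rows(apply(pairs, 2, function(pr) {
    tibble::tibble(a = pr[1], b = pr[2],
                   n_shared = length(intersect(sets[[pr[1]]], sets[[pr[2]]])))
  }))
  list(per_partition = per, intersections = inter)
}

#' Estimate a Zipf exponent from usage counts
#'
#' Ordinary least squares on log(count) against log(rank) over the ranks
#' whose counts reach `min_count` (the sampled tail flattens below a few
#' observations and is excluded from the fit).
#'
#' @param counts integer vector of per-resource counts.
#' @param min_count smallest count included in the fit.
#' @return the estimated exponent (positive for a decreasing law).
#' @export
estimate_zipf_exponent <- function(counts, min_count = 5L) {
  cnt <- sort(counts[counts > 0], decreasing = TRUE)
  keep <- cnt >= min_count
  if (sum(keep) < 3L) stop("too few ranks above min_count for a fit")
  r <- seq_along(cnt)[keep]
  fit <- stats::lm(log(cnt[keep]) ~ log(r))
  -unname(stats::coef(fit)[2])
}
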