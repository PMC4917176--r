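#' Strict and lenient span evaluation
#'
#' System mentions are scored against gold standoff annotations with
#' one-to-one span matching. In strict mode a true positive requires the
#' offsets to match exactly; in lenient mode any character overlap counts.
#' A strict match is always also a lenient match, so lenient metrics
#' dominate strict ones.
#'
#' @name evaluation
NULL

check_spans <- function(sp) {
  sp <- as.data.frame(sp)
  if (nrow(sp) && any(sp$end <= sp$start))
    stop("malformed span: end <= start")
  sp
}

#' Match gold and system spans
#'
#' One-to-one maximum-cardinality matching, preferring larger overlaps
#' (ties broken by left-most gold span, then left-most system span). Spans
#' are (start, end) half-open within one document.
#'
#' @param gold,system data frames with `start` and `end` columns.
#' @param mode `"strict"` (exact offsets) or `"lenient"` (any overlap).
#' @return list with `mode`, `TP`, `FP`, `FN`.
#' @export
match_spans <- function(gold, system, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  gold <- check_spans(gold); system <- check_spans(system)
  ng <- nrow(gold); ns <- nrow(system)
  edges <- NULL
  if (ng && ns) {
    ov <- outer(seq_len(ng), seq_len(ns), Vectorize(function(i, j) {
      max(0L, min(gold$end[i], system$end[j]) -
            max(gold$start[i], system$start[j]))
    }))
    if (mode == "strict") {
      ok <- outer(seq_len(ng), seq_len(ns), Vectorize(function(i, j) {
        gold$start[i] == system$start[j] && gold$end[i] == system$end[j]
      }))
      ov[!ok] <- 0L
    }
    idx <- which(ov > 0, arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- data.frame(g = idx[, 1], s = idx[, 2],
                          w = ov[idx])
      edges <- edges[order(-edges$w, gold$start[edges$g],
                           system$start[edges$s]), , drop = FALSE]
    }
  }
  tp <- 0L
  if (!is.null(edges)) {
    # Kuhn's augmenting-path maximum bipartite matching; gold vertices are
    # tried in preference order so larger overlaps are matched first
    adj <- split(edges$s, edges$g)  # split keeps the preference order
    match_s <- rep(NA_integer_, ns)
    try_g <- function(g, env) {
      for (s in adj[[as.character(g)]]) {
        if (env$seen[s]) next
        env$seen[s] <- TRUE
        if (is.na(match_s[s]) || try_g(match_s[s], env)) {
          match_s[s] <<- g
          return(TRUE)
        }
      }
      FALSE
    }
    for (g in unique(edges$g)) {
      e <- new.env(parent = emptyenv())
      e$seen <- rep(FALSE, ns)
      try_g(g, e)
    }
    tp <- sum(!is.na(match_s))
  }
  list(mode = mode, TP = tp, FP = ns - tp, FN = ng - tp)
}

#' Precision, recall and F from a match result
#'
#' Empty denominators are flagged (`precision_defined` / `recall_defined`)
#' and the corresponding metric reported as 0 with a warning.
#'
#' @param r list from [match_spans()] (fields TP, FP, FN).
#' @return list with precision, recall, f1 and the defined-flags.
#' @export
score_prf <- function(r) {
  stopifnot(r$TP >= 0, r$FP >= 0, r$FN >= 0)
  p_def <- (r$TP + r$FP) > 0
  r_def <- (r$TP + r$FN) > 0
  if (!p_def) warning("precision undefined (no system spans); reported as 0")
  if (!r_def) warning("recall undefined (no gold spans); reported as 0")
  p <- if (p_def) r$TP / (r$TP + r$FP) else 0
  rc <- if (r_def) r$TP / (r$TP + r$FN) else 0
  f1 <- if (p + rc > 0) 2 * p * rc / (p + rc) else 0
  list(precision = p, recall = rc, f1 = f1,
       precision_defined = p_def, recall_defined = r_def)
}

#' Rank-based AUC with tie correction
#'
#' Equivalent to the Mann-Whitney statistic: the probability that a
#' randomly chosen positive scores above a randomly chosen negative, with
#' ties counted half.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical (or coercible) vector; TRUE marks positives.
#' @return AUC in \[0, 1\].
#' @export
score_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a mention table against gold annotations
#'
#' Convenience wrapper: per-document strict and lenient matching with
#' counts pooled over the corpus before computing precision/recall/F.
#'
#' @param mentions mention tibble (doc_id, stream, start, end).
#' @param gold gold tibble (doc_id, stream, start, end).
#' @param streams which streams to evaluate (default body only).
#' @return tibble with one row per mode: mode, TP, FP, FN, precision,
#'   recall, f1.
#' @export
evaluate_mentions <- function(mentions, gold, streams = "body") {
  if (!"stream" %in% names(gold)) gold$stream <- "body"
  mentions <- mentions[mentions$stream %in% streams, , drop = FALSE]
  gold <- gold[gold$stream %in% streams, , drop = FALSE]
  docs <- union(unique(mentions$doc_id), unique(gold$doc_id))
  gsplit <- split(gold[, c("start", "end")], gold$doc_id)
  msplit <- split(mentions[, c("start", "end")], mentions$doc_id)
  empty_sp <- data.frame(start = integer(), end = integer())
  out <- lapply(c("strict", "lenient"), function(mode) {
    tp <- fp <- fn <- 0L
    for (d in docs) {
      m <- match_spans(gsplit[[d]] %||% empty_sp,
                       msplit[[d]] %||% empty_sp, mode)
      tp <- tp + m$TP; fp <- fp + m$FP; fn <- fn + m$FN
    }
    s <- suppressWarnings(score_prf(list(TP = tp, FP = fp, FN = fn)))
    tibble::tibble(mode = mode, TP = tp, FP = fp, FN = fn,
                   precision = s$precision, recall = s$recall, f1 = s$f1)
  })
  dplyr::bind_rows(out)
}
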