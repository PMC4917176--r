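#' Rule-feature false-positive filter
#'
#' A post-processing classifier scores each accepted mention purely from its
#' rule-match profile: 17 binary indicators (one per rule) plus the total
#' number of rules matched, 18 features in all. No lexical or
#' morpho-syntactic features are used, so the classifier learns exclusively
#' from the recogniser's own evidence and permuting surface strings leaves
#' its predictions unchanged. Mentions for which the classifier is at least
#' `confidence` sure of being false positives are removed.
#'
#' @name ml_filter
NULL

FILTER_FAMILIES <- c("random_forest", "naive_bayes", "svm_linear", "svm_rbf")
LABEL_LEVELS <- c("false_positive", "true_positive")

#' Encode mentions as rule-feature vectors
#'
#' @param rules list of integer vectors of matched rule ids (e.g. the
#'   `rules` column of a mention tibble), or a mention tibble with such a
#'   column.
#' @return data frame with 18 columns: `r1` ... `r17` as two-level factors
#'   ("0"/"1") and numeric `rule_count`.
#' @export
featurize <- function(rules) {
  if (is.data.frame(rules)) rules <- rules$rules
  ids <- unlist(rules, use.names = FALSE)
  if (length(ids) && (any(ids < 1L) || any(ids > N_RULES)))
    stop("rule id outside [1, ", N_RULES, "]: config/rule mismatch")
  flags <- vapply(rules, function(r) as.integer(seq_len(N_RULES) %in% r),
                  integer(N_RULES))
  flags <- if (length(rules)) t(flags) else
    matrix(integer(), ncol = N_RULES)
  df <- as.data.frame(lapply(seq_len(N_RULES), function(j)
    factor(flags[, j], levels = c("0", "1"))))
  names(df) <- paste0("r", seq_len(N_RULES))
  df$rule_count <- as.numeric(rowSums(flags))
  df
}

#' Label system mentions against gold annotations
#'
#' Aligns each mention to the gold standoff annotations of its document and
#' stream; a mention is a `true_positive` if it matches some gold span
#' (exactly, in strict mode; with any character overlap, in lenient mode)
#' and a `false_positive` otherwise.
#'
#' @param mentions mention tibble (from [recognize_corpus()]).
#' @param gold gold tibble: doc_id, start, end, name, stream, caption_idx.
#' @param mode `"lenient"` (default) or `"strict"`.
#' @return the mention tibble with a `label` column.
#' @export
label_mentions <- function(mentions, gold, mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  if (!"caption_idx" %in% names(gold)) gold$caption_idx <- NA_integer_
  if (!"stream" %in% names(gold)) gold$stream <- "body"
  gkey <- paste(gold$doc_id, gold$stream,
                ifelse(is.na(gold$caption_idx), 0L, gold$caption_idx))
  mkey <- paste(mentions$doc_id, mentions$stream,
                ifelse(is.na(mentions$caption_idx), 0L,
                       mentions$caption_idx))
  gsplit <- split(seq_len(nrow(gold)), gkey)
  lab <- vapply(seq_len(nrow(mentions)), function(i) {
    idx <- gsplit[[mkey[i]]]
    if (is.null(idx)) return("false_positive")
    hit <- if (mode == "strict") {
      any(gold$start[idx] == mentions$start[i] &
            gold$end[idx] == mentions$end[i])
    } else {
      any(gold$start[idx] < mentions$end[i] &
            gold$end[idx] > mentions$start[i])
    }
    if (hit) "true_positive" else "false_positive"
  }, character(1))
  mentions$label <- lab
  mentions
}

#' Train the false-positive filter
#'
#' @param data labelled mentions: a tibble with a `rules` list-column and a
#'   `label` column with both values `"true_positive"` and
#'   `"false_positive"` present.
#' @param family one of `"random_forest"`, `"naive_bayes"`, `"svm_linear"`,
#'   `"svm_rbf"`.
#' @param seed integer seed recorded in the model metadata; all stochastic
#'   steps are seeded so the same data and seed give identical predictions.
#' @return object of class `resmine_filter`.
#' @export
train_filter <- function(data, family = "random_forest", seed = 1L) {
  family <- match.arg(family, FILTER_FAMILIES)
  y <- factor(data$label, levels = LABEL_LEVELS)
  missing_class <- LABEL_LEVELS[!LABEL_LEVELS %in% y]
  if (length(missing_class))
    stop("training data lacks class: ", paste(missing_class, collapse = ", "))
  x <- featurize(data)
  set.seed(seed)
  fit <- switch(family,
    random_forest = randomForest::randomForest(x, y, ntree = 200),
    naive_bayes = e1071::naiveBayes(x, y, laplace = 1),
    svm_linear = e1071::svm(x_to_numeric(x), y, kernel = "linear",
                            probability = TRUE, scale = FALSE),
    svm_rbf = e1071::svm(x_to_numeric(x), y, kernel = "radial",
                         probability = TRUE, scale = FALSE))
  structure(list(family = family, fit = fit, seed = seed,
                 trained_n = nrow(x)),
            class = "resmine_filter")
}

x_to_numeric <- function(x) {
  out <- as.data.frame(lapply(x, function(col)
    if (is.factor(col)) as.numeric(as.character(col)) else col))
  as.matrix(out)
}

#' Predict false-positive probabilities
#'
#' @param model `resmine_filter`.
#' @param mentions mention tibble (or anything [featurize()] accepts).
#' @return numeric vector of P(false positive) in \[0, 1\].
#' @export
predict_filter <- function(model, mentions) {
  x <- featurize(mentions)
  if (nrow(x) == 0L) return(numeric())
  switch(model$family,
    random_forest = unname(
      stats::predict(model$fit, x, type = "prob")[, "false_positive"]),
    naive_bayes = unname(
      stats::predict(model$fit, x, type = "raw")[, "false_positive"]),
    {
      pr <- stats::predict(model$fit, x_to_numeric(x), probability = TRUE)
      unname(attr(pr, "probabilities")[, "false_positive"])
    })
}

#' @export
print.resmine_filter <- function(x, ...) {
  cat("<resmine_filter> family=", x$family, " n=", x$trained_n,
      " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Repeated k-fold cross-validation of filter families
#'
#' The labelled data are shuffled `repeats` times; each shuffle is split
#' into `folds` folds and every family is trained/evaluated on each fold.
#' Precision, recall and F (for the true-positive class) are computed from
#' the confusion counts pooled over the folds of each repeat, AUC from the
#' pooled scores, and means and standard deviations are reported over
#' repeats.
#'
#' @param data labelled mention tibble (see [train_filter()]).
#' @param families character vector of model families.
#' @param folds,repeats cross-validation layout.
#' @param seed integer seed.
#' @return tibble with one row per family: precision/recall/f1/auc means
#'   and standard deviations.
#' @export
cross_validate <- function(data, families = c("random_forest", "naive_bayes"),
                           folds = 10L, repeats = 10L, seed = 1L) {
  n <- nrow(data)
  if (folds > n) stop("more folds (", folds, ") than observations (", n, ")")
  families <- vapply(families, match.arg, character(1),
                     choices = FILTER_FAMILIES)
  set.seed(seed)
  per_repeat <- list()
  for (rep_i in seq_len(repeats)) {
    ord <- sample.int(n)
    fold_id <- rep_len(seq_len(folds), n)[order(ord)]
    for (fam in families) {
      tp <- fp <- fn <- tn <- 0L
      scores <- numeric(n); truth <- character(n)
      for (f in seq_len(folds)) {
        tr <- data[fold_id != f, , drop = FALSE]
        te <- data[fold_id == f, , drop = FALSE]
        if (length(unique(tr$label)) < 2L) next
        mod <- train_filter(tr, fam, seed = seed * 1000L + rep_i)
        p_fp <- predict_filter(mod, te)
        pred_tp <- p_fp < 0.5
        is_tp <- te$label == "true_positive"
        tp <- tp + sum(pred_tp & is_tp)
        fp <- fp + sum(pred_tp & !is_tp)
        fn <- fn + sum(!pred_tp & is_tp)
        tn <- tn + sum(!pred_tp & !is_tp)
        scores[fold_id == f] <- 1 - p_fp
        truth[fold_id == f] <- te$label
      }
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      auc <- score_auc(scores, truth == "true_positive")
      per_repeat[[length(per_repeat) + 1L]] <- tibble::tibble(
        family = fam, repeat_i = rep_i, precision = prec, recall = rec,
        f1 = f1, auc = auc)
    }
  }
  res <- dplyr::bind_rows(per_repeat)
  out <- dplyr::summarise(
    dplyr::group_by(res, .data$family),
    precision_sd = stats::sd(.data$precision), precision = mean(.data$precision),
    recall_sd = stats::sd(.data$recall), recall = mean(.data$recall),
    f1_sd = stats::sd(.data$f1), f1 = mean(.data$f1),
    auc_sd = stats::sd(.data$auc), auc = mean(.data$auc),
    .groups = "drop")
  out[, c("family", "precision", "precision_sd", "recall", "recall_sd",
          "f1", "f1_sd", "auc", "auc_sd")]
}

#' Apply the filter to accepted mentions
#'
#' A mention is removed iff the model is at least `confidence` sure it is a
#' false positive (the boundary itself is removal); retained mentions keep
#' their `filter_confidence` (P(false positive)) for audit.
#'
#' @param mentions mention tibble.
#' @param model `resmine_filter`.
#' @param confidence removal threshold on P(false positive).
#' @return the retained subset of `mentions` with a `filter_confidence`
#'   column.
#' @export
apply_filter <- function(mentions, model, confidence = 0.80) {
  if (nrow(mentions) == 0L) {
    mentions$filter_confidence <- numeric()
    return(mentions)
  }
  p_fp <- predict_filter(model, mentions)
  mentions$filter_confidence <- p_fp
  mentions[p_fp < confidence, , drop = FALSE]
}
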