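#' Journal and resource clustering by SVD
#'
#' A sparse resource x journal matrix of document-level mention counts is
#' decomposed with a singular value decomposition of the raw counts (no
#' centering or scaling: centering would densify the sparse matrix, which
#' is why a PCA is not used). The leading singular direction separates
#' journals by sheer scale of mentions and is dropped; components 2 and 3
#' give the 2-D embedding of journals (or, via the same decomposition's
#' left vectors, of resources).
#'
#' @name clustering
NULL

#' Build the sparse resource x journal count matrix
#'
#' Cell (r, j) holds the document-level mention count of resource r in
#' journal j within the partition (summed over years); zero cells are not
#' stored.
#'
#' @param u `resmine_usage`.
#' @param partition partition name.
#' @return `Matrix::dgCMatrix` with resource rownames and journal colnames.
#' @export
build_count_matrix <- function(u, partition) {
  cells <- part_cells(u, partition)
  if (nrow(cells) == 0L) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(0L, 0L)))
  }
  agg <- dplyr::summarise(
    dplyr::group_by(cells, .data$canonical, .data$journal),
    doc_count = sum(.data$doc_count), .groups = "drop")
  res <- sort(unique(agg$canonical))
  jou <- sort(unique(agg$journal))
  Matrix::sparseMatrix(
    i = match(agg$canonical, res), j = match(agg$journal, jou),
    x = as.numeric(agg$doc_count), dims = c(length(res), length(jou)),
    dimnames = list(res, jou))
}

# top-`rank` singular triplets of a sparse matrix via the eigen
# decomposition of the Gram matrix over the smaller dimension
sparse_svd <- function(m, rank) {
  r <- nrow(m); j <- ncol(m)
  rank <- min(rank, r, j)
  if (j <= r) {
    eg <- eigen(as.matrix(Matrix::crossprod(m)), symmetric = TRUE)
    d2 <- pmax(eg$values[seq_len(rank)], 0)
    d <- sqrt(d2)
    v <- eg$vectors[, seq_len(rank), drop = FALSE]
    u <- matrix(0, r, rank)
    pos <- d > max(d[1], .Machine$double.eps) * 1e-10
    if (any(pos)) {
      u[, pos] <- as.matrix(m %*% v[, pos, drop = FALSE]) %*%
        diag(1 / d[pos], sum(pos))
    }
  } else {
    eg <- eigen(as.matrix(Matrix::tcrossprod(m)), symmetric = TRUE)
    d2 <- pmax(eg$values[seq_len(rank)], 0)
    d <- sqrt(d2)
    u <- eg$vectors[, seq_len(rank), drop = FALSE]
    v <- matrix(0, j, rank)
    pos <- d > max(d[1], .Machine$double.eps) * 1e-10
    if (any(pos)) {
      v[, pos] <- as.matrix(Matrix::crossprod(m, u[, pos, drop = FALSE])) %*%
        diag(1 / d[pos], sum(pos))
    }
  }
  list(d = d, u = u, v = v)
}

#' Project journals or resources onto singular directions
#'
#' Computes the top-`rank` singular triplets of the raw count matrix and
#' returns the 2-D embedding on components 2 and 3 (with `drop_first`,
#' the default, since component 1 is a scale separation). With
#' `transpose = TRUE` the row entities (resources) are embedded using the
#' same decomposition's left singular vectors.
#'
#' @param m sparse count matrix from [build_count_matrix()].
#' @param k number of components retained for the embedding.
#' @param drop_first drop the first (scale) component and embed on
#'   components 2..k.
#' @param transpose embed resources (rows) instead of journals (columns).
#' @param rank number of singular values computed (for variance fractions).
#' @param log1p apply a log1p transform to the counts first (off by
#'   default; the decomposition is of raw counts).
#' @return object of class `resmine_projection`: list with `coords` (tibble
#'   entity + one column per retained component, coordinates scaled by the
#'   singular values), `singular_values`, `variance_fractions`, `degenerate`
#'   (TRUE when a retained singular value is zero).
#' @export
svd_project <- function(m, k = 3L, drop_first = TRUE, transpose = FALSE,
                        rank = 10L, log1p = FALSE) {
  if (min(dim(m)) < k) stop("k exceeds matrix rank bound: min(dim) < k")
  if (log1p) m <- Matrix::Matrix(log1p(m), sparse = TRUE)
  dec <- sparse_svd(m, max(rank, k))
  comps <- if (drop_first) seq(2L, k) else seq_len(k)
  vecs <- if (transpose) dec$u else dec$v
  entities <- if (transpose) rownames(m) else colnames(m)
  coords <- vecs[, comps, drop = FALSE] %*% diag(dec$d[comps], length(comps))
  colnames(coords) <- paste0("comp", comps)
  tol <- max(dec$d) * 1e-6  # Gram-matrix route loses ~half the precision
  degenerate <- any(dec$d[comps] <= tol)
  if (degenerate)
    warning("retained singular value is (near) zero: projection degenerate")
  structure(list(
    coords = tibble::tibble(entity = entities %||%
                              as.character(seq_len(nrow(coords))),
                            tibble::as_tibble(coords)),
    singular_values = dec$d,
    variance_fractions = if (sum(dec$d^2) > 0) dec$d^2 / sum(dec$d^2) else
      rep(NA_real_, length(dec$d)),
    k = k, drop_first = drop_first, transpose = transpose,
    degenerate = degenerate), class = "resmine_projection")
}

#' Variance explained per component
#'
#' Fractions sigma_i^2 / sum(sigma_j^2) over the computed rank.
#'
#' @param p `resmine_projection`.
#' @return numeric vector summing to 1.
#' @export
variance_explained <- function(p) {
  stopifnot(inherits(p, "resmine_projection"))
  if (all(p$singular_values == 0)) stop("all-zero matrix: no variance")
  p$variance_fractions
}

#' @export
print.resmine_projection <- function(x, ...) {
  cat("<resmine_projection> ", nrow(x$coords), " entities on components ",
      paste(setdiff(colnames(x$coords), "entity"), collapse = ", "),
      if (x$degenerate) " (degenerate)", "\n", sep = "")
  invisible(x)
}
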