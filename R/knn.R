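#' Build a nearest-neighbour training space
#'
#' The classifier space is spanned by the FOS-selected terms: each training
#' patient sits at the coordinates of their term values (11-dimensional for
#' the published model) with a +/-1 risk label. Queries are classified by
#' majority vote of the `k` nearest training points under the chosen
#' metric.
#'
#' @param coordinates numeric matrix, rows = training patients, columns =
#'   selected terms.
#' @param labels vector in `{-1, +1}`, one per row.
#' @param terms character vector naming the columns (defaults to existing
#'   column names).
#' @param k neighbourhood size; odd, `<=` number of training points
#'   (default 3).
#' @param metric distance metric; only `"euclidean"` is implemented.
#' @param ids optional training-point identifiers (default row names or
#'   index).
#' @return object of class `fos3nn_space`.
#' @export
training_space <- function(coordinates, labels, terms = colnames(coordinates),
                           k = 3, metric = "euclidean", ids = NULL) {
  stopifnot(is.matrix(coordinates))
  n <- nrow(coordinates)
  if (n == 0) stop("empty training space")
  if (length(labels) != n) stop("labels must match training rows")
  if (!all(labels %in% c(-1, 1))) stop("labels must be coded -1/+1")
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd so majority vote cannot tie")
  if (k > n) stop("k exceeds the number of training points")
  metric <- match.arg(metric, "euclidean")
  if (is.null(ids)) ids <- rownames(coordinates) %||% as.character(seq_len(n))
  structure(list(coordinates = unname(coordinates), labels = as.numeric(labels),
                 terms = terms, k = k, metric = metric, ids = as.character(ids)),
            class = "fos3nn_space")
}

#' Classify queries by k-nearest-neighbour majority vote
#'
#' For each query row the `k` training points at smallest Euclidean
#' distance vote with their labels; distance ties at the k-th neighbour are
#' broken by training insertion order (earlier points win), so exactly `k`
#' points vote and, with odd `k` and binary labels, no vote can tie.
#'
#' @param space a [training_space()].
#' @param query numeric matrix with the same number of columns as the
#'   space.
#' @return data.frame with one row per query: `predicted` (+1/-1),
#'   `votes_high` (count of +1 neighbours) and list-columns
#'   `neighbour_ids`, `neighbour_distances`, `neighbour_labels`
#'   (each sorted by increasing distance).
#' @export
knn_classify <- function(space, query) {
  stopifnot(inherits(space, "fos3nn_space"))
  if (is.vector(query)) query <- matrix(query, nrow = 1)
  stopifnot(is.matrix(query))
  tr <- space$coordinates
  if (ncol(query) != ncol(tr)) stop("query dimension does not match training space")
  # squared Euclidean distances, all pairs
  d2 <- outer(rowSums(query^2), rowSums(tr^2), "+") - 2 * tcrossprod(query, tr)
  d2[d2 < 0] <- 0
  k <- space$k
  res <- lapply(seq_len(nrow(query)), function(q) {
    ord <- order(d2[q, ], seq_len(ncol(d2)))[seq_len(k)]
    labs <- space$labels[ord]
    list(predicted = if (sum(labs) > 0) 1 else -1,
         votes_high = sum(labs == 1),
         ids = space$ids[ord],
         dist = sqrt(d2[q, ord]),
         labs = labs)
  })
  out <- data.frame(predicted = vapply(res, `[[`, 0, "predicted"),
                    votes_high = vapply(res, `[[`, 0L, "votes_high"))
  out$neighbour_ids <- lapply(res, `[[`, "ids")
  out$neighbour_distances <- lapply(res, `[[`, "dist")
  out$neighbour_labels <- lapply(res, `[[`, "labs")
  rownames(out) <- rownames(query)
  out
}

#' Append training points to a space
#'
#' Supports the second validation protocol, where the classifier is
#' refilled with all previously seen patients before scoring a further
#' hold-out set. Original points keep their insertion order (and hence
#' their tie-breaking priority); new points follow.
#'
#' @param space a [training_space()].
#' @param coordinates new rows (same column count).
#' @param labels labels in `{-1, +1}` for the new rows.
#' @param ids optional identifiers for the new rows.
#' @return a new `fos3nn_space`.
#' @export
augment_space <- function(space, coordinates, labels, ids = NULL) {
  stopifnot(inherits(space, "fos3nn_space"))
  if (is.null(coordinates) || nrow(coordinates) == 0) return(space)
  stopifnot(is.matrix(coordinates), ncol(coordinates) == ncol(space$coordinates))
  if (length(labels) != nrow(coordinates)) stop("labels must match new rows")
  if (!all(labels %in% c(-1, 1))) stop("labels must be coded -1/+1")
  if (is.null(ids)) {
    ids <- rownames(coordinates) %||%
      as.character(length(space$ids) + seq_len(nrow(coordinates)))
  }
  training_space(rbind(space$coordinates, unname(coordinates)),
                 c(space$labels, as.numeric(labels)),
                 terms = space$terms, k = space$k, metric = space$metric,
                 ids = c(space$ids, as.character(ids)))
}

#' @export
print.fos3nn_space <- function(x, ...) {
  cat(sprintf("%d-NN space: %d training points, %d dimensions (%d high / %d low)\n",
              x$k, nrow(x$coordinates), ncol(x$coordinates),
              sum(x$labels == 1), sum(x$labels == -1)))
  invisible(x)
}
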