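#' Fit the per-marker range normalization
#'
#' Each marker is mapped by a per-marker affine (min-max) transform so that
#' the training minimum lands on `lo` and the training maximum on `hi`
#' (defaults 0.02 and 13.5). This equalizes the weight of markers whose
#' laboratory scales differ by orders of magnitude (e.g. HGB in g/L vs ANC
#' in 10^9 cells/L) before cross-product terms are formed and before
#' distances are computed in the classifier space.
#'
#' A constant (zero-range) marker cannot be min-max scaled; it is mapped to
#' the range midpoint `(lo + hi)/2` and flagged degenerate with a warning.
#' The fitted transform is applied unchanged to unseen patients, whose
#' values may fall outside `[lo, hi]`; they are not clipped.
#'
#' @param x numeric matrix (rows = training patients, columns = markers) or
#'   a patient table, in which case the 12 CBC columns are used.
#' @param lo,hi target range bounds, `lo < hi`.
#' @return object of class `fos3nn_normalization`: list with `offset`,
#'   `scale`, `degenerate` (named per marker), `lo`, `hi`, `markers`.
#' @export
fit_normalization <- function(x, lo = 0.02, hi = 13.5) {
  if (inherits(x, "fos3nn_patients")) x <- marker_matrix(x)
  stopifnot(is.matrix(x), is.numeric(x), lo < hi)
  if (nrow(x) < 2) stop("need at least 2 training records to fit normalization")
  if (is.null(colnames(x))) colnames(x) <- paste0("m", seq_len(ncol(x)))
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value for patient %s, marker %s",
                 rownames(x)[bad[1]] %||% bad[1], colnames(x)[bad[2]]))
  }
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  rng <- maxs - mins
  degenerate <- rng == 0
  scale <- ifelse(degenerate, 0, (hi - lo) / rng)
  offset <- ifelse(degenerate, (lo + hi) / 2, lo - mins * scale)
  if (any(degenerate)) {
    warning("constant marker(s) mapped to range midpoint: ",
            paste(colnames(x)[degenerate], collapse = ", "), call. = FALSE)
  }
  structure(
    list(offset = stats::setNames(offset, colnames(x)),
         scale = stats::setNames(scale, colnames(x)),
         degenerate = stats::setNames(degenerate, colnames(x)),
         lo = lo, hi = hi, markers = colnames(x)),
    class = "fos3nn_normalization")
}

#' Apply a fitted normalization
#'
#' @param params a `fos3nn_normalization` object from [fit_normalization()].
#' @param x numeric matrix or patient table with the fitted marker columns.
#' @return numeric matrix of mapped values, same shape, columns in the
#'   fitted marker order.
#' @export
apply_normalization <- function(params, x) {
  stopifnot(inherits(params, "fos3nn_normalization"))
  if (inherits(x, "fos3nn_patients")) x <- marker_matrix(x)
  stopifnot(is.matrix(x))
  if (is.null(colnames(x))) {
    if (ncol(x) != length(params$markers)) stop("marker count mismatch")
    colnames(x) <- params$markers
  }
  miss <- setdiff(params$markers, colnames(x))
  if (length(miss)) stop("missing marker column(s): ", paste(miss, collapse = ", "))
  x <- x[, params$markers, drop = FALSE]
  out <- sweep(sweep(x, 2, params$scale, "*"), 2, params$offset, "+")
  out
}

#' @export
print.fos3nn_normalization <- function(x, ...) {
  cat(sprintf("Range normalization to [%g, %g] over %d markers\n",
              x$lo, x$hi, length(x$markers)))
  if (any(x$degenerate)) {
    cat("  degenerate (constant) markers:",
        paste(x$markers[x$degenerate], collapse = ", "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
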