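#' Expand markers into the first- and second-order candidate set
#'
#' From `p` normalized marker columns, builds the ordered candidate algebra
#' of `p + p(p+1)/2` terms: the `p` first-order terms in the fixed marker
#' order, followed by all unordered pairs `(i, j)` with `i <= j` in
#' lexicographic order (pairs with `i == j` are squares). For the 12 CBC
#' markers this is the 90-term candidate set searched by FOS. Cross-product
#' columns are the elementwise products of the normalized marker columns,
#' so marker-scale differences do not dominate the products.
#'
#' @param x numeric matrix of normalized marker values (rows = patients),
#'   with unique column names.
#' @return object of class `fos3nn_candidates`: list with `terms`
#'   (data.frame: `name`, `kind`, `i`, `j`) and `values` (matrix, one
#'   column per term, columns named by term).
#' @export
build_candidate_set <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  nm <- colnames(x)
  if (is.null(nm)) stop("marker matrix must have column names")
  if (anyDuplicated(nm)) stop("duplicate marker names")
  if (!all(is.finite(x))) stop("non-finite marker values")
  p <- ncol(x)
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  terms <- data.frame(
    name = c(nm, paste0(nm[pairs[, "row"]], "*", nm[pairs[, "col"]])),
    kind = rep(c("first_order", "cross_product"), c(p, nrow(pairs))),
    i = c(seq_len(p), pairs[, "row"]),
    j = c(seq_len(p), pairs[, "col"]),
    stringsAsFactors = FALSE)
  vals <- cbind(x, x[, pairs[, "row"], drop = FALSE] * x[, pairs[, "col"], drop = FALSE])
  colnames(vals) <- terms$name
  structure(list(terms = terms, values = vals, markers = nm),
            class = "fos3nn_candidates")
}

#' @export
print.fos3nn_candidates <- function(x, ...) {
  cat(sprintf("Candidate set: %d terms (%d first-order, %d second-order) x %d patients\n",
              nrow(x$terms), sum(x$terms$kind == "first_order"),
              sum(x$terms$kind == "cross_product"), nrow(x$values)))
  invisible(x)
}

#' Parse term labels against a marker alphabet
#'
#' Term labels follow the `"A"` / `"A*B"` convention (e.g. `"ANC0"`,
#' `"PLT28*ANC28"`); pairs are stored canonically with `i <= j` so
#' `"B*A"` and `"A*B"` name the same term.
#'
#' @param labels character vector of term labels.
#' @param markers marker name alphabet (default [cbc_marker_names()]).
#' @return data.frame with columns `name`, `kind`, `i`, `j`.
#' @export
parse_terms <- function(labels, markers = cbc_marker_names()) {
  parts <- strsplit(labels, "*", fixed = TRUE)
  out <- lapply(seq_along(parts), function(k) {
    pr <- parts[[k]]
    idx <- match(pr, markers)
    if (anyNA(idx) || !(length(pr) %in% 1:2)) {
      stop("unknown term label: ", labels[k])
    }
    if (length(pr) == 1) {
      data.frame(name = markers[idx], kind = "first_order", i = idx, j = idx,
                 stringsAsFactors = FALSE)
    } else {
      i <- min(idx); j <- max(idx)
      data.frame(name = paste0(markers[i], "*", markers[j]),
                 kind = "cross_product", i = i, j = j, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Project patients onto a list of selected terms
#'
#' Evaluates each term (first-order marker or pairwise product) on the
#' normalized marker matrix, producing the coordinate matrix used as the
#' nearest-neighbour feature space.
#'
#' @param terms character vector of term labels, or a term data.frame as
#'   returned by [parse_terms()].
#' @param x normalized marker matrix with marker column names.
#' @return numeric matrix, one column per term in the given order (possibly
#'   zero columns).
#' @export
project_selected <- function(terms, x) {
  stopifnot(is.matrix(x))
  if (is.character(terms)) terms <- parse_terms(terms, colnames(x))
  if (length(terms) == 0 || nrow(terms) == 0) {
    return(matrix(numeric(0), nrow = nrow(x), ncol = 0,
                  dimnames = list(rownames(x), NULL)))
  }
  if (any(terms$i > ncol(x)) || any(terms$j > ncol(x))) stop("term index out of range")
  out <- sapply(seq_len(nrow(terms)), function(k) {
    if (terms$kind[k] == "first_order") x[, terms$i[k]]
    else x[, terms$i[k]] * x[, terms$j[k]]
  })
  out <- matrix(out, nrow = nrow(x))
  dimnames(out) <- list(rownames(x), terms$name)
  out
}

#' The published 11-term model preset
#'
#' The 11 optimal terms selected on the original 14-patient training
#' cohort, shipped as a preset so the published feature space can be used
#' for projection and classification with user-supplied normalization.
#' All but `ANC0` are cross-products; day-0 and day-7/28 ANC terms
#' dominate.
#'
#' @return character vector of 11 term labels.
#' @export
published_terms <- function() {
  c("PLT28*ANC28", "ANC0*ANC0", "ANC0", "ANC0*ANC7", "ANC7*HGB28",
    "HGB7*PLT7", "HGB0*ANC7", "ANC0*WBC28", "ANC7*ANC28", "ANC0*ANC28",
    "PLT7*ANC7")
}
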