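#' Bundle a fitted pipeline into a portable model object
#'
#' A trained FOS-3NN model carries everything needed to classify new
#' patients: the marker alphabet, the fitted normalization, the selected
#' terms with their FOS bookkeeping, and the training points (coordinates +
#' labels) that populate the nearest-neighbour space.
#'
#' @param fos a `fos3nn_fos_model` from [fos_select()].
#' @param normalization the `fos3nn_normalization` fitted on the training
#'   cohort.
#' @param coordinates training coordinate matrix (rows = patients, columns
#'   = selected terms).
#' @param labels training labels in `{-1, +1}`.
#' @param ids training patient identifiers.
#' @param k neighbourhood size for classification (default 3).
#' @return list of class `fos3nn_model`.
#' @export
fos3nn_model <- function(fos, normalization, coordinates, labels, ids = NULL,
                         k = 3) {
  stopifnot(inherits(fos, "fos3nn_fos_model"),
            inherits(normalization, "fos3nn_normalization"))
  if (ncol(coordinates) != length(fos$terms)) {
    stop("training coordinates do not match selected terms")
  }
  structure(list(markers = normalization$markers, normalization = normalization,
                 fos = fos, coordinates = unname(coordinates),
                 labels = as.numeric(labels),
                 ids = as.character(ids %||% rownames(coordinates) %||%
                                      seq_along(labels)),
                 k = as.integer(k)),
            class = "fos3nn_model")
}

#' Classify new patients with a trained model
#'
#' Applies the stored normalization, projects onto the selected terms and
#' runs the k-NN majority vote against the stored training points.
#'
#' @param object a `fos3nn_model`.
#' @param patients a patient table or raw marker matrix.
#' @param ... unused.
#' @return the audit data.frame of [knn_classify()], with `patient_id`.
#' @export
predict.fos3nn_model <- function(object, patients, ...) {
  raw <- if (inherits(patients, "fos3nn_patients")) marker_matrix(patients) else patients
  norm <- apply_normalization(object$normalization, raw)
  coords <- project_selected(object$fos$terms, norm)
  space <- training_space(object$coordinates, object$labels,
                          terms = object$fos$terms, k = object$k,
                          ids = object$ids)
  out <- knn_classify(space, coords)
  cbind(patient_id = rownames(raw) %||% as.character(seq_len(nrow(raw))), out)
}

#' Model JSON serialization
#'
#' Writes/reads the portable model JSON: markers, normalization parameters,
#' selected terms, coefficients `a`, weights `g`, MSE reductions `Q`,
#' residual MSE and the training points. Numbers are serialized at full
#' double precision so a round trip is lossless.
#'
#' @param model a `fos3nn_model`.
#' @param path file path.
#' @return `read_fos3nn_model()` returns the reconstructed `fos3nn_model`.
#' @export
write_fos3nn_model <- function(model, path) {
  stopifnot(inherits(model, "fos3nn_model"))
  nz <- model$normalization
  payload <- list(
    markers = as.list(model$markers),
    normalization = list(offset = as.list(nz$offset), scale = as.list(nz$scale),
                         degenerate = as.list(nz$degenerate),
                         lo = nz$lo, hi = nz$hi),
    include_constant = model$fos$include_constant,
    terms = as.list(model$fos$terms),
    a = model$fos$a, g = model$fos$g, Q = model$fos$Q, D = model$fos$D,
    residual_mse = model$fos$residual_mse, msq_y = model$fos$msq_y,
    k = model$k,
    training_points = lapply(seq_along(model$labels), function(i) {
      list(id = model$ids[i], coords = model$coordinates[i, ],
           label = model$labels[i])
    }))
  atomic_write_json(payload, path)
}

#' @rdname write_fos3nn_model
#' @export
read_fos3nn_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  markers <- unlist(p$markers)
  nz <- structure(list(
    offset = stats::setNames(unlist(p$normalization$offset), markers),
    scale = stats::setNames(unlist(p$normalization$scale), markers),
    degenerate = stats::setNames(unlist(p$normalization$degenerate), markers),
    lo = p$normalization$lo, hi = p$normalization$hi, markers = markers),
    class = "fos3nn_normalization")
  terms <- unlist(p$terms) %||% character(0)
  fos <- structure(list(
    terms = terms, term_idx = NA_integer_,
    include_constant = isTRUE(p$include_constant),
    a = unlist(p$a), g = unlist(p$g), Q = unlist(p$Q), D = unlist(p$D),
    alpha = NULL, C = NULL,
    residual_mse = p$residual_mse, msq_y = p$msq_y,
    n = length(p$training_points), excluded = integer(0),
    stop_reason = "loaded", config = NULL), class = "fos3nn_fos_model")
  coords <- do.call(rbind, lapply(p$training_points, function(tp) unlist(tp$coords)))
  if (is.null(coords)) coords <- matrix(numeric(0), 0, length(terms))
  labels <- vapply(p$training_points, function(tp) as.numeric(tp$label), 0)
  ids <- vapply(p$training_points, function(tp) as.character(tp$id), "")
  colnames(coords) <- terms
  fos3nn_model(fos, nz, coords, labels, ids = ids, k = p$k %||% 3)
}

#' @export
print.fos3nn_model <- function(x, ...) {
  cat(sprintf("FOS-3NN model: %d terms, %d training points, k = %d\n",
              length(x$fos$terms), length(x$labels), x$k))
  cat("  terms:", paste(x$fos$terms, collapse = ", "), "\n")
  invisible(x)
}
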