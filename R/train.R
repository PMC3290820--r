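#' Train a FOS-3NN model on a labelled cohort
#'
#' Runs the full training stage: fits the [0.02, 13.5] range normalization
#' on the training cohort, expands the 12 CBC markers into the 90-term
#' candidate set, selects terms by Fast Orthogonal Search against the
#' +/-1 risk outcome, and stores the training patients' coordinates in the
#' selected-term space for nearest-neighbour classification.
#'
#' @param patients labelled patient table (`risk_label` required, +1/-1).
#' @param config a [fos_config()].
#' @param k neighbourhood size for the classifier stage (default 3).
#' @param lo,hi normalization range bounds.
#' @return a `fos3nn_model`.
#' @export
train_fos3nn <- function(patients, config = fos_config(), k = 3,
                         lo = 0.02, hi = 13.5) {
  patients <- as_patients(as.data.frame(patients))
  if (!"risk_label" %in% names(patients) || anyNA(patients$risk_label)) {
    stop("training patients must all carry a risk_label (+1/-1); ",
         "run the labelling stage first")
  }
  y <- patients$risk_label
  raw <- marker_matrix(patients)
  nz <- fit_normalization(raw, lo = lo, hi = hi)
  norm <- apply_normalization(nz, raw)
  cand <- build_candidate_set(norm)
  fos <- fos_select(cand, y, config)
  coords <- project_selected(fos$terms, norm)
  fos3nn_model(fos, nz, coords, y, ids = patients$patient_id, k = k)
}

#' Build a classifier on a fixed term list (no FOS search)
#'
#' Places the training patients in the coordinate space of a user-supplied
#' term list — typically the published 11-term preset
#' ([published_terms()]) — with a freshly fitted normalization, so the
#' published feature space can be reused on new cohorts. The FOS stage is
#' bypassed; the returned model carries no regression coefficients, only
#' the classifier space.
#'
#' @inheritParams train_fos3nn
#' @param terms character vector of term labels over the 12 CBC markers.
#' @return a `fos3nn_model`.
#' @export
train_preset <- function(patients, terms = published_terms(), k = 3,
                         lo = 0.02, hi = 13.5) {
  patients <- as_patients(as.data.frame(patients))
  if (!"risk_label" %in% names(patients) || anyNA(patients$risk_label)) {
    stop("training patients must all carry a risk_label (+1/-1); ",
         "run the labelling stage first")
  }
  y <- patients$risk_label
  raw <- marker_matrix(patients)
  nz <- fit_normalization(raw, lo = lo, hi = hi)
  norm <- apply_normalization(nz, raw)
  parsed <- parse_terms(terms, nz$markers)
  coords <- project_selected(parsed, norm)
  fos <- structure(list(
    terms = parsed$name, term_idx = NA_integer_, include_constant = FALSE,
    a = numeric(0), g = numeric(0), Q = numeric(0), D = numeric(0),
    alpha = NULL, C = NULL, residual_mse = NA_real_, msq_y = mean(y^2),
    n = nrow(norm), excluded = integer(0), stop_reason = "preset",
    config = NULL), class = "fos3nn_fos_model")
  fos3nn_model(fos, nz, coords, y, ids = patients$patient_id, k = k)
}
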