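#' Synthetic cohort specification
#'
#' Describes the generative model used to emulate a chemotherapy cohort:
#' lognormal CBC marker values (counts are positive and right-skewed) with
#' group-specific day-7 nadir and day-28 recovery levels for WBC and ANC,
#' and per-cycle Bernoulli adverse-event processes whose rates differ by
#' risk group. Defaults are chosen once to reflect clinical reality:
#' baseline medians near population norms (WBC 6, HGB 130, PLT 250, ANC 4,
#' in the units of the patient record), a day-7 nadir at about half of
#' baseline for low-risk patients versus severe neutropenic depression
#' (12% of baseline, ANC around 0.5) for high-risk patients, and
#' incomplete day-28 recovery (60% of baseline) in the high-risk group.
#' HGB and PLT move mildly and identically in both groups, so only the
#' markers the method treats as informative (WBC/ANC at days 7 and 28)
#' separate the groups beyond noise.
#'
#' @param n_patients cohort size.
#' @param high_risk_fraction fraction of high-risk patients (default 0.5).
#' @param baseline named medians for `wbc`, `hgb`, `plt`, `anc`.
#' @param sdlog lognormal log-scale sd for every marker draw (default
#'   0.25).
#' @param nadir_factor day-7 WBC/ANC multiplier per group
#'   (`c(low = , high = )`).
#' @param recovery_factor day-28 WBC/ANC multiplier per group.
#' @param hgb_day_factor,plt_day_factor day-7/day-28 multipliers shared by
#'   both groups for HGB and PLT.
#' @param event_rates list of per-group event probabilities; see
#'   [generate_cohort()].
#' @param seed RNG seed (integer).
#' @return list of class `fos3nn_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 35, high_risk_fraction = 0.5,
                        baseline = c(wbc = 6, hgb = 130, plt = 250, anc = 4),
                        sdlog = 0.25,
                        nadir_factor = c(low = 0.5, high = 0.12),
                        recovery_factor = c(low = 0.95, high = 0.6),
                        hgb_day_factor = c(d7 = 0.92, d28 = 0.95),
                        plt_day_factor = c(d7 = 0.85, d28 = 0.95),
                        event_rates = list(
                          high = list(hospitalization = 0.10, dose_reduction = 0.40,
                                      day7_omission = 0.30, delay = 0.40,
                                      delay_days = c(7, 14, 21)),
                          low = list(hospitalization = 0.001, dose_reduction = 0.002,
                                     day7_omission = 0.002, delay_early = 0.003,
                                     delay_late = 0.15, delay_days = c(3, 7))),
                        seed = 1L) {
  stopifnot(n_patients >= 2,
            high_risk_fraction >= 0, high_risk_fraction <= 1, sdlog > 0,
            all(baseline > 0), all(nadir_factor > 0), all(recovery_factor > 0))
  structure(list(n_patients = as.integer(n_patients),
                 high_risk_fraction = high_risk_fraction, baseline = baseline,
                 sdlog = sdlog, nadir_factor = nadir_factor,
                 recovery_factor = recovery_factor,
                 hgb_day_factor = hgb_day_factor, plt_day_factor = plt_day_factor,
                 event_rates = event_rates, seed = as.integer(seed)),
            class = "fos3nn_cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws marker values and treatment-event courses for `n_patients`
#' according to a [cohort_spec()]. Each marker value is
#' `median * exp(N(0, sdlog))` with the group- and day-specific median.
#' Event courses are per-cycle Bernoulli draws (6 cycles): high-risk
#' patients receive elevated rates of hospitalization, early dose
#' reduction, day-7 omission and treatment delay, so that the rule-based
#' label of [assign_risk()] agrees with the generating group for the large
#' majority of patients (>= 95% at default rates; disagreements are
#' reported in the `label_agreement` field). Low-risk patients may still
#' have benign late delays. Fully reproducible from the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return list with `patients` (a `fos3nn_patients` frame, no
#'   `risk_label`), `events` (long per-cycle data.frame), `group` (named
#'   +1/-1 vector of generating groups) and `label_agreement` (fraction of
#'   patients whose rule-based label matches the generating group).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "fos3nn_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  n_high <- round(spec$high_risk_fraction * n)
  group <- c(rep(1, n_high), rep(-1, n - n_high))
  group <- group[sample.int(n)]
  ids <- sprintf("P%03d", seq_len(n))
  names(group) <- ids
  hi <- group == 1
  draw <- function(median) median * exp(stats::rnorm(n, 0, spec$sdlog))
  gfac <- function(fac) ifelse(hi, fac[["high"]], fac[["low"]])
  b <- spec$baseline
  patients <- data.frame(
    patient_id = ids,
    age = round(stats::runif(n, 30, 70), 1),
    height_cm = round(stats::rnorm(n, 162, 6), 1),
    weight_kg = round(stats::rnorm(n, 68, 10), 1),
    wbc_d0 = draw(b[["wbc"]]),
    hgb_d0 = draw(b[["hgb"]]),
    plt_d0 = draw(b[["plt"]]),
    anc_d0 = draw(b[["anc"]]),
    wbc_d7 = draw(b[["wbc"]]) * gfac(spec$nadir_factor),
    hgb_d7 = draw(b[["hgb"]]) * spec$hgb_day_factor[["d7"]],
    plt_d7 = draw(b[["plt"]]) * spec$plt_day_factor[["d7"]],
    anc_d7 = draw(b[["anc"]]) * gfac(spec$nadir_factor),
    wbc_d28 = draw(b[["wbc"]]) * gfac(spec$recovery_factor),
    hgb_d28 = draw(b[["hgb"]]) * spec$hgb_day_factor[["d28"]],
    plt_d28 = draw(b[["plt"]]) * spec$plt_day_factor[["d28"]],
    anc_d28 = draw(b[["anc"]]) * gfac(spec$recovery_factor),
    stringsAsFactors = FALSE)
  patients$bmi <- round(patients$weight_kg / (patients$height_cm / 100)^2, 1)
  for (col in cbc_marker_columns()) patients[[col]] <- round(patients[[col]], 2)

  events <- do.call(rbind, lapply(seq_len(n), function(i) {
    r <- if (hi[i]) spec$event_rates$high else spec$event_rates$low
    delay_p <- if (hi[i]) rep(r$delay, 6) else
      c(rep(r$delay_early, 3), rep(r$delay_late, 3))
    delayed <- stats::runif(6) < delay_p
    data.frame(
      patient_id = ids[i], cycle = 1:6,
      delay_days = ifelse(delayed,
                          sample(r$delay_days, 6, replace = TRUE), 0L),
      hospitalization = stats::runif(6) < r$hospitalization,
      dose_reduction = c(stats::runif(3) < r$dose_reduction, rep(FALSE, 3)),
      day7_treatment_given = !c(stats::runif(3) < r$day7_omission, rep(FALSE, 3)),
      stringsAsFactors = FALSE)
  }))
  labels <- label_courses(events)
  agreement <- mean(labels$risk_label[match(ids, labels$patient_id)] == group)
  list(patients = as_patients(patients), events = events, group = group,
       label_agreement = agreement)
}

#' Planted-signal specification and generator
#'
#' Test harness for FOS term recovery: `p` markers are drawn i.i.d.
#' standard lognormal, range-normalized, and expanded to the full
#' first-/second-order candidate set; the outcome is
#' `y = sign(sum_k beta_k z(term_k) + N(0, noise_sd))`, where `z(.)`
#' z-scores the chosen candidate columns (the raw columns are all
#' positive, so an uncentred sign rule would be constant).
#'
#' @param terms list of planted terms: integer scalars (first-order) or
#'   pairs `c(i, j)` (cross-products; `i == j` is a square).
#' @param beta coefficients, one per planted term.
#' @param noise_sd Gaussian label-noise sd (0 for a noiseless plant).
#' @param p number of markers.
#' @return list of class `fos3nn_planted_spec`.
#' @export
planted_spec <- function(terms, beta = rep(1, length(terms)), noise_sd = 0.25,
                         p = 6) {
  stopifnot(length(terms) >= 1, length(beta) == length(terms),
            all(is.finite(beta)), noise_sd >= 0)
  for (tt in terms) stopifnot(length(tt) %in% 1:2, all(tt >= 1), all(tt <= p))
  structure(list(terms = terms, beta = beta, noise_sd = noise_sd,
                 p = as.integer(p)), class = "fos3nn_planted_spec")
}

#' @rdname planted_spec
#' @param spec a `fos3nn_planted_spec`.
#' @param n number of observations.
#' @param seed RNG seed.
#' @return `generate_planted()` returns a list: `candidates` (a
#'   `fos3nn_candidates` ready for [fos_select()]), `y` (+1/-1 vector) and
#'   `true_terms` (names of the planted candidate columns).
#' @export
generate_planted <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "fos3nn_planted_spec"), n >= 4)
  set.seed(seed)
  X <- matrix(stats::rlnorm(n * spec$p), n, spec$p,
              dimnames = list(NULL, paste0("m", seq_len(spec$p))))
  Xn <- apply_normalization(fit_normalization(X), X)
  cand <- build_candidate_set(Xn)
  term_name <- function(tt) {
    if (length(tt) == 1) colnames(Xn)[tt]
    else paste0(colnames(Xn)[min(tt)], "*", colnames(Xn)[max(tt)])
  }
  true_terms <- vapply(spec$terms, term_name, "")
  Z <- scale(cand$values[, true_terms, drop = FALSE])
  lin <- as.vector(Z %*% spec$beta) +
    if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd) else 0
  y <- ifelse(lin >= 0, 1, -1)
  list(candidates = cand, y = y, true_terms = true_terms)
}
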