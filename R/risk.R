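#' Risk-labelling configuration
#'
#' The retrospective high/low label is a composite of adverse events over
#' the 6-cycle course. `nominal_cycle_length` (days) sets the long-delay
#' threshold: a cycle counts as a "delay beyond 40 days" when its start
#' slips more than `long_delay_threshold = 40 - nominal_cycle_length` days
#' past schedule (default 12 with 28-day cycles, so the gap between
#' consecutive cycle starts exceeds 40 days). `day7_applicable` should be
#' FALSE for regimens without a day-7/8 administration, in which case the
#' day-7 omission rule cannot fire.
#'
#' @param nominal_cycle_length scheduled cycle length in days (default 28).
#' @param long_delay_threshold days of slippage beyond which a single delay
#'   is itself high-risk (default `40 - nominal_cycle_length`).
#' @param day7_applicable does the regimen schedule a day-7/8 dose?
#' @return list of class `fos3nn_risk_config`.
#' @export
risk_config <- function(nominal_cycle_length = 28,
                        long_delay_threshold = 40 - nominal_cycle_length,
                        day7_applicable = TRUE) {
  stopifnot(nominal_cycle_length > 0, long_delay_threshold > 0)
  structure(list(nominal_cycle_length = nominal_cycle_length,
                 long_delay_threshold = long_delay_threshold,
                 day7_applicable = isTRUE(day7_applicable)),
            class = "fos3nn_risk_config")
}

#' Assign the retrospective high/low risk label for one treatment course
#'
#' A patient is high risk (+1) if ANY of the following fires, otherwise
#' low risk (-1); mixed characteristics always resolve to the higher risk
#' level:
#' \describe{
#'   \item{hospitalization}{any hospitalization during the course;}
#'   \item{three_delays}{3 or more cycles started late (`delay_days > 0`);}
#'   \item{long_delay}{any single delay exceeding the configured
#'     long-delay threshold (cycle gap beyond 40 days);}
#'   \item{delay_after_first}{cycle 2 started late (a delay immediately
#'     after the first treatment);}
#'   \item{day7_omission}{day-7 dose not given in any of cycles 1-3
#'     (when the regimen schedules one);}
#'   \item{dose_reduction}{dose reduction in any of cycles 1-3.}
#' }
#' Delays first occurring after cycle 3 that trigger none of the above
#' leave the patient low risk.
#'
#' @param course data.frame with one row per cycle (1-6) and columns
#'   `cycle`, `delay_days`, `hospitalization`, `dose_reduction`,
#'   `day7_treatment_given`.
#' @param config a [risk_config()].
#' @return list with `label` (+1/-1) and `fired` (character vector of rule
#'   names justifying a high label; empty for low).
#' @export
assign_risk <- function(course, config = risk_config()) {
  stopifnot(is.data.frame(course))
  need <- c("cycle", "delay_days", "hospitalization", "dose_reduction",
            "day7_treatment_given")
  miss <- setdiff(need, names(course))
  if (length(miss)) stop("course is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(course) < 1 || nrow(course) > 6) stop("course must have 1-6 cycle records")
  if (anyDuplicated(course$cycle)) stop("duplicate cycle records")
  if (any(course$delay_days < 0)) stop("delay_days must be >= 0")
  course <- course[order(course$cycle), , drop = FALSE]
  first3 <- course$cycle <= 3
  fired <- character(0)
  if (any(as.logical(course$hospitalization))) fired <- c(fired, "hospitalization")
  if (sum(course$delay_days > 0) >= 3) fired <- c(fired, "three_delays")
  if (any(course$delay_days > config$long_delay_threshold)) fired <- c(fired, "long_delay")
  if (any(course$cycle == 2 & course$delay_days > 0)) fired <- c(fired, "delay_after_first")
  if (config$day7_applicable &&
      any(first3 & !as.logical(course$day7_treatment_given))) {
    fired <- c(fired, "day7_omission")
  }
  if (any(first3 & as.logical(course$dose_reduction))) fired <- c(fired, "dose_reduction")
  list(label = if (length(fired)) 1 else -1, fired = fired)
}

#' Label every patient in an events table
#'
#' @param events data.frame in the events-CSV layout: one row per
#'   patient-cycle with columns `patient_id`, `cycle`, `delay_days`,
#'   `hospitalization`, `dose_reduction`, `day7_treatment_given`.
#' @param config a [risk_config()].
#' @return data.frame with `patient_id`, `risk_label` (+1/-1) and
#'   `fired_rules` (comma-separated audit).
#' @export
label_courses <- function(events, config = risk_config()) {
  stopifnot(is.data.frame(events), "patient_id" %in% names(events))
  ids <- unique(as.character(events$patient_id))
  rows <- lapply(ids, function(id) {
    r <- assign_risk(events[events$patient_id == id, , drop = FALSE], config)
    data.frame(patient_id = id, risk_label = r$label,
               fired_rules = paste(r$fired, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort-level label summary
#'
#' @param labelled output of [label_courses()] (or any frame with
#'   `risk_label` and optional `fired_rules`).
#' @return list with `high`, `low` counts and `rule_counts` (patients per
#'   fired rule).
#' @export
cohort_label_summary <- function(labelled) {
  if (is.null(labelled) || nrow(labelled) == 0) {
    return(list(high = 0L, low = 0L, rule_counts = integer(0)))
  }
  fired <- strsplit(labelled$fired_rules %||% character(nrow(labelled)), ",", fixed = TRUE)
  rules <- table(unlist(lapply(fired, function(f) unique(f[nzchar(f)]))))
  list(high = sum(labelled$risk_label == 1),
       low = sum(labelled$risk_label == -1),
       rule_counts = if (length(rules)) stats::setNames(as.integer(rules), names(rules))
                     else integer(0))
}

#' @rdname label_courses
#' @param path events CSV path.
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("hospitalization", "dose_reduction", "day7_treatment_given")) {
    if (col %in% names(ev)) ev[[col]] <- as.logical(ev[[col]])
  }
  ev
}
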