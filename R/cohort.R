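## Cohort data model: baseline covariates, visit-level biomarker
## observations, and one outcome record per patient, with CSV I/O,
## validation, eligibility filtering, age standardization and
## descriptive epidemiology.

MARKERS <- c("lgd", "p53", "sox2")

#' Construct and validate a surveillance cohort
#'
#' Bundles the three tables a Barrett's-esophagus surveillance analysis
#' consumes: one baseline row per patient (`patient_id`, `age_years`,
#' `female`), one row per surveillance visit (`patient_id`, `time_years`,
#' the three dichotomized biomarkers `lgd`/`p53`/`sox2` coded 0/1/NA, and
#' the time-varying covariates `esophagitis`, `long_segment`), and exactly
#' one outcome row per patient (`event_time_years`, `event`,
#' `entry_time_years`). Times are fractional years since the index
#' endoscopy (t = 0).
#'
#' Validation enforces: unique patient ids; ages in (18, 110); every visit
#' and outcome referencing a known patient; strictly increasing visit
#' times within patient with a visit at t = 0; no visit after the
#' patient's event/censoring time; and indicator coding of all binary
#' fields. Missing `esophagitis`/`long_segment` at a follow-up visit are
#' carried forward from the previous visit; missing at the index visit is
#' an error.
#'
#' @param baselines data.frame with columns `patient_id`, `age_years`, `female`.
#' @param visits data.frame with columns `patient_id`, `time_years`,
#'   `lgd`, `p53`, `sox2`, `esophagitis`, `long_segment`.
#' @param outcomes data.frame with columns `patient_id`, `event_time_years`,
#'   `event`, and optionally `entry_time_years` (default 0).
#' @param age_scaler optional `c(mean, sd)` frozen age standardization.
#' @return An object of class `be_cohort`.
#' @seealso [read_cohort()], [apply_eligibility_filters()], [standardize_age()]
#' @export
new_cohort <- function(baselines, visits, outcomes, age_scaler = NULL) {
  baselines <- as.data.frame(baselines, stringsAsFactors = FALSE)
  visits <- as.data.frame(visits, stringsAsFactors = FALSE)
  outcomes <- as.data.frame(outcomes, stringsAsFactors = FALSE)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s table is missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(baselines, c("patient_id", "age_years", "female"), "baseline")
  need(visits, c("patient_id", "time_years", MARKERS, "esophagitis",
                 "long_segment"), "visits")
  need(outcomes, c("patient_id", "event_time_years", "event"), "outcomes")

  baselines$patient_id <- as.character(baselines$patient_id)
  visits$patient_id <- as.character(visits$patient_id)
  outcomes$patient_id <- as.character(outcomes$patient_id)
  if (anyDuplicated(baselines$patient_id))
    stop("duplicate patient_id in baseline table: ",
         paste(unique(baselines$patient_id[duplicated(baselines$patient_id)]),
               collapse = ", "), call. = FALSE)
  if (nrow(baselines) == 0L) stop("empty cohort", call. = FALSE)

  bad_age <- baselines$age_years <= 18 | baselines$age_years >= 110 |
    is.na(baselines$age_years)
  if (any(bad_age))
    stop("age_years outside (18, 110) for patient(s): ",
         paste(baselines$patient_id[bad_age], collapse = ", "), call. = FALSE)
  check_indicator(baselines$female, "female (baseline)")

  for (tab in list(list(visits, "visits"), list(outcomes, "outcomes"))) {
    unknown <- setdiff(unique(tab[[1]]$patient_id), baselines$patient_id)
    if (length(unknown))
      stop(sprintf("unknown patient_id in %s table: %s", tab[[2]],
                   paste(unknown, collapse = ", ")), call. = FALSE)
  }

  if (is.null(outcomes$entry_time_years)) outcomes$entry_time_years <- 0
  outcomes$entry_time_years[is.na(outcomes$entry_time_years)] <- 0
  check_indicator(outcomes$event, "event (outcomes)")
  if (anyDuplicated(outcomes$patient_id))
    stop("more than one outcome record for patient(s): ",
         paste(unique(outcomes$patient_id[duplicated(outcomes$patient_id)]),
               collapse = ", "), call. = FALSE)
  no_outcome <- setdiff(baselines$patient_id, outcomes$patient_id)
  if (length(no_outcome))
    stop("no outcome record for patient(s): ",
         paste(no_outcome, collapse = ", "), call. = FALSE)
  if (any(outcomes$event_time_years <= outcomes$entry_time_years))
    stop("event_time_years must exceed entry_time_years; offending patient(s): ",
         paste(outcomes$patient_id[outcomes$event_time_years <=
                                     outcomes$entry_time_years],
               collapse = ", "), call. = FALSE)

  for (m in MARKERS) visits[[m]] <- normalize_marker(visits[[m]], m)
  visits <- visits[order(visits$patient_id, visits$time_years), , drop = FALSE]
  rownames(visits) <- NULL

  ev <- stats::setNames(outcomes$event_time_years, outcomes$patient_id)
  sp <- split(seq_len(nrow(visits)), visits$patient_id)
  for (pid in baselines$patient_id) {
    idx <- sp[[pid]]
    if (is.null(idx))
      stop("patient ", pid, " has no visits", call. = FALSE)
    tt <- visits$time_years[idx]
    if (any(is.na(tt)) || any(tt < 0))
      stop("invalid visit time for patient ", pid, call. = FALSE)
    if (tt[1] != 0)
      stop("patient ", pid, " has no index visit at time 0", call. = FALSE)
    if (any(duplicated(tt)))
      stop("duplicate visit time for patient ", pid, " at t = ",
           paste(tt[duplicated(tt)], collapse = ", "), call. = FALSE)
    late <- tt > ev[pid]
    if (any(late))
      stop("visit after event/censoring time for patient ", pid, " at t = ",
           paste(tt[late], collapse = ", "), call. = FALSE)
    # carry forward time-varying covariates; required at index
    for (cv in c("esophagitis", "long_segment")) {
      v <- visits[[cv]][idx]
      if (is.na(v[1]))
        stop(cv, " missing at index visit for patient ", pid, call. = FALSE)
      for (j in seq_along(v)[-1]) if (is.na(v[j])) v[j] <- v[j - 1]
      visits[[cv]][idx] <- v
    }
  }
  check_indicator(visits$esophagitis, "esophagitis (visits)")
  check_indicator(visits$long_segment, "long_segment (visits)")

  structure(list(baselines = baselines, visits = visits,
                 outcomes = outcomes, age_scaler = age_scaler),
            class = "be_cohort")
}

check_indicator <- function(x, what) {
  if (any(is.na(x)) || !all(x %in% c(0, 1)))
    stop(what, " must be coded 0/1 with no missing values", call. = FALSE)
  invisible(TRUE)
}

## Dichotomized marker dialects: histology {"NDBE","LGD","IND",""} with
## indefinite-for-dysplasia treated as missing; immunohistochemistry
## {"normal","aberrant",""}; numeric 0/1 accepted everywhere.
normalize_marker <- function(x, marker) {
  if (is.numeric(x)) {
    bad <- !is.na(x) & !(x %in% c(0, 1))
    if (any(bad)) stop("invalid numeric code for ", marker, ": ",
                       paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    return(as.numeric(x))
  }
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  codes <- c("0" = 0, "1" = 1,
             "NDBE" = 0, "LGD" = 1, "IND" = NA,
             "normal" = 0, "aberrant" = 1)
  known <- x %in% c(names(codes), "")
  if (!all(known))
    stop("invalid code for ", marker, ": ",
         paste(unique(x[!known]), collapse = ", "), call. = FALSE)
  out <- rep(NA_real_, length(x))
  has <- x != ""
  out[has] <- codes[x[has]]
  out
}

#' Read a cohort from three CSV tables
#'
#' Expects `baseline.csv` (patient_id, age_years, female), `visits.csv`
#' (patient_id, time_years, lgd, p53, sox2, esophagitis, long_segment) and
#' `outcomes.csv` (patient_id, event_time_years, event, optionally
#' entry_time_years); UTF-8 with a header row and "." as decimal
#' separator. Marker codes are normalized to 0/1/NA, with the histology
#' code `"IND"` (indefinite for dysplasia) mapped to missing.
#'
#' @param baseline_path,visits_path,outcomes_path CSV file paths.
#' @return A validated [new_cohort()] object, visits sorted by time.
#' @export
read_cohort <- function(baseline_path, visits_path, outcomes_path) {
  for (p in c(baseline_path, visits_path, outcomes_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE,
                                    colClasses = NA, encoding = "UTF-8")
  new_cohort(rd(baseline_path), rd(visits_path), rd(outcomes_path))
}

#' Write a cohort to three CSV tables
#'
#' Inverse of [read_cohort()]: writes `baseline.csv`, `visits.csv` and
#' `outcomes.csv` under `dir`. Round-tripping a validated cohort
#' reproduces it field for field.
#'
#' @param cohort A `be_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "be_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("baseline.csv", "visits.csv", "outcomes.csv"))
  utils::write.csv(cohort$baselines, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$visits, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$outcomes, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' @export
print.be_cohort <- function(x, ...) {
  cat(sprintf("Barrett's surveillance cohort: %d patients, %d visits, %d events\n",
              nrow(x$baselines), nrow(x$visits), sum(x$outcomes$event)))
  if (!is.null(x$age_scaler))
    cat(sprintf("  age standardized against mean %.2f, sd %.2f\n",
                x$age_scaler[1], x$age_scaler[2]))
  invisible(x)
}

#' Apply the study's eligibility filters
#'
#' Removes patients whose event or censoring falls inside the run-in
#' window (default six months, excluding prevalent neoplasia) and
#' patients with all three biomarkers missing at every visit (no usable
#' tissue). Retained patients get `entry_time_years` set to
#' `min_followup_years`, i.e. delayed entry / left truncation, so
#' person-time is follow-up minus the run-in.
#'
#' @param cohort A `be_cohort`.
#' @param min_followup_years Run-in length in years (default 0.5).
#' @return `list(cohort = filtered be_cohort, report = exclusion counts)`;
#'   the report has fields `n_eligible`, `n_excluded_short_followup`,
#'   `n_excluded_no_marker_data`, `n_included`.
#' @export
apply_eligibility_filters <- function(cohort, min_followup_years = 0.5) {
  stopifnot(inherits(cohort, "be_cohort"))
  oc <- cohort$outcomes
  n_eligible <- nrow(cohort$baselines)

  short <- oc$patient_id[oc$event_time_years < min_followup_years]
  vis <- cohort$visits
  has_marker <- tapply(
    rowSums(!is.na(vis[MARKERS])) > 0, vis$patient_id, any)
  no_marker <- names(has_marker)[!has_marker]
  no_marker <- setdiff(no_marker, short)  # count each exclusion once

  keep <- setdiff(cohort$baselines$patient_id, c(short, no_marker))
  if (length(keep) == 0L)
    stop("no patients remain after eligibility filtering", call. = FALSE)

  bl <- cohort$baselines[cohort$baselines$patient_id %in% keep, , drop = FALSE]
  vs <- vis[vis$patient_id %in% keep, , drop = FALSE]
  oc <- oc[oc$patient_id %in% keep, , drop = FALSE]
  oc$entry_time_years <- min_followup_years
  rownames(bl) <- rownames(vs) <- rownames(oc) <- NULL

  report <- list(n_eligible = n_eligible,
                 n_excluded_short_followup = length(short),
                 n_excluded_no_marker_data = length(no_marker),
                 n_included = length(keep))
  list(cohort = new_cohort(bl, vs, oc, age_scaler = cohort$age_scaler),
       report = report)
}

#' Freeze age standardization on a cohort
#'
#' Stores the included cohort's sample mean and sd (denominator n - 1) of
#' `age_years` in the cohort's `age_scaler`; all downstream model
#' matrices use `(age - mean)/sd`. The scaler is persisted with any
#' fitted model and reused verbatim when scoring new patients.
#'
#' @param cohort A `be_cohort` with at least two distinct ages.
#' @return The cohort with `age_scaler` set.
#' @export
standardize_age <- function(cohort) {
  stopifnot(inherits(cohort, "be_cohort"))
  ages <- cohort$baselines$age_years
  if (length(unique(ages)) < 2)
    stop("age standardization requires at least two distinct ages", call. = FALSE)
  s <- stats::sd(ages)
  if (s == 0) stop("zero age variance", call. = FALSE)
  cohort$age_scaler <- c(mean = mean(ages), sd = s)
  cohort
}

## Standardized age per patient under a frozen scaler.
scaled_age <- function(age_years, age_scaler) {
  if (is.null(age_scaler)) stop("age_scaler not set; call standardize_age()",
                                call. = FALSE)
  (age_years - age_scaler[[1]]) / age_scaler[[2]]
}

#' Crude incidence rate per 100 person-years
#'
#' Person-time is follow-up minus the run-in: the sum over patients of
#' `event_time_years - entry_time_years`. The 95% CI is the exact Poisson
#' interval for the event count.
#'
#' @param cohort A filtered `be_cohort` (entry times set).
#' @return `list(rate, lower, upper, events, person_years)`, rate per 100
#'   person-years.
#' @export
compute_incidence <- function(cohort) {
  stopifnot(inherits(cohort, "be_cohort"))
  oc <- cohort$outcomes
  py <- sum(oc$event_time_years - oc$entry_time_years)
  if (py <= 0) stop("zero person-years at risk", call. = FALSE)
  events <- sum(oc$event)
  ci <- stats::poisson.test(events, T = py)$conf.int
  list(rate = 100 * events / py,
       lower = 100 * ci[1], upper = 100 * ci[2],
       events = events, person_years = py)
}
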