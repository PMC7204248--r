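#' Construct a right-censored survival dataset
#'
#' The basic container used throughout the package: one row per patient,
#' with a follow-up time in months, an event indicator (1 = death,
#' 0 = censored) and, optionally, a calendar entry (enrolment) time used
#' by the administrative data-cut operator.
#'
#' @param time Numeric vector of strictly positive follow-up times, in
#'   months.
#' @param event Integer/numeric vector of event indicators, each 0 or 1.
#' @param entry Optional numeric vector of calendar enrolment times
#'   (months from study start), all non-negative. Either supplied for
#'   every patient or omitted entirely.
#' @param label Free-text label for the dataset (e.g. `"12mo"`).
#'
#' @return An object of class `survival_dataset`: a list with elements
#'   `records` (a data frame with columns `time`, `event` and optionally
#'   `entry`) and `label`.
#' @examples
#' ds <- survival_dataset(time = c(3, 5, 7, 9), event = c(1, 0, 1, 0))
#' ds
#' @export
survival_dataset <- function(time, event, entry = NULL, label = "") {
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) == 0L) {
    stop("a survival dataset must contain at least one record", call. = FALSE)
  }
  if (length(event) != length(time)) {
    stop("'time' and 'event' must have the same length", call. = FALSE)
  }
  bad_t <- which(!is.finite(time) | time <= 0)
  if (length(bad_t)) {
    stop(sprintf("non-positive or non-finite time in row %d", bad_t[1L]),
         call. = FALSE)
  }
  bad_e <- which(!(event %in% c(0, 1)))
  if (length(bad_e)) {
    stop(sprintf("event indicator outside {0,1} in row %d", bad_e[1L]),
         call. = FALSE)
  }
  records <- data.frame(time = time, event = event)
  if (!is.null(entry)) {
    entry <- as.numeric(entry)
    if (length(entry) != length(time)) {
      stop("'entry' must be supplied for every patient or not at all",
           call. = FALSE)
    }
    bad_a <- which(!is.finite(entry) | entry < 0)
    if (length(bad_a)) {
      stop(sprintf("negative or non-finite entry time in row %d", bad_a[1L]),
           call. = FALSE)
    }
    records$entry <- entry
  }
  structure(list(records = records, label = as.character(label)),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf("Survival dataset%s: n = %d, events = %d, max follow-up = %.3g months\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              nrow(r), sum(r$event), max(r$time)))
  invisible(x)
}

#' Number of patients in a survival dataset
#' @param ds A `survival_dataset`.
#' @return Integer count of records.
#' @export
n_patients <- function(ds) nrow(ds$records)

#' Number of observed events in a survival dataset
#' @param ds A `survival_dataset`.
#' @return Integer count of events.
#' @export
n_events <- function(ds) sum(ds$records$event)

#' Read a survival dataset from CSV
#'
#' Expects a comma-separated file with a header row. Column names are
#' configurable through `column_map`, so files using e.g. `os_months` /
#' `death` can be read without editing.
#'
#' @param path Path to the CSV file.
#' @param column_map Named character vector or list mapping the canonical
#'   names `time`, `event` and (optionally) `entry` to the column names
#'   used in the file. Defaults to identity.
#' @param label Dataset label, defaults to the file name.
#' @return A [survival_dataset()]. Row order of the file is preserved.
#' @export
read_dataset <- function(path,
                         column_map = c(time = "time", event = "event"),
                         label = basename(path)) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  column_map <- unlist(column_map)
  if (!all(c("time", "event") %in% names(column_map))) {
    stop("'column_map' must map at least 'time' and 'event'", call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(column_map), names(df))
  if (length(missing_cols)) {
    stop(sprintf("column(s) not found in %s: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  entry <- if ("entry" %in% names(column_map)) df[[column_map[["entry"]]]]
  survival_dataset(time = df[[column_map[["time"]]]],
                   event = df[[column_map[["event"]]]],
                   entry = entry, label = label)
}

#' Write a survival dataset to CSV
#' @param ds A `survival_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  utils::write.csv(ds$records, path, row.names = FALSE)
  invisible(path)
}

#' Specify an administrative data cut
#'
#' A data cut is a database lock at a fixed calendar time: all patients
#' without an event by the lock are administratively censored there. The
#' minimum follow-up of the resulting dataset is the lock time minus the
#' latest enrolment.
#'
#' @param lock_time Calendar lock time in months from study start.
#' @param label Free-text cut label (e.g. `"24mo"`).
#' @return An object of class `data_cut_spec`.
#' @export
data_cut_spec <- function(lock_time, label = sprintf("%gmo", lock_time)) {
  stopifnot(is.finite(lock_time), lock_time > 0)
  structure(list(lock_time = lock_time, label = as.character(label)),
            class = "data_cut_spec")
}

#' Apply an administrative data cut
#'
#' Takes a calendar-anchored dataset (each record has an `entry` time;
#' `time` is measured from entry, so the calendar observation time is
#' `entry + time`) and truncates it at a database lock. Records whose
#' observation ends before the lock are kept as-is; all others are
#' administratively censored at `lock_time - entry`.
#'
#' @param ds A `survival_dataset` whose records carry `entry` times.
#' @param cut A [data_cut_spec()].
#' @return A `survival_dataset` labelled with the cut's label. Entry
#'   times are retained so cuts compose.
#' @examples
#' ds <- survival_dataset(time = 8, event = 1, entry = 2)
#' apply_data_cut(ds, data_cut_spec(7))$records  # censored at 5 months
#' @export
apply_data_cut <- function(ds, cut) {
  stopifnot(inherits(ds, "survival_dataset"), inherits(cut, "data_cut_spec"))
  r <- ds$records
  if (is.null(r$entry)) {
    stop("apply_data_cut requires calendar entry times", call. = FALSE)
  }
  if (any(r$entry >= cut$lock_time)) {
    stop("database lock precedes the enrolment of some patients",
         call. = FALSE)
  }
  cal_end <- r$entry + r$time
  keep <- cal_end < cut$lock_time
  time <- ifelse(keep, r$time, cut$lock_time - r$entry)
  event <- ifelse(keep, r$event, 0)
  survival_dataset(time = time, event = event, entry = r$entry,
                   label = cut$label)
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit estimate of the survivor function. Tied
#' event times are grouped; censorings tied with an event time are
#' processed after the events at that time (the standard convention).
#'
#' @param ds A `survival_dataset`.
#' @return An object of class `step_survival_curve` with fields
#'   `event_times` (ascending distinct event times), `survival` (the
#'   estimate immediately after each event time), `at_risk` (risk-set
#'   size at each event time), `n_events` (deaths at each event time)
#'   and `max_follow_up`. With no events the curve is flat at 1.
#' @examples
#' ds <- survival_dataset(time = c(3, 5, 7, 9), event = c(1, 0, 1, 0))
#' km <- km_estimate(ds)
#' survival_at(km, 6)   # 0.75
#' rmst_km(km, 9)       # 6.75
#' @export
km_estimate <- function(ds) {
  stopifnot(inherits(ds, "survival_dataset"))
  r <- ds$records
  max_fu <- max(r$time)
  ev_times <- sort(unique(r$time[r$event == 1]))
  if (length(ev_times) == 0L) {
    return(structure(list(event_times = numeric(0), survival = numeric(0),
                          at_risk = integer(0), n_events = integer(0),
                          max_follow_up = max_fu, label = ds$label),
                     class = "step_survival_curve"))
  }
  # risk set at t: everyone with observation time >= t (censoring at an
  # event time counts as still at risk there)
  at_risk <- vapply(ev_times, function(t) sum(r$time >= t), numeric(1))
  d <- vapply(ev_times, function(t) sum(r$time == t & r$event == 1),
              numeric(1))
  surv <- cumprod(1 - d / at_risk)
  structure(list(event_times = ev_times, survival = surv,
                 at_risk = as.integer(at_risk), n_events = as.integer(d),
                 max_follow_up = max_fu, label = ds$label),
            class = "step_survival_curve")
}

#' @export
print.step_survival_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve%s: %d event times, max follow-up %.3g months\n",
              if (nzchar(x$label %||% "")) paste0(" [", x$label, "]") else "",
              length(x$event_times), x$max_follow_up))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function lookup. The curve is only defined
#' within the observed follow-up: queries beyond `max_follow_up` are an
#' error, because extrapolation is the job of the parametric models.
#'
#' @param curve A `step_survival_curve`.
#' @param t Time in months, `0 <= t <= max_follow_up`.
#' @return Survival probability at `t`.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "step_survival_curve"))
  vapply(t, function(ti) {
    if (!is.finite(ti) || ti < 0 || ti > curve$max_follow_up) {
      stop(sprintf("t = %g is outside the curve's support [0, %g]",
                   ti, curve$max_follow_up), call. = FALSE)
    }
    k <- sum(curve$event_times <= ti)
    if (k == 0L) 1 else curve$survival[k]
  }, numeric(1))
}

#' Restricted mean survival time from a Kaplan-Meier curve
#'
#' Exact area under the step function on `[0, tau]`.
#'
#' @param curve A `step_survival_curve`.
#' @param tau Horizon in months, `tau <= max_follow_up`.
#' @return RMST in months.
#' @export
rmst_km <- function(curve, tau) {
  stopifnot(inherits(curve, "step_survival_curve"))
  if (!is.finite(tau) || tau < 0 || tau > curve$max_follow_up) {
    stop(sprintf("tau = %g is outside the curve's support [0, %g]",
                 tau, curve$max_follow_up), call. = FALSE)
  }
  if (tau == 0) return(0)
  ts <- curve$event_times[curve$event_times < tau]
  ss <- curve$survival[seq_along(ts)]
  # step heights on [0, tau]: survival is 1 before the first event
  knots <- c(0, ts, tau)
  heights <- c(1, ss)
  sum(heights * diff(knots))
}

#' Export a Kaplan-Meier curve as a data frame
#' @param curve A `step_survival_curve`.
#' @return Data frame with columns `time`, `survival`, `at_risk`.
#' @export
km_as_data_frame <- function(curve) {
  data.frame(time = curve$event_times, survival = curve$survival,
             at_risk = curve$at_risk)
}
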