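#' I-FSIGTT dosing and sampling protocol
#'
#' Describes the insulin-modified frequently sampled intravenous glucose
#' tolerance test: a dextrose bolus at time 0, an exogenous insulin bolus
#' 20 minutes later, and a fixed blood-sampling schedule from -60 to 180
#' minutes. The protocol object drives series validation, the fit window,
#' and the event timing of the synthetic-cohort simulator.
#'
#' @param dextrose_dose Dextrose dose in mg per kg body mass.
#' @param insulin_dose Insulin dose in IU per kg body mass.
#' @param dextrose_time Time of the dextrose bolus (minutes); defines t = 0.
#' @param insulin_time Time of the insulin bolus, minutes after dextrose.
#' @param sample_times Scheduled sampling times in minutes relative to the
#'   dextrose bolus. Must be strictly increasing and contain exactly two
#'   pre-dextrose samples (times <= 0).
#'
#' @return An object of class `ifsigtt_protocol`.
#' @examples
#' ifsigtt_protocol()
#' @export
ifsigtt_protocol <- function(dextrose_dose = 300,
                             insulin_dose = 0.02,
                             dextrose_time = 0,
                             insulin_time = 20,
                             sample_times = c(-60, 0, 2, 5, 7, 10, 15, 19,
                                              22, 25, 30, 35, 40, 50, 60,
                                              75, 90, 120, 150, 180)) {
  stopifnot(is.numeric(sample_times), length(sample_times) >= 2)
  if (any(diff(sample_times) <= 0)) {
    stop("sample_times must be strictly increasing", call. = FALSE)
  }
  if (insulin_time <= dextrose_time) {
    stop("insulin_time must be after dextrose_time", call. = FALSE)
  }
  if (sum(sample_times <= 0) != 2) {
    stop("protocol requires exactly two pre-dextrose samples (times <= 0)",
         call. = FALSE)
  }
  structure(
    list(dextrose_dose = dextrose_dose,
         insulin_dose = insulin_dose,
         dextrose_time = dextrose_time,
         insulin_time = insulin_time,
         sample_times = as.numeric(sample_times)),
    class = "ifsigtt_protocol"
  )
}

#' @export
print.ifsigtt_protocol <- function(x, ...) {
  cat("I-FSIGTT protocol\n")
  cat(sprintf("  dextrose: %g mg/kg IV at t = %g min\n",
              x$dextrose_dose, x$dextrose_time))
  cat(sprintf("  insulin:  %g IU/kg IV at t = %g min\n",
              x$insulin_dose, x$insulin_time))
  cat(sprintf("  sampling: %d time points, %g to %g min\n",
              length(x$sample_times), min(x$sample_times),
              max(x$sample_times)))
  invisible(x)
}

#' Validate a subject series against the sampling protocol
#'
#' Report-only check: flags scheduled times with no sample, unscheduled
#' extra times, and scheduled samples whose glucose or insulin value is
#' missing. Never modifies the series.
#'
#' @param series A [subject_series()] object.
#' @param protocol An [ifsigtt_protocol()] object.
#'
#' @return A data frame with columns `issue` (one of `"missing_time"`,
#'   `"unscheduled_time"`, `"missing_value"`), `time_min` and `detail`;
#'   zero rows when the series matches the schedule exactly.
#' @export
validate_series <- function(series, protocol = ifsigtt_protocol()) {
  stopifnot(inherits(series, "subject_series"),
            inherits(protocol, "ifsigtt_protocol"))
  sched <- protocol$sample_times
  issues <- data.frame(issue = character(), time_min = numeric(),
                       detail = character(), stringsAsFactors = FALSE)
  add <- function(issue, time, detail) {
    rbind(issues, data.frame(issue = issue, time_min = time, detail = detail,
                             stringsAsFactors = FALSE))
  }
  for (t in sched[!(sched %in% series$times)]) {
    issues <- add("missing_time", t, "scheduled time not sampled")
  }
  for (t in series$times[!(series$times %in% sched)]) {
    issues <- add("unscheduled_time", t, "sample at unscheduled time")
  }
  on_sched <- series$times %in% sched
  for (i in which(on_sched & is.na(series$glucose))) {
    issues <- add("missing_value", series$times[i], "glucose missing")
  }
  for (i in which(on_sched & is.na(series$insulin))) {
    issues <- add("missing_value", series$times[i], "insulin missing")
  }
  issues[order(issues$time_min), , drop = FALSE]
}
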