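#' One subject's paired glucose/insulin time series
#'
#' The atomic input of the pipeline: one animal's glucose and insulin
#' measurements over the I-FSIGTT, with its group label and (optional)
#' age. Missing measurements are allowed and kept as `NA`; they are never
#' imputed.
#'
#' @param subject_id Character label, unique within a cohort.
#' @param group `"foal"` or `"horse"`.
#' @param times Sampling times in minutes relative to the dextrose bolus;
#'   strictly increasing.
#' @param glucose Blood glucose in mg/dL, one value per time (`NA` allowed;
#'   non-missing values must be positive).
#' @param insulin Serum insulin in uIU/mL, one value per time (`NA`
#'   allowed; non-missing values must be non-negative).
#' @param age Age (hours for foals, years for horses) or `NA`.
#'
#' @return An object of class `subject_series`.
#' @examples
#' s <- subject_series("f1", "foal", c(-60, 0, 2), c(160, 166, 320), c(8, 8.3, 70))
#' s
#' @export
subject_series <- function(subject_id, group, times, glucose, insulin,
                           age = NA_real_) {
  group <- match.arg(group, c("foal", "horse"))
  times <- as.numeric(times)
  glucose <- as.numeric(glucose)
  insulin <- as.numeric(insulin)
  if (length(times) == 0) stop("series has no samples", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (length(glucose) != length(times) || length(insulin) != length(times)) {
    stop("glucose and insulin must have one value per time", call. = FALSE)
  }
  if (any(glucose <= 0, na.rm = TRUE)) {
    stop("glucose values must be positive", call. = FALSE)
  }
  if (any(insulin < 0, na.rm = TRUE)) {
    stop("insulin values must be non-negative", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), group = group,
         age = as.numeric(age), times = times, glucose = glucose,
         insulin = insulin),
    class = "subject_series"
  )
}

#' @export
print.subject_series <- function(x, ...) {
  cat(sprintf("<subject_series> %s (%s), %d samples, t in [%g, %g] min\n",
              x$subject_id, x$group, length(x$times), min(x$times),
              max(x$times)))
  n_na <- sum(is.na(x$glucose)) + sum(is.na(x$insulin))
  if (n_na > 0) cat(sprintf("  %d missing measurement(s)\n", n_na))
  invisible(x)
}

#' @export
as.data.frame.subject_series <- function(x, ...) {
  data.frame(subject_id = x$subject_id, group = x$group,
             age_hours = x$age, time_min = x$times,
             glucose_mg_dl = x$glucose, insulin_uIU_ml = x$insulin,
             stringsAsFactors = FALSE)
}

#' A cohort of subject series under one protocol
#'
#' @param subjects List of [subject_series()] objects with unique ids.
#' @param protocol The shared [ifsigtt_protocol()].
#'
#' @return An object of class `ifsigtt_cohort`.
#' @export
ifsigtt_cohort <- function(subjects, protocol = ifsigtt_protocol()) {
  stopifnot(is.list(subjects), inherits(protocol, "ifsigtt_protocol"))
  for (s in subjects) {
    if (!inherits(s, "subject_series")) {
      stop("all subjects must be subject_series objects", call. = FALSE)
    }
  }
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate subject_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(subjects = subjects, protocol = protocol),
            class = "ifsigtt_cohort")
}

#' @export
print.ifsigtt_cohort <- function(x, ...) {
  groups <- vapply(x$subjects, function(s) s$group, character(1))
  cat(sprintf("<ifsigtt_cohort> %d subjects (%d foal, %d horse)\n",
              length(x$subjects), sum(groups == "foal"),
              sum(groups == "horse")))
  invisible(x)
}

#' @export
length.ifsigtt_cohort <- function(x) length(x$subjects)

#' @export
as.data.frame.ifsigtt_cohort <- function(x, ...) {
  do.call(rbind, lapply(x$subjects, as.data.frame))
}

cohort_groups <- function(cohort) {
  vapply(cohort$subjects, function(s) s$group, character(1))
}

cohort_ids <- function(cohort) {
  vapply(cohort$subjects, function(s) s$subject_id, character(1))
}

#' Read a cohort from the tidy long CSV schema
#'
#' Expects columns `subject_id, group, time_min, glucose_mg_dl,
#' insulin_uIU_ml` (plus optional `age_hours`), one row per subject and
#' time. Rows are sorted by time within subject (stable sort); subjects
#' keep their order of first appearance. Empty measurement cells become
#' `NA` and are listed in the parse report attached as attribute
#' `"parse_report"`.
#'
#' @param path Path to a CSV file.
#' @param protocol The [ifsigtt_protocol()] the cohort was collected under.
#'
#' @return An [ifsigtt_cohort()]; `attr(, "parse_report")` is a data frame
#'   listing missing cells (subject, time, variable).
#' @export
read_cohort_csv <- function(path, protocol = ifsigtt_protocol()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop("schema error: cannot parse CSV (",
                             conditionMessage(e), ")", call. = FALSE)
  )
  required <- c("subject_id", "group", "time_min", "glucose_mg_dl",
                "insulin_uIU_ml")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("schema error: no data rows", call. = FALSE)

  num <- function(col, allow_na) {
    raw <- trimws(df[[col]])
    out <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(out))
    if (length(bad) > 0) {
      stop(sprintf("parse error: non-numeric %s in row %d (%s)",
                   col, bad[1] + 1L, raw[bad[1]]), call. = FALSE)
    }
    if (!allow_na && anyNA(out)) {
      stop(sprintf("parse error: empty %s in row %d", col,
                   which(is.na(out))[1] + 1L), call. = FALSE)
    }
    out
  }
  df$time_min <- num("time_min", allow_na = FALSE)
  df$glucose_mg_dl <- num("glucose_mg_dl", allow_na = TRUE)
  df$insulin_uIU_ml <- num("insulin_uIU_ml", allow_na = TRUE)
  age <- if ("age_hours" %in% names(df)) num("age_hours", TRUE) else
    rep(NA_real_, nrow(df))

  key <- paste(df$subject_id, df$time_min, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("integrity error: duplicate (subject, time) = (%s, %g)",
                 d$subject_id, d$time_min), call. = FALSE)
  }

  ids <- unique(df$subject_id)
  report <- data.frame(subject_id = character(), time_min = numeric(),
                       variable = character(), stringsAsFactors = FALSE)
  subjects <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- df[df$subject_id == ids[i], , drop = FALSE]
    ord <- order(rows$time_min)            # order() is a stable sort
    rows <- rows[ord, , drop = FALSE]
    for (v in c("glucose_mg_dl", "insulin_uIU_ml")) {
      miss <- which(is.na(rows[[v]]))
      if (length(miss) > 0) {
        report <- rbind(report, data.frame(
          subject_id = ids[i], time_min = rows$time_min[miss],
          variable = v, stringsAsFactors = FALSE))
      }
    }
    subjects[[i]] <- subject_series(
      subject_id = ids[i], group = rows$group[1], times = rows$time_min,
      glucose = rows$glucose_mg_dl, insulin = rows$insulin_uIU_ml,
      age = age[df$subject_id == ids[i]][ord][1])
  }
  out <- ifsigtt_cohort(subjects, protocol)
  attr(out, "parse_report") <- report
  out
}

#' Write a cohort to the tidy long CSV schema
#'
#' Inverse of [read_cohort_csv()]: values round-trip at full double
#' precision.
#'
#' @param cohort An [ifsigtt_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "ifsigtt_cohort"))
  df <- as.data.frame(cohort)
  for (v in c("time_min", "glucose_mg_dl", "insulin_uIU_ml", "age_hours")) {
    df[[v]] <- vapply(df[[v]], function(x)
      if (is.na(x)) "" else format(x, digits = 17), character(1))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Apply the basal-insulin enrollment filter
#'
#' Subjects whose time-0 (fasting baseline) insulin exceeds 20 uIU/mL are
#' excluded from the cohort, mirroring the enrollment criterion of the
#' study design. The inequality is strict: a subject at exactly the
#' threshold is retained.
#'
#' @param cohort An [ifsigtt_cohort()].
#' @param threshold Exclusion threshold in uIU/mL.
#'
#' @return A list with elements `cohort` (the filtered cohort) and
#'   `excluded` (character vector of removed subject ids).
#' @export
apply_enrollment_filter <- function(cohort, threshold = 20) {
  stopifnot(inherits(cohort, "ifsigtt_cohort"))
  baseline <- vapply(cohort$subjects, function(s) {
    i <- which(s$times == 0)
    if (length(i) != 1 || is.na(s$insulin[i])) {
      stop("validation error: subject ", s$subject_id,
           " has no time-0 insulin value", call. = FALSE)
    }
    s$insulin[i]
  }, numeric(1))
  keep <- baseline <= threshold
  list(cohort = ifsigtt_cohort(cohort$subjects[keep], cohort$protocol),
       excluded = cohort_ids(cohort)[!keep])
}
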