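#' Trapezoidal area under the curve
#'
#' Composite trapezoid over the samples falling inside `[t_start, t_end]`;
#' no extrapolation outside the sampled range and no baseline subtraction
#' (total area). Missing values are dropped, which is equivalent to linear
#' interpolation across the gap.
#'
#' @param times Sampling times, strictly increasing (minutes).
#' @param values Concentrations at `times` (`NA` allowed).
#' @param t_start,t_end Integration window (minutes).
#' @return The area, in concentration x min.
#' @examples
#' auc_trapezoid(c(0, 10, 20), c(0, 10, 0), 0, 20)  # 100
#' @export
auc_trapezoid <- function(times, values, t_start = 0, t_end = 180) {
  stopifnot(length(times) == length(values))
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  keep <- times >= t_start & times <= t_end & !is.na(values)
  t <- times[keep]
  v <- values[keep]
  if (length(t) < 2) {
    stop("validation error: need >= 2 samples in the AUC window",
         call. = FALSE)
  }
  sum(diff(t) * (v[-1] + v[-length(v)]) / 2)
}

#' Post-insulin glucose nadir
#'
#' The minimum glucose observed after the insulin bolus (t > 20 min by
#' default) and the time at which it occurs; ties are broken by the
#' earliest time.
#'
#' @param series A [subject_series()].
#' @param insulin_time Time of the insulin bolus (minutes).
#' @return A list with `nadir_time` (minutes) and `glucose_nadir` (mg/dL).
#' @export
glucose_nadir <- function(series, insulin_time = 20) {
  stopifnot(inherits(series, "subject_series"))
  keep <- series$times > insulin_time & !is.na(series$glucose)
  if (!any(keep)) {
    stop("validation error: no post-insulin glucose samples",
         call. = FALSE)
  }
  t <- series$times[keep]
  g <- series$glucose[keep]
  i <- which.min(g)  # which.min returns the first (earliest) minimum
  list(nadir_time = t[i], glucose_nadir = g[i])
}

#' Per-subject response summary
#'
#' Bundles the time-0 baselines, total trapezoidal AUCs for glucose and
#' insulin over 0-180 minutes, and the post-insulin glucose nadir.
#'
#' @param series A [subject_series()].
#' @param t_start,t_end AUC window (minutes).
#' @param insulin_time Insulin bolus time for the nadir scan.
#' @return A one-row data frame of class `response_summary`.
#' @export
summarize_subject <- function(series, t_start = 0, t_end = 180,
                              insulin_time = 20) {
  stopifnot(inherits(series, "subject_series"))
  i0 <- which(series$times == 0)
  if (length(i0) != 1) {
    stop("validation error: subject ", series$subject_id,
         " lacks a time-0 sample", call. = FALSE)
  }
  nad <- glucose_nadir(series, insulin_time)
  out <- data.frame(
    subject_id = series$subject_id, group = series$group,
    baseline_glucose = series$glucose[i0],
    baseline_insulin = series$insulin[i0],
    auc_glucose = auc_trapezoid(series$times, series$glucose, t_start,
                                t_end),
    auc_insulin = auc_trapezoid(series$times, series$insulin, t_start,
                                t_end),
    glucose_nadir = nad$glucose_nadir, nadir_time = nad$nadir_time,
    stringsAsFactors = FALSE)
  class(out) <- c("response_summary", "data.frame")
  out
}
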