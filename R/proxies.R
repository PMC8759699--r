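#' Convert glucose from mg/dL to mmol/L
#'
#' Division by the molar mass of glucose expressed as mg/dL per mmol/L.
#'
#' @param glucose Glucose in mg/dL (>= 0).
#' @param factor mg/dL per mmol/L; 18.016 by default.
#' @return Glucose in mmol/L.
#' @export
mgdl_to_mmoll <- function(glucose, factor = 18.016) {
  if (any(glucose < 0)) stop("glucose must be >= 0", call. = FALSE)
  glucose / factor
}

#' Homeostasis model assessment of insulin resistance (HOMA-IR)
#'
#' `(glucose_mmol x insulin) / 22.5`, glucose converted to mmol/L.
#'
#' @param glucose Fasting glucose, mg/dL.
#' @param insulin Fasting insulin, uIU/mL.
#' @return HOMA-IR (mmol/L x uIU/mL).
#' @export
homa_ir <- function(glucose, insulin) {
  if (any(glucose < 0) || any(insulin < 0)) {
    stop("inputs must be >= 0", call. = FALSE)
  }
  mgdl_to_mmoll(glucose) * insulin / 22.5
}

#' Homeostasis model assessment of beta-cell function (HOMA-BC%)
#'
#' `20 x insulin / (glucose_mmol - 3.5)` with glucose in mmol/L (the
#' default), or the literal mg/dL rendering `20 x insulin / (glucose -
#' 63)`; 63 mg/dL is 3.5 mmol/L, so the two variants differ only by the
#' conversion factor in the denominator.
#'
#' @param glucose Fasting glucose, mg/dL; must exceed 63.
#' @param insulin Fasting insulin, uIU/mL.
#' @param variant `"mmol"` (default) or `"mgdl"`.
#' @return HOMA-BC in percent.
#' @export
homa_bc_pct <- function(glucose, insulin, variant = c("mmol", "mgdl")) {
  variant <- match.arg(variant)
  if (any(glucose <= 63)) {
    stop("domain error: HOMA-BC% requires glucose > 63 mg/dL",
         call. = FALSE)
  }
  denom <- switch(variant,
                  mmol = mgdl_to_mmoll(glucose) - 3.5,
                  mgdl = glucose - 63)
  20 * insulin / denom
}

#' Quantitative insulin sensitivity check index (QUICKI)
#'
#' `1 / (log10(insulin) + log10(glucose))` with glucose in mg/dL (the
#' canonical form of the index).
#'
#' @param glucose Fasting glucose, mg/dL (> 0).
#' @param insulin Fasting insulin, uIU/mL (> 0).
#' @return QUICKI (dimensionless).
#' @export
quicki <- function(glucose, insulin) {
  if (any(glucose <= 0) || any(insulin <= 0)) {
    stop("domain error: QUICKI requires positive inputs", call. = FALSE)
  }
  s <- log10(insulin) + log10(glucose)
  if (any(s == 0)) stop("domain error: log sum is zero", call. = FALSE)
  1 / s
}

#' Reciprocal square root of insulin (RISQI)
#'
#' @param insulin Fasting insulin, uIU/mL (> 0).
#' @return RISQI, (uIU/mL)^(-1/2).
#' @export
risqi <- function(insulin) {
  if (any(insulin <= 0)) {
    stop("domain error: RISQI requires insulin > 0", call. = FALSE)
  }
  insulin^(-0.5)
}

#' Modified insulin-to-glucose ratio (MIRG)
#'
#' `(800 - 0.3 (insulin - 50)^2) / (glucose - 30)` with glucose in mg/dL
#' (the canonical form; the printed constants 800, 50 and 30 are on the
#' mg/dL scale).
#'
#' @param glucose Fasting glucose, mg/dL; must exceed 30.
#' @param insulin Fasting insulin, uIU/mL.
#' @return MIRG, (uIU/mL)^2 x dL/mg.
#' @export
mirg <- function(glucose, insulin) {
  if (any(glucose <= 30)) {
    stop("domain error: MIRG requires glucose > 30 mg/dL", call. = FALSE)
  }
  (800 - 0.3 * (insulin - 50)^2) / (glucose - 30)
}

#' Fasting proxy panel for one subject
#'
#' Computes the five fasting surrogate indices (HOMA-IR, HOMA-BC%,
#' QUICKI, RISQI, MIRG) from the time-0 glucose/insulin pair — the
#' fasting baseline draw, distinct from the -60/0 mean used as the
#' minimal-model basal anchor.
#'
#' @param series A [subject_series()] with non-missing time-0 glucose and
#'   insulin.
#' @param homa_bc_variant Passed to [homa_bc_pct()].
#' @return A one-row data frame of class `proxy_panel` with columns
#'   `subject_id`, `group`, `baseline_glucose`, `baseline_insulin`,
#'   `homa_ir`, `homa_bc_pct`, `quicki`, `risqi`, `mirg`.
#' @export
proxy_panel <- function(series, homa_bc_variant = "mmol") {
  stopifnot(inherits(series, "subject_series"))
  i0 <- which(series$times == 0)
  if (length(i0) != 1 || is.na(series$glucose[i0]) ||
      is.na(series$insulin[i0])) {
    stop("validation error: subject ", series$subject_id,
         " lacks a complete time-0 glucose/insulin pair", call. = FALSE)
  }
  g <- series$glucose[i0]
  i <- series$insulin[i0]
  wrap <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("proxy '%s' failed for subject %s: %s", name,
                   series$subject_id, conditionMessage(e)), call. = FALSE)
    })
  }
  out <- data.frame(
    subject_id = series$subject_id, group = series$group,
    baseline_glucose = g, baseline_insulin = i,
    homa_ir = wrap("homa_ir", homa_ir(g, i)),
    homa_bc_pct = wrap("homa_bc_pct",
                       homa_bc_pct(g, i, variant = homa_bc_variant)),
    quicki = wrap("quicki", quicki(g, i)),
    risqi = wrap("risqi", risqi(i)),
    mirg = wrap("mirg", mirg(g, i)),
    stringsAsFactors = FALSE)
  class(out) <- c("proxy_panel", "data.frame")
  out
}
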