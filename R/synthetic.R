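# RNG hygiene: run expr with a local seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic-cohort presets
#'
#' Parameter centres for the two response phenotypes the simulator
#' emulates. The foal-like preset has high basal glucose (166 mg/dL),
#' high insulin sensitivity (18.3 on the reporting scale) and a modest,
#' fast-decaying insulin excursion, producing the steep post-dextrose
#' spike, deep post-insulin nadir and rebound to baseline by 180 min seen
#' in neonates. The horse-like preset has lower basal glucose (104
#' mg/dL), twenty-fold lower insulin sensitivity (0.9) and a larger,
#' slowly decaying insulin excursion, so glucose stays elevated for most
#' of the test. Basal values, SI and Sg centres are anchored to the
#' group medians of the study population; the insulin-curve shape
#' parameters reproduce the first-phase (AIRg ~605 vs ~370 uIU/mL x min)
#' and exogenous-bolus features of the group insulin profiles.
#'
#' Insulin is generated parametrically as
#' `I(t) = Ib + A1 t exp(-k1 t) + A2 exp(-k2 (t - 20)) [t >= 20]`
#' (endogenous first phase plus the exogenous bolus at 20 min); glucose
#' follows by integrating the minimal model.
#'
#' @param label `"foal_like"` or `"horse_like"`.
#' @return A list of class `cohort_preset`: centres `Gb_center`,
#'   `Ib_center`, `SI_center` (reporting scale), `Sg_center`, `p2_center`,
#'   insulin-curve parameters `A1, k1, A2, k2`, the glucose distribution
#'   volume `vd_dl_per_kg`, and the noise levels `between_subject_cv`,
#'   `measurement_cv` (glucose), `measurement_cv_insulin`.
#' @export
cohort_preset <- function(label = c("foal_like", "horse_like")) {
  label <- match.arg(label)
  base <- list(label = label, between_subject_cv = 0.25,
               measurement_cv = 0.03, measurement_cv_insulin = 0.08,
               si_scale = 1e4)
  spec <- switch(label,
    foal_like = list(Gb_center = 166, Ib_center = 8.3, SI_center = 18.3,
                     Sg_center = 0.02, p2_center = 0.06,
                     A1 = 173, k1 = 0.5, A2 = 60, k2 = 0.18,
                     vd_dl_per_kg = 1.6),
    horse_like = list(Gb_center = 104, Ib_center = 8.0, SI_center = 0.9,
                      Sg_center = 0.010, p2_center = 0.015,
                      A1 = 106, k1 = 0.5, A2 = 200, k2 = 0.03,
                      vd_dl_per_kg = 1.35))
  structure(c(base, spec), class = "cohort_preset")
}

#' @export
print.cohort_preset <- function(x, ...) {
  cat(sprintf("<cohort_preset> %s: Gb %g mg/dL, Ib %g uIU/mL, SI %g, Sg %g\n",
              x$label, x$Gb_center, x$Ib_center, x$SI_center, x$Sg_center))
  invisible(x)
}

# Parametric insulin curve for a drawn subject (uIU/mL).
insulin_curve <- function(t, Ib, A1, k1, A2, k2, insulin_time = 20) {
  Ib + A1 * pmax(t, 0) * exp(-k1 * pmax(t, 0)) +
    ifelse(t >= insulin_time,
           A2 * exp(-k2 * (t - insulin_time)), 0)
}

#' Generate one synthetic I-FSIGTT subject
#'
#' Draws subject-level parameters log-normally around the preset centres
#' (coefficient of variation `between_subject_cv`; curve time constants
#' k1, k2 and the distribution volume are held fixed), builds the
#' parametric insulin curve, integrates the minimal model for glucose
#' with `G0 = Gb + dextrose_dose / vd`, samples both analytes at the
#' protocol times (pre-dextrose samples return basal values), applies
#' multiplicative Gaussian measurement noise, and clips glucose at >= 20
#' mg/dL and insulin at >= 0.5 uIU/mL. Identical `(preset, seed)` always
#' yields an identical series; the caller's RNG stream is untouched.
#'
#' @param preset A [cohort_preset()].
#' @param seed Integer seed for this subject's stream.
#' @param protocol The [ifsigtt_protocol()] defining events and sampling.
#' @param subject_id,age Metadata for the resulting series.
#' @return A [subject_series()]; the generating parameters are attached
#'   as attribute `"truth"` (a list with the drawn `minmod_params` and
#'   insulin-curve values).
#' @export
generate_subject <- function(preset, seed,
                             protocol = ifsigtt_protocol(),
                             subject_id = sprintf("%s_%d", preset$label,
                                                  seed),
                             age = NA_real_) {
  stopifnot(inherits(preset, "cohort_preset"))
  with_seed(seed, {
    cv <- preset$between_subject_cv
    sdlog <- sqrt(log(1 + cv^2))
    draw <- function(center) center * exp(stats::rnorm(1, 0, sdlog))
    Gb <- draw(preset$Gb_center)
    Ib <- draw(preset$Ib_center)
    SI <- draw(preset$SI_center) / preset$si_scale   # internal scale
    Sg <- draw(preset$Sg_center)
    p2 <- draw(preset$p2_center)
    A1 <- draw(preset$A1)
    A2 <- draw(preset$A2)
    G0 <- Gb + protocol$dextrose_dose / preset$vd_dl_per_kg
    params <- minmod_params(Sg, p2, SI * p2, G0, Gb, Ib)

    times <- protocol$sample_times
    post <- times > 0
    insulin_true <- ifelse(post,
                           insulin_curve(times, Ib, A1, preset$k1, A2,
                                         preset$k2, protocol$insulin_time),
                           Ib)
    insulin <- pmax(0.5, insulin_true *
                      (1 + stats::rnorm(length(times), 0,
                                        preset$measurement_cv_insulin)))

    # The ground-truth forcing is the piecewise-linear interpolant of the
    # sampled (measured) insulin -- the same convention the fitting stage
    # uses -- so noise-free subjects are exactly recoverable and tests
    # isolate estimation error from forcing model error.
    ft <- times[times >= 0]
    fy <- insulin[times >= 0]
    forcing <- structure(
      function(t) pmax(0, stats::approx(ft, fy, xout = t, rule = 2)$y),
      times = ft, values = fy, class = "insulin_forcing")

    glucose_true <- numeric(length(times))
    glucose_true[!post] <- Gb
    glucose_true[post] <- minmod_simulate(params, forcing, times[post])
    glucose <- pmax(20, glucose_true *
                      (1 + stats::rnorm(length(times), 0,
                                        preset$measurement_cv)))
    out <- subject_series(subject_id,
                          if (preset$label == "foal_like") "foal" else
                            "horse",
                          times, glucose, insulin, age)
    attr(out, "truth") <- list(params = params, A1 = A1, A2 = A2,
                               k1 = preset$k1, k2 = preset$k2)
    out
  })
}

#' Generate a synthetic two-group cohort
#'
#' Default sizes (12 foals, 8 horses) mirror the study population.
#' Per-subject seeds are drawn from the master seed so each subject has
#' an independent, reproducible stream; foal ages (hours, 24-60) and
#' horse ages (years, 3-14) are drawn uniformly.
#'
#' @param n_foal,n_horse Group sizes (>= 0).
#' @param seed Master seed.
#' @param protocol The shared [ifsigtt_protocol()].
#' @param foal_preset,horse_preset [cohort_preset()] objects.
#' @return An [ifsigtt_cohort()].
#' @examples
#' generate_cohort(2, 2, seed = 1)
#' @export
generate_cohort <- function(n_foal = 12, n_horse = 8, seed = 1,
                            protocol = ifsigtt_protocol(),
                            foal_preset = cohort_preset("foal_like"),
                            horse_preset = cohort_preset("horse_like")) {
  stopifnot(n_foal >= 0, n_horse >= 0)
  n <- n_foal + n_horse
  if (n == 0) return(ifsigtt_cohort(list(), protocol))
  with_seed(seed, {
    subject_seeds <- sample.int(.Machine$integer.max - 1, n)
    foal_ages <- stats::runif(n_foal, 24, 60)
    horse_ages <- stats::runif(n_horse, 3, 14)
  })
  subjects <- vector("list", n)
  for (i in seq_len(n_foal)) {
    subjects[[i]] <- generate_subject(
      foal_preset, subject_seeds[i], protocol,
      subject_id = sprintf("foal_%02d", i), age = foal_ages[i])
  }
  for (j in seq_len(n_horse)) {
    subjects[[n_foal + j]] <- generate_subject(
      horse_preset, subject_seeds[n_foal + j], protocol,
      subject_id = sprintf("horse_%02d", j), age = horse_ages[j])
  }
  ifsigtt_cohort(subjects, protocol)
}
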