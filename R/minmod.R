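#' Basal glucose and insulin
#'
#' Basal concentrations anchor the minimal model: both pre-dextrose
#' samples (-60 and 0 minutes) are baseline draws, so the basal values are
#' the mean of whatever pre-dextrose measurements are available.
#'
#' @param series A [subject_series()].
#' @return A list with `Gb` (mg/dL) and `Ib` (uIU/mL).
#' @examples
#' s <- subject_series("f1", "foal", c(-60, 0, 2), c(160, 166, 320), c(8, 8, 70))
#' basal_values(s)  # Gb = 163, Ib = 8
#' @export
basal_values <- function(series) {
  stopifnot(inherits(series, "subject_series"))
  pre <- series$times <= 0
  g <- series$glucose[pre]
  i <- series$insulin[pre]
  if (!any(pre) || (all(is.na(g)) && all(is.na(i)))) {
    stop("validation error: no pre-dextrose samples", call. = FALSE)
  }
  list(Gb = mean(g, na.rm = TRUE), Ib = mean(i, na.rm = TRUE))
}

#' Insulin forcing function
#'
#' The minimal model treats measured insulin as a known input. This builds
#' a piecewise-linear interpolant through the post-dextrose (t >= 0)
#' insulin samples, extended as a constant beyond the last sample and
#' clipped at zero.
#'
#' @param series A [subject_series()] with at least two non-missing
#'   insulin samples at t >= 0.
#' @return A function `t -> I(t)` (uIU/mL) of class `insulin_forcing`,
#'   carrying its knots as attributes `"times"` and `"values"`.
#' @export
insulin_forcing <- function(series) {
  stopifnot(inherits(series, "subject_series"))
  keep <- series$times >= 0 & !is.na(series$insulin)
  ft <- series$times[keep]
  fy <- series$insulin[keep]
  if (length(ft) < 2) {
    stop("validation error: need >= 2 insulin samples at t >= 0",
         call. = FALSE)
  }
  f <- function(t) {
    pmax(0, stats::approx(ft, fy, xout = t, rule = 2)$y)
  }
  structure(f, times = ft, values = fy, class = "insulin_forcing")
}

#' Minimal model parameters
#'
#' Parameters of Bergman's glucose minimal model with a remote insulin
#' compartment X(t):
#' \deqn{dG/dt = -(Sg + X) G + Sg Gb, \quad dX/dt = -p2 X + p3 (I(t) - Ib)}
#' Insulin sensitivity is the derived quantity SI = p3/p2 (min^-1 per
#' uIU/mL internally); `si_scale` converts it to the reporting scale used
#' throughout (default 1e4).
#'
#' @param Sg Glucose effectiveness, min^-1 (>= 0).
#' @param p2 Remote-insulin decay rate, min^-1 (> 0).
#' @param p3 Remote-insulin gain, min^-2 per (uIU/mL) (>= 0).
#' @param G0 Fitted glucose at t = 0+ after mixing, mg/dL (> Gb).
#' @param Gb Basal glucose, mg/dL.
#' @param Ib Basal insulin, uIU/mL.
#' @return An object of class `minmod_params` with derived field `SI`.
#' @export
minmod_params <- function(Sg, p2, p3, G0, Gb, Ib) {
  if (Sg < 0) stop("Sg must be >= 0", call. = FALSE)
  if (p2 <= 0) stop("p2 must be > 0", call. = FALSE)
  if (p3 < 0) stop("p3 must be >= 0", call. = FALSE)
  if (G0 <= Gb) stop("G0 must exceed Gb", call. = FALSE)
  structure(list(Sg = Sg, p2 = p2, p3 = p3, G0 = G0, Gb = Gb, Ib = Ib,
                 SI = p3 / p2),
            class = "minmod_params")
}

#' @export
print.minmod_params <- function(x, ...) {
  cat("Minimal model parameters\n")
  cat(sprintf("  Sg = %.4g min^-1,  p2 = %.4g min^-1,  p3 = %.4g\n",
              x$Sg, x$p2, x$p3))
  cat(sprintf("  SI = p3/p2 = %.4g (x 1e4 = %.3g on reporting scale)\n",
              x$SI, x$SI * 1e4))
  cat(sprintf("  G0 = %.4g, Gb = %.4g mg/dL; Ib = %.4g uIU/mL\n",
              x$G0, x$Gb, x$Ib))
  invisible(x)
}

#' Simulate the glucose minimal model
#'
#' Integrates the minimal model from t = 0 with X(0) = 0, using a
#' fixed-step fourth-order Runge-Kutta scheme whose steps are aligned with
#' the forcing knots and the output grid (the right-hand side is smooth
#' inside every step). With the default `hmax` of 0.1 min the relative
#' integration error is far below 1e-8 for physiological rate constants.
#'
#' @param params A [minmod_params()] object.
#' @param insulin An [insulin_forcing()] object, or any function
#'   `t -> I(t)` (a plain function is sampled on a 0.1-min grid).
#' @param t_grid Increasing output times (minutes), starting at >= 0.
#' @param hmax Maximum integration step, minutes.
#' @return Numeric vector of glucose (mg/dL) on `t_grid`.
#' @export
minmod_simulate <- function(params, insulin, t_grid, hmax = 0.1) {
  stopifnot(inherits(params, "minmod_params"), is.numeric(t_grid),
            length(t_grid) >= 1)
  if (any(diff(t_grid) <= 0) || t_grid[1] < 0) {
    stop("t_grid must be increasing and start at >= 0", call. = FALSE)
  }
  if (inherits(insulin, "insulin_forcing")) {
    ft <- attr(insulin, "times")
    fy <- attr(insulin, "values")
  } else if (is.function(insulin)) {
    ft <- seq(0, max(t_grid), by = 0.1)
    fy <- insulin(ft)
  } else {
    stop("insulin must be a function or insulin_forcing", call. = FALSE)
  }
  g <- minmod_integrate_cpp(as.numeric(t_grid), params$Sg, params$p2,
                            params$p3, params$G0, params$Gb, params$Ib,
                            as.numeric(ft), as.numeric(fy), hmax)
  if (any(!is.finite(g))) {
    stop("numerical error: integrator produced non-finite glucose",
         call. = FALSE)
  }
  g
}

#' Acute insulin response to glucose (AIRg)
#'
#' First-phase insulin release: the trapezoidal integral of the insulin
#' increment above basal, truncated at zero, over the first 10 minutes
#' after the dextrose bolus.
#'
#' @param series A [subject_series()].
#' @param Ib Basal insulin (uIU/mL); defaults to [basal_values()].
#' @param window Integration window in minutes.
#' @return AIRg in uIU/mL x min.
#' @export
compute_airg <- function(series, Ib = basal_values(series)$Ib,
                         window = c(0, 10)) {
  stopifnot(inherits(series, "subject_series"))
  keep <- series$times >= window[1] & series$times <= window[2] &
    !is.na(series$insulin)
  t <- series$times[keep]
  v <- pmax(series$insulin[keep] - Ib, 0)
  if (length(t) < 2) {
    stop("validation error: need >= 2 insulin samples in the AIRg window",
         call. = FALSE)
  }
  sum(diff(t) * (v[-1] + v[-length(v)]) / 2)
}

#' Fit settings for the minimal model
#'
#' @param t_fit_start First time (minutes) included in the least-squares
#'   fit; the default 2 is the first post-dextrose sample, so no data are
#'   discarded for mixing artefacts (G0 is free and absorbs mixing).
#' @param t_fit_end Last time included in the fit.
#' @param n_starts Number of deterministic multi-start initialisations
#'   (a log-spaced grid over the parameter box).
#' @param bounds Named list of length-2 vectors giving box constraints for
#'   `Sg`, `p2`, `p3` and the G0 multiplier `g0_rel` (G0 in
#'   `g0_rel * Gb`).
#' @param si_scale Factor from internal SI = p3/p2 (min^-1 per uIU/mL) to
#'   the reporting scale.
#' @param airg_window AIRg integration window, minutes.
#' @param hmax Integration step bound used during fitting; coarser than
#'   the [minmod_simulate()] default because the residual surface is
#'   insensitive below ~1e-6 relative integration error.
#' @return A list of class `minmod_control`.
#' @export
minmod_control <- function(t_fit_start = 2, t_fit_end = 180, n_starts = 16,
                           bounds = list(Sg = c(1e-4, 0.15),
                                         p2 = c(1e-3, 1),
                                         p3 = c(0, 1e-2),
                                         g0_rel = c(1 + 1e-6, 5)),
                           si_scale = 1e4, airg_window = c(0, 10),
                           hmax = 0.5) {
  stopifnot(n_starts >= 1, t_fit_end > t_fit_start)
  structure(list(t_fit_start = t_fit_start, t_fit_end = t_fit_end,
                 n_starts = n_starts, bounds = bounds, si_scale = si_scale,
                 airg_window = airg_window, hmax = hmax),
            class = "minmod_control")
}

# Deterministic multi-start grid: log-spaced interior points of the box
# for (Sg, p2, p3) crossed with two G0 starts anchored at the observed
# post-dextrose maximum.
start_grid <- function(n_starts, bounds, Gb, g_max) {
  logpts <- function(b, k, floor_pos = 1e-7) {
    lo <- max(b[1], floor_pos)
    exp(seq(log(lo), log(b[2]), length.out = k + 2))[2:(k + 1)]
  }
  k <- max(2, ceiling(n_starts^(1 / 4)))
  g0_hi <- bounds$g0_rel[2] * Gb
  g0_starts <- pmin(pmax(c(g_max, 1.3 * g_max), Gb * 1.05), g0_hi)
  grid <- expand.grid(Sg = logpts(bounds$Sg, k),
                      p2 = logpts(bounds$p2, k),
                      p3 = logpts(bounds$p3, k),
                      G0 = g0_starts)
  grid[seq_len(min(n_starts, nrow(grid))), , drop = FALSE]
}

#' Fit the glucose minimal model to one I-FSIGTT series
#'
#' Estimates (Sg, p2, p3, G0) by unweighted nonlinear least squares on the
#' post-dextrose glucose samples, with measured insulin as the forcing
#' input and basal values fixed from the pre-dextrose samples. A
#' deterministic multi-start (log-spaced grid over the parameter box,
#' Levenberg-Marquardt refinement with box bounds) guards against local
#' minima; the best converged start is returned. Attaches the derived
#' quantities SI = p3/p2 (reporting scale), AIRg, and DI = SI x AIRg.
#'
#' @param series A [subject_series()] with at least 8 glucose samples in
#'   the fit window.
#' @param protocol The [ifsigtt_protocol()] (used for the insulin-bolus
#'   time in diagnostics; fitting itself only needs the series).
#' @param control A [minmod_control()] list of fit settings.
#'
#' @return An object of class `minmod_fit` with components `params`
#'   ([minmod_params()]), `SI` (reporting scale), `AIRg`, `DI`,
#'   `residual_sse`, `n_points_fit`, `converged`, `n_starts`, `at_bound`,
#'   `data` (times/observed/fitted in the fit window), `insulin` (the
#'   forcing), `starts` (per-start diagnostics) and `control`.
#' @seealso [minmod_simulate()], [compute_airg()], [disposition_index()]
#' @export
ifsigtt_fit <- function(series, protocol = ifsigtt_protocol(),
                        control = minmod_control()) {
  stopifnot(inherits(series, "subject_series"),
            inherits(control, "minmod_control"))
  bas <- basal_values(series)
  forcing <- insulin_forcing(series)
  keep <- series$times >= control$t_fit_start &
    series$times <= control$t_fit_end & !is.na(series$glucose)
  t_fit <- series$times[keep]
  g_obs <- series$glucose[keep]
  if (length(t_fit) < 8) {
    stop("validation error: need >= 8 post-dextrose glucose samples in ",
         "the fit window", call. = FALSE)
  }
  b <- control$bounds
  lower <- c(b$Sg[1], b$p2[1], b$p3[1], b$g0_rel[1] * bas$Gb)
  upper <- c(b$Sg[2], b$p2[2], b$p3[2], b$g0_rel[2] * bas$Gb)

  resid_fun <- function(par) {
    p <- minmod_params(par[1], par[2], par[3], par[4], bas$Gb, bas$Ib)
    minmod_simulate(p, forcing, t_fit, hmax = control$hmax) - g_obs
  }

  starts <- start_grid(control$n_starts, b, bas$Gb, max(g_obs))
  diag_rows <- vector("list", nrow(starts))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- pmin(pmax(as.numeric(starts[i, ]), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$info %in% 1:4
    sse <- if (is.null(fit)) NA_real_ else fit$deviance
    diag_rows[[i]] <- data.frame(start = i, Sg0 = par0[1], p20 = par0[2],
                                 p30 = par0[3], G00 = par0[4], sse = sse,
                                 converged = ok, info = if (is.null(fit))
                                   NA_integer_ else fit$info)
    if (ok && (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  diagnostics <- do.call(rbind, diag_rows)
  if (is.null(best)) {
    stop("fit error: no multi-start converged; see diagnostics",
         call. = FALSE)
  }
  par <- best$par
  tol_b <- 1e-8 * pmax(1, abs(upper))
  at_bound <- any(par - lower < tol_b & lower > 0) | any(upper - par < tol_b)
  if (at_bound) {
    warning("fitted parameter at a box bound for subject ",
            series$subject_id, call. = FALSE)
  }
  params <- minmod_params(par[1], par[2], par[3], par[4], bas$Gb, bas$Ib)
  SI <- params$SI * control$si_scale
  AIRg <- compute_airg(series, Ib = bas$Ib, window = control$airg_window)
  fitted_g <- minmod_simulate(params, forcing, t_fit, hmax = control$hmax)
  structure(
    list(subject_id = series$subject_id, group = series$group,
         params = params, SI = SI, AIRg = AIRg, DI = SI * AIRg,
         residual_sse = best$deviance, n_points_fit = length(t_fit),
         converged = TRUE, n_starts = nrow(starts), at_bound = at_bound,
         data = data.frame(time_min = t_fit, observed = g_obs,
                           fitted = fitted_g),
         insulin = forcing, starts = diagnostics, control = control),
    class = "minmod_fit")
}

#' Disposition index
#'
#' Beta-cell output normalised to insulin sensitivity: DI = SI x AIRg.
#'
#' @param fit A `minmod_fit` object.
#' @return DI (reporting scale of SI times uIU/mL x min).
#' @export
disposition_index <- function(fit) {
  stopifnot(inherits(fit, "minmod_fit"))
  fit$SI * fit$AIRg
}

#' @export
print.minmod_fit <- function(x, ...) {
  cat(sprintf("Minimal model fit: %s (%s)\n", x$subject_id, x$group))
  cat(sprintf("  SI = %.3g   Sg = %.3g min^-1   AIRg = %.4g   DI = %.4g\n",
              x$SI, x$params$Sg, x$AIRg, x$DI))
  cat(sprintf("  SSE = %.4g over %d points (%d starts%s)\n",
              x$residual_sse, x$n_points_fit, x$n_starts,
              if (x$at_bound) ", at bound" else ""))
  invisible(x)
}

#' @export
coef.minmod_fit <- function(object, ...) {
  with(object$params, c(Sg = Sg, p2 = p2, p3 = p3, G0 = G0))
}

#' @export
fitted.minmod_fit <- function(object, ...) object$data$fitted

#' @export
residuals.minmod_fit <- function(object, ...) {
  object$data$observed - object$data$fitted
}

#' @export
predict.minmod_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$data$fitted)
  minmod_simulate(object$params, object$insulin, times,
                  hmax = object$control$hmax)
}

#' @export
summary.minmod_fit <- function(object, ...) {
  out <- list(
    subject_id = object$subject_id, group = object$group,
    coefficients = coef(object),
    indices = c(SI = object$SI, Sg = object$params$Sg, AIRg = object$AIRg,
                DI = object$DI),
    basal = c(Gb = object$params$Gb, Ib = object$params$Ib),
    residual_sse = object$residual_sse,
    rmse = sqrt(object$residual_sse / object$n_points_fit),
    n_points_fit = object$n_points_fit,
    n_starts_converged = sum(object$starts$converged),
    at_bound = object$at_bound)
  class(out) <- "summary.minmod_fit"
  out
}

#' @export
print.summary.minmod_fit <- function(x, ...) {
  cat(sprintf("Minimal model fit summary: %s (%s)\n", x$subject_id,
              x$group))
  cat("Kinetic parameters:\n")
  print(signif(x$coefficients, 4))
  cat("Derived indices:\n")
  print(signif(x$indices, 4))
  cat(sprintf("Basal: Gb = %.4g mg/dL, Ib = %.4g uIU/mL\n",
              x$basal["Gb"], x$basal["Ib"]))
  cat(sprintf("RMSE %.3g mg/dL over %d points; %d/%s starts converged%s\n",
              x$rmse, x$n_points_fit, x$n_starts_converged,
              "all", if (x$at_bound) "; parameter at bound" else ""))
  invisible(x)
}

#' @export
plot.minmod_fit <- function(x, ...) {
  t_fine <- seq(0, max(x$data$time_min), by = 1)
  g_fine <- minmod_simulate(x$params, x$insulin, t_fine,
                            hmax = x$control$hmax)
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  plot(x$data$time_min, x$data$observed, xlab = "time (min)",
       ylab = "glucose (mg/dL)",
       main = sprintf("%s: minimal model fit", x$subject_id), ...)
  graphics::lines(t_fine, g_fine, col = "steelblue", lwd = 2)
  graphics::abline(h = x$params$Gb, lty = 3)
  ft <- attr(x$insulin, "times")
  plot(ft, attr(x$insulin, "values"), type = "b", xlab = "time (min)",
       ylab = "insulin (uIU/mL)", main = "insulin forcing")
  graphics::abline(h = x$params$Ib, lty = 3)
  invisible(x)
}

#' Simulate replicate glucose series from a fitted minimal model
#'
#' Draws `nsim` replicates of the fitted glucose trajectory with
#' multiplicative Gaussian measurement noise, useful for visual posterior
#' predictive style checks of the fit.
#'
#' @param object A `minmod_fit`.
#' @param nsim Number of replicates.
#' @param seed Optional RNG seed (restored on exit).
#' @param cv Multiplicative measurement coefficient of variation.
#' @param ... Unused.
#' @return A matrix with one column per replicate, rows matching the fit
#'   window times.
#' @export
simulate.minmod_fit <- function(object, nsim = 1, seed = NULL, cv = 0.03,
                                ...) {
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }
  g <- object$data$fitted
  out <- vapply(seq_len(nsim),
                function(i) g * (1 + stats::rnorm(length(g), 0, cv)),
                numeric(length(g)))
  rownames(out) <- object$data$time_min
  out
}
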