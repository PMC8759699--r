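test_that("basal values average the pre-dextrose samples", {
  s <- subject_series("f", "foal", c(-60, 0, 2), c(160, 166, 320),
                      c(8, 8, 70))
  b <- basal_values(s)
  expect_equal(b$Gb, 163)
  expect_equal(b$Ib, 8)

  s1 <- subject_series("h", "horse", c(0, 2), c(104, 280), c(6, 50))
  expect_equal(basal_values(s1)$Gb, 104)

  post_only <- subject_series("x", "foal", c(2, 5), c(300, 280), c(60, 40))
  expect_error(basal_values(post_only), "no pre-dextrose")
})

test_that("insulin forcing interpolates linearly and extrapolates flat", {
  s <- subject_series("f", "foal", c(0, 10), c(166, 230), c(8, 28))
  f <- insulin_forcing(s)
  expect_equal(f(5), 18)
  expect_equal(f(50), 28)         # constant beyond last sample

  s2 <- subject_series("f", "foal", c(0, 2, 5), c(166, 320, 280),
                       c(8, 40, 20))
  f2 <- insulin_forcing(s2)
  expect_equal(f2(3), 40 + (20 - 40) / 3, tolerance = 1e-12)

  one <- subject_series("f", "foal", c(-60, 0), c(166, 166), c(8, 8))
  expect_error(insulin_forcing(one), ">= 2 insulin samples")
})

test_that("simulation fixed point: basal forcing and G0 = Gb stays at Gb", {
  # G0 must exceed Gb by the type invariant; an epsilon above basal must
  # stay within integrator tolerance of Gb under basal forcing.
  Gb <- 120
  p <- minmod_params(Sg = 0.02, p2 = 0.05, p3 = 1e-4, G0 = Gb + 1e-9,
                     Gb = Gb, Ib = 8)
  flat <- structure(function(t) rep(8, length(t)),
                    times = c(0, 180), values = c(8, 8),
                    class = "insulin_forcing")
  g <- minmod_simulate(p, flat, c(0, 10, 60, 180))
  expect_equal(g, rep(Gb, 4), tolerance = 1e-8)
})

test_that("p3 = 0 reduces to mono-exponential glucose decay", {
  p <- minmod_params(Sg = 0.02, p2 = 0.05, p3 = 0, G0 = 300, Gb = 166,
                     Ib = 8)
  # any forcing: X stays 0 when p3 = 0
  s <- generate_subject(noise_free_preset("foal_like"), 7)
  f <- insulin_forcing(s)
  tt <- c(2, 5, 30, 60, 120, 180)
  g <- minmod_simulate(p, f, tt)
  closed <- 166 + (300 - 166) * exp(-0.02 * tt)
  expect_lt(max(abs(g - closed)) / 166, 1e-6)
  expect_equal(g[3], closed[3], tolerance = 1e-9)
})

test_that("integrator agrees with an independent stiff ODE solver", {
  skip_if_not_installed("deSolve")
  s <- generate_subject(noise_free_preset("foal_like"), 11)
  f <- insulin_forcing(s)
  p <- minmod_params(Sg = 0.02, p2 = 0.05, p3 = 18.3e-4 * 0.05, G0 = 300,
                     Gb = 166, Ib = 8)
  tt <- c(10, 30, 60, 120, 180)
  mine <- minmod_simulate(p, f, tt)
  rhs <- function(t, y, parms) {
    list(c(-(p$Sg + y[2]) * y[1] + p$Sg * p$Gb,
           -p$p2 * y[2] + p$p3 * (f(t) - p$Ib)))
  }
  ref <- deSolve::lsoda(c(G = p$G0, X = 0), c(0, tt), rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  expect_equal(mine, unname(ref[-1, "G"]), tolerance = 1e-5)
})

test_that("increasing p3 never raises simulated glucose", {
  s <- generate_subject(noise_free_preset("foal_like"), 3)
  f <- insulin_forcing(s)
  tt <- seq(1, 180, by = 1)
  p3s <- c(0, 1e-5, 5e-5, 1e-4, 5e-4)
  prev <- NULL
  for (p3 in p3s) {
    p <- minmod_params(0.02, 0.05, p3, 300, 166, 8)
    g <- minmod_simulate(p, f, tt)
    if (!is.null(prev)) expect_true(all(g <= prev + 1e-9))
    prev <- g
  }
})

test_that("AIRg is the truncated incremental trapezoid over 0-10 min", {
  flat <- subject_series("f", "foal", c(0, 2, 5, 7, 10), rep(100, 5),
                         rep(8, 5))
  expect_equal(compute_airg(flat, Ib = 8), 0)

  tri <- subject_series("f", "foal", c(0, 5, 10), rep(100, 3),
                        c(8, 108, 8))
  expect_equal(compute_airg(tri, Ib = 8), 500)

  # negative increments are truncated, not subtracted
  dip <- subject_series("f", "foal", c(0, 5, 10), rep(100, 3),
                        c(8, 2, 8))
  expect_equal(compute_airg(dip, Ib = 8), 0)

  sparse <- subject_series("f", "foal", c(0, 20), c(100, 100), c(8, 9))
  expect_error(compute_airg(sparse, Ib = 8), "AIRg window")
})

test_that("fit recovers generating parameters on noise-free subjects", {
  for (label in c("foal_like", "horse_like")) {
    s <- generate_subject(noise_free_preset(label), 5)
    truth <- attr(s, "truth")$params
    f <- ifsigtt_fit(s)
    expect_true(f$converged)
    rel <- abs(coef(f) - c(truth$Sg, truth$p2, truth$p3, truth$G0)) /
      c(truth$Sg, truth$p2, truth$p3, truth$G0)
    expect_lt(max(rel), 1e-3)
    expect_equal(f$params$SI, f$params$p3 / f$params$p2)   # SI identity
    expect_equal(f$DI, f$SI * f$AIRg)                      # DI identity
  }
})

test_that("multi-start selection is deterministic", {
  s <- generate_subject(cohort_preset("foal_like"), 21)
  f1 <- ifsigtt_fit(s)
  f2 <- ifsigtt_fit(s)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$residual_sse, f2$residual_sse)
})

test_that("fit refuses series with too few post-dextrose points", {
  s <- subject_series("f", "foal", c(-60, 0, 2, 5, 10, 30),
                      c(160, 166, 320, 300, 250, 180),
                      c(8, 8, 90, 60, 30, 10))
  expect_error(ifsigtt_fit(s), ">= 8 post-dextrose")
})

test_that("disposition index is the SI x AIRg product", {
  s <- generate_subject(noise_free_preset("foal_like"), 2)
  f <- ifsigtt_fit(s)
  expect_equal(disposition_index(f), f$SI * f$AIRg)
  f0 <- f
  f0$SI <- 0
  f0$DI <- 0
  expect_equal(disposition_index(f0), 0)
  f2 <- f
  f2$SI <- 2
  f2$AIRg <- 500
  expect_equal(disposition_index(f2), 1000)
})

test_that("fit methods expose the usual modelling surface", {
  s <- generate_subject(cohort_preset("foal_like"), 31)
  f <- ifsigtt_fit(s)
  expect_named(coef(f), c("Sg", "p2", "p3", "G0"))
  expect_length(residuals(f), f$n_points_fit)
  expect_equal(fitted(f) + residuals(f), f$data$observed)
  expect_equal(predict(f), fitted(f))
  g <- predict(f, times = c(30, 60))
  expect_length(g, 2)
  sm <- summary(f)
  expect_s3_class(sm, "summary.minmod_fit")
  expect_output(print(sm), "Derived indices")
  reps <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(reps), c(f$n_points_fit, 3))
})
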