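Package: ifsigtt
Title: Minimal Model Analysis of Insulin-Modified Frequently Sampled IV
    Glucose Tolerance Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the insulin-modified frequently sampled
    intravenous glucose tolerance test (I-FSIGTT) in equine cohorts.
    Fits Bergman's glucose minimal model with measured insulin as the
    forcing input to estimate insulin sensitivity (SI), glucose
    effectiveness (Sg), the acute insulin response to glucose (AIRg) and
    the disposition index (DI); computes the fasting proxy indices
    HOMA-IR, HOMA-BC%, QUICKI, RISQI and MIRG; summarises responses by
    trapezoidal areas under the curve and glucose nadir; and compares
    cohorts with the nonparametric and parametric tests used in the
    field (Mann-Whitney U, Friedman with Dunn's post hoc versus
    baseline, Spearman rank correlation, pooled-variance t). A
    synthetic-cohort generator emulating neonatal-foal-like and
    adult-horse-like responses makes the whole pipeline testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
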