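# ifsigtt

Minimal model analysis of the insulin-modified frequently sampled
intravenous glucose tolerance test (I-FSIGTT) for equine cohorts —
built for veterinary endocrinology work comparing insulin/glucose
dynamics between groups (e.g. neonatal foals vs adult horses), and for
anyone who needs a fully scripted, reproducible alternative to
point-and-click minimal-model software.

The test: a dextrose bolus (300 mg/kg IV) at t = 0, an insulin bolus
(0.02 IU/kg IV) at t = 20 min, blood sampled at 20 fixed times from
-60 to 180 min. The model: Bergman's glucose minimal model with a
remote insulin-action compartment,

    dG/dt = -(Sg + X) G + Sg Gb        G(0) = G0
    dX/dt = -p2 X + p3 (I(t) - Ib)     X(0) = 0

with measured insulin I(t) as the forcing input. Per subject the
package estimates glucose effectiveness **Sg**, insulin sensitivity
**SI = p3/p2**, the acute insulin response **AIRg** (incremental
insulin area, 0-10 min) and the disposition index **DI = SI x AIRg**,
plus the fasting proxy indices **HOMA-IR**, **HOMA-BC%**, **QUICKI**,
**RISQI** and **MIRG**, trapezoidal glucose/insulin **AUCs** and the
post-insulin glucose nadir. Cohorts are compared with Mann-Whitney U
(medians/IQR), pooled-variance t (AUC means/CIs), Friedman + Dunn's
versus baseline within groups, and Spearman correlation of foal age
with SI. A synthetic-cohort generator with foal-like and horse-like
presets makes the whole pipeline runnable and testable without animal
data.

## Worked example

Fit one synthetic foal-like subject:

```r
library(ifsigtt)
s <- generate_subject(cohort_preset("foal_like"), seed = 42)
f <- ifsigtt_fit(s)
summary(f)
#> Minimal model fit summary: foal_like_42 (foal)
#> Kinetic parameters:
#>        Sg        p2        p3        G0
#> 3.862e-02 3.364e-02 1.047e-04 4.258e+02
#> Derived indices:
#>        SI        Sg      AIRg        DI
#> 3.113e+01 3.862e-02 6.194e+02 1.928e+04
#> Basal: Gb = 228.1 mg/dL, Ib = 7.778 uIU/mL
#> RMSE 5.36 mg/dL over 18 points; 16/all starts converged
```

This subject drew a high basal glucose (Gb 228 mg/dL) and a high
insulin sensitivity (SI 31 on the reporting scale, i.e. 31 x 10^-4
min^-1 per uIU/mL) — a foal-typical phenotype; the RMSE of 5.4 mg/dL
is consistent with the generator's 3% glucometer noise. `coef()`,
`predict()`, `residuals()`, `plot()` and `simulate()` work as usual
for a fitted model object.

Full cohort analysis (12 foals vs 8 horses):

```r
report <- run_analysis(generate_cohort(12, 8, seed = 1))
report
#> I-FSIGTT analysis report
#>   subjects: 20 in, 20 retained, 0 filter-excluded, 0 fit-failed
#> Between-group comparisons:
#>          endpoint      foal     horse       stat        p
#>                SI 1.739e+01 1.124e+00     U = 96 1.59e-05
#>                Sg 2.058e-02 1.042e-02     U = 82 7.30e-03
#>              AIRg 5.175e+02 3.974e+02     U = 87 1.52e-03
#>                DI 9.051e+03 4.064e+02     U = 96 1.59e-05
#>           homa_ir 3.496e+00 1.953e+00     U = 82 7.30e-03
#>       homa_bc_pct 3.601e+01 6.087e+01     U = 16 1.24e-02
#>            quicki 3.173e-01 3.450e-01     U = 14 7.30e-03
#>             risqi 3.427e-01 3.667e-01     U = 40 5.71e-01
#>              mirg 2.393e+00 3.269e+00     U = 19 2.52e-02
#>       auc_glucose 2.600e+04 3.112e+04 t = -2.054 5.48e-02
#>       auc_insulin 2.495e+03 8.575e+03 t = -9.134 3.53e-08
#>  baseline_glucose 1.464e+02 1.078e+02     U = 89 7.14e-04
#>  baseline_insulin 8.524e+00 7.439e+00     U = 56 5.71e-01
#> Foal age vs SI: rho = 0.042, p = 0.897
```

Foal-like subjects come out roughly twenty-fold more insulin sensitive
than horse-like ones (median SI 17.4 vs 1.1, Mann-Whitney p = 1.6e-5)
with a correspondingly higher disposition index, while the beta-cell
proxies (HOMA-BC%, MIRG) and both AUCs run higher in the horse-like
group — the pattern the presets encode. `write_report(report, "out/")`
writes the five result files (per-subject fits, proxies, summaries;
comparisons as CSV and JSON).

Cohorts can equally be read from a tidy CSV
(`subject_id,group,age_hours,time_min,glucose_mg_dl,insulin_uIU_ml`)
via `read_cohort_csv()`; `apply_enrollment_filter()` drops subjects
with baseline insulin above 20 uIU/mL. A thin command-line wrapper
lives at `inst/cli/ifsigtt.R` (`analyze` / `simulate` subcommands).

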