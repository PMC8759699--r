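---
title: "Minimal model analysis of the I-FSIGTT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal model analysis of the I-FSIGTT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifsigtt)
```

## The test and the model

The insulin-modified frequently sampled intravenous glucose tolerance
test (I-FSIGTT) perturbs the glucose-insulin system twice: a dextrose
bolus (300 mg/kg IV) at time 0 and a small exogenous insulin bolus
(0.02 IU/kg IV) 20 minutes later, with blood sampled at 20 fixed times
from -60 to 180 minutes. `ifsigtt` analyses the resulting paired
glucose/insulin series with Bergman's glucose minimal model, in which
insulin acts on glucose through a "remote" effect compartment $X(t)$:

$$\frac{dG}{dt} = -\bigl(S_g + X(t)\bigr)\,G(t) + S_g\,G_b, \qquad
  \frac{dX}{dt} = -p_2\,X(t) + p_3\,\bigl(I(t) - I_b\bigr),$$

with $G(0) = G_0$, $X(0) = 0$. Measured insulin $I(t)$ is the forcing
input (piecewise-linear through the post-dextrose samples, constant
beyond the last one, clipped at zero); glucose is fitted. The model's
assumptions are the standard ones: one well-mixed glucose pool, insulin
action proportional to the insulin increment above basal and delayed
through the first-order remote compartment, and glucose self-disposal at
the basal-insulin rate $S_g$. Insulin kinetics are *not* modelled — the
measured concentrations are taken at face value — so the method is
agnostic to whether insulin is endogenous or injected.

Reported quantities per subject:

* $S_g$ (min$^{-1}$): glucose effectiveness — glucose's capacity to
  mediate its own disposal.
* $S_I = p_3/p_2$: insulin sensitivity. Internally $S_I$ is in
  min$^{-1}$ per ($\mu$IU/mL); reported values are scaled by `si_scale`
  (default $10^4$), which places them on the numeric scale used in the
  equine minimal-model literature (healthy adult horses around 0.5-3,
  neonatal foals an order of magnitude higher).
* AIRg ($\mu$IU/mL$\cdot$min): acute insulin response to glucose — the
  trapezoidal integral of $\max(I - I_b, 0)$ over 0-10 minutes.
  Truncating negative increments keeps brief dips below basal from
  cancelling genuine first-phase release.
* DI $= S_I \times$ AIRg: disposition index, beta-cell output normalised
  to insulin sensitivity. The identity holds exactly for every fitted
  subject.

Basal values $G_b, I_b$ are the mean of the two pre-dextrose draws (-60
and 0 minutes); both are baseline samples under the protocol, and
averaging them halves assay noise in the anchor. The fasting *proxy*
indices, by contrast, use the time-0 pair alone, matching the convention
that proxies are computed from the single fasting sample taken
immediately before the test.

## Fitting

Free parameters are $(S_g, p_2, p_3, G_0)$; $G_b, I_b$ are fixed.
The objective is the unweighted sum of squared glucose residuals over
samples with $2 \le t \le 180$ minutes: the fit window starts at the
first post-dextrose sample, with $G_0$ free to absorb the mixing
transient rather than discarding early points. Optimisation is
Levenberg-Marquardt (`minpack.lm::nls.lm`) under box constraints

* $S_g \in [10^{-4}, 0.15]$ min$^{-1}$, $p_2 \in [10^{-3}, 1]$
  min$^{-1}$, $p_3 \in [0, 10^{-2}]$, $G_0 \in (G_b, 5\,G_b]$,

spanning published equine values for both age groups, from a
deterministic multi-start grid (default 16 starts: log-spaced interior
points of the box for the rates, two $G_0$ starts anchored at the
observed post-dextrose maximum). The best converged start wins;
identical input and settings always reproduce the identical fit. A fit
that ends on a box bound is flagged (`at_bound`) and a warning raised:
in low-$S_I$ subjects the likelihood can be nearly flat along the
$p_3/p_2$ ridge, and the flag marks exactly the fits whose $p_2, p_3$
are individually untrustworthy even when $S_I$ remains usable. The
group-level statistics are rank-based and tolerate this.

## Numerical integration

The ODE system is integrated by a fixed-step classical Runge-Kutta
scheme written in C++, with steps aligned to the forcing knots and the
output grid so the right-hand side is smooth within every step. The
step bound is 0.1 min for `minmod_simulate()` (relative error well
below $10^{-8}$ against both the $p_3 = 0$ closed form and an
independent `deSolve::lsoda` reference at rtol $10^{-10}$) and 0.5 min
inside the fitting loop, where the coarser grid changes fitted
parameters by less than $10^{-6}$ relative while tripling throughput —
material, because a cohort analysis performs tens of thousands of
integrations across the multi-start fits.

## Statistics

The between-group plan mirrors standard practice for these endpoints:
medians with IQR (type-7 interpolated quartiles) and two-sided
Mann-Whitney U for the model parameters, proxies and baselines; means
with t-based 95% CIs and the pooled-variance t-test for the
normally-behaved AUC endpoints; no correction across endpoints, since
each describes a different aspect of glucose/insulin homeostasis. The
Mann-Whitney implementation switches deterministically between the
exact null (group sizes totalling at most 25, no ties) and the
tie-corrected normal approximation with continuity correction. Spearman
correlation (foal age vs $S_I$) uses an exact full-permutation p-value
for $n < 10$ and the t approximation otherwise. Within-group time
courses use Friedman's test on complete blocks (incomplete subjects
dropped listwise and counted) with Dunn's z comparisons of each time
against baseline, Bonferroni-adjusted over those $k - 1$ comparisons
only — the family matches the question "which times differ from
baseline", not all pairwise contrasts. When every block is fully tied
the Friedman tie correction degenerates; the statistic is then reported
as 0 with p = 1.

## The synthetic cohort

The generator exists so the whole pipeline is testable without animal
data. Each subject draws its parameters log-normally (between-subject
CV 25%, keeping everything positive) around preset centres anchored to
the two phenotypes the pipeline must distinguish:

| centre | foal-like | horse-like |
|---|---|---|
| $G_b$ (mg/dL) | 166 | 104 |
| $I_b$ ($\mu$IU/mL) | 8.3 | 8.0 |
| $S_I$ (reporting scale) | 18.3 | 0.9 |
| $S_g$ (min$^{-1}$) | 0.02 | 0.01 |
| $p_2$ (min$^{-1}$) | 0.06 | 0.015 |

Insulin is generated parametrically, not from a secretion model,
because the analysis treats it as an input:
$I(t) = I_b + A_1 t e^{-k_1 t} + A_2 e^{-k_2 (t-20)}\,[t \ge 20]$ —
an endogenous first phase plus the exogenous bolus. The amplitudes are
set so the centre subjects reproduce the field-typical first-phase
areas (AIRg $\approx 605$ foal, $\approx 370$ horse) and total insulin
exposure (foal insulin AUC $\approx 2{,}400$, horse $\approx 8{,}400$
$\mu$IU/mL$\cdot$min; the horse bolus decays slowly, $k_2 = 0.03$,
emulating the sustained insulin excursion of adults). $G_0$ is
$G_b + \text{dose}/V_d$ with $V_d$ 1.6 dL/kg (foal) and 1.35 dL/kg
(horse). Measurement noise is multiplicative Gaussian — 3% CV for
glucometer glucose, 8% for ELISA insulin, plausible assay-level values
chosen as assumptions, not measurements — and concentrations are
clipped at 20 mg/dL and 0.5 $\mu$IU/mL.

One deliberate convention: the generator's ground-truth forcing is the
piecewise-linear interpolant of the *sampled* insulin, the same
convention the fitting stage uses. Noise-free subjects are therefore
exactly recoverable, and recovery tests isolate estimation error from
forcing-model error. The cost is that the generator does not probe the
interpolation error a continuous insulin profile would induce between
samples; with the protocol's dense early sampling that error is small,
but it is real data's problem, not the simulator's.

Other features of real data the generator does not emulate: no age
dependence of $S_I$ within the foal group (the age-$S_I$ correlation in
a synthetic cohort is null by construction), no glucose counterregulation
(glucagon, cortisol) at the hypoglycaemic nadir, no assay floor/ceiling
censoring, and independence of all subject-level parameters (real
$G_b$ and $S_I$ co-vary). Passing tests on synthetic cohorts therefore
demonstrate that the estimation and statistical machinery recovers
known structure under realistic noise — not that the model is adequate
for any particular animal.

## Problem sizes in the checks

The packaged checks use the sizes a desk run can afford: single-subject
recovery on noise-free centre subjects; a 50-subject Monte-Carlo
recovery study at 3% glucose noise (median $|S_I|$ relative error
under 10%); the full 12-vs-8 pipeline; and a 20-master-seed replication
of the group separation (Mann-Whitney p < 0.01 on fitted $S_I$ in at
least 95% of seeds). Exact-test equivalence is enumerated exhaustively
up to 10 pooled observations (Mann-Whitney) and n = 7 (Spearman).

## Known limitations

* MinMod-style commercial software applies unpublished weighting and
  windowing conventions; this implementation states its own (unweighted
  SSE, fit from 2 min, AIRg over 0-10 min truncated at basal) and its
  absolute parameter values are comparable across subjects analysed the
  same way, but only approximately against other software.
* $p_2$ and $p_3$ are weakly identified when insulin action is small;
  interpret them individually only when `at_bound` is `FALSE` and the
  residual RMSE is a few mg/dL.
* The enrollment filter and the proxies require a complete time-0
  sample; there is no fallback to the -60 min draw.
* HOMA indices are computed on mmol/L glucose (conversion factor
  18.016); the literal mg/dL rendering of HOMA-BC% (constant 63) is
  available as `variant = "mgdl"` and differs by ~0.1% through the
  rounded constant.
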