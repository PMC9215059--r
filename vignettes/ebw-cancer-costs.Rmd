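---
title: "Attributing future cancer costs to excess body weight: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing future cancer costs to excess body weight: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pifcost)
```

## The model

`pifcost` implements a comparative risk assessment macrosimulation: it asks
what share of the direct healthcare costs of cancer would disappear if the
population's body-mass-index (BMI) distribution were different. Excess body
weight (EBW, BMI >= 25 kg/m^2) raises the incidence of a dozen cancers; the
package quantifies the cost consequences of that excess exposure at the
population level, by sex, for a future cost year.

The central quantity is the potential impact fraction,

$$PIF = \frac{\sum_i P_i RR_i - \sum_i P'_i RR_i}{\sum_i P_i RR_i},$$

where \(P_i\) is the baseline proportion of the population in BMI category
\(i\), \(P'_i\) the proportion under a counterfactual scenario, and
\(RR_i\) the relative risk of the cancer in category \(i\) relative to the
reference (BMI < 25 kg/m^2). When the counterfactual puts everyone in the
reference category — the theoretical minimum risk exposure level — the PIF
is the population attributable fraction (PAF). Attributable cost is PIF
times the cost of the cancer in the target year; the lag between exposure
and outcome (default 10 years, the typical follow-up of the cohort studies
behind the relative risks) is enforced between the prevalence year and the
cost year.

Three ingredient models feed the PIF:

1. **Dose-response relative risks.** Meta-analytic RRs are published per
   \(x\) kg/m^2 of BMI (usually \(x = 5\)). Under the log-linear
   dose-response model they rescale as \(RR_1 = \exp(\log(RR_x)/x)\)
   (`rescale_rr()`) and expand over categories as
   \(RR_c = RR_1^{M_c - ref}\) (`categorical_profile()`), where \(M_c\) is
   the category median and \(ref\) the reference category's value. Where a
   published pooled RR mixes incidence and mortality studies,
   `pool_random_effects()` re-pools the per-study log-RRs by
   DerSimonian–Laird random effects on incidence studies only.
2. **Counterfactual scenarios** (`apply_scenario()`): a supplied target
   distribution (e.g. rolling BMI back to an earlier survey); freezing the
   distribution at a reference year; eliminating obesity classes II–III
   (BMI >= 35 kg/m^2); or a 1 kg/m^2 reduction of mean BMI among the
   exposed.
3. **Cost projection** (`fit_and_project()`): ordinary least squares of
   annual cost on calendar year, evaluated at the target year with a
   t-distribution prediction interval, then converted to international
   dollars by a purchasing power parity factor (`ppp_convert()`, default
   2.281 R$ per US$, the 2019 Brazilian factor).

`ebw_attribution()` assembles these into one run; `ebw_savings()` repeats
the attribution across a list of scenarios against a projected future
baseline and reports the cost savings each scenario would buy.

## Uncertainty propagation

Sampling uncertainty is propagated by Monte Carlo simulation
(`simulate_pif()`, default 10,000 iterations). Each iteration draws

* the baseline prevalence of each BMI category from a binomial distribution
  at the stratum's effective sample size, renormalised so the drawn
  proportions sum to 1 (a multinomial single-partition mode is available);
* the log relative risk from a normal distribution centred on the published
  log point estimate, with standard error back-calculated from the 95% CI
  as \((\log CI_{high} - \log CI_{low}) / (2 \times 1.959964)\). The draw
  is made once per subtype on the published per-\(x\) scale and shared
  across categories, since all categorical RRs derive from the same
  dose-response coefficient; rescaling and categorical expansion are
  re-applied per draw.

The PIF is evaluated per draw; negative draws are rounded to 0 (reducing
BMI is assumed not to raise cancer risk) before summarising, per draw
rather than on the summary percentiles. The 50th percentile is the central
estimate and the 2.5th/97.5th percentiles form the 95% uncertainty
interval. Counterfactuals that are functions of the baseline (truncation,
mean shift, hold-at-baseline) are re-derived inside each draw; fixed target
distributions stay fixed.

## Design choices where the design was open

* **Reference exposure value.** Published category definitions give only
  "< 25 kg/m^2" for the reference; the exponent in \(RR_c\) needs a value.
  The package uses the reference category's median (default 22 kg/m^2),
  configurable through `bmi_schema()`. Only differences \(M_c - ref\)
  matter, so this choice shifts all category RRs coherently.
* **Category medians.** Defaults 22, 27, 32, 37 kg/m^2 for
  <25, 25–<30, 30–<35, >=35; real analyses should supply survey-estimated
  medians via `bmi_schema()`.
* **Truncation scenario reallocation.** Mass eliminated above the BMI
  threshold moves to the adjacent category just below it
  (a minimal-change assumption); `scenario_truncate(reallocate_to =
  "reference")` reallocates to the reference category instead.
* **Mean-shift scenario.** With categorical exposure, a 1 kg/m^2 mean
  reduction cannot be expressed as a movement of category masses without
  further assumptions. It is realised as a median shift
  \(M_c \to M_c - 1\) for exposed categories when computing the
  counterfactual \(RR_c\), which is exactly equivalent, under the
  log-linear model, to lowering every exposed person's BMI by 1 kg/m^2.
  Prevalences are unchanged.
* **Fixed-cost attribution intervals.** The attributable-cost interval
  multiplies the PIF interval by the point cost rather than drawing the
  cost too: published attribution tables are consistent with cost held
  fixed (bounds divided by cost reproduce the printed PIF bounds), and
  cost-projection uncertainty is reported separately on the projection.
* **Future baseline prevalence.** Savings analyses need a baseline BMI
  distribution at an intermediate year (e.g. 2030). `project_prevalence()`
  extrapolates each category proportion linearly between two observed
  surveys, clips to [0, 1] and renormalises — a deliberately transparent
  rule; results of the savings analysis depend on it.
* **Site-level reporting.** For subtypes covering part of a topographic
  site (oesophageal adenocarcinoma, cardia stomach, advanced prostate,
  postmenopausal breast), the site PIF is the subtype attributable cost
  divided by the site's total cost (`pif_site()`), so the attributable
  cost is preserved while the denominator widens.
* **Year centring.** The cost regression centres calendar year before
  fitting: the fit is identical, the normal equations better conditioned.
* **Pooling estimator.** "Random effects" without a named estimator is
  taken as DerSimonian–Laird, the conventional default; the fit is
  delegated to `metafor::rma(method = "DL")`.

## The synthetic-data generator

`synthetic_config()` fixes a fully-known ground truth so every stage can be
tested without survey or registry access:

* **Prevalence.** Category counts are drawn from a multinomial over the
  true proportions at the stratum's effective sample size, so counts
  partition \(n\) and observed proportions sum to 1 exactly; per-category
  Wald binomial CIs are attached. The default effective sample size is
  30,000 per sex stratum — the order of magnitude of a national health
  survey's per-sex subsample of public-system adults. The complex survey
  design of a real survey (stratification, clustering, weights) is *not*
  emulated; effective sample size is the only sampling knob, so passing
  tests say nothing about design effects in real data.
* **Costs.** Annual values follow `intercept + slope * (year - first_year)`
  plus additive Gaussian noise floored at zero — the simplest process
  matching a linear-regression-based projection. Real cost series have
  policy shocks and autocorrelation that this does not emulate.
* **Ground truth.** `ground_truth_pif()` evaluates the PIF deterministically
  on the noise-free truth, giving a recovery target for the Monte Carlo
  pipeline.

Default true proportions (0.42/0.34/0.16/0.08 female, 0.44/0.36/0.14/0.06
male) mirror the adult BMI distribution of a middle-income country; the
default RR fixtures use published per-5 values (1.50 and 1.12 with their
CIs).

## Numerical choices and degenerate inputs

* Simplex checks use a 1e-9 tolerance; generated tables satisfy them
  exactly by construction (counts partition \(n\)).
* `effective_n = Inf` denotes a noise-free prevalence (draws collapse to
  the point values), used for deterministic pipeline runs.
* An all-zero binomial draw (possible only at tiny effective sample sizes)
  is replaced by the point proportions before renormalising.
* 1.959964 rather than 1.96 is used in the CI/SE back-calculation; the
  difference is below reporting precision but keeps round trips exact.
* Negative cost projections are floored at 0 with a warning; a truncation
  scenario whose threshold exceeds every category warns and returns the
  baseline unchanged.
* Reports round to 2 decimal places; intermediate computation never rounds.

## Problem sizes used in the test-suite

The bundled tests run the Monte Carlo recovery check with 10,000 iterations
on one dataset for the median-vs-truth comparison, and 200 replicate
datasets at 2,000 iterations each for interval coverage (expected between
90% and 99% at nominal 95%); property checks iterate over dozens of random
small instances under fixed seeds. These sizes were chosen to give stable
verdicts at interactive runtimes.

## Worked example

```{r}
cfg <- synthetic_config(seed = 42)
prev <- generate_prevalence(cfg)
costs <- generate_cost_series(cfg)
fit <- ebw_attribution(prev, cfg$rr_table, costs,
                       mc = mc_config(n_iterations = 2000, seed = 1))
fit
```

```{r, fig.width = 6, fig.height = 4}
plot(fit, stratum = "F")
```

## Known limitations

* Cohort-level BMI trajectories, lag-specific risk accumulation and
  recurrent events are outside the model: exposure at one year is linked
  to cost at one later year through a single lag.
* The linear prevalence projection and linear cost trend are transparent
  but crude; structural breaks in either invalidate them.
* Attribution assumes the categorical RRs transfer to the target
  population, and self-reported BMI misclassification is not modelled.
* Interval widths depend on the per-stratum effective sample sizes, which
  real analyses must supply; with unknown survey sizes only qualitative
  interval comparisons are meaningful.
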