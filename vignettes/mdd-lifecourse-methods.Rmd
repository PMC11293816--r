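---
title: "Modelling educational inequalities in MDD across the life course"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling educational inequalities in MDD across the life course}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mddcourse)
```

## The model

`mddcourse` treats adult depression as a two-state continuous-time
process on the age axis: an individual is either *healthy* or in an
episode of major depressive disorder (MDD), moving healthy to MDD with
the **incidence hazard** $\lambda(t)$ and MDD to healthy with the
**remittance hazard** $\mu(t)$, both piecewise constant on age bands
(5-year bands from 18, closing with the short band $[63, 65)$).
Mortality is deliberately absent: life courses run from age 18 to
censoring at 65, so "years with MDD" are years lived with MDD in a
fixed 47-year window. Each of the four strata (sex by education, where
education contrasts 10 years — junior general secondary — with 16 years
— university) has its own hazards and its own MDD prevalence at age 18,
which seeds the initial state.

The marginal MDD probability $p(t)$ of this chain solves
$p'(t) = \lambda(t)\,(1 - p) - \mu(t)\,p$, which within a band has the
closed form
$p(t) = p_{eq} + (p_0 - p_{eq})\,e^{-(\lambda + \mu)(t - t_0)}$ with
$p_{eq} = \lambda / (\lambda + \mu)$. `analytic_state_probability()`
chains this across bands and is the package's *oracle*: the simulation
engine is validated against it, never the other way around. Two further
closed forms follow: the ever-MDD probability by 65 (first passage
depends on the integrated incidence hazard alone,
$p_{18} + (1 - p_{18})(1 - e^{-\int \lambda})$) and the expected years
in MDD ($\int_{18}^{65} p(t)\,dt$, integrated exactly band by band).

## Simulation engine

`run_simulation()` draws each life course by exact inverse-transform
sampling: given the current age and state, the next transition age
solves $\Lambda(t) = -\log u$ across band boundaries, so there is no
time-step discretisation bias and the oracle comparison is sharp. Each
individual owns a counter-based RNG substream (splitmix64 keyed by seed
and individual index), making results bit-reproducible and independent
of iteration order or stratum subsetting. The default run simulates
125000 individuals per stratum — 500000 in all, evenly divided over the
four strata, enough to push the Monte Carlo standard error of a
life-course prevalence below 0.15 percentage points. An optional
*history* rate table replaces both hazards after an individual's first
remission, expressing dynamics that differ once a depression history
exists; passing the original table reproduces the no-switching run
bit for bit.

Reported statistics follow the tabulated conventions: life-course
prevalence counts anyone ever in MDD, including those already ill at 18;
mean age of onset averages the first entry age over those healthy at 18
who ever enter (prevalent cases are excluded); mean duration averages
total MDD years — summed across episodes and censored at 65 — over all
ever-MDD individuals, including those ill at 18. The duration
denominator including prevalent cases is a literal reading of
"individuals who experienced MDD"; it is a one-line switch in
`summarize_life_courses()` if the stricter incident-only reading is
wanted. Age-specific prevalence is point-in-time state at integer ages
(not band-averaged), matching a prevalence-at-age reading of the usual
prevalence figure. Values are reported rounded half away from zero to
one decimal (with a $10^{-9}$ guard against binary representation of
decimal inputs); internal computation is full precision.

## Estimating the rates

The estimation input is a two-wave panel: per person sex, education
years, baseline age and MDD status, follow-up MDD status after an
irregular gap, and nine modifiable factors. Incidence models use the
baseline-healthy, remittance models the baseline-ill, with the
follow-up status (or recovery) as a binary outcome in a multivariable
logistic regression on age-band indicators, sex, education years,
log follow-up gap and any factor covariates.

Three numerical choices matter and were made after the first
implementation exposed their absence as bias:

* **Interval censoring.** Over a multi-year gap a person can enter MDD
  *and* remit, so the observed 0-to-1 fraction understates incidence by
  roughly $\mu g / 2$ — at realistic remittance (0.3/yr) and gaps
  (2-5 yr) a 25-40% bias. `build_rate_table()` therefore inverts the
  two-state closed form jointly:
  $\theta = -\log(1 - p_{01} - p_{10})/g$,
  $\lambda = \theta\,p_{01}/(p_{01}+p_{10})$,
  $\mu = \theta\,p_{10}/(p_{01}+p_{10})$, evaluated per record at its
  own predicted probabilities and gap, then averaged within stratum and
  band (marginal prediction over the stratum's covariate rows). The
  naive single-jump inversion $-\log(1-p)/g$ is retained as
  `conversion = "single_jump"` and as the exported
  `probability_to_hazard()`; a regression test documents how far it
  falls short under heavy masking.
* **Exposure.** Gaps vary, and a gap-marginal predicted probability
  inverted at each record's own gap is biased upward by about
  $\mathrm{var}(g)/\bar g^2$ (Jensen, via $E[1/g] > 1/\bar g$). The
  log-gap covariate lets predictions track exposure, making the
  record-level conversion consistent.
* **Band anchoring.** A record observed over $[a, a+g]$ informs the
  hazard around $a + g/2$; anchoring bands on the baseline age instead
  shifts banded hazards by about (hazard trend) $\times\, g/2$. Bands
  are therefore assigned by the interval midpoint, in fitting and
  prediction alike.

Prevalence at 18 comes from a logistic model of baseline status on sex,
education and age among the youngest records, predicted at age 18; the
age term removes the window-mean bias so the window can be widened
(the pipeline uses 25) to stabilise the estimate, with an empirical
per-stratum fallback when the model is degenerate. Missing factor
cells are filled once by stochastic-regression imputation (linear model
on sex, education, age and baseline status, plus a residual draw,
snapped to the nearest valid level) under a fixed seed — a deliberately
simple, deterministic, replaceable stand-in for a full multiple-
imputation procedure. The model defaults to a single pooled additive
fit rather than fully stratified per-stratum fits: the education-years
coefficient must exist as a single term because the mediation screen
consumes it, and the synthetic world's dynamics are additive on the
log-hazard scale, so the pooled fit loses little.

## Mediation screen and counterfactuals

The screen refits the incidence model with and without one factor and
reports $100 (\beta_{\text{total}} - \beta_{\text{adjusted}}) /
\beta_{\text{total}}$ on the education-years log-odds coefficient
(difference of coefficients). It runs on the incidence direction only,
and the method is the simplest defensible default — its sole downstream
consumer is a ranking, from which the top three factors are kept. In
the default synthetic world those are quality of social contacts,
health literacy and smoking, mirroring the factors the real analysis
selected. Difference-of-coefficients on a logistic scale is mildly
non-collapsible; the half-mediated validation fixture shows the
resulting attenuation is a few percentage points at these outcome
frequencies, which cannot disturb a ranking this coarse.

Counterfactuals use marginal standardization (g-computation style): the
fitted models are re-averaged over a covariate distribution in which
the low-education records' swapped factors are replaced by *joint rows*
resampled, with a fixed seed, from the same-sex high-education group.
Resampling joint rows rather than independent marginals preserves the
swapped factors' correlation, which is the natural reading of giving
the low-education group "the same distribution"; with a single swapped
factor the two coincide. High-education strata are never altered, and
the age-18 prevalence is not counterfactually changed (only transition
rates are standardized); both are asserted by tests. Two limiting cases
pin the construction down: identical factor distributions leave the
rate table unchanged up to resampling noise, and when education acts
only through the swapped factors, the joint swap closes the
low/high rate gap entirely.

Inequalities are summarised per sex as gaps oriented so that positive
means worse for low education (prevalence low−high in percentage
points; onset high−low in years, larger meaning earlier onset with low
education; duration low−high in years), reduced under a counterfactual
by $100(1 - \text{gap}_{cf}/\text{gap}_{base})$, and pooled across
sexes by the unweighted mean — valid because simulated strata are
evenly sized, and refused otherwise.

## The synthetic cohort and what passing tests show

No individual-level data are public, so `generate_cohort()` creates a
panel with known dynamics: education-graded categorical/ordinal factor
distributions (nine factors; occupational and leisure-time physical
activity are collapsed into one to keep the count at nine), baseline
status from a logistic model at the baseline age, and — crucially — the
follow-up status by *exact event-history simulation* of the
ground-truth process over each record's gap, so multiple transitions
within a gap occur exactly as interval censoring implies and estimation
must genuinely undo it. Missingness is MCAR at a configurable rate
(default 5%), keeping recovery tests unbiased; real missingness is
unlikely to be MCAR, and the imputation is correspondingly simple.
Default rates were chosen once to give an MDD-like world — incidence
declining from roughly 0.019 to 0.004 per person-year across
adulthood for low-educated women down to 0.005-0.002 for
high-educated men, remittance near 0.3/yr, age-18 prevalence 3-8%, a
2.5-fold low/high gap in life-course prevalence — with about 40% of
the education effect on incidence flowing through the three selected
factors. What passing tests show is that the machinery is correct under
these idealised conditions (additive log-hazard truth, MCAR, uniform
ages, no attrition or mortality); they cannot show that the logistic
working model or the mediation method is adequate for any particular
real cohort.

Two further configurations exist purely to give validation checks
statistical power, designed by power calculation before the tests were
frozen. At realistic MDD rates a 50000-record panel yields only ~140
incidence events per 5-year band, so band-level hazard estimates carry
8-20% sampling error and a 10% recovery tolerance would mostly measure
noise. `benchmark_config()` (incidence and remittance ~0.3/yr, ~50%
baseline prevalence, three wide bands, 1.5-2.5 yr gaps) yields
thousands of events per cell so the same tolerance sits at roughly four
standard errors; `roundtrip_config()` (incidence ~0.06/yr) keeps
lifetime prevalence unsaturated so an estimate-then-simulate round trip
can be checked to 1.5 percentage points. The two regimes — high
interval event rates versus unsaturated lifetime prevalence — are
mutually exclusive in one configuration, which is why there are two.

## Numerical and testing conventions

Simultaneous statistical comparisons are bounded family-wise. The
engine-versus-oracle check compares simulated and analytic prevalence
at every integer age for 20 random rate tables (3840 cells, strongly
age-correlated); asserting a plain 3-standard-error band per cell would
reject a provably exact engine more often than not, so the suite
asserts the 3-SE *confidence level* family-wise: a Bonferroni-adjusted
bound on the maximum z-score plus a binomial cap on the number of
per-cell exceedances, with exact binomial tests where expected counts
are tiny. Degenerate inputs are handled explicitly: zero hazards give
censoring at 65 and constant prevalence curves; $\lambda + \mu = 0$
bands propagate $p$ unchanged; interval probabilities with
$p_{01} + p_{10} \ge 1$ are rejected as unidentifiable; a zero total
education effect makes the mediating percentage an error, not a number;
ties in the mediation ranking break alphabetically.

Problem sizes throughout (50000-record cohorts for estimation checks;
100000 life courses per oracle table; 500000 for the headline
simulation; 25000 per stratum in round-trip comparisons) are the
package's own choices, set where the quantity under test has standard
error well inside the tolerance asserted against it.

## Known limitations

The two-state model has no episode memory beyond the optional
history-table switch, no time-varying covariates within a life course,
no mortality and no attrition; transition rates are assumed stationary
over calendar time. The mediation screen is associational — no
exposure-mediator interaction decomposition or sensitivity analysis for
unmeasured confounding. External rate files can be loaded through a
documented column mapping, but the package ships no third-party data:
absolute published estimates are reproducible only when the study's
deposited rate tables are supplied as that optional input.
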