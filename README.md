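# mddcourse

Educational inequalities in major depressive disorder (MDD) across the
adult life course, quantified by microsimulation. The package is for
epidemiologists and health-inequality researchers who want to (i) turn
two-wave panel data into age-banded MDD incidence and remittance
hazards by sex and education, (ii) simulate individual MDD life courses
from 18 to 65 under those hazards, and (iii) ask how much the
inequalities would shrink if modifiable factors — quality of social
contacts, health literacy, smoking — were distributed in the
low-education group as they are in the high-education group.

## Model

Depression is a two-state continuous-time process: healthy → MDD with
incidence hazard λ(t), MDD → healthy with remittance hazard μ(t), both
piecewise constant on 5-year age bands over [18, 65); mortality is not
modelled. The marginal MDD probability solves

    p'(t) = λ(t) (1 − p) − μ(t) p,

which has a closed form within each band — the package carries this
solution (`analytic_state_probability()`) as an independent oracle for
its exact inverse-transform simulation engine. Rates are estimated by
logistic transition models on interval-censored panel observations; per
record the predicted onset/recovery probabilities (p01, p10) over gap g
are converted to hazards by jointly inverting the two-state closed
form,

    θ = −log(1 − p01 − p10) / g,   λ = θ p01/(p01+p10),   μ = θ p10/(p01+p10),

which corrects for transitions masked by a return within the interval.
Counterfactual rate tables re-average the fitted models after replacing
the low-education group's selected factors with joint rows resampled
from the same-sex high-education group (marginal standardization).
Outcomes per stratum are life-course prevalence (% ever in MDD), mean
age of onset, and mean duration (years in MDD among the ever-ill);
inequalities are low-vs-high gaps, and a counterfactual's effect is the
percentage gap reduction 100 (1 − gap_cf / gap_base).

Because the underlying cohort data are not public, a synthetic-cohort
generator with known ground-truth dynamics (`generator_config()`,
`generate_cohort()`) stands in for them; every stage is validated
against that ground truth or against the closed-form oracle.

## Worked example

```r
library(mddcourse)

cfg    <- generator_config(n_individuals = 50000, seed = 1)
cohort <- impute_factors(generate_cohort(cfg), seed = 2)

rates <- build_rate_table(
  list(incidence  = fit_transition_model(cohort, "incidence"),
       remittance = fit_transition_model(cohort, "remittance")),
  fit_baseline_prevalence(cohort, max_age = 25), cohort)

sim     <- run_simulation(rates, simulation_settings(125000, seed = 10))
summary <- summarize_life_courses(sim)
summary[, c("stratum", "life_course_prevalence", "mean_age_onset", "mean_duration")]
#>       stratum life_course_prevalence mean_age_onset mean_duration
#> 1  female_low                   38.0           34.9          4.58
#> 2 female_high                   19.2           35.8          3.28
#> 3    male_low                   31.3           35.3          4.39
#> 4   male_high                   15.3           35.9          3.18

education_gaps(summary)
#>      sex    outcome   gap
#> 1 female prevalence 18.86
#> 2 female      onset  0.90
#> 3 female   duration  1.30
#> 4   male prevalence 16.03
#> 5   male      onset  0.66
#> 6   male   duration  1.21

select_top_factors(screen_mediators(cohort), 3)
#> [1] "social_contact_quality" "health_literacy"        "smoking"
```

Reading: in this synthetic world 38.0% of low-educated women ever
experience MDD between 18 and 65 versus 19.2% of high-educated women —
an 18.9 percentage-point gap; low-educated women develop MDD 0.9 years
earlier and spend 1.3 more years with it. The mediation screen ranks
quality of social contacts, health literacy and smoking as the
strongest mediators of the education–incidence association; feeding
their counterfactual equalization through `run_scenarios()` yields the
gap reductions (see `analysis/05_counterfactuals.R`).

The `analysis/` directory holds the full numbered workflow
(01 generate → 02 estimate → 03 screen mediators → 04 simulate →
05 counterfactuals → 06 published identities), each stage writing its
tables under `results/`.

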