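# shared fixtures: model fitting shortcut, special-purpose generator
# configurations, hand-built life courses, random rate tables

fit_models <- function(cohort, bands = age_bands(),
                       extras = character()) {
  list(incidence = fit_transition_model(cohort, "incidence", extras,
                                        bands),
       remittance = fit_transition_model(cohort, "remittance", extras,
                                         bands))
}

estimate_table <- function(cohort, bands = age_bands(),
                           extras = character(), max_age = 25) {
  build_rate_table(fit_models(cohort, bands, extras),
                   fit_baseline_prevalence(cohort, max_age),
                   cohort, bands)
}

# education acts on incidence only through the three selected factors
# (direct education coefficients zero); with equal_probs the education
# groups share every factor distribution, removing the gap entirely
full_mediation_config <- function(n = 50000, seed = 1,
                                  equal_probs = FALSE) {
  k <- 3
  fs <- default_factor_specs()
  if (equal_probs)
    for (nm in names(fs)) fs[[nm]]$probs$low <- fs[[nm]]$probs$high
  generator_config(
    n_individuals = n, seed = seed, followup_gap_range = c(1.5, 2.5),
    factor_specs = fs,
    true_hazards = list(
      incidence = list(
        log_intercepts = seq(log(0.30), by = -0.03, length.out = k),
        female = 0.10, education_years = 0,
        factors = list(social_contact_quality = -0.35,
                       health_literacy = -0.2,
                       smoking = c(`0` = 0, `1` = 0.1, `2` = 0.3))),
      remittance = list(
        log_intercepts = rep(log(0.30), k),
        female = -0.05, education_years = 0,
        factors = list(social_contact_quality = 0.15))),
    baseline_prevalence_coefs = c(intercept = 0, female = 0.1,
                                  education_years = 0, age = 0),
    bands = age_bands(16))
}

# half of the 6-year education effect on the incidence log hazard flows
# through quality of social contacts: direct -0.2, mediated
# -0.5 * (0.7 - 0.3) = -0.2
mediation_split_config <- function(n = 50000, seed = 5) {
  fs <- default_factor_specs()
  fs$social_contact_quality <- list(
    type = "ordinal", levels = 0:1,
    probs = list(low = c(0.7, 0.3), high = c(0.3, 0.7)))
  generator_config(
    n_individuals = n, seed = seed, followup_gap_range = c(1.5, 2.5),
    factor_specs = fs,
    true_hazards = list(
      incidence = list(
        log_intercepts = seq(log(0.30), by = -0.03, length.out = 3),
        female = 0.1, education_years = -0.2 / 6,
        factors = list(social_contact_quality = -0.5)),
      remittance = list(
        log_intercepts = rep(log(0.30), 3),
        female = -0.05, education_years = 0, factors = list())),
    baseline_prevalence_coefs = c(intercept = 0, female = 0.1,
                                  education_years = 0, age = 0),
    bands = age_bands(16))
}

random_rate_table <- function(seed, bands = age_bands()) {
  set.seed(seed)
  k <- length(bands) - 1
  rate_table(bands,
             matrix(runif(k * 4, 0.002, 0.10), k),
             matrix(runif(k * 4, 0.05, 0.60), k),
             runif(4, 0, 0.25),
             provenance = "ground_truth")
}

# hand-built life courses: `events` is a list (one entry per individual)
# of data.frames with columns age, state ("mdd"/"healthy")
toy_life_courses <- function(initial, events,
                             stratum = "female_low") {
  n <- length(initial)
  strata <- strata_table()
  onset <- mdd_years <- numeric(n)
  for (i in seq_len(n)) {
    ev <- events[[i]]
    onset[i] <- if (!is.null(ev) && any(ev$state == "mdd"))
      min(ev$age[ev$state == "mdd"]) else NA_real_
    age <- 18
    state <- initial[i]
    total <- 0
    if (!is.null(ev)) for (j in seq_len(nrow(ev))) {
      if (state == "mdd") total <- total + ev$age[j] - age
      age <- ev$age[j]
      state <- ev$state[j]
    }
    if (state == "mdd") total <- total + 65 - age
    mdd_years[i] <- total
  }
  ind <- tibble::tibble(
    id = seq_len(n), stratum = stratum,
    sex = strata$sex[strata$stratum == stratum],
    education = strata$education[strata$stratum == stratum],
    initial_state = initial,
    ever_mdd = initial == "mdd" | !is.na(onset),
    onset_age = onset, mdd_years = mdd_years,
    n_transitions = vapply(events, function(e)
      if (is.null(e)) 0L else nrow(e), integer(1)))
  trs <- lapply(seq_len(n), function(i) {
    ev <- events[[i]]
    if (is.null(ev) || nrow(ev) == 0) return(NULL)
    tibble::tibble(id = i, stratum = stratum, age = ev$age,
                   state = ev$state)
  })
  trs <- do.call(rbind, trs[!vapply(trs, is.null, logical(1))])
  if (is.null(trs))
    trs <- tibble::tibble(id = integer(), stratum = character(),
                          age = numeric(), state = character())
  structure(list(individuals = ind, transitions = trs,
                 bands = as.numeric(age_bands()),
                 settings = simulation_settings(n, 1)),
            class = "life_courses")
}
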