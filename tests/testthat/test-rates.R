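test_that("probability-to-hazard inversion matches closed forms", {
  expect_equal(probability_to_hazard(0, 1), 0)
  expect_equal(probability_to_hazard(1 - exp(-1), 1), 1, tolerance = 1e-12)
  expect_equal(probability_to_hazard(0.5, 2), log(2) / 2,
               tolerance = 1e-12)
  expect_error(probability_to_hazard(1, 1), "infinite")
  expect_error(probability_to_hazard(-0.1, 1), "p <")
  expect_error(probability_to_hazard(0.5, 0), "gap")
})

test_that("probability and hazard conversions are mutual inverses", {
  p <- c(0, 1e-6, seq(0.01, 0.999, by = 0.01))
  for (gap in c(0.5, 1, 3.7)) {
    h <- probability_to_hazard(p, gap)
    expect_equal(hazard_to_probability(h, gap), p, tolerance = 1e-12)
    expect_true(all(diff(h) > 0))
  }
  h <- c(0, 0.01, 0.3, 2)
  expect_equal(probability_to_hazard(hazard_to_probability(h, 2.5), 2.5),
               h, tolerance = 1e-12)
})

test_that("joint two-state inversion recovers the generating hazards exactly", {
  for (par in list(c(0.05, 0.4, 2), c(0.3, 0.3, 1.5), c(0.01, 0.05, 5))) {
    lam <- par[1]; mu <- par[2]; g <- par[3]
    theta <- lam + mu
    p01 <- lam / theta * (1 - exp(-theta * g))
    p10 <- mu / theta * (1 - exp(-theta * g))
    hz <- interval_hazards(p01, p10, g)
    expect_equal(hz$incidence, lam, tolerance = 1e-12)
    expect_equal(hz$remittance, mu, tolerance = 1e-12)
  }
  # one-way limit coincides with the single-jump inversion
  hz <- interval_hazards(0.3, 0, 2)
  expect_equal(hz$incidence, probability_to_hazard(0.3, 2),
               tolerance = 1e-12)
  expect_equal(hz$remittance, 0)
  expect_equal(interval_hazards(0, 0, 3), list(incidence = 0,
                                               remittance = 0))
  expect_error(interval_hazards(0.6, 0.5, 1), "identifiable")
})

test_that("baseline prevalence: empirical fallback and degenerate limits", {
  # single-stratum toy set: 10 records, 3 baseline cases -> 0.30
  toy <- tibble::tibble(
    id = 1:10, sex = "female", education = "low", education_years = 10,
    age_baseline = 18.5, mdd_baseline = c(rep(1, 3), rep(0, 7)),
    followup_gap = 2, mdd_followup = 0)
  expect_warning(p_toy <- fit_baseline_prevalence(toy), "degenerate")
  expect_equal(unname(p_toy), 0.3)
  # all-zero outcome: prevalence 0 in every stratum present
  coh <- generate_cohort(generator_config(n_individuals = 2000, seed = 2))
  coh$mdd_baseline <- 0L
  expect_true(all(fit_baseline_prevalence(coh) == 0))
  # a stratum with no young records is reported by name
  old <- coh
  old$age_baseline[old$sex == "male" & old$education == "high"] <- 50
  expect_error(fit_baseline_prevalence(old), "male_high")
  expect_error(fit_baseline_prevalence(coh[0, ]), "empty")
})

test_that("baseline prevalence recovers the generating model within 3 SE", {
  # z-scores use the estimator's own standard error at the age-18
  # prediction point (binomial noise plus the age-extrapolation
  # component), via an independent refit of the same model; the bound is
  # family-wise over 3 seeds x 4 strata with allowance for mild
  # finite-sample overdispersion of the link-scale z
  for (sd in 19:21) {
    cfg <- roundtrip_config(seed = sd)
    coh <- generate_cohort(cfg)
    est <- fit_baseline_prevalence(coh, max_age = 25)
    tru <- true_rate_table(cfg)$prevalence_at_18
    young <- coh[coh$age_baseline <= 25, ]
    young$age_over_18 <- young$age_baseline - 18
    fit <- stats::glm(mdd_baseline ~ sex + education_years + age_over_18,
                      family = stats::binomial(), data = young)
    new <- strata_table()
    new$education_years <- c(low = 10, high = 16)[new$education]
    new$age_over_18 <- 0
    pr <- stats::predict(fit, newdata = new, type = "link",
                         se.fit = TRUE)
    z <- (stats::qlogis(est[new$stratum]) -
            stats::qlogis(tru[new$stratum])) / pr$se.fit
    expect_lt(max(abs(z)), 4.5)
  }
})

test_that("transition models refuse empty or eventless risk sets", {
  coh <- generate_cohort(generator_config(n_individuals = 1000, seed = 6))
  coh$mdd_followup <- coh$mdd_baseline  # nobody transitions
  expect_error(fit_transition_model(coh, "incidence"), "0 events")
  none_ill <- coh[coh$mdd_baseline == 0, ]
  expect_error(fit_transition_model(none_ill, "remittance"), "0 records")
})

test_that("a null education effect is recovered as such", {
  cfg <- benchmark_config(seed = 43)
  cfg$true_hazards$incidence$education_years <- 0
  coh <- impute_factors(generate_cohort(cfg), seed = 2)
  m <- fit_transition_model(coh, "incidence", bands = cfg$bands)
  sm <- summary(m$fit)$coefficients
  expect_lt(abs(sm["education_years", "Estimate"]),
            3 * sm["education_years", "Std. Error"])
})

test_that("built rate tables recover known hazards in every band", {
  cfg <- benchmark_config(seed = 1)
  coh <- impute_factors(generate_cohort(cfg), seed = 2)
  tru <- true_rate_table(cfg)
  est <- estimate_table(coh, cfg$bands)
  expect_true(all(abs(est$incidence / tru$incidence - 1) < 0.10))
  expect_true(all(abs(est$remittance / tru$remittance - 1) < 0.10))
  expect_equal(est$provenance, "empirical")
})

test_that("a cohort covering only part of the age axis is rejected by band", {
  cfg <- generator_config(n_individuals = 3000, seed = 12,
                          baseline_age_range = c(18, 40))
  coh <- impute_factors(generate_cohort(cfg), seed = 2)
  expect_error(estimate_table(coh), "no at-risk records")
})

test_that("single-jump conversion understates hazards under heavy masking", {
  # remission within the interval hides incidence events; the two-state
  # inversion corrects for this, the single-jump inversion cannot
  cfg <- benchmark_config(seed = 3)
  coh <- impute_factors(generate_cohort(cfg), seed = 2)
  tru <- true_rate_table(cfg)
  models <- fit_models(coh, cfg$bands)
  prev <- fit_baseline_prevalence(coh, 25)
  sj <- build_rate_table(models, prev, coh, cfg$bands,
                         conversion = "single_jump")
  ts <- build_rate_table(models, prev, coh, cfg$bands)
  expect_true(all(sj$incidence < ts$incidence))
  expect_lt(max(sj$incidence / tru$incidence), 0.9)
})

test_that("stochastic-regression imputation fills factor cells determinately", {
  coh <- generate_cohort(generator_config(n_individuals = 5000, seed = 9,
                                          missing_rate = 0.15))
  imp1 <- impute_factors(coh, seed = 4)
  imp2 <- impute_factors(coh, seed = 4)
  expect_identical(imp1, imp2)
  fac <- setdiff(names(coh), c("id", "sex", "education",
                               "education_years", "age_baseline",
                               "mdd_baseline", "followup_gap",
                               "mdd_followup"))
  expect_true(all(!is.na(imp1[, fac])))
  for (nm in fac)
    expect_true(all(imp1[[nm]] %in% unique(coh[[nm]][!is.na(coh[[nm]])])))
  expect_false(identical(impute_factors(coh, seed = 5)[[fac[1]]],
                         imp1[[fac[1]]]))
})

test_that("participation-to-prevalence ratio flags adequate representation", {
  expect_equal(participation_prevalence_ratio(10, 100, 10, 100),
               list(ratio = 1, adequate = TRUE))
  r <- participation_prevalence_ratio(47, 100, 50, 100)
  expect_equal(r$ratio, 0.94)
  expect_true(r$adequate)
  r3 <- participation_prevalence_ratio(30, 100, 10, 100)
  expect_equal(r3$ratio, 3)
  expect_false(r3$adequate)
  expect_error(participation_prevalence_ratio(5, 100, 0, 100), "zero")
  expect_error(participation_prevalence_ratio(5.5, 100, 10, 100),
               "integers")
  expect_error(participation_prevalence_ratio(101, 100, 10, 100),
               "exceed")
})
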