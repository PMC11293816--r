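test_that("invalid configurations are rejected with the offending field", {
  expect_error(generator_config(p_female = 1.2), "p_female")
  expect_error(generator_config(missing_rate = -0.1), "missing_rate")
  expect_error(generator_config(followup_gap_range = c(0, 2)),
               "followup_gap_range")
  expect_error(
    generator_config(education_years_levels = c(low = 9, high = 16)),
    "education_years_levels")
  expect_error(generator_config(factor_specs = local({
    fs <- default_factor_specs()
    fs$diet$probs$low <- c(0.5, 0.4, 0.4)
    fs
  })), "factor_specs\\$diet")
  expect_error(generator_config(true_hazards = local({
    th <- default_true_hazards()
    th$incidence$log_intercepts <- th$incidence$log_intercepts[-1]
    th
  })), "log_intercepts")
})

test_that("an empty cohort request yields an empty, well-formed table", {
  coh <- generate_cohort(generator_config(n_individuals = 0))
  expect_equal(nrow(coh), 0)
  expect_true(all(c("id", "sex", "education_years", "mdd_baseline",
                    "mdd_followup", "social_contact_quality") %in%
                    names(coh)))
})

test_that("no-dynamics limit: zero hazards and prevalence give an all-zero panel", {
  cfg <- generator_config(
    n_individuals = 2000, seed = 3,
    true_hazards = local({
      th <- default_true_hazards()
      th$incidence$log_intercepts <- rep(-Inf, 10)
      th$remittance$log_intercepts <- rep(-Inf, 10)
      th
    }),
    baseline_prevalence_coefs = c(intercept = -Inf, female = 0,
                                  education_years = 0, age = 0))
  coh <- generate_cohort(cfg)
  expect_true(all(coh$mdd_baseline == 0))
  expect_true(all(coh$mdd_followup == 0))
})

test_that("cohorts are bit-identical given config and seed", {
  cfg <- generator_config(n_individuals = 3000, seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cfg
  cfg2$seed <- 100
  expect_false(identical(generate_cohort(cfg)$mdd_followup,
                         generate_cohort(cfg2)$mdd_followup))
})

test_that("factor draws match their education-conditional distributions", {
  cfg <- generator_config(n_individuals = 50000, seed = 21,
                          missing_rate = 0)
  coh <- generate_cohort(cfg)
  for (nm in c("social_contact_quality", "smoking", "health_literacy")) {
    for (lev in c("low", "high")) {
      x <- coh[[nm]][coh$education == lev]
      p <- cfg$factor_specs[[nm]]$probs[[lev]]
      obs <- tabulate(x + 1, nbins = length(p))
      expect_gt(stats::chisq.test(obs, p = p)$p.value, 0.01)
    }
  }
})

test_that("follow-up states agree with the closed-form two-state solution", {
  # flat hazards with no covariate effects: every record shares
  # (lambda, mu), so the interval outcome has an exact analytic law
  lam <- 0.08
  mu <- 0.35
  cfg <- generator_config(
    n_individuals = 50000, seed = 7, missing_rate = 0,
    true_hazards = list(
      incidence = list(log_intercepts = rep(log(lam), 10), female = 0,
                       education_years = 0, factors = list()),
      remittance = list(log_intercepts = rep(log(mu), 10), female = 0,
                        education_years = 0, factors = list())),
    baseline_prevalence_coefs = c(intercept = -2, female = 0,
                                  education_years = 0, age = 0))
  coh <- generate_cohort(cfg)
  theta <- lam + mu
  free <- coh[coh$mdd_baseline == 0, ]
  p01 <- (lam / theta) * (1 - exp(-theta * free$followup_gap))
  se <- sqrt(sum(p01 * (1 - p01))) / nrow(free)
  expect_lt(abs(mean(free$mdd_followup) - mean(p01)), 3 * se)
  ill <- coh[coh$mdd_baseline == 1, ]
  p11 <- 1 - (mu / theta) * (1 - exp(-theta * ill$followup_gap))
  se11 <- sqrt(sum(p11 * (1 - p11))) / nrow(ill)
  expect_lt(abs(mean(ill$mdd_followup) - mean(p11)), 3 * se11)
})

test_that("missingness masks factor cells at the configured MCAR rate", {
  cfg <- generator_config(n_individuals = 20000, seed = 13,
                          missing_rate = 0.1)
  coh <- generate_cohort(cfg)
  fr <- colMeans(is.na(coh[, names(cfg$factor_specs)]))
  expect_true(all(abs(fr - 0.1) < 3 * sqrt(0.1 * 0.9 / 20000)))
  expect_true(all(!is.na(coh$mdd_baseline)))
})

test_that("true_rate_table reproduces hand-evaluated linear predictors", {
  cfg <- generator_config(n_individuals = 10)
  tr <- true_rate_table(cfg)
  th <- cfg$true_hazards$incidence
  fs <- cfg$factor_specs
  # female_low, first band, by hand
  lp <- th$log_intercepts[1] + th$female + th$education_years * (10 - 13) +
    th$factors$social_contact_quality *
      sum(0:2 * fs$social_contact_quality$probs$low) +
    th$factors$health_literacy *
      sum(0:2 * fs$health_literacy$probs$low) +
    sum(th$factors$smoking * fs$smoking$probs$low)
  expect_equal(tr$incidence[1, "female_low"], exp(lp), tolerance = 1e-12)

  # constant-hazard configuration: 0.02 in every cell
  flat <- generator_config(true_hazards = list(
    incidence = list(log_intercepts = rep(log(0.02), 10), female = 0,
                     education_years = 0, factors = list()),
    remittance = list(log_intercepts = rep(log(0.3), 10), female = 0,
                      education_years = 0, factors = list())))
  expect_true(all(abs(true_rate_table(flat)$incidence - 0.02) < 1e-12))

  # no education effect anywhere: low and high columns coincide
  noedu <- generator_config(
    factor_specs = local({
      fs <- default_factor_specs()
      for (nm in names(fs)) fs[[nm]]$probs$low <- fs[[nm]]$probs$high
      fs
    }),
    true_hazards = local({
      th <- default_true_hazards()
      th$incidence$education_years <- 0
      th$remittance$education_years <- 0
      th
    }))
  tn <- true_rate_table(noedu)
  expect_equal(tn$incidence[, "female_low"], tn$incidence[, "female_high"])
  expect_equal(tn$remittance[, "male_low"], tn$remittance[, "male_high"])
})

test_that("configuration YAML round trip preserves the generated cohort", {
  cfg <- generator_config(n_individuals = 500, seed = 8)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  cfg2 <- read_generator_config(path)
  expect_equal(generate_cohort(cfg), generate_cohort(cfg2),
               ignore_attr = TRUE)
})

test_that("cohort CSV round trip preserves records", {
  coh <- generate_cohort(generator_config(n_individuals = 200, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(coh),
               ignore_attr = TRUE)
  expect_equal(attr(back, "factor_types")[["smoking"]], "categorical")
})
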