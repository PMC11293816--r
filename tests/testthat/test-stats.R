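test_that("life-course summaries match hand-computed toy cases", {
  # one individual, healthy throughout
  lc0 <- toy_life_courses("healthy", list(NULL))
  s0 <- summarize_life_courses(lc0)
  expect_equal(s0$life_course_prevalence, 0)
  expect_equal(s0$n_ever, 0)
  expect_true(is.na(s0$mean_age_onset))
  expect_true(is.na(s0$mean_duration))

  # one individual entering MDD at 30 and remitting at 33
  lc1 <- toy_life_courses("healthy", list(
    data.frame(age = c(30, 33), state = c("mdd", "healthy"))))
  s1 <- summarize_life_courses(lc1)
  expect_equal(s1$life_course_prevalence, 100)
  expect_equal(s1$mean_age_onset, 30)
  expect_equal(s1$mean_duration, 3)

  # an individual starting in MDD contributes to prevalence and duration
  # but never to onset
  lc2 <- toy_life_courses(
    c("mdd", "healthy"),
    list(data.frame(age = 20, state = "healthy"),
         data.frame(age = c(40, 45), state = c("mdd", "healthy"))))
  s2 <- summarize_life_courses(lc2)
  expect_equal(s2$life_course_prevalence, 100)
  expect_equal(s2$mean_age_onset, 40)   # prevalent case excluded
  expect_equal(s2$mean_duration, (2 + 5) / 2)

  # multiple episodes accumulate duration
  lc3 <- toy_life_courses("healthy", list(
    data.frame(age = c(25, 26, 60, 62), state = c("mdd", "healthy",
                                                  "mdd", "healthy"))))
  expect_equal(summarize_life_courses(lc3)$mean_duration, 3)
})

test_that("mean duration among the ever-ill matches the conditional oracle", {
  rt <- constant_rate_table(0.1, 0.4, prevalence_at_18 = 0)
  sim <- run_simulation(rt, simulation_settings(50000, seed = 29),
                        strata = "male_low")
  s <- summarize_life_courses(sim)
  oracle <- analytic_mdd_years(rt, "male_low") /
    analytic_ever_probability(rt, "male_low")
  dur <- sim$individuals$mdd_years[sim$individuals$ever_mdd]
  expect_lt(abs(s$mean_duration - oracle),
            3 * stats::sd(dur) / sqrt(length(dur)))
})

test_that("age-specific prevalence is bounded by life-course prevalence and tracks the oracle", {
  rt <- random_rate_table(55)
  sim <- run_simulation(rt, simulation_settings(20000, seed = 31))
  s <- summarize_life_courses(sim)
  asp <- age_specific_prevalence(sim)
  for (st in strata_table()$stratum) {
    p <- asp$prevalence[asp$stratum == st]
    expect_true(all(p <= s$life_course_prevalence[s$stratum == st] / 100 +
                      1e-12))
    oracle <- analytic_state_probability(rt, st, 18:65)
    se <- sqrt(pmax(oracle * (1 - oracle), 1e-12) / 20000)
    expect_true(all(abs(p - oracle) < 4.5 * se + 1e-12))
  }
})

test_that("education gaps reproduce the published arithmetic", {
  rep_tab <- reported_lifecourse_estimates()
  f <- rep_tab[rep_tab$sex == "female", ]
  g <- inequality_gaps(f[f$education == "low", ],
                       f[f$education == "high", ])
  expect_equal(g$gap[g$outcome == "prevalence"], 20.8)
  m <- rep_tab[rep_tab$sex == "male", ]
  gm <- inequality_gaps(m[m$education == "low", ],
                        m[m$education == "high", ])
  expect_equal(gm$gap[gm$outcome == "onset"], 0.9, tolerance = 1e-12)
  same <- inequality_gaps(f[f$education == "low", ],
                          f[f$education == "low", ])
  expect_true(all(same$gap == 0))
  expect_error(inequality_gaps(f[f$education == "low", ],
                               m[m$education == "high", ]), "one sex")
})

test_that("gap reductions are exact at their fixed points", {
  expect_equal(gap_reduction(20.8, 20.8), 0)
  expect_equal(gap_reduction(1, 0), 100)
  expect_equal(gap_reduction(0.9, 0.45), 50)
  expect_equal(gap_reduction(2, 3), -50)
  expect_error(gap_reduction(0, 1), "zero")
})

test_that("sex pooling is the unweighted mean under equal stratum sizes", {
  expect_equal(pooled_summary(35.3, 28.6), 31.95)
  expect_equal(round_half_up(pooled_summary(35.3, 28.6)), 32.0)
  expect_equal(round_half_up(pooled_summary(14.5, 11.3)), 12.9)
  expect_equal(pooled_summary(7, 7), 7)
  expect_error(pooled_summary(1, 2, n_female = 10, n_male = 20),
               "weights")
})

test_that("reported statistics round half away from zero", {
  expect_equal(round_half_up((20.8 + 17.3) / 2), 19.1)
  expect_equal(round_half_up((26.7 + 30.4) / 2), 28.6)
  expect_equal(round_half_up(2.45), 2.5)
  expect_equal(round_half_up(-0.85), -0.9)
  expect_equal(round_half_up(1.04), 1.0)
  expect_equal(round_half_up(123.456, 2), 123.46)
})

test_that("Monte Carlo SE is zero for deterministic dynamics and shrinks as 1/sqrt(n)", {
  rt0 <- constant_rate_table(0, 0, prevalence_at_18 = 0)
  prev_stat <- function(lc)
    summarize_life_courses(lc)$life_course_prevalence[1]
  se0 <- monte_carlo_se(rt0, simulation_settings(500, seed = 2), 3,
                        prev_stat)
  expect_equal(se0, 0)
  rt <- constant_rate_table(0.02, 0.35, prevalence_at_18 = 0.05)
  se_small <- monte_carlo_se(rt, simulation_settings(2000, seed = 3), 12,
                             prev_stat)
  se_big <- monte_carlo_se(rt, simulation_settings(32000, seed = 4), 12,
                           prev_stat)
  # true ratio 4; replicate noise leaves a broad but conclusive window
  expect_gt(se_small / se_big, 1.6)
  expect_lt(se_small / se_big, 10)
  # binomial bound at this size
  expect_lt(se_big, 3 * sqrt(0.5 * 0.5 / 32000) * 100)
})

test_that("raising incidence increases prevalence and advances onset", {
  lo <- constant_rate_table(0.01, 0.4, prevalence_at_18 = 0.02)
  hi <- constant_rate_table(0.05, 0.4, prevalence_at_18 = 0.02)
  st <- simulation_settings(20000, seed = 41)
  s_lo <- summarize_life_courses(run_simulation(lo, st))
  s_hi <- summarize_life_courses(run_simulation(hi, st))
  expect_true(all(s_hi$life_course_prevalence >
                    s_lo$life_course_prevalence))
  expect_true(all(s_hi$mean_age_onset < s_lo$mean_age_onset))
})

test_that("life-course export writes one row per event plus the initial state", {
  rt <- constant_rate_table(0.3, 0.5, prevalence_at_18 = 0.5)
  sim <- run_simulation(rt, simulation_settings(50, seed = 13))
  path <- withr::local_tempfile(fileext = ".csv")
  write_life_courses(sim, path)
  ev <- utils::read.csv(path)
  expect_equal(nrow(ev), 200 + nrow(sim$transitions))
  expect_true(all(ev$state %in% c("healthy", "mdd")))
})
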