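#' Counterfactual scenario
#'
#' Names the modifiable factors whose low-education distribution is to be
#' replaced by the high-education distribution: one factor per scenario
#' for single-factor effects, or all selected factors at once for the
#' joint effect.
#'
#' @param name Scenario label.
#' @param swapped_factors Non-empty character vector of factor names.
#' @return A `scenario` object.
#' @export
scenario <- function(name, swapped_factors) {
  if (length(swapped_factors) < 1)
    stop("scenario must swap at least one factor", call. = FALSE)
  structure(list(name = name,
                 swapped_factors = unique(swapped_factors)),
            class = "scenario")
}

#' Read a scenario list from YAML
#'
#' Expects a sequence of maps with `name` and `swapped_factors` keys.
#'
#' @param path YAML file path.
#' @return List of `scenario` objects.
#' @export
read_scenarios <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(x) scenario(x$name, unlist(x$swapped_factors)))
}

# swap the scenario's factor columns in the low-education rows with joint
# rows resampled from the high-education group of the same sex
swap_factor_rows <- function(cohort, swapped_factors, seed) {
  out <- cohort
  withr::with_seed(seed, {
    for (sx in c("female", "male")) {
      low <- which(cohort$education == "low" & cohort$sex == sx)
      high <- which(cohort$education == "high" & cohort$sex == sx)
      if (!length(low)) next
      if (!length(high))
        stop("no high-education donors for sex ", sx, call. = FALSE)
      donor <- high[sample.int(length(high), length(low), replace = TRUE)]
      for (nm in swapped_factors)
        out[[nm]][low] <- cohort[[nm]][donor]
    }
  })
  out
}

#' Counterfactual rate table for the low-education group
#'
#' Marginal standardization (g-computation style): the fitted transition
#' models are re-averaged over a counterfactual covariate distribution in
#' which the low-education records' swapped factors are replaced by joint
#' rows resampled (with a fixed seed) from the same-sex high-education
#' group -- preserving the swapped factors' correlation -- while all other
#' covariates keep their observed low-education values. High-education
#' strata are untouched. Prevalence at age 18 is not counterfactually
#' altered.
#'
#' @param cohort A panel cohort (factor cells imputed).
#' @param models Fitted `incidence`/`remittance` models including the
#'   scenario's factors as covariates.
#' @param scen A [scenario()].
#' @param baseline Per-stratum prevalence at 18.
#' @param bands Age bands.
#' @param seed Seed of the factor resampling.
#' @param conversion Probability-to-hazard conversion, see
#'   [build_rate_table()].
#' @return A `rate_table` with provenance `"counterfactual:<factors>"`.
#' @export
counterfactual_rate_table <- function(cohort, models, scen, baseline,
                                      bands = age_bands(), seed = 1L,
                                      conversion = "two_state") {
  stopifnot(inherits(scen, "scenario"))
  missing_cohort <- setdiff(scen$swapped_factors, factor_columns(cohort))
  if (length(missing_cohort))
    stop("scenario factors not in cohort: ",
         paste(missing_cohort, collapse = ", "), call. = FALSE)
  for (dir in c("incidence", "remittance")) {
    absent <- setdiff(scen$swapped_factors,
                      models[[dir]]$extra_covariates)
    if (length(absent))
      stop("factor(s) ", paste(absent, collapse = ", "),
           " absent from the ", dir, " model", call. = FALSE)
  }
  cf <- swap_factor_rows(cohort, scen$swapped_factors, seed)
  build_rate_table(
    models, baseline, cf, bands, conversion,
    provenance = paste0("counterfactual:",
                        paste(scen$swapped_factors, collapse = "+")))
}

#' Run baseline and counterfactual simulations
#'
#' Builds the empirical (baseline) rate table plus one counterfactual
#' table per scenario, runs the microsimulation for each with identical
#' settings (same seed and size), and summarises the life courses. The
#' baseline is always included.
#'
#' @inheritParams counterfactual_rate_table
#' @param scenarios List of [scenario()] objects (may be empty).
#' @param settings A [simulation_settings()].
#' @return Named list: `baseline` plus one entry per scenario, each a list
#'   with `rate_table`, `life_courses` (NULL unless `keep_life_courses`)
#'   and `summary` (per-stratum life-course summary tibble).
#' @param keep_life_courses Keep the raw life courses in the result
#'   (memory-heavy at full size).
#' @export
run_scenarios <- function(cohort, models, scenarios, baseline,
                          bands = age_bands(),
                          settings = simulation_settings(),
                          seed = 1L, conversion = "two_state",
                          keep_life_courses = FALSE) {
  base_rt <- build_rate_table(models, baseline, cohort, bands, conversion)
  tables <- c(list(baseline = base_rt),
              stats::setNames(
                lapply(scenarios, function(sc)
                  counterfactual_rate_table(cohort, models, sc, baseline,
                                            bands, seed, conversion)),
                vapply(scenarios, `[[`, character(1), "name")))
  lapply(tables, function(rt) {
    lc <- run_simulation(rt, settings)
    list(rate_table = rt,
         life_courses = if (keep_life_courses) lc else NULL,
         summary = summarize_life_courses(lc))
  })
}
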