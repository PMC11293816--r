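#' Default modifiable-factor specifications
#'
#' Nine modifiable factors with education-conditional categorical/ordinal
#' distributions: combined occupational and leisure-time moderate-to-vigorous
#' physical activity (`mvpa`), smoking (never/former/current, entering
#' models as two indicators), alcohol intake, diet quality, sleep duration,
#' network size, quality of social contacts, partner status and health
#' literacy. Ordinal factors are coded 0/1/2 (or 0/1 for partner status)
#' and enter linear predictors linearly; categorical factors enter as level
#' indicators. Probabilities are education-graded: the low-education group
#' has less favourable profiles, most markedly for quality of social
#' contacts, health literacy and smoking.
#'
#' @return Named list of factor specifications, each with `type`
#'   (`"ordinal"` or `"categorical"`), integer `levels`, and per-education
#'   probability vectors `probs$low`, `probs$high` (each summing to 1).
#' @export
default_factor_specs <- function() {
  spec <- function(type, levels, low, high)
    list(type = type, levels = levels, probs = list(low = low, high = high))
  list(
    mvpa = spec("ordinal", 0:2, c(0.35, 0.40, 0.25), c(0.25, 0.40, 0.35)),
    smoking = spec("categorical", 0:2,
                   c(0.35, 0.25, 0.40), c(0.55, 0.30, 0.15)),
    alcohol = spec("ordinal", 0:2, c(0.30, 0.50, 0.20), c(0.20, 0.60, 0.20)),
    diet = spec("ordinal", 0:2, c(0.45, 0.35, 0.20), c(0.25, 0.40, 0.35)),
    sleep = spec("ordinal", 0:2, c(0.25, 0.35, 0.40), c(0.15, 0.35, 0.50)),
    network_size = spec("ordinal", 0:2,
                        c(0.40, 0.35, 0.25), c(0.25, 0.35, 0.40)),
    social_contact_quality = spec("ordinal", 0:2,
                                  c(0.45, 0.35, 0.20), c(0.20, 0.35, 0.45)),
    partner = spec("ordinal", 0:1, c(0.35, 0.65), c(0.25, 0.75)),
    health_literacy = spec("ordinal", 0:2,
                           c(0.50, 0.35, 0.15), c(0.15, 0.35, 0.50)))
}

#' Default ground-truth hazard coefficients
#'
#' Log-hazard models for incidence and remittance: one intercept per age
#' band (incidence declines with age, remittance roughly constant), a
#' female indicator, a per-year education slope (education centred at 13
#' years, the midpoint of the 10- vs 16-year comparison), and coefficients
#' for the three effect-carrying modifiable factors. A scalar factor
#' coefficient is an ordinal slope; a named per-level vector gives
#' categorical level effects.
#'
#' @param bands Band boundaries from [age_bands()].
#' @return List with `incidence` and `remittance` coefficient sets.
#' @export
default_true_hazards <- function(bands = age_bands()) {
  k <- n_bands(validate_bands(bands))
  inc_int <- seq(-4.75, by = -0.14, length.out = k)
  list(
    incidence = list(
      log_intercepts = inc_int,
      female = 0.30,
      education_years = -0.12,
      factors = list(
        social_contact_quality = -0.18,
        health_literacy = -0.10,
        smoking = c(`0` = 0, `1` = 0.05, `2` = 0.25))),
    remittance = list(
      log_intercepts = rep(log(0.28), k),
      female = -0.05,
      education_years = 0.03,
      factors = list(social_contact_quality = 0.08)))
}

#' Power-designed configurations for estimator validation
#'
#' Two generator configurations designed by a power calculation (not by
#' the disease model) so that a 50000-record cohort pins down the
#' quantities each validation check compares. At realistic MDD rates such
#' a cohort yields only ~140 incidence events per 5-year band -- far too
#' few for tight tolerances -- so both use elevated rates and three wide
#' age bands, with small covariate effects so the logistic working model
#' is close to correctly specified.
#'
#' `benchmark_config()` targets per-band hazard recovery: incidence and
#' remittance ~0.3/yr, ~50% baseline prevalence and 1.5-2.5 year gaps
#' give several thousand events per band and direction, so the per-cell
#' hazard standard error (~2.5%, after the roughly threefold noise
#' amplification of the interval-probability inversion) puts a 10%
#' recovery tolerance at about four standard errors. Lifetime prevalence
#' saturates at these rates, so the estimate-then-simulate round trip is
#' instead validated by `roundtrip_config()`: incidence ~0.06/yr keeps
#' the life-course prevalence unsaturated (~93%) while ~30% baseline
#' prevalence keeps the remittance risk set large; the round-trip
#' life-course prevalence is then reproducible to a few tenths of a
#' percentage point.
#'
#' @param n_individuals,seed Passed to [generator_config()].
#' @param bands Age bands (default three 15-16 year bands).
#' @return A `generator_config`.
#' @export
benchmark_config <- function(n_individuals = 50000L, seed = 1L,
                             bands = age_bands(16)) {
  k <- n_bands(validate_bands(bands))
  generator_config(
    n_individuals = n_individuals, seed = seed,
    followup_gap_range = c(1.5, 2.5),
    true_hazards = list(
      incidence = list(
        log_intercepts = seq(log(0.30), by = -0.03, length.out = k),
        female = 0.10,
        education_years = -0.03,
        factors = list()),
      remittance = list(
        log_intercepts = rep(log(0.30), k),
        female = -0.05,
        education_years = 0.015,
        factors = list())),
    baseline_prevalence_coefs = c(intercept = 0, female = 0.10,
                                  education_years = -0.05, age = 0),
    bands = bands)
}

#' @rdname benchmark_config
#' @export
roundtrip_config <- function(n_individuals = 50000L, seed = 1L,
                             bands = age_bands(16)) {
  k <- n_bands(validate_bands(bands))
  generator_config(
    n_individuals = n_individuals, seed = seed,
    followup_gap_range = c(2, 3),
    true_hazards = list(
      incidence = list(
        log_intercepts = seq(log(0.06), by = -0.01, length.out = k),
        female = 0.10,
        education_years = -0.03,
        factors = list()),
      remittance = list(
        log_intercepts = rep(log(0.30), k),
        female = -0.05,
        education_years = 0.015,
        factors = list())),
    baseline_prevalence_coefs = c(intercept = -0.85, female = 0.10,
                                  education_years = -0.05, age = 0),
    bands = bands)
}

#' Synthetic-cohort generator configuration
#'
#' Defines the two-wave panel the generator emulates: stratum composition,
#' education-conditional modifiable-factor distributions, ground-truth
#' age-banded log-hazard coefficients for MDD incidence and remittance, a
#' logistic model for MDD prevalence at baseline, irregular follow-up gaps
#' and MCAR missingness in factor cells.
#'
#' @param n_individuals Number of panel records.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   configuration and this seed.
#' @param p_female Probability a record is female.
#' @param p_low_education Probability of low (10-year) education.
#' @param education_years_levels Named years for the two compared levels;
#'   must be exactly `c(low = 10, high = 16)`.
#' @param baseline_age_range Uniform range of baseline ages (years).
#' @param followup_gap_range Uniform range of follow-up gaps (years),
#'   minimum strictly positive.
#' @param factor_specs Modifiable-factor distributions, see
#'   [default_factor_specs()].
#' @param true_hazards Ground-truth hazard coefficients, see
#'   [default_true_hazards()].
#' @param baseline_prevalence_coefs Named logistic coefficients for MDD at
#'   baseline: `intercept` (at age 18, 13 education years, male), `female`,
#'   `education_years` (per year, centred at 13), `age` (per year above
#'   18), plus optional factor-named terms.
#' @param missing_rate Probability each factor cell is masked (MCAR).
#' @param bands Age bands of the ground-truth hazards.
#' @return A validated `generator_config` object.
#' @export
generator_config <- function(n_individuals = 50000L,
                             seed = 1L,
                             p_female = 0.58,
                             p_low_education = 0.5,
                             education_years_levels = c(low = 10, high = 16),
                             baseline_age_range = c(18, 65),
                             followup_gap_range = c(2, 5),
                             factor_specs = default_factor_specs(),
                             true_hazards = default_true_hazards(bands),
                             baseline_prevalence_coefs = c(
                               intercept = -3.1, female = 0.35,
                               education_years = -0.10, age = 0.012),
                             missing_rate = 0.05,
                             bands = age_bands()) {
  cfg <- structure(
    list(n_individuals = as.integer(n_individuals), seed = as.numeric(seed),
         p_female = p_female, p_low_education = p_low_education,
         education_years_levels = education_years_levels,
         baseline_age_range = baseline_age_range,
         followup_gap_range = followup_gap_range,
         factor_specs = factor_specs, true_hazards = true_hazards,
         baseline_prevalence_coefs = baseline_prevalence_coefs,
         missing_rate = missing_rate,
         bands = as.numeric(validate_bands(bands))),
    class = "generator_config")
  validate_generator_config(cfg)
}

config_error <- function(field, msg)
  stop("invalid generator configuration: field '", field, "' ", msg,
       call. = FALSE)

validate_generator_config <- function(cfg) {
  prob_ok <- function(p) is.numeric(p) && length(p) == 1 &&
    is.finite(p) && p >= 0 && p <= 1
  if (is.na(cfg$n_individuals) || cfg$n_individuals < 0)
    config_error("n_individuals", "must be a non-negative count")
  if (!prob_ok(cfg$p_female)) config_error("p_female", "must be in [0, 1]")
  if (!prob_ok(cfg$p_low_education))
    config_error("p_low_education", "must be in [0, 1]")
  if (!prob_ok(cfg$missing_rate))
    config_error("missing_rate", "must be in [0, 1]")
  ey <- cfg$education_years_levels
  if (!identical(sort(names(ey)), c("high", "low")) ||
      ey[["low"]] != 10 || ey[["high"]] != 16)
    config_error("education_years_levels",
                 "must be exactly c(low = 10, high = 16)")
  ar <- cfg$baseline_age_range
  if (length(ar) != 2 || ar[1] < 18 || ar[2] > 65 || ar[1] > ar[2])
    config_error("baseline_age_range", "must lie within [18, 65]")
  gr <- cfg$followup_gap_range
  if (length(gr) != 2 || gr[1] <= 0 || gr[1] > gr[2])
    config_error("followup_gap_range",
                 "must have 0 < min <= max (years)")
  k <- n_bands(cfg$bands)
  for (nm in names(cfg$factor_specs)) {
    fs <- cfg$factor_specs[[nm]]
    if (!fs$type %in% c("ordinal", "categorical"))
      config_error(paste0("factor_specs$", nm), "has unknown type")
    for (lev in c("low", "high")) {
      p <- fs$probs[[lev]]
      if (length(p) != length(fs$levels) || any(p < 0) ||
          abs(sum(p) - 1) > 1e-8)
        config_error(paste0("factor_specs$", nm),
                     paste0("probabilities for education '", lev,
                            "' must be non-negative and sum to 1"))
    }
  }
  for (dir in c("incidence", "remittance")) {
    th <- cfg$true_hazards[[dir]]
    if (length(th$log_intercepts) != k)
      config_error(paste0("true_hazards$", dir, "$log_intercepts"),
                   sprintf("must have one value per age band (%d)", k))
    unknown <- setdiff(names(th$factors), names(cfg$factor_specs))
    if (length(unknown))
      config_error(paste0("true_hazards$", dir, "$factors"),
                   paste("names unknown factor(s):",
                         paste(unknown, collapse = ", ")))
  }
  cfg
}

#' Read / write a generator configuration as YAML
#'
#' @param cfg A `generator_config`.
#' @param path YAML file path.
#' @return `read_generator_config()` returns a validated
#'   `generator_config`.
#' @export
write_generator_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "generator_config"))
  out <- unclass(cfg)
  # yaml drops names on atomic vectors; keep named entries as maps
  out$education_years_levels <- as.list(out$education_years_levels)
  out$baseline_prevalence_coefs <- as.list(out$baseline_prevalence_coefs)
  for (dir in c("incidence", "remittance"))
    out$true_hazards[[dir]]$factors <-
      lapply(out$true_hazards[[dir]]$factors, function(co)
        if (length(co) > 1) as.list(co) else co)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$education_years_levels <- unlist(raw$education_years_levels)
  raw$baseline_prevalence_coefs <- unlist(raw$baseline_prevalence_coefs)
  raw$baseline_age_range <- as.numeric(unlist(raw$baseline_age_range))
  raw$followup_gap_range <- as.numeric(unlist(raw$followup_gap_range))
  raw$bands <- as.numeric(unlist(raw$bands))
  raw$factor_specs <- lapply(raw$factor_specs, function(fs) {
    fs$levels <- as.numeric(unlist(fs$levels))
    fs$probs <- lapply(fs$probs, function(p) as.numeric(unlist(p)))
    fs
  })
  for (dir in c("incidence", "remittance")) {
    raw$true_hazards[[dir]]$log_intercepts <-
      as.numeric(unlist(raw$true_hazards[[dir]]$log_intercepts))
    raw$true_hazards[[dir]]$factors <-
      lapply(raw$true_hazards[[dir]]$factors, unlist)
  }
  do.call(generator_config, raw)
}
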