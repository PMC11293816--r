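# contribution of one factor to a linear predictor: scalar coefficient =
# ordinal slope; named per-level vector = categorical level effects
factor_contribution <- function(values, coef) {
  if (length(coef) == 1) return(unname(coef) * values)
  out <- unname(coef[as.character(values)])
  out[is.na(values)] <- NA_real_
  out
}

# sex/education/factor part of a ground-truth log-hazard linear predictor
# (everything except the per-band intercept)
hazard_lp_base <- function(df, th) {
  lp <- th$female * (df$sex == "female") +
    th$education_years * (df$education_years - EDUCATION_CENTER)
  for (nm in names(th$factors))
    lp <- lp + factor_contribution(df[[nm]], th$factors[[nm]])
  lp
}

baseline_lp <- function(df, coefs, age) {
  lp <- coefs[["intercept"]] +
    coefs[["female"]] * (df$sex == "female") +
    coefs[["education_years"]] * (df$education_years - EDUCATION_CENTER)
  if ("age" %in% names(coefs)) lp <- lp + coefs[["age"]] * (age - 18)
  extra <- setdiff(names(coefs),
                   c("intercept", "female", "education_years", "age"))
  for (nm in extra) lp <- lp + coefs[[nm]] * df[[nm]]
  lp
}

empty_cohort <- function(factor_names) {
  base <- tibble::tibble(
    id = integer(), sex = character(), education = character(),
    education_years = numeric(), age_baseline = numeric(),
    mdd_baseline = integer(), followup_gap = numeric(),
    mdd_followup = integer())
  for (nm in factor_names) base[[nm]] <- numeric()
  base
}

#' Generate a synthetic two-wave panel cohort
#'
#' Draws covariates from education-conditional distributions, baseline MDD
#' status from the configured logistic model at the baseline age, and the
#' follow-up MDD status by exact event-history simulation of the
#' ground-truth two-state process over each record's follow-up gap --
#' possibly multiple transitions within the gap, so that estimation has to
#' recover hazards rather than single-jump probabilities. Factor cells are
#' then masked completely at random at `missing_rate`. Deterministic given
#' the configuration seed.
#'
#' @param config A [generator_config()].
#' @return A tibble of panel records (`id`, `sex`, `education`,
#'   `education_years`, `age_baseline`, `mdd_baseline`, `followup_gap`,
#'   `mdd_followup`, one column per modifiable factor), with attributes
#'   `factor_types`, `factor_levels` and `generator_config`.
#' @export
generate_cohort <- function(config) {
  cfg <- validate_generator_config(config)
  n <- cfg$n_individuals
  factor_names <- names(cfg$factor_specs)
  if (n == 0L) return(empty_cohort(factor_names))

  df <- withr::with_seed(cfg$seed, {
    sex <- ifelse(stats::runif(n) < cfg$p_female, "female", "male")
    education <- ifelse(stats::runif(n) < cfg$p_low_education,
                        "low", "high")
    out <- tibble::tibble(
      id = seq_len(n), sex = sex, education = education,
      education_years = unname(cfg$education_years_levels[education]),
      age_baseline = stats::runif(n, cfg$baseline_age_range[1],
                                  cfg$baseline_age_range[2]),
      followup_gap = stats::runif(n, cfg$followup_gap_range[1],
                                  cfg$followup_gap_range[2]))
    for (nm in factor_names) {
      fs <- cfg$factor_specs[[nm]]
      val <- integer(n)
      for (lev in c("low", "high")) {
        sel <- education == lev
        if (any(sel))
          val[sel] <- sample(fs$levels, sum(sel), replace = TRUE,
                             prob = fs$probs[[lev]])
      }
      out[[nm]] <- val
    }
    p0 <- stats::plogis(baseline_lp(out, cfg$baseline_prevalence_coefs,
                                    out$age_baseline))
    out$mdd_baseline <- as.integer(stats::runif(n) < p0)
    # MCAR mask, drawn before leaving the seeded block
    out_mask <- matrix(stats::runif(n * length(factor_names)) <
                         cfg$missing_rate, n)
    attr(out, "mcar_mask") <- out_mask
    out
  })

  k <- n_bands(cfg$bands)
  inc_mat <- exp(outer(hazard_lp_base(df, cfg$true_hazards$incidence),
                       cfg$true_hazards$incidence$log_intercepts, "+"))
  rem_mat <- exp(outer(hazard_lp_base(df, cfg$true_hazards$remittance),
                       cfg$true_hazards$remittance$log_intercepts, "+"))
  stopifnot(ncol(inc_mat) == k)
  df$mdd_followup <- as.integer(cpp_simulate_interval(
    cfg$bands, inc_mat, rem_mat, df$age_baseline, df$followup_gap,
    as.integer(df$mdd_baseline), cfg$seed, 0))

  mask <- attr(df, "mcar_mask")
  attr(df, "mcar_mask") <- NULL
  for (j in seq_along(factor_names))
    df[[factor_names[j]]][mask[, j]] <- NA_real_

  df <- df[, c("id", "sex", "education", "education_years", "age_baseline",
               "mdd_baseline", "followup_gap", "mdd_followup",
               factor_names)]
  attr(df, "factor_types") <-
    vapply(cfg$factor_specs, `[[`, character(1), "type")
  attr(df, "factor_levels") <- lapply(cfg$factor_specs, `[[`, "levels")
  attr(df, "generator_config") <- cfg
  df
}

#' Ground-truth rate table implied by a generator configuration
#'
#' Evaluates the configured log-hazard models at each stratum's expected
#' factor profile: ordinal factors at their mean level, categorical factors
#' at their probability-weighted level effects. Together with the
#' baseline-prevalence model predicted at age 18, this yields the exact
#' stratum-by-band hazard table that parameter-recovery tests compare
#' against.
#'
#' @param config A [generator_config()].
#' @return A `rate_table` with provenance `"ground_truth"`.
#' @export
true_rate_table <- function(config) {
  cfg <- validate_generator_config(config)
  k <- n_bands(cfg$bands)
  inc <- rem <- matrix(NA_real_, k, 4,
                       dimnames = list(NULL, STRATA$stratum))
  prev <- numeric(4)
  names(prev) <- STRATA$stratum
  for (i in seq_len(nrow(STRATA))) {
    s <- STRATA$stratum[i]
    edu <- STRATA$education[i]
    for (dir in c("incidence", "remittance")) {
      th <- cfg$true_hazards[[dir]]
      lp <- th$female * (STRATA$sex[i] == "female") +
        th$education_years *
          (cfg$education_years_levels[[edu]] - EDUCATION_CENTER)
      for (nm in names(th$factors)) {
        fs <- cfg$factor_specs[[nm]]
        co <- th$factors[[nm]]
        lp <- lp + if (length(co) == 1)
          unname(co) * sum(fs$levels * fs$probs[[edu]])
        else
          sum(unname(co[as.character(fs$levels)]) * fs$probs[[edu]])
      }
      h <- exp(th$log_intercepts + lp)
      if (dir == "incidence") inc[, s] <- h else rem[, s] <- h
    }
    proto <- data.frame(
      sex = STRATA$sex[i],
      education_years = cfg$education_years_levels[[edu]])
    prev[s] <- stats::plogis(
      baseline_lp(proto, cfg$baseline_prevalence_coefs, 18))
  }
  rate_table(cfg$bands, inc, rem, prev, provenance = "ground_truth")
}

#' Read / write a panel cohort as CSV
#'
#' One row per panel record with a header; missing factor cells are empty.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param path CSV path.
#' @param factor_types Optional named character vector (`"ordinal"` /
#'   `"categorical"`) re-attached on read; defaults to ordinal for all
#'   factor columns except `smoking`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, factor_types = NULL) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  fixed <- c("id", "sex", "education", "education_years", "age_baseline",
             "mdd_baseline", "followup_gap", "mdd_followup")
  miss <- setdiff(fixed, names(df))
  if (length(miss))
    stop("cohort CSV lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  fac <- setdiff(names(df), fixed)
  if (is.null(factor_types)) {
    factor_types <- stats::setNames(rep("ordinal", length(fac)), fac)
    if ("smoking" %in% fac) factor_types[["smoking"]] <- "categorical"
  }
  attr(df, "factor_types") <- factor_types
  df
}

factor_columns <- function(cohort) {
  fixed <- c("id", "sex", "education", "education_years", "age_baseline",
             "mdd_baseline", "followup_gap", "mdd_followup")
  setdiff(names(cohort), fixed)
}

factor_types_of <- function(cohort) {
  ft <- attr(cohort, "factor_types")
  fac <- factor_columns(cohort)
  out <- stats::setNames(rep("ordinal", length(fac)), fac)
  if (!is.null(ft)) out[names(ft)[names(ft) %in% fac]] <-
      ft[names(ft) %in% fac]
  out
}
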