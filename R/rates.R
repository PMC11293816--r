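#' Impute missing modifiable-factor values
#'
#' Single stochastic-regression imputation: for each factor column with
#' missing cells, a linear model on sex, education years, baseline age and
#' baseline MDD status is fitted to the observed rows, and missing cells
#' are filled with the prediction plus a residual-scale normal draw,
#' snapped to the nearest valid factor level. Deterministic given `seed`.
#'
#' @param cohort A panel cohort tibble.
#' @param seed Integer seed for the imputation draws.
#' @return The cohort with no missing factor cells.
#' @export
impute_factors <- function(cohort, seed = 1L) {
  fac <- factor_columns(cohort)
  withr::with_seed(seed, {
    for (nm in fac) {
      x <- cohort[[nm]]
      miss <- is.na(x)
      if (!any(miss)) next
      obs <- !miss
      levels_ok <- sort(unique(x[obs]))
      fit <- stats::lm(
        x[obs] ~ sex + education_years + age_baseline + mdd_baseline,
        data = cohort[obs, ])
      pred <- stats::predict(fit, newdata = cohort[miss, ])
      draw <- pred + stats::rnorm(sum(miss), 0, stats::sigma(fit))
      snapped <- levels_ok[pmax(1, pmin(length(levels_ok),
        findInterval(draw, c(-Inf, levels_ok[-1] - diff(levels_ok) / 2))))]
      cohort[[nm]][miss] <- snapped
    }
  })
  cohort
}

#' Estimate MDD prevalence at age 18 per stratum
#'
#' Logistic regression of baseline MDD status on sex, education years and
#' age among the youngest records (baseline age at most `max_age`),
#' predicted for each stratum at age 18; the age term removes the bias of
#' predicting below the window's mean age, so the window can be widened to
#' stabilise the estimate. If the model is degenerate (constant outcome,
#' inestimable coefficients or non-convergence) the estimate falls back to
#' each stratum's empirical proportion, with a warning.
#'
#' @param cohort A panel cohort tibble.
#' @param max_age Upper baseline age of the "youngest" window (default 20).
#' @return Named probability vector over the strata present in the cohort.
#' @export
fit_baseline_prevalence <- function(cohort, max_age = 20) {
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  strata_present <- unique(stratum_id(cohort$sex, cohort$education))
  strata_present <- STRATA$stratum[STRATA$stratum %in% strata_present]
  young <- cohort[cohort$age_baseline <= max_age, ]
  ys <- stratum_id(young$sex, young$education)
  empty <- setdiff(strata_present, unique(ys))
  if (length(empty))
    stop("no records aged <= ", max_age, " in stratum: ",
         paste(empty, collapse = ", "), call. = FALSE)
  empirical <- vapply(strata_present,
                      function(s) mean(young$mdd_baseline[ys == s]),
                      numeric(1))
  out <- NULL
  if (length(unique(young$mdd_baseline)) == 2 &&
      length(unique(young$sex)) == 2 &&
      length(unique(young$education_years)) == 2) {
    young$age_over_18 <- young$age_baseline - 18
    rhs <- c("sex", "education_years",
             if (length(unique(young$age_over_18)) > 1) "age_over_18")
    fit <- tryCatch(
      suppressWarnings(stats::glm(
        stats::reformulate(rhs, response = "mdd_baseline"),
        family = stats::binomial(), data = young)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$converged && !anyNA(stats::coef(fit))) {
      new <- STRATA[STRATA$stratum %in% strata_present, ]
      new$education_years <- EDUCATION_YEARS[new$education]
      new$age_over_18 <- 0
      out <- stats::setNames(
        as.numeric(stats::predict(fit, newdata = new, type = "response")),
        new$stratum)
    }
  }
  if (is.null(out)) {
    if (any(empirical > 0 & empirical < 1))
      warning("baseline prevalence model degenerate; ",
              "using empirical stratum proportions", call. = FALSE)
    out <- empirical
  }
  out
}

# model frame shared by fitting and prediction. The age band is the band
# containing the midpoint of the observation interval: a record observed
# over [a, a + gap] carries information about the hazard around a + gap/2,
# and anchoring on the baseline age instead biases banded hazards by about
# slope * gap/2 when hazards trend with age.
transition_frame <- function(rows, breaks, extra, types,
                             xlevels = NULL) {
  labs <- band_labels(breaks)
  mf <- data.frame(
    age_band = factor(labs[band_index(rows$age_baseline +
                                        rows$followup_gap / 2, breaks)],
                      levels = labs),
    sex = factor(rows$sex, levels = c("male", "female")),
    education_years = as.numeric(rows$education_years),
    log_gap = log(as.numeric(rows$followup_gap)))
  for (nm in extra) {
    if (identical(types[[nm]], "categorical")) {
      lev <- if (!is.null(xlevels) && nm %in% names(xlevels))
        xlevels[[nm]] else sort(unique(rows[[nm]]))
      mf[[nm]] <- factor(rows[[nm]], levels = lev)
    } else {
      mf[[nm]] <- as.numeric(rows[[nm]])
    }
  }
  mf
}

at_risk_rows <- function(cohort, direction) {
  if (direction == "incidence") cohort[cohort$mdd_baseline == 0, ]
  else cohort[cohort$mdd_baseline == 1, ]
}

#' Fit a transition model
#'
#' Multivariable logistic regression for one transition direction.
#' Incidence uses records MDD-free at baseline with follow-up MDD as the
#' outcome; remittance uses records with MDD at baseline with recovery
#' (1 - follow-up MDD) as the outcome. The linear predictor contains
#' age-band indicators (band of the baseline age), sex, education years,
#' log follow-up gap (exposure; dropped when gaps are constant) and any
#' requested modifiable-factor covariates. The log-gap term lets predicted
#' interval probabilities track each record's exposure, so that
#' [build_rate_table()]'s conversion of the predicted probability into a
#' hazard at the record's own gap is consistent -- without it, averaging
#' hazards inverted at heterogeneous gaps from a gap-marginal probability
#' is biased upward by about var(gap)/mean(gap)^2.
#'
#' @param cohort A panel cohort tibble (impute factors first if
#'   `extra_covariates` have missing cells).
#' @param direction `"incidence"` or `"remittance"`.
#' @param extra_covariates Modifiable-factor column names to include.
#' @param bands Age bands.
#' @return A `transition_model`: list with the fitted `glm`, `direction`,
#'   `bands`, `extra_covariates` and factor types.
#' @export
fit_transition_model <- function(cohort,
                                 direction = c("incidence", "remittance"),
                                 extra_covariates = character(),
                                 bands = age_bands()) {
  direction <- match.arg(direction)
  breaks <- validate_bands(bands)
  types <- factor_types_of(cohort)
  rows <- at_risk_rows(cohort, direction)
  outcome <- if (direction == "incidence") rows$mdd_followup
             else 1L - rows$mdd_followup
  keep <- stats::complete.cases(
    rows[, c("age_baseline", "sex", "education_years", extra_covariates),
         drop = FALSE])
  rows <- rows[keep, ]
  outcome <- outcome[keep]
  if (nrow(rows) == 0 || sum(outcome) < 1 || sum(1 - outcome) < 1)
    stop("cannot fit ", direction, " model: risk set has ", nrow(rows),
         " records, ", sum(outcome), " events", call. = FALSE)
  mf <- transition_frame(rows, breaks, extra_covariates, types)
  mf <- droplevels(mf)
  mf$.outcome <- outcome
  rhs <- c(if (nlevels(mf$age_band) > 1) "age_band",
           if (nlevels(mf$sex) > 1) "sex",
           if (length(unique(mf$education_years)) > 1) "education_years",
           if (length(unique(mf$log_gap)) > 1) "log_gap",
           extra_covariates)
  if (length(rhs) == 0) rhs <- "1"
  fit <- suppressWarnings(stats::glm(
    stats::reformulate(rhs, response = ".outcome"),
    family = stats::binomial(), data = mf))
  co <- stats::coef(fit)
  if (!fit$converged || anyNA(co) || any(abs(co) > 15))
    stop("unstable ", direction, " model (possible separation): ",
         paste(sprintf("%s=%.2f", names(co), co), collapse = ", "),
         call. = FALSE)
  structure(list(direction = direction, fit = fit, bands = breaks,
                 extra_covariates = extra_covariates,
                 factor_types = types),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("<transition_model>", x$direction, "\n")
  print(stats::coef(x$fit))
  invisible(x)
}

#' Predict interval transition probabilities
#'
#' @param model A `transition_model`.
#' @param rows Panel records supplying covariates.
#' @return Predicted probability of the modelled interval outcome for each
#'   row.
#' @export
predict_transition_probability <- function(model, rows) {
  mf <- transition_frame(rows, model$bands, model$extra_covariates,
                         model$factor_types, model$fit$xlevels)
  if ("age_band" %in% names(model$fit$xlevels)) {
    miss <- setdiff(levels(droplevels(mf$age_band)),
                    model$fit$xlevels$age_band)
    if (length(miss))
      stop("model has no at-risk records in band(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  as.numeric(stats::predict(model$fit, newdata = mf, type = "response"))
}

#' Convert an interval probability to a constant hazard
#'
#' Exponential waiting-time inversion: a probability p of at least one
#' event in `gap` years under a constant hazard corresponds to
#' -log(1 - p) / gap events per person-year. Monotone increasing in p.
#'
#' @param p Probabilities in \[0, 1).
#' @param gap Interval lengths in years, > 0.
#' @return Hazards in events per person-year.
#' @examples
#' probability_to_hazard(1 - exp(-1), 1) # 1
#' probability_to_hazard(0.5, 2)         # log(2)/2
#' @export
probability_to_hazard <- function(p, gap) {
  if (any(!is.finite(p)) || any(p < 0) || any(gap <= 0))
    stop("need 0 <= p < 1 and gap > 0", call. = FALSE)
  if (any(p >= 1))
    stop("p = 1 implies an infinite hazard", call. = FALSE)
  -log(1 - p) / gap
}

#' @rdname probability_to_hazard
#' @param hazard Hazards in events per person-year, >= 0.
#' @export
hazard_to_probability <- function(hazard, gap) {
  if (any(hazard < 0) || any(gap <= 0))
    stop("need hazard >= 0 and gap > 0", call. = FALSE)
  1 - exp(-hazard * gap)
}

#' Joint two-state inversion of interval transition probabilities
#'
#' Under the two-state chain with constant hazards (lambda, mu) over an
#' interval of length `gap`, the observed transition probabilities are
#' p01 = pi (1 - e^(-theta gap)) and p10 = (1 - pi)(1 - e^(-theta gap))
#' with theta = lambda + mu and pi = lambda/theta. Inverting:
#' theta = -log(1 - p01 - p10)/gap, lambda = theta p01/(p01 + p10),
#' mu = theta p10/(p01 + p10). Unlike the single-jump inversion
#' [probability_to_hazard()], this accounts for transitions masked by a
#' return to the origin state within the interval (e.g. onset followed by
#' remission before follow-up).
#'
#' @param p01 Probability healthy at baseline, MDD at follow-up.
#' @param p10 Probability MDD at baseline, healthy at follow-up.
#' @param gap Interval length in years.
#' @return List with components `incidence` (lambda) and `remittance`
#'   (mu), events per person-year.
#' @export
interval_hazards <- function(p01, p10, gap) {
  if (any(p01 < 0) || any(p10 < 0) || any(gap <= 0))
    stop("need p01, p10 >= 0 and gap > 0", call. = FALSE)
  tot <- p01 + p10
  if (any(tot >= 1))
    stop("p01 + p10 must be < 1 (hazards not identifiable)",
         call. = FALSE)
  theta <- ifelse(tot > 0, -log(1 - tot) / gap, 0)
  share <- ifelse(tot > 0, p01 / tot, 0)
  lam <- ifelse(tot > 1e-12, theta * share, p01 / gap)
  mu <- ifelse(tot > 1e-12, theta * (1 - share), p10 / gap)
  list(incidence = lam, remittance = mu)
}

#' Build an empirical rate table from fitted transition models
#'
#' Marginal prediction: for every stratum and age band, the fitted models
#' predict each at-risk record's interval probabilities of onset and of
#' remission at that record's own covariates; the pair is converted to
#' hazards at the record's own follow-up gap and the hazards are averaged
#' over the stratum's records in the band. The default conversion inverts
#' the two-state closed form jointly ([interval_hazards()]), which corrects
#' for transitions masked by a return within the interval;
#' `conversion = "single_jump"` uses [probability_to_hazard()] on each
#' direction separately.
#'
#' @param models List with `incidence` and `remittance`
#'   `transition_model`s sharing the same bands.
#' @param baseline Named per-stratum prevalence at 18 from
#'   [fit_baseline_prevalence()].
#' @param reference_cohort Panel records supplying the covariate
#'   distribution for the marginal prediction.
#' @param bands Age bands.
#' @param conversion `"two_state"` (default) or `"single_jump"`.
#' @param provenance Provenance tag of the resulting table.
#' @return A `rate_table`.
#' @export
build_rate_table <- function(models, baseline,
                             reference_cohort, bands = age_bands(),
                             conversion = c("two_state", "single_jump"),
                             provenance = "empirical") {
  conversion <- match.arg(conversion)
  breaks <- validate_bands(bands)
  stopifnot(inherits(models$incidence, "transition_model"),
            inherits(models$remittance, "transition_model"))
  if (!identical(as.numeric(models$incidence$bands), breaks) ||
      !identical(as.numeric(models$remittance$bands), breaks))
    stop("models and bands disagree on age-band boundaries",
         call. = FALSE)
  k <- n_bands(breaks)
  if (!all(STRATA$stratum %in% names(baseline)))
    stop("baseline prevalence must cover the four strata", call. = FALSE)
  inc <- rem <- matrix(NA_real_, k, 4,
                       dimnames = list(NULL, STRATA$stratum))
  for (direction in c("incidence", "remittance")) {
    rows <- at_risk_rows(reference_cohort, direction)
    sid <- stratum_id(rows$sex, rows$education)
    bid <- band_index(rows$age_baseline + rows$followup_gap / 2, breaks)
    empty <- character()
    # p01: onset probability from the incidence model, p10: recovery
    # probability from the remittance model, both at the rows' covariates
    p01 <- predict_transition_probability(models$incidence, rows)
    p10 <- predict_transition_probability(models$remittance, rows)
    hz <- switch(conversion,
      two_state = interval_hazards(p01, p10, rows$followup_gap),
      single_jump = list(
        incidence = probability_to_hazard(pmin(p01, 1 - 1e-12),
                                          rows$followup_gap),
        remittance = probability_to_hazard(pmin(p10, 1 - 1e-12),
                                           rows$followup_gap)))
    h <- if (direction == "incidence") hz$incidence else hz$remittance
    for (s in STRATA$stratum) {
      for (b in seq_len(k)) {
        sel <- sid == s & bid == b
        if (!any(sel)) {
          empty <- c(empty, sprintf("%s %s", s, band_labels(breaks)[b]))
          next
        }
        if (direction == "incidence") inc[b, s] <- mean(h[sel])
        else rem[b, s] <- mean(h[sel])
      }
    }
    if (length(empty))
      stop("no at-risk records for ", direction, " in: ",
           paste(empty, collapse = "; "), call. = FALSE)
  }
  rate_table(breaks, inc, rem, baseline[STRATA$stratum],
             provenance = provenance)
}

#' Participation-to-prevalence ratio
#'
#' Representativeness check: the proportion of a subgroup among study
#' participants divided by its proportion in the source population. A
#' ratio between 0.8 and 1.2 indicates adequate representation.
#'
#' @param subgroup_count_in_sample,sample_size Subgroup and total counts
#'   among participants.
#' @param subgroup_count_in_population,population_size Subgroup and total
#'   counts in the source population.
#' @return List with `ratio` and logical `adequate`.
#' @examples
#' participation_prevalence_ratio(47, 100, 50, 100) # 0.94, adequate
#' @export
participation_prevalence_ratio <- function(subgroup_count_in_sample,
                                           sample_size,
                                           subgroup_count_in_population,
                                           population_size) {
  counts <- c(subgroup_count_in_sample, sample_size,
              subgroup_count_in_population, population_size)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sample_size < 1 || population_size < 1 ||
      subgroup_count_in_sample > sample_size ||
      subgroup_count_in_population > population_size)
    stop("subgroup counts must not exceed their totals", call. = FALSE)
  if (subgroup_count_in_population == 0)
    stop("population proportion is zero; ratio undefined", call. = FALSE)
  ratio <- (subgroup_count_in_sample / sample_size) /
    (subgroup_count_in_population / population_size)
  list(ratio = ratio, adequate = ratio >= 0.8 && ratio <= 1.2)
}
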