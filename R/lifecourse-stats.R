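#' Round half away from zero
#'
#' Reported life-course statistics are rounded half-up to one decimal (the
#' convention of the tabulated results), unlike base R's round-half-even.
#' A small epsilon guards against binary representation error in values
#' such as 19.05 arising from decimal arithmetic.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Summarise simulated life courses per stratum
#'
#' Computes, for each stratum: the life-course prevalence (percentage ever
#' in the MDD state between 18 and 65, counting those already in MDD at
#' 18); the mean age of onset (average age of first MDD entry among
#' individuals healthy at 18 who ever develop MDD -- prevalent cases at 18
#' are excluded); and the mean duration (average total years in the MDD
#' state, censored at 65 and summed across episodes, among all ever-MDD
#' individuals including those starting in MDD). Onset and duration are
#' `NA` with `n_ever = 0` when no one ever has MDD.
#'
#' @param lc A `life_courses` object from [run_simulation()].
#' @return Tibble with one row per stratum: `stratum`, `sex`, `education`,
#'   `n`, `n_ever`, `life_course_prevalence` (%), `mean_age_onset`
#'   (years), `mean_duration` (years).
#' @export
summarize_life_courses <- function(lc) {
  stopifnot(inherits(lc, "life_courses"))
  ind <- lc$individuals
  if (nrow(ind) == 0) stop("no life courses to summarise", call. = FALSE)
  strata <- unique(ind$stratum)
  strata <- STRATA$stratum[STRATA$stratum %in% strata]
  rows <- lapply(strata, function(s) {
    x <- ind[ind$stratum == s, ]
    ever <- x$ever_mdd
    onset_set <- x$initial_state == "healthy" & ever
    tibble::tibble(
      stratum = s, sex = STRATA$sex[STRATA$stratum == s],
      education = STRATA$education[STRATA$stratum == s],
      n = nrow(x), n_ever = sum(ever),
      life_course_prevalence = 100 * mean(ever),
      mean_age_onset = if (any(onset_set))
        mean(x$onset_age[onset_set]) else NA_real_,
      mean_duration = if (any(ever))
        mean(x$mdd_years[ever]) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Age-specific MDD prevalence of simulated life courses
#'
#' Point-in-time prevalence: the share of individuals occupying the MDD
#' state at each integer age, determined by the initial state and the
#' parity of transitions up to that age.
#'
#' @param lc A `life_courses` object.
#' @param ages Integer ages to evaluate (default 18:65).
#' @return Tibble with `stratum`, `age`, `prevalence` (probability).
#' @export
age_specific_prevalence <- function(lc, ages = 18:65) {
  stopifnot(inherits(lc, "life_courses"))
  ind <- lc$individuals
  tr <- lc$transitions
  strata <- unique(ind$stratum)
  strata <- STRATA$stratum[STRATA$stratum %in% strata]
  out <- lapply(strata, function(s) {
    x <- ind[ind$stratum == s, ]
    t_s <- tr[tr$stratum == s, ]
    init <- as.integer(x$initial_state == "mdd")
    prev <- vapply(ages, function(a) {
      cnt <- tabulate(t_s$id[t_s$age <= a], nbins = nrow(x))
      mean((init + cnt) %% 2L)
    }, numeric(1))
    tibble::tibble(stratum = s, age = ages, prevalence = prev)
  })
  do.call(rbind, out)
}

#' Educational inequality gaps for one sex
#'
#' Gaps are oriented so that positive values mean a worse outcome for the
#' low-education group: prevalence gap = low - high (percentage points),
#' onset gap = high - low (years; larger values mean earlier onset with
#' low education), duration gap = low - high (years).
#'
#' @param low,high One-row life-course summaries (same sex) for the low-
#'   and high-education stratum, with fields `life_course_prevalence`,
#'   `mean_age_onset`, `mean_duration`.
#' @return Tibble with `outcome` (`prevalence`, `onset`, `duration`) and
#'   `gap`.
#' @export
inequality_gaps <- function(low, high) {
  if (!is.null(low$sex) && !is.null(high$sex) &&
      !identical(low$sex, high$sex))
    stop("gaps compare education groups within one sex", call. = FALSE)
  tibble::tibble(
    outcome = c("prevalence", "onset", "duration"),
    gap = c(low$life_course_prevalence - high$life_course_prevalence,
            high$mean_age_onset - low$mean_age_onset,
            low$mean_duration - high$mean_duration))
}

#' Education gaps for every sex in a summary table
#'
#' @param summary Per-stratum summary tibble from
#'   [summarize_life_courses()].
#' @return Tibble with `sex`, `outcome`, `gap`.
#' @export
education_gaps <- function(summary) {
  out <- lapply(unique(summary$sex), function(sx) {
    g <- inequality_gaps(
      summary[summary$sex == sx & summary$education == "low", ],
      summary[summary$sex == sx & summary$education == "high", ])
    g$sex <- sx
    g[, c("sex", "outcome", "gap")]
  })
  do.call(rbind, out)
}

#' Percentage reduction of an inequality gap
#'
#' @param baseline_gap Gap under the empirical rates (non-zero).
#' @param counterfactual_gap Gap under the counterfactual rates.
#' @return 100 (1 - counterfactual_gap / baseline_gap); exactly 0 when the
#'   gaps are equal and exactly 100 when the counterfactual gap is 0.
#' @export
gap_reduction <- function(baseline_gap, counterfactual_gap) {
  if (any(baseline_gap == 0))
    stop("baseline gap is zero; reduction undefined", call. = FALSE)
  100 * (1 - counterfactual_gap / baseline_gap)
}

#' Pool a statistic over the two sexes
#'
#' Unweighted mean of the female and male values, valid because simulated
#' strata are evenly sized by construction.
#'
#' @param female,male Numeric values (vectorised).
#' @param n_female,n_male Optional stratum sizes; pooling refuses unequal
#'   sizes rather than silently misweighting.
#' @return Elementwise mean.
#' @examples
#' pooled_summary(35.3, 28.6) # 31.95 -> 32.0 after half-up rounding
#' @export
pooled_summary <- function(female, male, n_female = NULL, n_male = NULL) {
  if (!is.null(n_female) && !is.null(n_male) &&
      !isTRUE(all(n_female == n_male)))
    stop("stratum sizes differ; supply explicit weights instead of ",
         "the unweighted pooled mean", call. = FALSE)
  (female + male) / 2
}

#' Monte Carlo standard error of a simulation statistic
#'
#' Runs independent-seed replicate simulations and returns the standard
#' deviation of the statistic across replicates.
#'
#' @param rates A `rate_table`.
#' @param settings A [simulation_settings()]; replicate r uses seed
#'   `settings$seed + r`.
#' @param n_replicates Number of replicates (>= 2).
#' @param statistic Function mapping a `life_courses` object to a numeric
#'   vector.
#' @return Standard error (vector if the statistic is vector-valued).
#' @export
monte_carlo_se <- function(rates, settings, n_replicates, statistic) {
  stopifnot(n_replicates >= 2)
  vals <- lapply(seq_len(n_replicates), function(r) {
    st <- settings
    st$seed <- settings$seed + r
    as.numeric(statistic(run_simulation(rates, st)))
  })
  m <- do.call(cbind, vals)
  if (nrow(m) == 1) stats::sd(m[1, ]) else apply(m, 1, stats::sd)
}
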