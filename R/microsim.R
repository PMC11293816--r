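#' Sample the age of the next transition under piecewise-constant hazards
#'
#' Inverse-transform sampling across band boundaries: the next event occurs
#' at the age t where the integrated hazard from `current_age` equals
#' -log(u). Exact (no time-step discretisation); if the cumulative hazard to
#' age 65 never reaches -log(u), the draw is censored and `Inf` is returned.
#'
#' @param hazard_by_band Non-negative hazards (events/person-year), one per
#'   band.
#' @param current_age Age in \[18, 65) at which the clock starts.
#' @param u A uniform(0,1) draw.
#' @param bands Band boundaries from [age_bands()].
#' @return The event age in (`current_age`, 65), or `Inf` if censored at 65.
#' @examples
#' # constant hazard 0.1 from age 20: -log(exp(-1)) = 1 = 0.1 * 10
#' sample_waiting_time(rep(0.1, 10), 20, exp(-1)) # 30
#' @export
sample_waiting_time <- function(hazard_by_band, current_age, u,
                                bands = age_bands()) {
  breaks <- validate_bands(bands)
  if (length(hazard_by_band) != n_bands(breaks))
    stop("need one hazard per band", call. = FALSE)
  if (any(!is.finite(hazard_by_band)) || any(hazard_by_band < 0))
    stop("hazards must be finite and non-negative", call. = FALSE)
  if (!is.finite(u) || u <= 0 || u >= 1)
    stop("u must lie strictly in (0, 1)", call. = FALSE)
  if (current_age < breaks[1] || current_age >= breaks[length(breaks)])
    stop("current_age must lie in [18, 65)", call. = FALSE)
  cpp_invert_cum_hazard(breaks, as.numeric(hazard_by_band),
                        current_age, -log(u))
}

#' Simulation settings
#'
#' @param n_per_stratum Life courses per sex-by-education stratum. The
#'   default 125000 gives 500000 in total, evenly divided over the four
#'   strata.
#' @param seed Integer seed; life courses are drawn from per-individual
#'   counter-based substreams of this seed, so results are independent of
#'   iteration order.
#' @param history_rates Optional `rate_table` used for all of an
#'   individual's draws after their first remission (sensitivity model for
#'   depression history).
#' @return A `simulation_settings` list.
#' @export
simulation_settings <- function(n_per_stratum = 125000L, seed = 1L,
                                history_rates = NULL) {
  stopifnot(n_per_stratum >= 1, is.finite(seed))
  if (!is.null(history_rates) && !inherits(history_rates, "rate_table"))
    stop("history_rates must be a rate_table", call. = FALSE)
  structure(list(n_per_stratum = as.integer(n_per_stratum),
                 seed = as.numeric(seed)[1], history_rates = history_rates),
            class = "simulation_settings")
}

#' Simulate one MDD life course
#'
#' Draws the initial state at 18 from the stratum's prevalence, then
#' alternates incidence (while healthy) and remittance (while in MDD)
#' waiting-time draws until censoring at 65. If `history_rates` is given,
#' every draw after the first remission uses it instead (rate switching).
#'
#' @param rates A `rate_table`.
#' @param stratum One of `"female_low"`, `"female_high"`, `"male_low"`,
#'   `"male_high"`.
#' @param id Individual index; combined with `seed` it determines the RNG
#'   substream.
#' @param seed Integer seed.
#' @param history_rates Optional `rate_table` for post-remission draws.
#' @return A `life_course`: list with `id`, `sex`, `education`,
#'   `initial_state` (`"healthy"`/`"mdd"` at 18), `transitions` (data frame
#'   of `age`, `state` with strictly increasing ages and alternating
#'   states), and `censor_age = 65`.
#' @export
simulate_life_course <- function(rates, stratum, id = 1L, seed = 1L,
                                 history_rates = NULL) {
  lc <- run_simulation(rates,
                       simulation_settings(1L, seed, history_rates),
                       strata = stratum, id_offset = as.numeric(id) - 1)
  ind <- lc$individuals
  tr <- lc$transitions
  structure(list(
    id = id, sex = ind$sex[1], education = ind$education[1],
    initial_state = ind$initial_state[1],
    transitions = data.frame(age = tr$age, state = tr$state),
    censor_age = 65), class = "life_course")
}

#' Run the microsimulation
#'
#' Simulates `n_per_stratum` life courses for each stratum of the rate
#' table. Deterministic given `settings$seed` through per-individual
#' counter-based RNG substreams.
#'
#' @param rates A `rate_table` covering the four strata.
#' @param settings A [simulation_settings()] object.
#' @param strata Strata to simulate (default all four).
#' @param id_offset Internal: shifts individual substream ids.
#' @return A `life_courses` object: list with `individuals` (tibble: `id`,
#'   `stratum`, `sex`, `education`, `initial_state`, `ever_mdd`,
#'   `onset_age` of first MDD entry or `NA`, `mdd_years` total time in MDD
#'   censored at 65), `transitions` (tibble: `id`, `stratum`, `age`,
#'   `state`), and the settings used.
#' @export
run_simulation <- function(rates, settings = simulation_settings(),
                           strata = STRATA$stratum, id_offset = 0) {
  stopifnot(inherits(rates, "rate_table"),
            inherits(settings, "simulation_settings"))
  bad <- setdiff(strata, STRATA$stratum)
  if (length(bad))
    stop("unknown stratum: ", paste(bad, collapse = ", "), call. = FALSE)
  hist <- settings$history_rates
  use_history <- !is.null(hist)
  if (use_history && !identical(as.numeric(hist$bands),
                                as.numeric(rates$bands)))
    stop("history_rates must share the rate table's age bands",
         call. = FALSE)
  n <- settings$n_per_stratum
  ind_list <- list()
  tr_list <- list()
  for (j in seq_along(strata)) {
    s <- strata[j]
    res <- cpp_simulate_stratum(
      as.numeric(rates$bands), rates$incidence[, s], rates$remittance[, s],
      if (use_history) hist$incidence[, s] else rates$incidence[, s],
      if (use_history) hist$remittance[, s] else rates$remittance[, s],
      use_history, rates$prevalence_at_18[[s]], n,
      settings$seed,
      # distinct substream block per stratum, stable under subsetting
      id_offset + (match(s, STRATA$stratum) - 1) * n)
    init <- ifelse(res$initial_state == 1L, "mdd", "healthy")
    ind_list[[j]] <- tibble::tibble(
      id = seq_len(n), stratum = s,
      sex = STRATA$sex[STRATA$stratum == s],
      education = STRATA$education[STRATA$stratum == s],
      initial_state = init,
      ever_mdd = res$initial_state == 1L | !is.na(res$onset_age),
      onset_age = res$onset_age, mdd_years = res$mdd_years,
      n_transitions = res$n_transitions)
    if (length(res$trans_id))
      tr_list[[j]] <- tibble::tibble(
        id = res$trans_id, stratum = s, age = res$trans_age,
        state = ifelse(res$trans_state == 1L, "mdd", "healthy"))
  }
  structure(list(
    individuals = do.call(rbind, ind_list),
    transitions = if (length(tr_list)) do.call(rbind, tr_list) else
      tibble::tibble(id = integer(), stratum = character(),
                     age = numeric(), state = character()),
    bands = as.numeric(rates$bands), settings = settings),
    class = "life_courses")
}

#' @export
print.life_courses <- function(x, ...) {
  cat("<life_courses>", nrow(x$individuals), "individuals,",
      nrow(x$transitions), "transitions, seed", x$settings$seed, "\n")
  invisible(x)
}

#' Export life courses as long-format event history
#'
#' One row per individual-event: the age-18 initial state plus every
#' transition, columns `id`, `stratum`, `age`, `state`.
#'
#' @param lc A `life_courses` object.
#' @param path CSV path.
#' @export
write_life_courses <- function(lc, path) {
  stopifnot(inherits(lc, "life_courses"))
  start <- data.frame(id = lc$individuals$id,
                      stratum = lc$individuals$stratum, age = 18,
                      state = lc$individuals$initial_state)
  ev <- rbind(start, as.data.frame(lc$transitions))
  ev <- ev[order(ev$stratum, ev$id, ev$age), ]
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}
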