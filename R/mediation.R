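#' Mediation result from difference of coefficients
#'
#' @param factor Factor name.
#' @param direction Transition direction screened.
#' @param beta_total Education log-odds coefficient without the factor.
#' @param beta_adjusted Education log-odds coefficient with the factor.
#' @param tol `beta_total` values within `tol` of zero raise an
#'   undefined-mediation error.
#' @return A `mediation_result` list with `mediating_percentage` =
#'   100 (beta_total - beta_adjusted) / beta_total (signed).
#' @export
mediation_result <- function(factor, direction, beta_total, beta_adjusted,
                             tol = 1e-8) {
  if (!is.finite(beta_total) || abs(beta_total) <= tol)
    stop("total education effect is zero; mediating percentage undefined",
         call. = FALSE)
  structure(list(
    factor = factor, direction = direction, beta_total = beta_total,
    beta_adjusted = beta_adjusted,
    mediating_percentage = 100 * (beta_total - beta_adjusted) / beta_total),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "<mediation_result> %s (%s): beta_total=%.4f beta_adjusted=%.4f -> %.1f%%\n",
    x$factor, x$direction, x$beta_total, x$beta_adjusted,
    x$mediating_percentage))
  invisible(x)
}

#' Mediating percentage of one modifiable factor
#'
#' Difference-of-coefficients screen: the transition model is fitted with
#' and without the factor, and the share of the education-years log-odds
#' coefficient absorbed by the factor is reported as a signed percentage.
#'
#' @param cohort A panel cohort (factor cells imputed).
#' @param factor Factor column name.
#' @param direction Transition direction (`"incidence"` by default; the
#'   screen runs on incidence).
#' @param bands Age bands.
#' @return A [mediation_result()].
#' @export
mediating_percentage <- function(cohort, factor,
                                 direction = c("incidence", "remittance"),
                                 bands = age_bands()) {
  direction <- match.arg(direction)
  if (!factor %in% factor_columns(cohort))
    stop("factor '", factor, "' not found in cohort", call. = FALSE)
  m0 <- fit_transition_model(cohort, direction, character(), bands)
  m1 <- fit_transition_model(cohort, direction, factor, bands)
  b0 <- stats::coef(m0$fit)[["education_years"]]
  b1 <- stats::coef(m1$fit)[["education_years"]]
  mediation_result(factor, direction, b0, b1)
}

#' Screen all modifiable factors
#'
#' @param cohort A panel cohort (factor cells imputed).
#' @param factors Factor names to screen (default: all factor columns).
#' @inheritParams mediating_percentage
#' @return Tibble with one row per factor: `factor`, `direction`,
#'   `beta_total`, `beta_adjusted`, `mediating_percentage`, sorted by
#'   decreasing mediating percentage (ties alphabetical).
#' @export
screen_mediators <- function(cohort, factors = factor_columns(cohort),
                             direction = "incidence",
                             bands = age_bands()) {
  res <- lapply(factors, function(f)
    mediating_percentage(cohort, f, direction, bands))
  out <- tibble::tibble(
    factor = vapply(res, `[[`, character(1), "factor"),
    direction = direction,
    beta_total = vapply(res, `[[`, numeric(1), "beta_total"),
    beta_adjusted = vapply(res, `[[`, numeric(1), "beta_adjusted"),
    mediating_percentage = vapply(res, `[[`, numeric(1),
                                  "mediating_percentage"))
  out[order(-out$mediating_percentage, out$factor), ]
}

#' Select the top mediating factors
#'
#' @param results Tibble from [screen_mediators()] (incidence direction).
#' @param k Number of factors to keep (default 3).
#' @return Character vector of the `k` factor names with the largest
#'   mediating percentage, ties broken alphabetically.
#' @export
select_top_factors <- function(results, k = 3L) {
  stopifnot(nrow(results) >= 1, k >= 1)
  if (k > nrow(results))
    stop("k = ", k, " exceeds the ", nrow(results),
         " screened factors", call. = FALSE)
  ord <- order(-results$mediating_percentage, results$factor)
  results$factor[ord][seq_len(k)]
}
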