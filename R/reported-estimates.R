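#' Reported life-course estimates from the source study
#'
#' The published per-stratum life-course prevalence (%), mean age of onset
#' and mean duration (years) of MDD between ages 18 and 65, as tabulated
#' by the Lifelines-based microsimulation study this pipeline re-implements.
#' These serve as inputs to the gap, pooling and rounding operations (the
#' in-study arithmetic identities); the underlying individual-level data
#' are not public.
#'
#' @return Tibble with `sex`, `education`, `life_course_prevalence`,
#'   `mean_age_onset`, `mean_duration`.
#' @export
reported_lifecourse_estimates <- function() {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", "reported_lifecourse_estimates.csv",
                package = "mddcourse"),
    stringsAsFactors = FALSE))
}

#' Reported counterfactual gap reductions from the source study
#'
#' The published sex-specific percentage reductions of the educational
#' inequality in life-course prevalence, mean age of onset and mean
#' duration of MDD under the quality-of-social-contacts counterfactual and
#' under the joint swap of all selected factors.
#'
#' @return Tibble with `scenario`, `sex`, `outcome`, `reduction_pct`.
#' @export
reported_gap_reductions <- function() {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", "reported_gap_reductions.csv",
                package = "mddcourse"),
    stringsAsFactors = FALSE))
}
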