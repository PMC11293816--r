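#' Construct a rate table
#'
#' A rate table is the simulator input: for each sex-by-education stratum it
#' holds the MDD prevalence at age 18 and, per age band, the incidence
#' (healthy to MDD) and remittance (MDD to healthy) hazards in events per
#' person-year.
#'
#' @param bands Band boundaries from [age_bands()].
#' @param incidence,remittance Numeric matrices, one row per band and one
#'   column per stratum (`female_low`, `female_high`, `male_low`,
#'   `male_high`); non-negative finite hazards.
#' @param prevalence_at_18 Named probability vector, one entry per stratum.
#' @param provenance Free-text origin tag: `"empirical"`, `"ground_truth"`
#'   or `"counterfactual:<factors>"`.
#' @return An object of class `rate_table`.
#' @export
rate_table <- function(bands, incidence, remittance, prevalence_at_18,
                       provenance = "empirical") {
  breaks <- validate_bands(bands)
  k <- n_bands(breaks)
  incidence <- as.matrix(incidence)
  remittance <- as.matrix(remittance)
  strata <- STRATA$stratum
  if (is.null(colnames(incidence))) colnames(incidence) <- strata
  if (is.null(colnames(remittance))) colnames(remittance) <- strata
  if (is.null(names(prevalence_at_18))) names(prevalence_at_18) <- strata
  if (nrow(incidence) != k || nrow(remittance) != k)
    stop("hazard matrices must have one row per age band", call. = FALSE)
  if (!setequal(colnames(incidence), strata) ||
      !setequal(colnames(remittance), strata) ||
      !setequal(names(prevalence_at_18), strata))
    stop("rate table must cover the four strata: ",
         paste(strata, collapse = ", "), call. = FALSE)
  incidence <- incidence[, strata, drop = FALSE]
  remittance <- remittance[, strata, drop = FALSE]
  prevalence_at_18 <- prevalence_at_18[strata]
  if (any(!is.finite(incidence)) || any(incidence < 0) ||
      any(!is.finite(remittance)) || any(remittance < 0))
    stop("hazards must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(prevalence_at_18)) || any(prevalence_at_18 < 0) ||
      any(prevalence_at_18 > 1))
    stop("prevalence_at_18 must lie in [0, 1]", call. = FALSE)
  rownames(incidence) <- rownames(remittance) <- band_labels(breaks)
  structure(
    list(bands = breaks, incidence = incidence, remittance = remittance,
         prevalence_at_18 = prevalence_at_18, provenance = provenance),
    class = "rate_table")
}

#' Constant-hazard rate table
#'
#' Convenience constructor with the same hazards in every band, used for
#' closed-form checks and small examples.
#'
#' @param incidence,remittance Scalar hazards (events/person-year), recycled
#'   across bands and strata, or length-4 per-stratum vectors.
#' @param prevalence_at_18 Scalar or length-4 probability.
#' @inheritParams rate_table
#' @export
constant_rate_table <- function(incidence, remittance, prevalence_at_18 = 0,
                                bands = age_bands()) {
  k <- n_bands(validate_bands(bands))
  rate_table(
    bands,
    matrix(rep(rep(incidence, length.out = 4), each = k), nrow = k),
    matrix(rep(rep(remittance, length.out = 4), each = k), nrow = k),
    rep(prevalence_at_18, length.out = 4))
}

#' @export
print.rate_table <- function(x, ...) {
  cat("<rate_table> provenance:", x$provenance, "\n")
  cat("prevalence at 18:",
      paste(sprintf("%s=%.4f", names(x$prevalence_at_18),
                    x$prevalence_at_18), collapse = " "), "\n")
  cat("incidence hazards (events/person-year):\n")
  print(round(x$incidence, 5))
  cat("remittance hazards (events/person-year):\n")
  print(round(x$remittance, 5))
  invisible(x)
}

#' @export
as.data.frame.rate_table <- function(x, ...) {
  k <- n_bands(x$bands)
  strata <- STRATA
  rates <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    s <- strata$stratum[i]
    data.frame(stratum_sex = strata$sex[i],
               stratum_education = strata$education[i],
               band_start = x$bands[-(k + 1)], band_end = x$bands[-1],
               incidence_hazard = x$incidence[, s],
               remittance_hazard = x$remittance[, s],
               prevalence_at_18 = NA_real_, row.names = NULL)
  }))
  prev <- data.frame(stratum_sex = strata$sex,
                     stratum_education = strata$education,
                     band_start = NA_real_, band_end = NA_real_,
                     incidence_hazard = NA_real_,
                     remittance_hazard = NA_real_,
                     prevalence_at_18 = as.numeric(
                       x$prevalence_at_18[strata$stratum]))
  rbind(rates, prev)
}

#' Write / read a rate table as CSV
#'
#' The on-disk schema is long format with columns `stratum_sex`,
#' `stratum_education`, `band_start`, `band_end`, `incidence_hazard`,
#' `remittance_hazard`, `prevalence_at_18`: one row per stratum and band
#' (prevalence empty) plus one row per stratum carrying `prevalence_at_18`
#' (band columns empty). Externally produced rate files in a different
#' layout can be loaded by passing `col_map`, a named character vector
#' mapping the schema names above to the file's column names.
#'
#' @param x A `rate_table`.
#' @param path CSV path.
#' @param col_map Optional named character vector renaming file columns onto
#'   the schema, e.g. `c(incidence_hazard = "inc_rate")`.
#' @param provenance Provenance tag attached to the loaded table.
#' @return `read_rate_table()` returns a `rate_table`; `write_rate_table()`
#'   returns `path` invisibly.
#' @export
write_rate_table <- function(x, path) {
  stopifnot(inherits(x, "rate_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path, col_map = NULL,
                            provenance = "empirical") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(df))
        stop("column '", col_map[[nm]], "' not found in ", path,
             call. = FALSE)
      names(df)[names(df) == col_map[[nm]]] <- nm
    }
  }
  need <- c("stratum_sex", "stratum_education", "band_start", "band_end",
            "incidence_hazard", "remittance_hazard", "prevalence_at_18")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("rate table CSV lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$stratum <- stratum_id(df$stratum_sex, df$stratum_education)
  prev_rows <- !is.na(df$prevalence_at_18)
  rate_rows <- df[!prev_rows, ]
  breaks <- sort(unique(c(rate_rows$band_start, rate_rows$band_end)))
  k <- length(breaks) - 1L
  inc <- rem <- matrix(NA_real_, k, 4,
                       dimnames = list(NULL, STRATA$stratum))
  for (s in STRATA$stratum) {
    rows <- rate_rows[rate_rows$stratum == s, ]
    rows <- rows[order(rows$band_start), ]
    if (nrow(rows) != k)
      stop("stratum ", s, " does not cover all age bands", call. = FALSE)
    inc[, s] <- rows$incidence_hazard
    rem[, s] <- rows$remittance_hazard
  }
  prev <- df$prevalence_at_18[prev_rows]
  names(prev) <- df$stratum[prev_rows]
  rate_table(breaks, inc, rem, prev, provenance = provenance)
}
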