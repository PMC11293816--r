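#' Age bands for piecewise-constant hazards
#'
#' Partitions the simulated age range \[18, 65) into half-open bands
#' \[a, b). Bands are anchored at age 18; with the default 5-year width the
#' final band is the short band \[63, 65) because 47 years is not divisible
#' by 5.
#'
#' @param width Band width in years (default 5).
#' @param from,to Age range covered; transitions are modelled on
#'   \[`from`, `to`).
#' @return Numeric vector of band boundaries (first `from`, last `to`,
#'   strictly increasing), of class `age_bands`.
#' @examples
#' age_bands()        # 18, 23, ..., 63, 65
#' age_bands(10)      # 18, 28, 38, 48, 58, 65
#' @export
age_bands <- function(width = 5, from = 18, to = 65) {
  stopifnot(width > 0, to > from)
  breaks <- seq(from, to, by = width)
  if (breaks[length(breaks)] < to) breaks <- c(breaks, to)
  structure(breaks, class = "age_bands")
}

validate_bands <- function(breaks, from = 18, to = 65) {
  breaks <- as.numeric(breaks)
  if (length(breaks) < 2 || breaks[1] != from ||
      breaks[length(breaks)] != to || any(diff(breaks) <= 0))
    stop("age bands must be strictly increasing boundaries from ", from,
         " to ", to, call. = FALSE)
  breaks
}

n_bands <- function(breaks) length(breaks) - 1L

band_labels <- function(breaks) {
  k <- n_bands(breaks)
  sprintf("[%g,%g)", breaks[-(k + 1)], breaks[-1])
}

#' Assign ages to bands
#'
#' @param age Numeric ages.
#' @param breaks Band boundaries from [age_bands()].
#' @return Integer band index (1-based); ages at or beyond the last boundary
#'   are assigned to the final band, ages below the first are `NA`.
#' @export
band_index <- function(age, breaks) {
  breaks <- as.numeric(breaks)
  idx <- findInterval(age, breaks, rightmost.closed = FALSE)
  idx[idx >= length(breaks)] <- length(breaks) - 1L
  idx[idx < 1L] <- NA_integer_
  idx
}
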