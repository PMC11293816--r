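#' Closed-form MDD state probability for the two-state process
#'
#' Solves the forward equation p'(t) = lambda(t)(1 - p) - mu(t) p of the
#' healthy/MDD chain under piecewise-constant hazards. Within a band with
#' rates (lambda, mu) and entry value p0 at t0,
#' p(t) = p_eq + (p0 - p_eq) exp(-(lambda + mu)(t - t0)) with
#' p_eq = lambda/(lambda + mu); a band with lambda + mu = 0 keeps p
#' constant. Chained across bands from p(18) = prevalence at 18. This is
#' the independent oracle against which the microsimulation engine is
#' validated.
#'
#' @param rates A `rate_table`.
#' @param stratum Stratum id.
#' @param age Ages in \[18, 65\] (vectorised).
#' @return Probability of being in the MDD state at each age.
#' @examples
#' rt <- constant_rate_table(0.1, 0.4, prevalence_at_18 = 0)
#' analytic_state_probability(rt, "female_low", 28) # 0.2 * (1 - exp(-5))
#' @export
analytic_state_probability <- function(rates, stratum, age) {
  stopifnot(inherits(rates, "rate_table"))
  stratum <- match.arg(stratum, STRATA$stratum)
  if (any(age < rates$bands[1] | age > rates$bands[length(rates$bands)]))
    stop("age must lie in [18, 65]", call. = FALSE)
  lam <- rates$incidence[, stratum]
  mu <- rates$remittance[, stratum]
  breaks <- rates$bands
  k <- n_bands(breaks)
  # p at every band boundary
  p_bound <- numeric(k + 1)
  p_bound[1] <- rates$prevalence_at_18[[stratum]]
  for (b in seq_len(k)) {
    p_bound[b + 1] <- step_p(p_bound[b], lam[b], mu[b],
                             breaks[b + 1] - breaks[b])
  }
  vapply(age, function(a) {
    b <- band_index(a, breaks)
    if (a == breaks[1]) return(p_bound[1])
    step_p(p_bound[b], lam[b], mu[b], a - breaks[b])
  }, numeric(1))
}

step_p <- function(p0, lam, mu, dt) {
  theta <- lam + mu
  if (theta == 0) return(p0)
  peq <- lam / theta
  peq + (p0 - peq) * exp(-theta * dt)
}

#' Closed-form probability of ever experiencing MDD by 65
#'
#' First entry into MDD from the healthy state is governed by the incidence
#' hazard alone, so among individuals healthy at 18 the ever-MDD
#' probability is 1 - exp(-integrated incidence hazard to 65); individuals
#' already in MDD at 18 count with probability 1.
#'
#' @inheritParams analytic_state_probability
#' @return Probability of occupying the MDD state at least once in
#'   \[18, 65\].
#' @export
analytic_ever_probability <- function(rates, stratum) {
  stopifnot(inherits(rates, "rate_table"))
  stratum <- match.arg(stratum, STRATA$stratum)
  cum <- sum(rates$incidence[, stratum] * diff(rates$bands))
  p18 <- rates$prevalence_at_18[[stratum]]
  p18 + (1 - p18) * (1 - exp(-cum))
}

#' Closed-form expected years in MDD per individual
#'
#' Integrates the analytic state-probability curve over \[18, 65\] band by
#' band (exact piecewise-exponential integral), giving the expected total
#' MDD time per simulated individual, averaged over everyone in the
#' stratum.
#'
#' @inheritParams analytic_state_probability
#' @return Expected years spent in the MDD state between ages 18 and 65.
#' @export
analytic_mdd_years <- function(rates, stratum) {
  stopifnot(inherits(rates, "rate_table"))
  stratum <- match.arg(stratum, STRATA$stratum)
  lam <- rates$incidence[, stratum]
  mu <- rates$remittance[, stratum]
  breaks <- rates$bands
  k <- n_bands(breaks)
  p0 <- rates$prevalence_at_18[[stratum]]
  total <- 0
  for (b in seq_len(k)) {
    dt <- breaks[b + 1] - breaks[b]
    theta <- lam[b] + mu[b]
    if (theta == 0) {
      total <- total + p0 * dt
    } else {
      peq <- lam[b] / theta
      total <- total + peq * dt + (p0 - peq) * (1 - exp(-theta * dt)) / theta
      p0 <- step_p(p0, lam[b], mu[b], dt)
    }
  }
  total
}
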