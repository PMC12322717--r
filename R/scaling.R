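#' Effective parameters shared by the allometric scaling laws
#'
#' Bundles the normalization constants and exponents used by every scaling
#' function in the package.  Each constant is an *effective* parameter for a
#' fixed thermal domain and response: temperature enters only through the
#' dimensionless multiplier `fT`, and taxon-specific factors are absorbed
#' into the normalizations.
#'
#' @param b0 Metabolic normalization (mass^(1/4) time^-1).
#' @param fT Dimensionless thermal-response multiplier (> 0).
#' @param r0 Growth-rate normalization (mass^(1/4) time^-1).
#' @param K0 Carrying-capacity normalization (mass^(3/4) area^-1).
#' @param C0 Consumption normalization (mass^(-3/4) area).
#' @param a0_prime Dimensionless conversion factor linking interaction
#'   coefficients to consumption-rate ratios.
#' @param a0 Interaction normalization for the mass-ratio form of the
#'   competition coefficient.
#' @param g0 Generation-time proportionality constant (time mass^(-1/4)).
#'   Only the proportionality G ~ M^(1/4) is theory; `g0` is user-set.
#' @param alpha Interaction scaling exponent; default -1/4.
#' @param consumption_exponent Exponent of the consumption-rate law;
#'   default -1/4, but taxon-dependent values (e.g. -3/4) are admitted.
#'
#' @return An object of class `"scaling_constants"` (a named list).
#' @examples
#' sc <- scaling_constants()
#' metabolic_rate(16, sc)  # 16^(3/4) = 8
#' @export
scaling_constants <- function(b0 = 1, fT = 1, r0 = 1, K0 = 1, C0 = 1,
                              a0_prime = 1, a0 = 1, g0 = 1,
                              alpha = -1/4, consumption_exponent = -1/4) {
  consts <- c(b0 = b0, fT = fT, r0 = r0, K0 = K0, C0 = C0,
              a0_prime = a0_prime, a0 = a0, g0 = g0)
  if (any(!is.finite(consts)) || any(consts <= 0))
    stop("all normalization constants (and fT) must be finite and positive")
  structure(list(b0 = b0, fT = fT, r0 = r0, K0 = K0, C0 = C0,
                 a0_prime = a0_prime, a0 = a0, g0 = g0,
                 alpha = alpha,
                 consumption_exponent = consumption_exponent),
            class = "scaling_constants")
}

#' @export
print.scaling_constants <- function(x, ...) {
  cat("Allometric scaling constants:\n")
  cat(sprintf("  b0 = %g, fT = %g, r0 = %g, K0 = %g, C0 = %g\n",
              x$b0, x$fT, x$r0, x$K0, x$C0))
  cat(sprintf("  a0 = %g, a0' = %g, g0 = %g\n", x$a0, x$a0_prime, x$g0))
  cat(sprintf("  interaction exponent alpha = %g, consumption exponent = %g\n",
              x$alpha, x$consumption_exponent))
  invisible(x)
}

check_mass <- function(m, what = "body mass") {
  if (!is.numeric(m) || length(m) == 0 || any(!is.finite(m)) || any(m <= 0))
    stop(what, " must be positive and finite")
  invisible(m)
}

#' Whole-organism metabolic rate
#'
#' Metabolic rate of an individual of body mass `m`: `b0 * fT * m^(3/4)`
#' (mass time^-1).  Larger individuals spend more energy per unit time.
#'
#' @param m Body mass (> 0); vectorized.
#' @param constants A [scaling_constants()] object.
#' @return Metabolic rate, same length as `m`.
#' @export
metabolic_rate <- function(m, constants = scaling_constants()) {
  check_mass(m)
  constants$b0 * constants$fT * m^(3/4)
}

#' Mass-specific metabolic rate
#'
#' Metabolic rate per unit mass, `b0 * fT * m^(-1/4)` (time^-1): the
#' economy of larger body plans, decreasing with mass.
#'
#' @inheritParams metabolic_rate
#' @return Mass-specific rate, same length as `m`.
#' @export
mass_specific_rate <- function(m, constants = scaling_constants()) {
  check_mass(m)
  constants$b0 * constants$fT * m^(-1/4)
}

#' Maximum intrinsic growth rate of a population
#'
#' `r0 * M^(-1/4)` (time^-1), where `M` is the population mean body mass.
#' Mortality rate is expected to be proportional to the same law (the
#' reciprocal of generation time).
#'
#' @param M Population mean body mass (> 0); vectorized.
#' @inheritParams metabolic_rate
#' @return Growth rate, same length as `M`.
#' @export
max_growth_rate <- function(M, constants = scaling_constants()) {
  check_mass(M, "population mean mass")
  constants$r0 * M^(-1/4)
}

#' Maximum generation time (lifespan)
#'
#' `g0 * M^(1/4)` (time).  Theory fixes only the proportionality
#' G ~ M^(1/4); the constant `g0` is a free parameter.  For all `M`,
#' `generation_time(M) * max_growth_rate(M) == g0 * r0`.
#'
#' @inheritParams max_growth_rate
#' @return Generation time, same length as `M`.
#' @export
generation_time <- function(M, constants = scaling_constants()) {
  check_mass(M, "population mean mass")
  constants$g0 * M^(1/4)
}

#' Carrying capacity of biomass density
#'
#' Maximum sustainable biomass per unit area of a population in isolation:
#' `K0 * M^(-3/4) * M = K0 * M^(1/4)` (mass area^-1).  Follows from the
#' energetic equivalence rule; increases with body size.
#'
#' @inheritParams max_growth_rate
#' @return Biomass-density carrying capacity, same length as `M`.
#' @export
carrying_capacity <- function(M, constants = scaling_constants()) {
  check_mass(M, "population mean mass")
  constants$K0 * M^(1/4)
}

#' Carrying capacity of abundance density
#'
#' Individuals per unit area: `carrying_capacity(M) / M = K0 * M^(-3/4)`.
#' Unlike biomass density, abundance density *decreases* with body size
#' (Damuth's rule at the population level).
#'
#' @inheritParams max_growth_rate
#' @return Abundance-density carrying capacity, same length as `M`.
#' @export
abundance_carrying_capacity <- function(M, constants = scaling_constants()) {
  carrying_capacity(M, constants) / M
}

#' Average per-capita consumption rate
#'
#' `C0 * M^e` with exponent `e = constants$consumption_exponent`
#' (default -1/4, from combining the growth-rate and carrying-capacity laws;
#' mass^-1 area).  The exponent is configurable because empirical scalings
#' of consumption with size vary across taxa.
#'
#' @inheritParams max_growth_rate
#' @return Consumption rate, same length as `M`.
#' @export
consumption_rate <- function(M, constants = scaling_constants()) {
  check_mass(M, "population mean mass")
  constants$C0 * M^constants$consumption_exponent
}

#' Consumption rate from demographic parameters
#'
#' Under resource-mediated competition with fast resource dynamics, the
#' average consumption rate of a population follows from its demography as
#' `1 / (K * (1 + d/r))`.  Substituting the allometric laws for `K`, `r`
#' and `d` (with `d/r` constant) recovers the mass scaling of
#' [consumption_rate()].
#'
#' @param K Carrying capacity of biomass density (> 0).
#' @param r Maximum intrinsic growth rate (> 0).
#' @param d Mortality rate (>= 0); defaults to `r` (mortality at the
#'   reciprocal-generation-time scale), so only the ratio `d/r` matters.
#' @return Per-capita consumption rate.
#' @export
consumption_from_demographics <- function(K, r, d = r) {
  if (any(K <= 0) || any(r <= 0)) stop("K and r must be positive")
  if (any(d < 0)) stop("mortality rate d must be nonnegative")
  1 / (K * (1 + d / r))
}

#' Competitive interaction coefficient from body masses
#'
#' Dimensionless per-capita competitive effect of population `j` on `i`:
#' `a0 * (Mj/Mi)^alpha` with default `alpha = -1/4`.  Equivalently
#' `a0' * C(Mj)/C(Mi)` in terms of consumption rates.  The larger the body
#' size of `j` relative to `i`, the weaker its competitive effect (for
#' `alpha < 0`).  Coefficients are reciprocal:
#' `a_ij * a_ji = a0^2` for every mass pair.
#'
#' @param Mi,Mj Mean body masses of the focal and the competing population.
#' @param constants A [scaling_constants()] object supplying `a0` and
#'   `alpha`.
#' @return Interaction coefficient(s).
#' @export
interaction_coefficient <- function(Mi, Mj, constants = scaling_constants()) {
  check_mass(Mi); check_mass(Mj)
  constants$a0 * (Mj / Mi)^constants$alpha
}
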