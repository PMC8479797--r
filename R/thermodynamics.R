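#' Gas constant in kcal mol^-1 K^-1
#'
#' The molar gas constant expressed in the units used throughout the package
#' for binding free energies.
#'
#' @format A length-one numeric, 1.987204e-3 kcal mol^-1 K^-1.
#' @export
R_KCAL <- 1.987204e-3

#' Binding free-energy difference between two dissociation constants
#'
#' Computes the difference in binding free energy between a state of interest
#' and a reference state, `ddG = R * T * ln(kd1 / kd2)`.  By convention `kd1`
#' is the dissociation constant of the state of interest and `kd2` that of the
#' reference, so a *tighter* state of interest (smaller `kd1`) gives a
#' *negative* value.
#'
#' @param kd1 Dissociation constant of the state of interest (M). Vectorised.
#' @param kd2 Dissociation constant of the reference state (M).
#' @param temperature Absolute temperature in Kelvin. Default 298 K.
#' @param gas_constant Gas constant in kcal mol^-1 K^-1; default [R_KCAL].
#'
#' @return Free-energy difference(s) in kcal/mol.
#'
#' @details The function is antisymmetric in its two arguments, additive along
#'   a chain of states (`ddG(a, c) = ddG(a, b) + ddG(b, c)`), and invariant
#'   under multiplying both constants by the same positive factor.  Values are
#'   never rounded here; round only when formatting reports.
#'
#' @examples
#' delta_delta_g(1e-6, 1e-6)          # 0: same state
#' delta_delta_g(1 / 44, 1)           # ~ -2.24 kcal/mol for a 44-fold tighter state
#' @export
delta_delta_g <- function(kd1, kd2, temperature = 298,
                          gas_constant = R_KCAL) {
  stopifnot(is.numeric(kd1), is.numeric(kd2), is.numeric(temperature))
  if (any(!is.finite(kd1)) || any(kd1 <= 0))
    stop("'kd1' must be finite and > 0", call. = FALSE)
  if (any(!is.finite(kd2)) || any(kd2 <= 0))
    stop("'kd2' must be finite and > 0", call. = FALSE)
  if (any(temperature <= 0)) stop("'temperature' must be > 0 K", call. = FALSE)
  gas_constant * temperature * log(kd1 / kd2)
}

#' Fold change between two dissociation constants
#'
#' Ratio `kd_a / kd_b`; values above 1 mean state `a` binds more weakly than
#' state `b`.
#'
#' @param kd_a,kd_b Dissociation constants (M), both > 0. Vectorised.
#' @return Unitless ratio(s).
#' @examples
#' fold_change(206e-6, 15e-6)  # ~13.7-fold weaker
#' @export
fold_change <- function(kd_a, kd_b) {
  if (any(!is.finite(kd_a)) || any(kd_a <= 0) ||
      any(!is.finite(kd_b)) || any(kd_b <= 0))
    stop("dissociation constants must be finite and > 0", call. = FALSE)
  kd_a / kd_b
}

#' Free-energy difference with first-order error propagation
#'
#' Propagates uncertainties of the two dissociation constants into the
#' free-energy difference: `sigma_ddG = R*T*sqrt((s1/kd1)^2 + (s2/kd2)^2)`.
#' This is the usual delta-method approximation for `ln`, valid when the
#' relative errors are modest.
#'
#' @param kd1,kd2 Dissociation constants (M) of the state of interest and the
#'   reference state.
#' @param sd1,sd2 Their standard errors (M), `>= 0`. Default 0.
#' @inheritParams delta_delta_g
#'
#' @return A data frame with columns `ddg` and `sd`, both in kcal/mol.
#' @examples
#' propagate_uncertainty(340e-6, 90e-6, 1e-6)  # sd ~ 0.157 kcal/mol
#' @export
propagate_uncertainty <- function(kd1, sd1 = 0, kd2, sd2 = 0,
                                  temperature = 298, gas_constant = R_KCAL) {
  if (any(sd1 < 0) || any(sd2 < 0))
    stop("standard errors must be >= 0", call. = FALSE)
  ddg <- delta_delta_g(kd1, kd2, temperature, gas_constant)
  sd <- gas_constant * temperature * sqrt((sd1 / kd1)^2 + (sd2 / kd2)^2)
  data.frame(ddg = ddg, sd = sd)
}
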