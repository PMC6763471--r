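# Closed-form results: steady states, the long-time radius limit, the
# exponential-approach growth law, and the Hookean elastic strain.

#' Final cell radius
#'
#' The long-time limit of the cell radius under unperturbed growth,
#' `r_final = 3 k_uptake / k_consumption`. Uptake scales with the surface
#' and consumption with the volume, so growth stalls where the two balance;
#' wall mechanics and membrane permeability drop out of the limit.
#'
#' @param params a [cell_params()] object.
#' @return final radius in um.
#' @examples
#' r_final(cell_params()) # 3 um with the default constants
#' @export
r_final <- function(params) {
  stopifnot(inherits(params, "cell_params"))
  if (params$k_consumption == 0)
    stop("k_consumption = 0: the radius diverges (no final size)")
  3 * params$k_uptake / params$k_consumption
}

#' Approximate growth law for the cell radius
#'
#' Exponential approach of the radius to its final value,
#' `r(t) = r_final - (r_final - r_0) exp(-lambda (t - t_0))` with rate
#' `lambda = k_uptake R T / (r_final (Pi_ct + Pi_e))`. This is the
#' analytic simplification of the full ODE system under the quasi-steady
#' assumptions for turgor and osmolarity that hold during undisturbed
#' growth.
#'
#' @param params a [cell_params()] object.
#' @param r_0 radius at time `t_0` (um).
#' @param t_0 reference time (s).
#' @return an object of class `growth_law` with fields `r_final`, `r_0`,
#'   `t_0`, `lambda` (s^-1) and a function `radius(t)` evaluating the law.
#' @examples
#' gl <- growth_law(cell_params(), r_0 = 0.5)
#' gl$radius(c(0, 3600, 36000))
#' @export
growth_law <- function(params, r_0, t_0 = 0) {
  stopifnot(inherits(params, "cell_params"), r_0 > 0)
  rf <- r_final(params)
  Pi_e <- osmotic_pressure(params$c_e, params$temperature)
  # k_uptake * RT has units Pa um s^-1 once RT is taken per mmol um^-3
  lambda <- params$k_uptake * rt_internal(params$temperature) /
    (rf * (params$Pi_ct + Pi_e))
  gl <- list(
    r_final = rf, r_0 = r_0, t_0 = t_0, lambda = lambda,
    radius = function(t) rf - (rf - r_0) * exp(-lambda * (t - t_0))
  )
  class(gl) <- "growth_law"
  gl
}

#' @export
print.growth_law <- function(x, ...) {
  cat(sprintf(
    "Growth law: r_0 = %.3g um -> r_final = %.3g um, lambda = %.3g /s (tau = %.1f min)\n",
    x$r_0, x$r_final, x$lambda, 1 / x$lambda / 60))
  invisible(x)
}

#' Steady-state internal osmolarity during growth
#'
#' During growth turgor settles at the critical turgor pressure and water
#' flux is (quasi-)balanced, so the internal osmolarity is
#' `c_i = c_e + Pi_ct / (R T)`.
#'
#' @param params a [cell_params()] object.
#' @return osmolarity in mM.
#' @export
steady_osmolarity <- function(params) {
  stopifnot(inherits(params, "cell_params"))
  params$c_e + params$Pi_ct / (GAS_CONSTANT * params$temperature)
}

#' Internal osmolarity that balances a given turgor
#'
#' The internal osmolarity at which membrane water flux vanishes for turgor
#' `Pi_t0`: `c_i = c_e + Pi_t0 / (R T)`. Used to initialize simulations
#' from a measured turgor pressure.
#'
#' @param Pi_t0 turgor pressure in Pa (non-negative).
#' @param params a [cell_params()] object.
#' @return osmolarity in mM.
#' @export
initial_osmolarity_from_turgor <- function(Pi_t0, params) {
  stopifnot(inherits(params, "cell_params"), Pi_t0 >= 0)
  params$c_e + Pi_t0 / (GAS_CONSTANT * params$temperature)
}

#' Hookean elastic strain of the cell wall
#'
#' Linear thin-shell elastic strain under turgor:
#' `eps = (1 - nu)/E * Pi_t r / (2 d)`.
#'
#' @param Pi_t turgor pressure (Pa).
#' @param r cell radius (um).
#' @param params a [cell_params()] object.
#' @return dimensionless strain.
#' @export
elastic_strain <- function(Pi_t, r, params) {
  stopifnot(inherits(params, "cell_params"), r > 0)
  (1 - params$nu) / params$E * Pi_t * r / (2 * params$d)
}
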