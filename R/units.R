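#' @useDynLib scgm, .registration = TRUE
#' @importFrom stats median quantile cor rnorm rlnorm runif setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

# Internal unit system: length um, time s, pressure Pa, amount mmol.
# Concentrations are stored internally as mmol um^-3 and exposed as mM at
# every API boundary (1 mM = 1 mol m^-3 = 1e-15 mmol um^-3).

#' Physical constants
#'
#' The ideal gas constant in J mol^-1 K^-1.
#' @export
GAS_CONSTANT <- 8.314

# 1 mmol um^-3 expressed in mM
.MM_PER_MMOL_UM3 <- 1e15

#' Unit conversions
#'
#' Convert between the reporting units used throughout the interface
#' (mM, minutes, MPa) and the internal consistent unit system
#' (mmol um^-3, seconds, Pa). Round trips are exact to machine precision.
#'
#' @param x numeric vector to convert.
#' @return converted numeric vector.
#' @name unit-conversions
NULL

#' @rdname unit-conversions
#' @export
mM_to_mmol_um3 <- function(x) x / .MM_PER_MMOL_UM3

#' @rdname unit-conversions
#' @export
mmol_um3_to_mM <- function(x) x * .MM_PER_MMOL_UM3

#' @rdname unit-conversions
#' @export
min_to_s <- function(x) x * 60

#' @rdname unit-conversions
#' @export
s_to_min <- function(x) x / 60

#' @rdname unit-conversions
#' @export
MPa_to_Pa <- function(x) x * 1e6

#' @rdname unit-conversions
#' @export
Pa_to_MPa <- function(x) x / 1e6

#' Osmotic pressure from osmolarity (Boyle-van't Hoff)
#'
#' Converts an osmolyte concentration to the osmotic pressure it exerts,
#' `Pi = c R T`. A concentration in mM equals mol m^-3, so the product with
#' the gas constant (J mol^-1 K^-1) and temperature (K) is directly in Pa.
#'
#' @param c_mM osmolarity in mM (must be non-negative).
#' @param temperature temperature in K.
#' @return osmotic pressure in Pa.
#' @examples
#' osmotic_pressure(240, 303) # ~6.05e5 Pa for standard yeast medium
#' @export
osmotic_pressure <- function(c_mM, temperature = 303) {
  if (any(c_mM < 0)) stop("osmolarity must be non-negative")
  if (any(temperature <= 0)) stop("temperature must be positive")
  c_mM * GAS_CONSTANT * temperature
}

# RT expressed per internal concentration unit: Pa per (mmol um^-3)
rt_internal <- function(temperature) {
  GAS_CONSTANT * temperature * .MM_PER_MMOL_UM3
}
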