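#' Cell parameters for the single-cell growth model
#'
#' Container for the physical constants, rate constants and initial values
#' of one cell compartment. All values are given in reporting units:
#'
#' * `L_p` hydraulic conductivity per unit area (um s^-1 Pa^-1)
#' * `E` Young's modulus of the cell wall (Pa)
#' * `nu` Poisson's ratio (dimensionless, in (0, 0.5])
#' * `d` cell wall thickness (um)
#' * `phi` wall extensibility (Pa^-1 s^-1)
#' * `Pi_ct` critical turgor pressure, the plastic yield threshold (Pa)
#' * `k_uptake` osmolyte uptake rate constant (mmol um^-2 s^-1)
#' * `k_consumption` osmolyte consumption rate constant (mmol um^-3 s^-1)
#' * `c_e` external osmolarity (mM)
#' * `temperature` (K)
#' * `r_b0` radius of the solid (osmotically inactive) volume (um)
#' * `r_os0` initial radius of the osmotic volume (um)
#' * `Pi_t0` initial turgor pressure (Pa)
#' * `c_i0` initial internal osmolarity (mM); `NA` means "balance the
#'   initial turgor", i.e. `c_e + Pi_t0/(R T)` so water flux starts at zero
#'
#' The ratio `k_uptake / k_consumption` has units of length (um) and alone
#' fixes the final cell radius, `r_final = 3 k_uptake / k_consumption`.
#'
#' @param ... named parameter overrides of the defaults listed above.
#' @return an object of class `cell_params` (a named list).
#' @examples
#' p <- cell_params()
#' p$E
#' cell_params(k_uptake = 1.4e-16)$k_uptake
#' @export
cell_params <- function(...) {
  p <- default_params()
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_params(p)
}

#' Default parameter set
#'
#' The standard parameterization of the model: membrane permeability and
#' wall elasticity from single-cell measurements, critical turgor 0.2 MPa,
#' growth at 303 K in 240 mM medium, and equal osmolyte uptake and
#' consumption constants (2.0e-16), which place the final radius at 3 um.
#'
#' @return a `cell_params` object.
#' @export
default_params <- function() {
  p <- list(
    L_p = 1.19e-6,        # um s^-1 Pa^-1
    E = 2.58e6,           # Pa
    nu = 0.5,
    d = 0.115,            # um
    phi = 1e-3,           # Pa^-1 s^-1
    Pi_ct = 2.0e5,        # Pa
    k_uptake = 2.0e-16,   # mmol um^-2 s^-1
    k_consumption = 2.0e-16, # mmol um^-3 s^-1
    c_e = 240,            # mM
    temperature = 303,    # K
    r_b0 = 0.3,           # um
    r_os0 = 0.1,          # um
    Pi_t0 = 2.0e5,        # Pa
    c_i0 = NA_real_       # mM; NA -> c_e + Pi_t0/RT
  )
  class(p) <- "cell_params"
  p
}

validate_params <- function(p) {
  stopifnot(is.list(p))
  pos <- c("L_p", "E", "d", "phi", "Pi_ct", "k_uptake", "k_consumption",
           "temperature", "r_b0", "r_os0")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0)
      stop("parameter '", nm, "' must be a positive scalar")
  }
  if (!is.numeric(p$nu) || p$nu <= 0 || p$nu > 0.5)
    stop("Poisson's ratio 'nu' must lie in (0, 0.5]")
  if (p$c_e < 0) stop("external osmolarity 'c_e' must be non-negative")
  if (p$Pi_t0 < 0) stop("initial turgor 'Pi_t0' must be non-negative")
  if (!is.na(p$c_i0) && p$c_i0 < 0)
    stop("initial osmolarity 'c_i0' must be non-negative")
  class(p) <- "cell_params"
  p
}

#' @export
print.cell_params <- function(x, ...) {
  cat("Single-cell growth model parameters\n")
  cat(sprintf("  wall:      E = %.3g Pa, nu = %.2f, d = %.3g um, phi = %.3g /Pa/s\n",
              x$E, x$nu, x$d, x$phi))
  cat(sprintf("  membrane:  L_p = %.3g um/s/Pa, Pi_ct = %.3g Pa\n",
              x$L_p, x$Pi_ct))
  cat(sprintf("  osmolytes: k_uptake = %.3g, k_consumption = %.3g (k_u/c = %.3g um)\n",
              x$k_uptake, x$k_consumption, x$k_uptake / x$k_consumption))
  cat(sprintf("  medium:    c_e = %.4g mM, T = %.4g K\n", x$c_e, x$temperature))
  cat(sprintf("  initial:   r_os0 = %.3g um, r_b0 = %.3g um, Pi_t0 = %.3g Pa\n",
              x$r_os0, x$r_b0, x$Pi_t0))
  invisible(x)
}

#' Load / save parameter files
#'
#' Parameter files are YAML or JSON maps keyed by the `cell_params` field
#' names with values in reporting units. Unknown keys are an error; values
#' are validated for positivity on load.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @param params a `cell_params` object (for writing).
#' @return `read_params()` returns a `cell_params` object.
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported parameter file extension: ", ext)
  )
  do.call(cell_params, as.list(vals))
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "cell_params"))
  ext <- tolower(tools::file_ext(path))
  vals <- unclass(params)
  vals <- vals[!vapply(vals, function(v) is.na(v), logical(1))]
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(vals, path),
    json = jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported parameter file extension: ", ext)
  )
  invisible(path)
}
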