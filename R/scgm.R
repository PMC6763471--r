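# Single-compartment SCGM: state, ODE right-hand side pieces, and the
# integration driver.
#
# The model couples three state variables through water flux across the
# membrane and the mechanics of a thin-shell elasto-viscoplastic wall:
#   dV_os/dt = -J_w                         (volume follows water flux)
#   J_w      = L_p G (Pi_t + Pi_e - Pi_i)   (Kedem-Katchalsky, >0 outward)
#   dc_i/dt  = (k_u G - k_c V_t - c_i dV_os/dt) / V_os
#   dPi_t/dt = 2Ed/(1-nu) rdot/r^2 - Pi_t rdot/r - E phi/(1-nu) f_m
# with the Bingham yield term f_m = max(Pi_t - Pi_ct, 0).

#' Instantaneous cell state
#'
#' @param V_os osmotic (water-accessible) volume, um^3.
#' @param V_b solid volume (osmotically inactive), um^3.
#' @param Pi_t turgor pressure, Pa.
#' @param c_i internal osmolarity, mM.
#' @return a `cell_state` with derived total volume `V_t`, radius `r`
#'   (from the total volume: the wall encloses the whole cell) and surface
#'   area `G`.
#' @export
cell_state <- function(V_os, V_b, Pi_t, c_i) {
  stopifnot(V_os > 0, V_b >= 0, c_i >= 0)
  V_t <- V_os + V_b
  r <- (3 * V_t / (4 * pi))^(1 / 3)
  s <- list(V_os = V_os, V_b = V_b, Pi_t = Pi_t, c_i = c_i,
            V_t = V_t, r = r, G = 4 * pi * r^2)
  class(s) <- "cell_state"
  s
}

#' Initial state implied by a parameter set
#'
#' Builds the state at `t = 0` from the initial radii, initial turgor and
#' (unless given) the osmolarity that balances that turgor, so the
#' simulation starts with zero water flux.
#'
#' @param params a [cell_params()] object.
#' @return a [cell_state()].
#' @export
initial_state <- function(params) {
  stopifnot(inherits(params, "cell_params"))
  c_i0 <- if (is.na(params$c_i0)) {
    initial_osmolarity_from_turgor(params$Pi_t0, params)
  } else {
    params$c_i0
  }
  cell_state(V_os = sphere_volume(params$r_os0),
             V_b = sphere_volume(params$r_b0),
             Pi_t = params$Pi_t0, c_i = c_i0)
}

sphere_volume <- function(r) 4 / 3 * pi * r^3

#' Membrane water flux
#'
#' Kedem-Katchalsky volumetric water flux across the membrane,
#' `J_w = L_p G (Pi_t + Pi_e - Pi_i)`. Positive flux is outward, so
#' `dV_os/dt = -J_w`.
#'
#' @param state a [cell_state()].
#' @param params a [cell_params()].
#' @param c_e_now current external osmolarity in mM (defaults to the
#'   parameter set's `c_e`).
#' @return volumetric flux in um^3 s^-1.
#' @export
water_flux <- function(state, params, c_e_now = params$c_e) {
  stopifnot(inherits(state, "cell_state"), inherits(params, "cell_params"))
  Pi_e <- osmotic_pressure(c_e_now, params$temperature)
  Pi_i <- osmotic_pressure(state$c_i, params$temperature)
  params$L_p * state$G * (state$Pi_t + Pi_e - Pi_i)
}

#' Internal osmolarity rate
#'
#' Osmolyte uptake scales with the cell surface, consumption with the
#' total cell volume, and volume change dilutes (or concentrates) the
#' osmolytes dissolved in the osmotic water:
#' `dc_i/dt = (k_u G - k_c V_t)/V_os - c_i (dV_os/dt)/V_os`.
#'
#' @param state a [cell_state()].
#' @param params a [cell_params()].
#' @param Vdot rate of change of the osmotic volume, um^3 s^-1.
#' @return `dc_i/dt` in mM s^-1.
#' @export
osmolyte_rate <- function(state, params, Vdot = 0) {
  stopifnot(inherits(state, "cell_state"), inherits(params, "cell_params"))
  amount <- (params$k_uptake * state$G - params$k_consumption * state$V_t) /
    state$V_os # mmol um^-3 s^-1
  mmol_um3_to_mM(amount) - state$c_i * Vdot / state$V_os
}

#' Turgor pressure rate
#'
#' Serial Hookean + Bingham thin-shell wall mechanics expressed as a
#' single turgor ODE: elastic loading by radial expansion, the geometric
#' shell term, and plastic stress relaxation above the yield threshold.
#'
#' @param state a [cell_state()].
#' @param params a [cell_params()].
#' @param rdot rate of change of the radius, um s^-1.
#' @return `dPi_t/dt` in Pa s^-1.
#' @export
turgor_rate <- function(state, params, rdot = 0) {
  stopifnot(inherits(state, "cell_state"), inherits(params, "cell_params"))
  fm <- max(state$Pi_t - params$Pi_ct, 0)
  2 * params$E * params$d / (1 - params$nu) * rdot / state$r^2 -
    state$Pi_t * rdot / state$r -
    params$E * params$phi / (1 - params$nu) * fm
}

#' Assembled model right-hand side
#'
#' Reference (pure R) evaluation of the coupled derivative vector; the
#' integrator uses an equivalent compiled version. The radius rate follows
#' from the volume rate by the geometric chain rule `rdot = Vdot / G`
#' (solid volume constant).
#'
#' @param t time in seconds.
#' @param state a [cell_state()].
#' @param params a [cell_params()].
#' @param protocol a [shock_protocol()] (empty protocol means constant
#'   external osmolarity `params$c_e`).
#' @return named list with `dV_os` (um^3/s), `dPi_t` (Pa/s), `dc_i`
#'   (mM/s), `rdot` (um/s) and the instantaneous `J_w`.
#' @export
scgm_rhs <- function(t, state, params, protocol = shock_protocol()) {
  if (!all(is.finite(c(state$V_os, state$Pi_t, state$c_i))))
    stop("non-finite state at t = ", t)
  c_e_now <- protocol_value(protocol, t, params$c_e)
  J_w <- water_flux(state, params, c_e_now)
  dV <- -J_w
  rdot <- dV / state$G
  dPi <- turgor_rate(state, params, rdot)
  if (state$Pi_t <= 0 && dPi < 0) dPi <- 0
  list(dV_os = dV, dPi_t = dPi, dc_i = osmolyte_rate(state, params, dV),
       rdot = rdot, J_w = J_w)
}

#' Wall-mechanics regime
#'
#' `"EP"` (elasto-plastic, the wall yields and the cell grows) when the
#' turgor is at or above the critical turgor, `"E"` (ideal elastic) below.
#'
#' @param Pi_t turgor pressure(s), Pa.
#' @param Pi_ct critical turgor pressure, Pa.
#' @return character vector of `"E"` / `"EP"` flags.
#' @export
classify_regime <- function(Pi_t, Pi_ct) {
  ifelse(Pi_t >= Pi_ct, "EP", "E")
}

# default per-state absolute tolerances (internal units)
.default_atol <- function() {
  c(V_os = 1e-6, Pi_t = 1e-2, c_i = 1e-24, ln_rref = 1e-8,
    H = 1e-8, c_gly = 1e-24)
}

#' Simulate the single-cell growth model
#'
#' Adaptive stiff integration (`deSolve::lsoda`, compiled right-hand
#' side) of the three-ODE model, restarted at every protocol step so the
#' discontinuity in external osmolarity never falls inside an integrator
#' step. The reference radius -- the accumulated irreversible (plastic)
#' wall deformation -- is co-integrated, and each output row is labelled
#' with the elastic/elasto-plastic regime flag.
#'
#' @param params a [cell_params()] object.
#' @param initial a [cell_state()]; defaults to [initial_state()].
#' @param protocol a [shock_protocol()].
#' @param t_end simulation horizon in seconds.
#' @param dt_out output sampling interval in seconds.
#' @param hog optional [hog_params()]; when supplied, the active
#'   osmotic-stress response is co-integrated and the trajectory gains
#'   `hog1_active_fraction` and `c_gly_mM` columns.
#' @param rtol,atol integrator tolerances (`atol` per state, internal
#'   units).
#' @return a `scgm_trajectory`: a data frame with columns `time_s`,
#'   `V_os_um3`, `V_t_um3`, `r_um`, `Pi_t_Pa`, `c_i_mM`, `c_e_mM`,
#'   `J_w_um3_s`, `r_ref_um`, `regime`.
#' @examples
#' traj <- simulate_scgm(cell_params(), t_end = 600, dt_out = 60)
#' tail(traj, 2)
#' @export
simulate_scgm <- function(params, initial = NULL,
                          protocol = shock_protocol(),
                          t_end, dt_out = 60, hog = NULL,
                          rtol = 1e-8, atol = .default_atol()) {
  stopifnot(inherits(params, "cell_params"), t_end > 0, dt_out > 0)
  if (is.null(initial)) initial <- initial_state(params)
  stopifnot(inherits(initial, "cell_state"))
  if (!is.null(hog)) stopifnot(inherits(hog, "hog_params"))
  h <- if (is.null(hog)) hog_params_off() else hog

  RT <- rt_internal(params$temperature)
  parms <- c(params$L_p, params$E, params$nu, params$d, params$phi,
             params$Pi_ct, params$k_uptake, params$k_consumption,
             NA, # c_e slot, set per segment
             initial$V_b, RT,
             h$k_act, h$k_deact, mM_to_mmol_um3(h$k_gly), h$k_leak,
             h$Pi_ref)

  y <- c(V_os = initial$V_os, Pi_t = initial$Pi_t,
         c_i = mM_to_mmol_um3(initial$c_i),
         ln_rref = log(initial$r), H = h$H0,
         c_gly = mM_to_mmol_um3(h$c_gly0))

  grid <- seq(0, t_end, by = dt_out)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  segs <- protocol_segments(protocol, 0, t_end, params$c_e)

  rows <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    parms[9] <- mM_to_mmol_um3(segs$c_e_mM[i])
    inner <- grid[grid > segs$start[i] & grid < segs$end[i]]
    times <- unique(c(segs$start[i], inner, segs$end[i]))
    out <- deSolve::lsoda(y, times, func = "scgm_derivs", parms = parms,
                          dllname = "scgm", initfunc = "scgm_init",
                          nout = 1, outnames = "J_w",
                          rtol = rtol, atol = atol, maxsteps = 50000)
    if (attr(out, "istate")[1] < 0 || any(!is.finite(out)))
      stop(sprintf(
        "integrator failure in segment [%g, %g] s; last valid t = %g s",
        segs$start[i], segs$end[i], max(out[stats::complete.cases(out), 1])))
    # report grid rows only; a protocol-step time belongs to the segment it
    # starts (c_e is right-continuous)
    sel <- out[, "time"] %in% grid
    if (i < nrow(segs)) sel <- sel & out[, "time"] < segs$end[i]
    rows[[i]] <- cbind(out[sel, , drop = FALSE], c_e = segs$c_e_mM[i])
    y <- out[nrow(out), 1 + seq_along(y)]
    names(y) <- names(.default_atol())
  }
  out <- do.call(rbind, rows)

  traj <- data.frame(
    time_s = out[, "time"],
    V_os_um3 = out[, "V_os"],
    V_t_um3 = out[, "V_os"] + initial$V_b,
    Pi_t_Pa = out[, "Pi_t"],
    c_i_mM = mmol_um3_to_mM(out[, "c_i"]),
    c_e_mM = out[, "c_e"],
    J_w_um3_s = out[, "J_w"],
    r_ref_um = exp(out[, "ln_rref"])
  )
  traj$r_um <- (3 * traj$V_t_um3 / (4 * pi))^(1 / 3)
  traj$regime <- classify_regime(traj$Pi_t_Pa, params$Pi_ct)
  if (!is.null(hog)) {
    traj$hog1_active_fraction <- out[, "H"]
    traj$c_gly_mM <- mmol_um3_to_mM(out[, "c_gly"])
  }
  traj <- traj[, c("time_s", "V_os_um3", "V_t_um3", "r_um", "Pi_t_Pa",
                   "c_i_mM", "c_e_mM", "J_w_um3_s", "r_ref_um", "regime",
                   intersect(c("hog1_active_fraction", "c_gly_mM"),
                             names(traj)))]
  attr(traj, "params") <- params
  attr(traj, "hog") <- hog
  attr(traj, "protocol") <- protocol
  class(traj) <- c("scgm_trajectory", "data.frame")
  traj
}

#' Write a trajectory to CSV
#'
#' @param traj a `scgm_trajectory` (or coupled trajectory) data frame.
#' @param path output file path.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
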