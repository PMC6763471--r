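# Coupled mother-bud (and mother-two-bud) model. Compartments are linked
# by water exchange along the water-potential difference (Pi_t - Pi_i) and
# osmolyte exchange along the concentration difference, chosen fast enough
# that gradients between the compartments vanish on the growth time scale.
#
# Two integration paths implement that regime:
# * "instant" (default): the fast-exchange limit. The compartments share
#   one osmolarity and one turgor; the common turgor and the compartment
#   radii are solved per step from the integrated wall relations
#   ln r = ln r_ref + (1 - nu)/(2 d E) Pi r plus the water constraint.
#   This resolves the sub-mPa working over-pressures of osmolyte-limited
#   growth, which no integrable finite exchange coefficient can.
# * "explicit": finite L_x/k_x fluxes integrated directly. Adequate when
#   the pressures of interest are elastic-scale (1e4-1e5 Pa), e.g. for
#   the Young's-modulus sweep, and used to demonstrate gap decay.

#' Parameters of the coupled mother-bud model
#'
#' The bud inherits every mother parameter except the wall extensibility
#' (`phi_bud = q * phi_mother`) and, optionally, the Young's modulus. The
#' bud is instantiated at `t_budstart` with the mother's initial osmotic
#' radius (both compartments start from the same small volume) and the
#' mother's instantaneous turgor and osmolarity (continuity of the shared
#' cytoplasm).
#'
#' @param mother a [cell_params()] object for the mother compartment.
#' @param q extensibility ratio `phi_bud / phi_mother` (> 0).
#' @param t_budstart bud initialization time in seconds (>= 0).
#' @param r_bud_init initial osmotic radius of the bud (um); defaults to
#'   the mother's initial osmotic radius.
#' @param E_bud Young's modulus of the bud wall (Pa); defaults to the
#'   mother's.
#' @param L_x inter-compartment water exchange coefficient
#'   (um^3 s^-1 Pa^-1); default `1e6 * L_p * G(r_bud_init)`, far above the
#'   membrane flux scale of the young bud. Used by the `"explicit"`
#'   integration path; the default `"instant"` path is its limit.
#' @param k_x inter-compartment osmolyte exchange coefficient (um^3 s^-1);
#'   default `1e9 * k_uptake * G(r_bud_init) / c_e`.
#' @return an object of class `coupled_params`.
#' @export
coupled_params <- function(mother = cell_params(), q = 230,
                           t_budstart = 93 * 60,
                           r_bud_init = mother$r_os0,
                           E_bud = mother$E,
                           L_x = NULL, k_x = NULL) {
  stopifnot(inherits(mother, "cell_params"), q > 0, t_budstart >= 0,
            r_bud_init > 0, E_bud > 0)
  # bud solid volume scales with the cube of its initial osmotic radius
  V_b_bud <- sphere_volume(mother$r_b0) * (r_bud_init / mother$r_os0)^3
  r_bud_total <- ((sphere_volume(r_bud_init) + V_b_bud) * 3 / (4 * pi))^(1 / 3)
  G_bud <- 4 * pi * r_bud_total^2
  if (is.null(L_x)) L_x <- 1e6 * mother$L_p * G_bud
  if (is.null(k_x))
    k_x <- 1e9 * mother$k_uptake * G_bud / mM_to_mmol_um3(mother$c_e)
  stopifnot(L_x > 0, k_x > 0)
  structure(list(mother = mother, q = q, t_budstart = t_budstart,
                 r_bud_init = r_bud_init, V_b_bud = V_b_bud,
                 E_bud = E_bud, L_x = L_x, k_x = k_x),
            class = "coupled_params")
}

#' @export
print.coupled_params <- function(x, ...) {
  cat(sprintf(
    "Coupled mother-bud parameters: q = %.3g, t_budstart = %.1f min,\n  r_bud_init = %.3g um, L_x = %.3g um3/s/Pa, k_x = %.3g um3/s\n",
    x$q, x$t_budstart / 60, x$r_bud_init, x$L_x, x$k_x))
  print(x$mother)
  invisible(x)
}

#' Inter-compartment exchange fluxes
#'
#' Water flows from the compartment with the higher water potential
#' (`Pi_t - Pi_i`) to the other; osmolytes flow down the concentration
#' difference. Both fluxes are antisymmetric under swapping the
#' compartments, so exchange alone conserves water and osmolyte amounts.
#'
#' @param mother,bud [cell_state()] objects.
#' @param coupled a [coupled_params()] object.
#' @return list with `water` (um^3 s^-1, positive mother to bud) and
#'   `osmolyte` (mmol s^-1, positive mother to bud).
#' @export
exchange_fluxes <- function(mother, bud, coupled) {
  stopifnot(inherits(mother, "cell_state"), inherits(bud, "cell_state"),
            inherits(coupled, "coupled_params"))
  temp <- coupled$mother$temperature
  psi_m <- mother$Pi_t - osmotic_pressure(mother$c_i, temp)
  psi_b <- bud$Pi_t - osmotic_pressure(bud$c_i, temp)
  list(water = coupled$L_x * (psi_m - psi_b),
       osmolyte = coupled$k_x *
         (mM_to_mmol_um3(mother$c_i) - mM_to_mmol_um3(bud$c_i)))
}

# pack the parms vector for the compiled coupled RHS
.cscgm_parms <- function(coupled, n_comp, V_b_buds) {
  m <- coupled$mother
  per_comp <- c(m$phi, m$E, NA, # mother V_b filled by caller
                m$phi * coupled$q, coupled$E_bud, V_b_buds[1],
                m$phi * coupled$q, coupled$E_bud,
                if (length(V_b_buds) > 1) V_b_buds[2] else 0)
  c(n_comp, m$L_p, m$nu, m$d, m$Pi_ct, m$k_uptake, m$k_consumption,
    mM_to_mmol_um3(m$c_e), rt_internal(m$temperature),
    coupled$L_x, coupled$k_x, per_comp)
}

.coupled_atol <- function(n_comp) {
  rep(c(1e-6, 1e-2, 1e-24, 1e-8), n_comp)
}

# run the joint integration from t_budstart on; `buds` is a list of
# initial bud states (1 or 2)
.integrate_joint <- function(coupled, mother_state, buds, times,
                             rtol, maxsteps = 20000) {
  n_comp <- 1 + length(buds)
  V_b_buds <- vapply(buds, function(b) b$V_b, numeric(1))
  parms <- .cscgm_parms(coupled, n_comp, V_b_buds)
  parms[11 + 3] <- mother_state$V_b
  y <- c(mother_state$V_os, mother_state$Pi_t,
         mM_to_mmol_um3(mother_state$c_i), log(mother_state$r))
  for (b in buds)
    y <- c(y, b$V_os, b$Pi_t, mM_to_mmol_um3(b$c_i), log(b$r))
  out <- deSolve::lsoda(y, times, func = "cscgm_derivs", parms = parms,
                        dllname = "scgm", initfunc = "cscgm_init",
                        rtol = rtol, atol = .coupled_atol(n_comp),
                        maxsteps = maxsteps)
  if (attr(out, "istate")[1] < 0 || any(!is.finite(out)))
    stop(sprintf("integrator failure in coupled phase; last valid t = %g s",
                 max(out[stats::complete.cases(out), 1])))
  out
}

# columns for compartment j (1-based) of a joint-integration output
.comp_cols <- function(out, j, V_b, Pi_ct) {
  V_os <- out[, 4 * (j - 1) + 2]
  V_t <- V_os + V_b
  data.frame(
    V_os = V_os, V_t = V_t, r = (3 * V_t / (4 * pi))^(1 / 3),
    Pi_t = out[, 4 * (j - 1) + 3],
    c_i = mmol_um3_to_mM(out[, 4 * (j - 1) + 4]),
    r_ref = exp(out[, 4 * (j - 1) + 5]),
    regime = classify_regime(out[, 4 * (j - 1) + 3], Pi_ct)
  )
}

# joint phase in the fast-exchange limit: shared turgor and osmolarity
.integrate_joint_fast <- function(coupled, mother_state, buds, Pi_now,
                                  times, rtol) {
  m <- coupled$mother
  n_comp <- 1 + length(buds)
  V_b_buds <- vapply(buds, function(b) b$V_b, numeric(1))
  parms <- .cscgm_parms(coupled, n_comp, V_b_buds)
  parms[11 + 3] <- mother_state$V_b
  a <- c((1 - m$nu) / (2 * m$d * m$E),
         rep((1 - m$nu) / (2 * m$d * coupled$E_bud), length(buds)))
  radii <- c(mother_state$r, vapply(buds, function(b) b$r, numeric(1)))
  lnrref <- log(radii) - a * Pi_now * radii # mechanical reference radii
  V_tot <- mother_state$V_os + sum(vapply(buds, function(b) b$V_os,
                                          numeric(1)))
  y <- c(V_tot, mM_to_mmol_um3(mother_state$c_i) * V_tot, Pi_now, lnrref)
  out <- deSolve::lsoda(y, times, func = "cscgm_fast_derivs",
                        parms = parms, dllname = "scgm",
                        initfunc = "cscgm_fast_init",
                        nout = n_comp,
                        outnames = paste0("r", seq_len(n_comp)),
                        rtol = rtol,
                        atol = c(1e-6, 1e-22, 1e-2, rep(1e-8, n_comp)),
                        maxsteps = 20000)
  if (attr(out, "istate")[1] < 0 || any(!is.finite(out)))
    stop(sprintf("integrator failure in coupled phase; last valid t = %g s",
                 max(out[stats::complete.cases(out), 1])))
  out
}

# compartment columns from a fast-limit joint output
# (cols: 1 time, 2 V_tot, 3 N, 4 Pi, 4+j lnrref_j, 4+n_comp+j r_j)
.comp_cols_fast <- function(out, j, n_comp, V_b, Pi_ct) {
  r <- out[, 4 + n_comp + j]
  Pi <- out[, 4]
  V_t <- 4 / 3 * pi * r^3
  data.frame(
    V_os = V_t - V_b, V_t = V_t, r = r, Pi_t = Pi,
    c_i = mmol_um3_to_mM(out[, 3] / out[, 2]),
    r_ref = exp(out[, 4 + j]),
    regime = classify_regime(Pi, Pi_ct)
  )
}

.rename_comp <- function(df, suffix) {
  names(df) <- paste0(names(df), "_", suffix)
  df
}

#' Simulate the coupled mother-bud model
#'
#' The mother evolves alone until `t_budstart` (identical dynamics to
#' [simulate_scgm()] with the same parameters); at `t_budstart` a bud with
#' extensibility `q * phi_mother` is instantiated and the joint system is
#' integrated with water and osmolyte exchange. Uptake and consumption
#' constants are identical in both compartments.
#'
#' @param coupled a [coupled_params()] object.
#' @param t_end horizon in seconds (> `t_budstart`).
#' @param dt_out output interval in seconds.
#' @param rtol integrator relative tolerance.
#' @param exchange `"instant"` (fast-exchange limit, default) or
#'   `"explicit"` (finite `L_x`/`k_x` fluxes).
#' @return a `scgm_coupled_trajectory` data frame with `time_s` and, per
#'   compartment (`_mother`, `_bud`), columns `V_os`, `V_t`, `r`, `Pi_t`,
#'   `c_i`, `r_ref`, `regime`. Bud columns are `NA` before `t_budstart`.
#' @examples
#' \donttest{
#' cp <- coupled_params(q = 100, t_budstart = 60 * 60)
#' traj <- simulate_coupled(cp, t_end = 240 * 60, dt_out = 180)
#' }
#' @export
simulate_coupled <- function(coupled, t_end, dt_out = 180, rtol = 1e-8,
                             exchange = c("instant", "explicit")) {
  stopifnot(inherits(coupled, "coupled_params"), t_end > coupled$t_budstart)
  .simulate_multi(coupled, bud_radii = coupled$r_bud_init,
                  t_end = t_end, dt_out = dt_out, rtol = rtol,
                  exchange = match.arg(exchange))
}

#' Simulate a mother with two simultaneous buds
#'
#' Both buds exchange water and osmolytes with the mother but not with
#' each other. Equal initial sizes give identical bud trajectories; a
#' small initial difference is amplified and only the larger bud grows.
#'
#' @param coupled a [coupled_params()] object (bud 1 uses its
#'   `r_bud_init`).
#' @param r_bud2_init initial osmotic radius of the second bud (um).
#' @param t_end horizon in seconds.
#' @param dt_out output interval in seconds.
#' @param rtol integrator relative tolerance.
#' @return as [simulate_coupled()], with additional `_bud2` columns.
#' @param exchange `"instant"` or `"explicit"`, as in [simulate_coupled()].
#' @export
simulate_two_buds <- function(coupled, r_bud2_init = coupled$r_bud_init,
                              t_end, dt_out = 180, rtol = 1e-8,
                              exchange = c("instant", "explicit")) {
  stopifnot(inherits(coupled, "coupled_params"), r_bud2_init > 0,
            t_end > coupled$t_budstart)
  .simulate_multi(coupled,
                  bud_radii = c(coupled$r_bud_init, r_bud2_init),
                  t_end = t_end, dt_out = dt_out, rtol = rtol,
                  exchange = match.arg(exchange))
}

.simulate_multi <- function(coupled, bud_radii, t_end, dt_out, rtol,
                            exchange = "instant") {
  m <- coupled$mother
  tb <- coupled$t_budstart
  suffixes <- c("bud", "bud2")[seq_along(bud_radii)]

  grid <- seq(0, t_end, by = dt_out)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)

  # mother-only phase: same code path as the single-compartment model
  if (tb > 0) {
    pre <- simulate_scgm(m, t_end = tb, dt_out = dt_out, rtol = rtol)
    mother_now <- cell_state(
      V_os = pre$V_os_um3[nrow(pre)], V_b = pre$V_t_um3[1] - pre$V_os_um3[1],
      Pi_t = pre$Pi_t_Pa[nrow(pre)], c_i = pre$c_i_mM[nrow(pre)])
    rref_now <- pre$r_ref_um[nrow(pre)]
    pre <- pre[pre$time_s %in% grid & pre$time_s < tb, , drop = FALSE]
  } else {
    mother_now <- initial_state(m)
    rref_now <- mother_now$r
    pre <- NULL
  }

  # bud states inherit the mother's instantaneous turgor and osmolarity
  mk_bud <- function(r_os) {
    cell_state(V_os = sphere_volume(r_os),
               V_b = sphere_volume(m$r_b0) * (r_os / m$r_os0)^3,
               Pi_t = mother_now$Pi_t, c_i = mother_now$c_i)
  }
  buds <- lapply(bud_radii, mk_bud)

  times <- unique(c(tb, grid[grid > tb & grid < t_end], t_end))
  if (exchange == "explicit") {
    out <- .integrate_joint(coupled, mother_now, buds, times, rtol)
  } else {
    out <- .integrate_joint_fast(coupled, mother_now, buds,
                                 Pi_now = mother_now$Pi_t, times, rtol)
  }
  sel <- times %in% c(grid, tb)
  out <- out[sel, , drop = FALSE]

  comp_cols <- function(j, V_b) {
    if (exchange == "explicit") .comp_cols(out, j, V_b, m$Pi_ct)
    else .comp_cols_fast(out, j, 1 + length(buds), V_b, m$Pi_ct)
  }
  joint <- data.frame(time_s = out[, 1])
  mcols <- comp_cols(1, mother_now$V_b)
  # r_ref is reported relative to its phase-1 normalisation (r_ref(0) =
  # r(0)); the joint phase integrates only its log-increments
  mcols$r_ref <- mcols$r_ref * (rref_now / mcols$r_ref[1])
  joint <- cbind(joint, .rename_comp(mcols, "mother"))
  for (k in seq_along(buds)) {
    bcols <- comp_cols(k + 1, buds[[k]]$V_b)
    bcols$r_ref <- bcols$r_ref * (buds[[k]]$r / bcols$r_ref[1])
    joint <- cbind(joint, .rename_comp(bcols, suffixes[k]))
  }

  if (!is.null(pre)) {
    pre_df <- data.frame(time_s = pre$time_s)
    pre_m <- data.frame(V_os = pre$V_os_um3, V_t = pre$V_t_um3, r = pre$r_um,
                        Pi_t = pre$Pi_t_Pa, c_i = pre$c_i_mM,
                        r_ref = pre$r_ref_um, regime = pre$regime)
    pre_df <- cbind(pre_df, .rename_comp(pre_m, "mother"))
    for (sfx in suffixes) {
      empty <- data.frame(V_os = NA_real_, V_t = NA_real_, r = NA_real_,
                          Pi_t = NA_real_, c_i = NA_real_, r_ref = NA_real_,
                          regime = NA_character_)
      pre_df <- cbind(pre_df, .rename_comp(empty[rep(1, nrow(pre_df)), ],
                                           sfx))
    }
    rownames(pre_df) <- NULL
    joint <- rbind(pre_df, joint)
  }

  attr(joint, "coupled_params") <- coupled
  attr(joint, "t_budstart") <- tb
  class(joint) <- c("scgm_coupled_trajectory", "data.frame")
  joint
}

#' Sweep the mother-bud extensibility ratio
#'
#' Runs the coupled model over a grid of extensibility ratios `q` and
#' reports, for each, whether the bud and the mother expanded over the
#' horizon. The threshold ratio is the smallest `q` whose bud volume grew
#' by at least `growth_factor`.
#'
#' @param q_values extensibility ratios to test.
#' @param coupled base [coupled_params()] (its `q` is overridden).
#' @param t_end horizon in seconds.
#' @param growth_factor fold-change in bud total volume that counts as
#'   expansion. Below the threshold a stalled bud still creeps by a few
#'   fold over several hours (elastic stretch plus residual yield), while
#'   an expanding bud gains two to three orders of magnitude, so any
#'   factor in roughly 7-700 identifies the same transition; 10 sits well
#'   inside that window.
#' @param dt_out output interval (s).
#' @param rtol integrator relative tolerance.
#' @return data frame with columns `q`, `v_bud_start`, `v_bud_end`,
#'   `v_mother_end`, `bud_grew`, `mother_grew`; the threshold is in
#'   `attr(, "q_threshold")` (`NA` if no tested ratio expanded).
#' @export
sweep_extensibility <- function(q_values, coupled = coupled_params(),
                                t_end = 480 * 60, growth_factor = 10,
                                dt_out = 180, rtol = 1e-8) {
  res <- lapply(q_values, function(qv) {
    cp <- coupled
    cp$q <- qv
    traj <- simulate_coupled(cp, t_end = t_end, dt_out = dt_out, rtol = rtol)
    budded <- !is.na(traj$V_t_bud)
    v0 <- traj$V_t_bud[which(budded)[1]]
    vT <- traj$V_t_bud[nrow(traj)]
    vm0 <- traj$V_t_mother[which(budded)[1]]
    vmT <- traj$V_t_mother[nrow(traj)]
    data.frame(q = qv, v_bud_start = v0, v_bud_end = vT,
               v_mother_end = vmT,
               bud_grew = vT >= growth_factor * v0,
               mother_grew = vmT > vm0)
  })
  res <- do.call(rbind, res)
  grew <- res$q[res$bud_grew]
  attr(res, "q_threshold") <- if (length(grew)) min(grew) else NA_real_
  res
}

#' Sweep the bud-to-mother Young's modulus ratio
#'
#' With equal extensibilities (`q = 1`), tests whether softening or
#' stiffening the bud wall (`E_bud = ratio * E_mother`) lets the bud
#' expand, and what it costs the mother. Uses the explicit-exchange
#' integrator: a strongly softened bud expands through an elastic
#' instability, where the finite water supply through the neck limits the
#' dynamics and pressure differences are elastic-scale.
#'
#' @param E_ratios ratios `E_bud / E_mother` to test.
#' @param coupled base [coupled_params()]; `q` is forced to 1.
#' @param t_end horizon in seconds.
#' @param growth_factor fold-change in total volume that counts as growth.
#' @param dt_out output interval (s).
#' @return data frame with columns `E_ratio`, `bud_grew`, `mother_grew`,
#'   `v_bud_end`, `v_mother_end`.
#' @export
sweep_young_modulus <- function(E_ratios, coupled = coupled_params(),
                                t_end = 480 * 60, growth_factor = 2,
                                dt_out = 180) {
  stopifnot(all(E_ratios > 0))
  res <- lapply(E_ratios, function(er) {
    cp <- coupled
    cp$q <- 1
    cp$E_bud <- er * coupled$mother$E
    traj <- simulate_coupled(cp, t_end = t_end, dt_out = dt_out,
                             exchange = "explicit")
    budded <- !is.na(traj$V_t_bud)
    v0 <- traj$V_t_bud[which(budded)[1]]
    vm0 <- traj$V_t_mother[which(budded)[1]]
    data.frame(E_ratio = er,
               bud_grew = traj$V_t_bud[nrow(traj)] >= growth_factor * v0,
               mother_grew = traj$V_t_mother[nrow(traj)] >
                 growth_factor * vm0,
               v_bud_end = traj$V_t_bud[nrow(traj)],
               v_mother_end = traj$V_t_mother[nrow(traj)])
  })
  do.call(rbind, res)
}

#' Export a paired trajectory in the fitting input format
#'
#' Writes `time_min`, `v_mother_um3`, `v_bud_um3` (and `v_bud2_um3` when
#' present), volumes being total volumes as seen by microscopy.
#'
#' @param traj a `scgm_coupled_trajectory`.
#' @param path output CSV path.
#' @export
write_paired_csv <- function(traj, path) {
  stopifnot(inherits(traj, "scgm_coupled_trajectory"))
  df <- data.frame(time_min = s_to_min(traj$time_s),
                   v_mother_um3 = traj$V_t_mother,
                   v_bud_um3 = traj$V_t_bud)
  if ("V_t_bud2" %in% names(traj)) df$v_bud2_um3 <- traj$V_t_bud2
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
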