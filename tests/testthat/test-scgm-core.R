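# Single-compartment model: flux and rate operations, regime labels, and
# the integration driver.

sphere_vol <- function(r) 4 / 3 * pi * r^3

state_r12 <- function(c_i = 319.17) {
  # total radius 1.2 um (surface 18.0956 um^2), solid volume negligible
  cell_state(V_os = 4 / 3 * pi * 1.2^3, V_b = 0, Pi_t = 2e5, c_i = c_i)
}

test_that("water flux follows Kedem-Katchalsky with outward-positive sign", {
  p <- cell_params()
  # pressures balanced: no flux
  st <- state_r12(c_i = steady_osmolarity(p))
  expect_lt(abs(water_flux(st, p)), 1e-10)
  # printed initial osmolarity leaves +559.5 Pa outward drive at r = 1.2:
  # hand evaluation 1.19e-6 * 18.0956 * 559.53
  expect_equal(water_flux(state_r12(319.17), p), 0.012048,
               tolerance = 1e-4)
  # osmolarity well above balance pulls water in (volume grows)
  st2 <- state_r12(c_i = 2 * steady_osmolarity(p))
  expect_lt(water_flux(st2, p), 0)
})

test_that("osmolyte balance vanishes at the surface/volume fixed point", {
  p <- cell_params()
  mk <- function(r) cell_state(V_os = 4 / 3 * pi * r^3, V_b = 0,
                               Pi_t = 2e5, c_i = 300)
  # r = 3 k_u/k_c: uptake over the surface balances volume consumption
  expect_equal(osmolyte_rate(mk(3), p, Vdot = 0), 0, tolerance = 1e-12)
  # smaller radius: surface term dominates, osmolarity rises
  expect_gt(osmolyte_rate(mk(1.5), p, Vdot = 0), 0)
  # r = 1 um: algebraic simplification gives 2 k_c = 0.4 mM/s
  expect_equal(osmolyte_rate(mk(1), p, Vdot = 0), 0.4, tolerance = 1e-12)
  # dilution: growth at fixed amounts lowers concentration
  expect_lt(osmolyte_rate(mk(3), p, Vdot = 0.01),
            osmolyte_rate(mk(3), p, Vdot = 0))
})

test_that("turgor rate combines elastic loading and plastic relaxation", {
  p <- cell_params()
  below <- cell_state(V_os = 4, V_b = 0, Pi_t = 1.5e5, c_i = 300)
  expect_equal(turgor_rate(below, p, rdot = 0), 0)
  above <- cell_state(V_os = 4, V_b = 0, Pi_t = 2.5e5, c_i = 300)
  expect_lt(turgor_rate(above, p, rdot = 0), 0) # stress relaxation
  # hand evaluation at r = 1.2, rdot = 1e-4, Pi_t = Pi_ct:
  # 2Ed/(1-nu) rdot/r^2 - Pi_t rdot/r = 82.417 - 16.667
  expect_equal(turgor_rate(state_r12(300), p, rdot = 1e-4), 65.75,
               tolerance = 1e-4)
})

test_that("the assembled right-hand side vanishes at the growth fixed point", {
  p <- cell_params()
  st <- cell_state(V_os = 4 / 3 * pi * 3^3 - sphere_vol(0.3),
                   V_b = sphere_vol(0.3),
                   Pi_t = p$Pi_ct, c_i = steady_osmolarity(p))
  d <- scgm_rhs(0, st, p)
  expect_equal(d$dV_os, 0, tolerance = 1e-10)
  expect_equal(d$dc_i, 0, tolerance = 1e-10)
  expect_equal(d$dPi_t, 0, tolerance = 1e-8)
  bad <- st
  bad$Pi_t <- NaN
  expect_error(scgm_rhs(0, bad, p), "non-finite")
})

test_that("regime classification puts the yield boundary in EP", {
  expect_equal(classify_regime(1.9e5, 2e5), "E")
  expect_equal(classify_regime(2e5, 2e5), "EP")
  expect_equal(classify_regime(c(1e5, 3e5), 2e5), c("E", "EP"))
})

test_that("unperturbed growth plateaus at r_final with turgor at Pi_ct", {
  traj <- fx_growth()
  n <- nrow(traj)
  expect_lt(abs(traj$r_um[n] - 3) / 3, 1e-3)
  expect_lt(abs(traj$Pi_t_Pa[n] - 2e5) / 2e5, 1e-3)
  expect_equal(traj$regime[n], "EP")
  # radius is non-decreasing after the initial elastic transient
  late <- traj$r_um[traj$time_s > 120]
  expect_true(all(diff(late) > -1e-9))
  # doubling both rate constants: same plateau, faster approach
  p2 <- cell_params(k_uptake = 4e-16, k_consumption = 4e-16)
  tr2 <- simulate_scgm(p2, t_end = 1500 * 60, dt_out = 60)
  expect_lt(abs(tr2$r_um[nrow(tr2)] - 3) / 3, 1e-3)
  i200 <- which(traj$time_s == 200 * 60)
  expect_gt(tr2$r_um[i200], traj$r_um[i200])
})

test_that("volume bookkeeping matches the reported water flux", {
  traj <- fx_growth()
  # central finite differences of V_os against the -J_w column
  i <- 2:(nrow(traj) - 1)
  dv <- (traj$V_os_um3[i + 1] - traj$V_os_um3[i - 1]) /
    (traj$time_s[i + 1] - traj$time_s[i - 1])
  expect_lt(max(abs(dv + traj$J_w_um3_s[i])), 1e-5)
})

test_that("a hyperosmotic step shrinks the cell within seconds, elastically", {
  traj <- fx_shock_passive()
  i0 <- which(traj$time_s == 70 * 60)
  win <- traj[traj$time_s >= 70 * 60 & traj$time_s <= 80 * 60, ]
  v0 <- traj$V_t_um3[i0]
  vmin <- min(win$V_t_um3)
  v60 <- traj$V_t_um3[traj$time_s == 70 * 60 + 60]
  expect_gt(v0 - vmin, 0.2 * v0)          # a drastic volume loss
  expect_gt((v0 - v60) / (v0 - vmin), 0.9) # 90% of it within 60 s
  # the shock leaves the elasto-plastic regime...
  expect_equal(traj$regime[i0 + 2], "E")
  # ...where the reference radius (accumulated plastic strain) freezes
  e_phase <- traj$regime == "E" & traj$time_s > 70 * 60
  expect_lt(diff(range(traj$r_ref_um[e_phase])), 1e-9)
  # and turgor is clamped at or above zero throughout
  expect_true(all(traj$Pi_t_Pa > -1e-6))
})

test_that("external osmolarity reporting is right-continuous at steps", {
  p <- cell_params()
  prot <- shock_protocol(t_s = c(300, 900), c_e_mM = c(500, 325))
  traj <- simulate_scgm(p, protocol = prot, t_end = 1200, dt_out = 60)
  expect_equal(traj$c_e_mM[traj$time_s == 240], 240)
  expect_equal(traj$c_e_mM[traj$time_s == 300], 500)
  expect_equal(traj$c_e_mM[traj$time_s == 900], 325)
  expect_equal(protocol_value(prot, c(0, 300, 899.9, 900), 240),
               c(240, 500, 500, 325))
})

test_that("shock protocols validate their invariants", {
  expect_error(shock_protocol(c(10, 10), c(1, 2)), "strictly increasing")
  expect_error(shock_protocol(c(10, 5), c(1, 2)), "strictly increasing")
  expect_error(shock_protocol(10, -1), "non-negative")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- t_min: 70", "  c_e_mM: 500",
               "- t_min: 100", "  c_e_mM: 325"), path)
  prot <- read_protocol(path)
  expect_equal(prot$t_s, c(4200, 6000))
  expect_equal(prot$c_e_mM, c(500, 325))
})

test_that("trajectories export to tidy CSV", {
  traj <- simulate_scgm(cell_params(), t_end = 600, dt_out = 60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read.csv(path)
  expect_equal(names(back)[1:4], c("time_s", "V_os_um3", "V_t_um3", "r_um"))
  expect_equal(back$r_um, traj$r_um, tolerance = 1e-10)
})
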