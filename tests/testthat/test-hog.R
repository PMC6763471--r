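# Active osmotic-stress response: passive limit, boundedness, adaptation
# speed-up, and the four-phase shock behavior.

test_that("stress-response derivatives follow the deficit-sensing form", {
  hp <- hog_params()
  at_setpoint <- cell_state(V_os = 10, V_b = 0.1, Pi_t = hp$Pi_ref,
                            c_i = 320)
  # no deficit: activation decays
  d <- hog_rhs(at_setpoint, H = 0.3, c_gly = 0, hog = hp)
  expect_equal(d$dH, -hp$k_deact * 0.3)
  # full deficit from H = 0: activation at the full rate
  collapsed <- cell_state(V_os = 10, V_b = 0.1, Pi_t = 0, c_i = 320)
  expect_equal(hog_rhs(collapsed, H = 0, c_gly = 0, hog = hp)$dH, hp$k_act)
  # fixed point of the logistic balance under a constant deficit
  deficit <- 0.4
  part <- cell_state(V_os = 10, V_b = 0.1,
                     Pi_t = (1 - deficit) * hp$Pi_ref, c_i = 320)
  H_star <- hp$k_act * deficit / (hp$k_act * deficit + hp$k_deact)
  expect_equal(hog_rhs(part, H = H_star, c_gly = 0, hog = hp)$dH, 0,
               tolerance = 1e-15)
})

test_that("silencing glycerol production recovers the passive model", {
  p <- fx_shock_params()
  prot <- shock_protocol(70 * 60, 500)
  passive <- simulate_scgm(p, protocol = prot, t_end = 150 * 60,
                           dt_out = 30)
  off <- suppressWarnings(simulate_with_hog(
    p, hog_params(k_act = 0, k_deact = 0, k_gly = 0, k_leak = 0),
    protocol = prot, t_end = 150 * 60, dt_out = 30))
  expect_identical(off$V_t_um3, passive$V_t_um3)
  expect_identical(off$Pi_t_Pa, passive$Pi_t_Pa)
  # with sensing on but production off, volumes still match tightly
  sense <- simulate_with_hog(p, hog_params(k_gly = 0), protocol = prot,
                             t_end = 150 * 60, dt_out = 30)
  expect_equal(sense$V_t_um3, passive$V_t_um3, tolerance = 1e-6)
  expect_gt(max(sense$hog1_active_fraction), 0.1) # it did sense the shock
})

test_that("the active fraction stays inside [0, 1] across shock protocols", {
  p <- fx_shock_params()
  protocols <- list(
    shock_protocol(70 * 60, 600),
    shock_protocol(c(40, 70, 100) * 60, c(500, 240, 700)),
    shock_protocol(c(70, 100) * 60, c(500, 120))
  )
  for (prot in protocols) {
    h <- simulate_with_hog(p, hog_params(), protocol = prot,
                           t_end = 200 * 60, dt_out = 30)
    expect_true(all(h$hog1_active_fraction >= -1e-12))
    expect_true(all(h$hog1_active_fraction <= 1 + 1e-12))
    expect_true(all(h$c_gly_mM >= -1e-9))
  }
})

test_that("the response is silent without a shock", {
  h <- simulate_with_hog(fx_shock_params(), hog_params(),
                         t_end = 250 * 60, dt_out = 60)
  expect_lt(max(h$hog1_active_fraction), 0.05)
})

test_that("active osmolyte production accelerates volume adaptation", {
  p <- fx_shock_params()
  ctrl <- fx_noshock_control()
  recovery_time <- function(traj) {
    idx <- traj$time_s > 70 * 60 &
      traj$V_t_um3 >= 0.95 * ctrl$V_t_um3[match(traj$time_s, ctrl$time_s)]
    t <- traj$time_s[which(idx)[1]]
    if (is.na(t)) Inf else t
  }
  for (c_shock in c(400, 500, 600)) {
    prot <- shock_protocol(70 * 60, c_shock)
    passive <- simulate_scgm(p, protocol = prot, t_end = 600 * 60,
                             dt_out = 10)
    active <- simulate_with_hog(p, hog_params(), protocol = prot,
                                t_end = 600 * 60, dt_out = 10)
    expect_lt(recovery_time(active), recovery_time(passive))
  }
})

test_that("the shock response traverses the four phases in order", {
  p <- fx_shock_params()
  h <- simulate_with_hog(p, hog_params(), protocol = shock_protocol(70 * 60, 500),
                         t_end = 250 * 60, dt_out = 5)
  post <- h$time_s >= 70 * 60
  t_vmin <- h$time_s[post][which.min(h$V_t_um3[post])]
  t_hmax <- h$time_s[which.max(h$hog1_active_fraction)]
  v0 <- h$V_t_um3[h$time_s == 70 * 60]
  vmin <- min(h$V_t_um3[post])
  t_recover <- h$time_s[post][which(h$V_t_um3[post] >= v0)[1]]
  # phase 1: fast shrinkage right at the shock
  expect_lt(t_vmin - 70 * 60, 120)
  # phase 2: the signaling peak follows the volume minimum
  expect_gt(t_hmax, t_vmin)
  # phase 3: at peak signaling, size restoration is underway but not done
  v_at_hmax <- h$V_t_um3[h$time_s == t_hmax]
  expect_gt(v_at_hmax, vmin)
  expect_lt(vmin, v0)
  # restoration completes within 30 min of the shock
  expect_lt(t_recover - 70 * 60, 30 * 60)
  # phase 4: growth resumes in the elasto-plastic regime, with the
  # signal mostly switched off again
  expect_equal(h$regime[nrow(h)], "EP")
  expect_lt(h$hog1_active_fraction[nrow(h)],
            0.5 * max(h$hog1_active_fraction))
})

test_that("a hypoosmotic step after adaptation overshoots the control", {
  p <- fx_shock_params()
  ctrl <- fx_noshock_control()
  prot <- shock_protocol(c(70, 100) * 60, c(500, 325))
  h <- simulate_with_hog(p, hog_params(), protocol = prot,
                         t_end = 250 * 60, dt_out = 10)
  ctrl_at <- ctrl$V_t_um3[match(h$time_s, ctrl$time_s)]
  gap <- h$V_t_um3 - ctrl_at
  gap_before <- gap[h$time_s == 100 * 60]
  peak_after <- max(gap[h$time_s > 100 * 60 & h$time_s < 110 * 60])
  # an immediate swell within a minute of the dilution ...
  swell <- h$V_t_um3[h$time_s == 101 * 60] / h$V_t_um3[h$time_s == 100 * 60]
  expect_gt(swell, 1.2)
  # ... far above both the unshocked control and the pre-step excess ...
  expect_gt(peak_after, 0)
  expect_gt(peak_after, 3 * abs(gap_before))
  # ... and transient: the excess over the control decays again
  gap_late <- gap[h$time_s == 200 * 60]
  expect_lt(gap_late, 0.5 * peak_after)
})

test_that("small initial cells are flagged for the coupled response", {
  expect_warning(
    simulate_with_hog(cell_params(), hog_params(), t_end = 600,
                      dt_out = 60),
    "1.2 um")
})
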