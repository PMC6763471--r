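# Coupled mother-bud model: exchange fluxes, bud-expansion threshold,
# two-bud competition, and bookkeeping.

test_that("exchange fluxes are antisymmetric and follow the gradients", {
  cp <- coupled_params()
  a <- cell_state(V_os = 10, V_b = 0.1, Pi_t = 2e5, c_i = 320)
  b <- cell_state(V_os = 1, V_b = 0.05, Pi_t = 2e5, c_i = 300)
  # identical compartments: no flux
  same <- exchange_fluxes(a, a, cp)
  expect_equal(same$water, 0)
  expect_equal(same$osmolyte, 0)
  # higher mother concentration at equal turgor: osmolytes flow to bud
  fl <- exchange_fluxes(a, b, cp)
  expect_gt(fl$osmolyte, 0)
  # antisymmetry = conservation under exchange alone
  rev <- exchange_fluxes(b, a, cp)
  expect_equal(fl$water, -rev$water)
  expect_equal(fl$osmolyte, -rev$osmolyte)
})

test_that("the mother-only phase reproduces the single-cell model exactly", {
  cp <- coupled_params(q = 230, t_budstart = 93 * 60)
  traj <- simulate_coupled(cp, t_end = 200 * 60, dt_out = 180)
  single <- simulate_scgm(cell_params(), t_end = 93 * 60, dt_out = 180)
  pre <- traj[traj$time_s < 93 * 60, ]
  expect_identical(pre$V_os_mother,
                   single$V_os_um3[single$time_s < 93 * 60])
  expect_identical(pre$Pi_t_mother,
                   single$Pi_t_Pa[single$time_s < 93 * 60])
  expect_true(all(is.na(pre$V_t_bud)))
})

test_that("bud expansion requires a strongly higher bud extensibility", {
  cp <- coupled_params(t_budstart = 93 * 60)
  sw <- sweep_extensibility(10^seq(0, 3, by = 0.5), coupled = cp,
                            t_end = 480 * 60)
  # equal extensibility: the bud stalls while the mother grows on
  expect_false(sw$bud_grew[sw$q == 1])
  expect_gt(sw$v_mother_end[sw$q == 1], 100)
  # far above threshold both compartments grow
  expect_true(sw$bud_grew[sw$q == 1000])
  # outcome is monotone in q: no re-entrant failures above the threshold
  expect_true(all(diff(sw$bud_grew) >= 0))
  q_star <- attr(sw, "q_threshold")
  expect_gte(log10(q_star), 1)
  expect_lte(log10(q_star), 2.5)
})

swap_bud_sizes <- function(cp, factor) {
  cp2 <- cp
  cp2$r_bud_init <- factor * cp$r_bud_init
  cp2
}

test_that("equal twin buds stay identical; unequal buds diverge", {
  cp <- coupled_params(q = 230, t_budstart = 93 * 60)
  eq <- simulate_two_buds(cp, t_end = 300 * 60)
  expect_lt(max(abs(eq$V_t_bud - eq$V_t_bud2), na.rm = TRUE), 1e-8)
  uneq <- simulate_two_buds(cp, r_bud2_init = 0.9 * cp$r_bud_init,
                            t_end = 300 * 60)
  ib <- which(!is.na(uneq$V_t_bud))[1]
  n <- nrow(uneq)
  gap0 <- uneq$V_t_bud[ib] - uneq$V_t_bud2[ib]
  gapT <- uneq$V_t_bud[n] - uneq$V_t_bud2[n]
  expect_gt(gapT, 10 * gap0)                    # difference amplified
  expect_gt(uneq$V_t_bud[n], 10 * uneq$V_t_bud[ib])  # larger bud grows
  expect_lt(uneq$V_t_bud2[n], 0.1 * uneq$V_t_bud[n]) # smaller one loses
  # permutation symmetry: swapping the bud labels swaps the trajectories
  swap <- simulate_two_buds(swap_bud_sizes(cp, 0.9),
                            r_bud2_init = cp$r_bud_init,
                            t_end = 300 * 60)
  expect_equal(swap$V_t_bud, uneq$V_t_bud2, tolerance = 1e-5)
  expect_equal(swap$V_t_bud2, uneq$V_t_bud, tolerance = 1e-5)
})

test_that("only a strongly softened bud wall rescues growth at q = 1", {
  cp <- coupled_params(t_budstart = 93 * 60)
  sw <- sweep_young_modulus(c(0.01, 1, 2), coupled = cp, t_end = 480 * 60)
  expect_true(sw$bud_grew[sw$E_ratio == 0.01])
  expect_false(sw$mother_grew[sw$E_ratio == 0.01]) # at the mother's expense
  expect_false(sw$bud_grew[sw$E_ratio == 1])
  expect_false(sw$bud_grew[sw$E_ratio == 2])
})

test_that("osmolyte amounts balance uptake minus consumption globally", {
  cp <- coupled_params(q = 230, t_budstart = 93 * 60)
  tr <- simulate_coupled(cp, t_end = 300 * 60, dt_out = 180)
  ok <- !is.na(tr$V_t_bud)
  N <- mM_to_mmol_um3(tr$c_i_mother) * tr$V_os_mother +
    ifelse(ok, mM_to_mmol_um3(tr$c_i_bud) * tr$V_os_bud, 0)
  p <- cp$mother
  net <- p$k_uptake * (4 * pi * tr$r_mother^2 +
                         ifelse(ok, 4 * pi * tr$r_bud^2, 0)) -
    p$k_consumption * (tr$V_t_mother + ifelse(ok, tr$V_t_bud, 0))
  i <- which(ok)
  gained <- N[max(i)] - N[i[1]]
  integral <- sum((net[i[-length(i)]] + net[i[-1]]) / 2 *
                    diff(tr$time_s[i]))
  expect_lt(abs(gained - integral) / abs(gained), 1e-3)
})

test_that("explicit finite exchange keeps compartment gradients negligible", {
  cp <- coupled_params(q = 230, t_budstart = 93 * 60)
  tr <- simulate_coupled(cp, t_end = 200 * 60, dt_out = 180,
                         exchange = "explicit")
  ok <- which(!is.na(tr$V_t_bud))
  late <- ok[-(1:2)] # allow the insertion transient to relax
  rel_c_gap <- abs(tr$c_i_mother[late] - tr$c_i_bud[late]) /
    tr$c_i_mother[late]
  expect_lt(max(rel_c_gap), 1e-6)
  psi_m <- tr$Pi_t_mother[late] - osmotic_pressure(tr$c_i_mother[late])
  psi_b <- tr$Pi_t_bud[late] - osmotic_pressure(tr$c_i_bud[late])
  expect_lt(max(abs(psi_m - psi_b)), 1) # Pa
})

test_that("paired trajectories export in the fitting input format", {
  cp <- coupled_params(q = 230, t_budstart = 93 * 60)
  tr <- simulate_coupled(cp, t_end = 120 * 60, dt_out = 180)
  path <- withr::local_tempfile(fileext = ".csv")
  write_paired_csv(tr, path)
  back <- read_paired_csv(path)
  expect_equal(names(back), c("time_min", "v_mother_um3", "v_bud_um3"))
  expect_equal(back$time_min, tr$time_s / 60)
  expect_equal(back$v_mother_um3, tr$V_t_mother, tolerance = 1e-10)
})
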