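# Shared fixtures, computed lazily and cached for the whole test run.
# Everything is generated in code; the cache only avoids re-simulating the
# same deterministic objects across test files.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, build(), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

# the dataset-1-median parameter vector used for recovery experiments
fx_truth <- function() {
  c(k_uptake = 1.4e-16, k_uc = 1.21, phi_mother = 5.5e-4, q = 230,
    r_0 = 1.2, t_budstart = 93)
}

# one noiseless synthetic mother+bud pair at the median parameters
fx_clean_cell <- function() {
  fx_get("clean_cell", function() {
    generate_cell(cohort_spec(sigma = 0), theta = fx_truth())
  })
}

# the multi-start fit of the noiseless pair
fx_clean_fit <- function() {
  fx_get("clean_fit", function() {
    fit_pair(fx_clean_cell()$data, fit_spec(n_starts = 16, seed = 7))
  })
}

# a small noisy cohort and its fits (sigma = 1 um^3)
fx_cohort <- function() {
  fx_get("cohort", function() {
    generate_cohort(cohort_spec(n_cells = 6, sigma = 1, seed = 11))
  })
}

fx_cohort_fits <- function() {
  fx_get("cohort_fits", function() {
    lapply(fx_cohort()$cells, function(d) {
      fit_pair(d[, c("time_min", "v_mother_um3", "v_bud_um3")],
               fit_spec(n_starts = 12, n_polish = 4, seed = 3))
    })
  })
}

# long unperturbed growth run with the standard parameters
fx_growth <- function() {
  fx_get("growth", function() {
    simulate_scgm(cell_params(), t_end = 1500 * 60, dt_out = 60)
  })
}

# shock fixtures: a grown cell (r_os0 = 1.2 um) hit with 500 mM at 70 min
fx_shock_params <- function() cell_params(r_os0 = 1.2)

fx_shock_passive <- function() {
  fx_get("shock_passive", function() {
    simulate_scgm(fx_shock_params(),
                  protocol = shock_protocol(70 * 60, 500),
                  t_end = 250 * 60, dt_out = 5)
  })
}

fx_noshock_control <- function() {
  fx_get("noshock_control", function() {
    simulate_scgm(fx_shock_params(), t_end = 600 * 60, dt_out = 10)
  })
}
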