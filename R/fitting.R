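# Fitting the coupled model to mother+bud volume trajectory pairs:
# 6 free parameters (k_uptake, k_u/c, phi_mother, q, r_0, t_budstart),
# chi-squared objective, multi-start bounded least squares, and post-fit
# filtering.

#' Fit specification
#'
#' Free parameters, bounds, start count and normalization for
#' [fit_pair()]. The parameters are fitted on a log10 scale except
#' `t_budstart` (minutes, linear). When `t_budstart` is supplied by the
#' data it is excluded from the free set (5-parameter fit).
#'
#' @param n_starts number of Latin-hypercube multi-starts.
#' @param n_polish number of screened starts (ranked by initial
#'   chi-squared) refined by Levenberg-Marquardt.
#' @param seed RNG seed for the start set.
#' @param sigma volume noise scale used to normalize residuals (um^3).
#'   The chi-squared filter threshold is only meaningful relative to this
#'   declared scale and the trajectory length.
#' @param bounds named list of `c(lower, upper)` in natural units for
#'   `k_uptake` (mmol um^-2 s^-1), `k_uc` (um), `phi_mother` (Pa^-1 s^-1),
#'   `q`, `r_0` (um) and `t_budstart` (fraction of the observation span,
#'   0 to 1).
#' @param t_budstart fixed bud-start time in minutes, or `NA` to fit it.
#' @param chi2_stop stop launching further starts once a fit reaches this
#'   chi-squared (self-consistency runs on noiseless data finish early).
#' @param sim_rtol integrator relative tolerance during fitting.
#' @param maxiter per-start Levenberg-Marquardt iteration cap.
#' @return an object of class `fit_spec`.
#' @export
fit_spec <- function(n_starts = 24, n_polish = 8, seed = 1, sigma = 1,
                     bounds = list(k_uptake = c(1e-17, 1e-14),
                                   k_uc = c(0.3, 3),
                                   phi_mother = c(1e-9, 1e-1),
                                   q = c(1, 1e6),
                                   r_0 = c(0.5, 3),
                                   t_budstart = c(0, 0.8)),
                     t_budstart = NA_real_, chi2_stop = 1e-6,
                     sim_rtol = 1e-7, maxiter = 50) {
  stopifnot(n_starts >= 1, n_polish >= 1, sigma > 0)
  for (b in bounds) stopifnot(length(b) == 2, b[1] < b[2], b[1] >= 0)
  structure(list(n_starts = n_starts, n_polish = min(n_polish, n_starts),
                 seed = seed, sigma = sigma,
                 bounds = bounds, t_budstart = t_budstart,
                 chi2_stop = chi2_stop, sim_rtol = sim_rtol,
                 maxiter = maxiter),
            class = "fit_spec")
}

#' Read a mother+bud volume trajectory CSV
#'
#' Columns `time_min`, `v_mother_um3`, `v_bud_um3` (empty bud cells before
#' bud emergence are allowed) and optionally `cell_id` for cohort files.
#'
#' @param path CSV path.
#' @return a data frame (list of data frames split by `cell_id` when the
#'   column is present and `split = TRUE`).
#' @param split split a cohort file into one data frame per cell.
#' @export
read_paired_csv <- function(path, split = FALSE) {
  df <- read.csv(path)
  need <- c("time_min", "v_mother_um3", "v_bud_um3")
  if (!all(need %in% names(df)))
    stop("paired trajectory CSV must have columns ",
         paste(need, collapse = ", "))
  if (split && "cell_id" %in% names(df))
    return(split(df, df$cell_id))
  df
}

# coupled parameter object from a named parameter vector
.params_from_theta <- function(theta, base) {
  mother <- cell_params(
    k_uptake = theta[["k_uptake"]],
    k_consumption = theta[["k_uptake"]] / theta[["k_uc"]],
    phi = theta[["phi_mother"]],
    r_os0 = theta[["r_0"]],
    c_e = base$c_e, temperature = base$temperature, L_p = base$L_p,
    E = base$E, nu = base$nu, d = base$d, Pi_ct = base$Pi_ct,
    Pi_t0 = base$Pi_t0, r_b0 = base$r_b0)
  coupled_params(mother = mother, q = theta[["q"]],
                 t_budstart = min_to_s(theta[["t_budstart"]]))
}

# predicted total volumes on the data's time grid
.predict_pair <- function(theta, time_min, base, rtol) {
  cp <- .params_from_theta(theta, base)
  dts <- diff(time_min)
  if (any(dts <= 0) || max(dts) - min(dts) > 1e-6)
    stop("alignment error: observation times must be a uniform increasing grid")
  dt <- stats::median(dts)
  t_s <- min_to_s(time_min)
  traj <- simulate_coupled(cp, t_end = max(t_s), dt_out = min_to_s(dt),
                           rtol = rtol)
  idx <- match(round(t_s, 6), round(traj$time_s, 6))
  if (any(is.na(idx)))
    stop("alignment error: simulation grid does not cover the data grid")
  data.frame(time_min = time_min,
             v_mother_um3 = traj$V_t_mother[idx],
             v_bud_um3 = traj$V_t_bud[idx])
}

# residual vector; a missing simulated bud counts as volume zero, so data
# points before the fitted bud start penalize a too-late t_budstart
.pair_residuals <- function(observed, simulated, sigma) {
  rm_ <- (observed$v_mother_um3 - simulated$v_mother_um3) / sigma
  ob <- observed$v_bud_um3
  sb <- ifelse(is.na(simulated$v_bud_um3), 0, simulated$v_bud_um3)
  rb <- (ob[!is.na(ob)] - sb[!is.na(ob)]) / sigma
  c(rm_[!is.na(rm_)], rb)
}

#' Chi-squared distance between two paired trajectories
#'
#' `chi2 = sum[(V_m,obs - V_m,sim)^2 + (V_b,obs - V_b,sim)^2] / sigma^2`,
#' bud terms contributing only where the observed bud exists. Both inputs
#' must share the same time grid.
#'
#' @param observed,simulated data frames with columns `time_min`,
#'   `v_mother_um3`, `v_bud_um3`.
#' @param sigma volume noise scale (um^3).
#' @return dimensionless chi-squared.
#' @export
chi2_volume <- function(observed, simulated, sigma = 1) {
  stopifnot(sigma > 0)
  if (nrow(observed) != nrow(simulated) ||
      any(abs(observed$time_min - simulated$time_min) > 1e-8))
    stop("alignment error: observed and simulated time grids differ")
  sum(.pair_residuals(observed, simulated, sigma)^2)
}

#' Fit the coupled model to one mother+bud trajectory pair
#'
#' Multi-start bounded Levenberg-Marquardt least squares over the free
#' parameters; deterministic for a given `spec$seed`. Starts are a Latin
#' hypercube over the (log-scaled) bounds. Never throws on optimizer
#' failure: if every start fails, a non-converged result with infinite
#' chi-squared is returned.
#'
#' @param data data frame with `time_min`, `v_mother_um3`, `v_bud_um3`
#'   (at least 10 time points; bud cells may be `NA` before bud start).
#' @param spec a [fit_spec()].
#' @param base a [cell_params()] supplying every non-fitted parameter.
#' @param fixed optional named numeric vector of parameters to hold fixed
#'   (e.g. `c(q = 1e3)` for a profile over the extensibility ratio).
#' @param init optional named parameter vector added to the start set
#'   (e.g. a previous fit's estimate when profiling, the usual
#'   continuation strategy).
#' @return an object of class `scgm_fit` with elements `params` (named
#'   vector: `k_uptake`, `k_uc`, `phi_mother`, `q`, `r_0`, `t_budstart`
#'   in minutes), `chi2`, `converged`, `retained`, `residuals`,
#'   `max_v_mother`, `max_v_bud`, `starts` (per-start log).
#' @export
fit_pair <- function(data, spec = fit_spec(), base = cell_params(),
                     fixed = NULL, init = NULL) {
  stopifnot(inherits(spec, "fit_spec"), inherits(base, "cell_params"))
  if (nrow(data) < 10) stop("need at least 10 time points")
  if (any(stats::na.omit(c(data$v_mother_um3, data$v_bud_um3)) <= 0))
    stop("volumes must be positive")
  if (is.unsorted(data$time_min, strictly = TRUE))
    stop("alignment error: observation times must be strictly increasing")

  t_span <- max(data$time_min)
  fixed_tb <- !is.na(spec$t_budstart)
  if (fixed_tb) fixed <- c(fixed, t_budstart = spec$t_budstart)
  free <- setdiff(c("k_uptake", "k_uc", "phi_mother", "q", "r_0",
                    "t_budstart"), names(fixed))
  log_scaled <- setdiff(free, "t_budstart")

  lower <- upper <- numeric(length(free))
  names(lower) <- names(upper) <- free
  for (nm in free) {
    b <- spec$bounds[[nm]]
    if (nm == "t_budstart") b <- b * t_span
    if (nm %in% log_scaled) b <- log10(b)
    lower[nm] <- b[1]
    upper[nm] <- b[2]
  }

  to_theta <- function(par) {
    th <- par
    th[log_scaled] <- 10^th[log_scaled]
    c(th, fixed)
  }

  resid_fn <- function(par) {
    th <- to_theta(par)
    sim <- tryCatch(
      .predict_pair(th, data$time_min, base, spec$sim_rtol),
      error = function(e) NULL)
    if (is.null(sim)) return(rep(1e6, 2 * nrow(data)))
    .pair_residuals(data, sim, spec$sigma)
  }

  set.seed(spec$seed)
  starts <- lhs::randomLHS(spec$n_starts, length(free))
  starts <- t(t(starts) * (upper - lower) + lower)
  colnames(starts) <- free
  if (!is.null(init)) {
    par0 <- vapply(free, function(nm) {
      v <- init[[nm]]
      if (nm %in% log_scaled) v <- log10(v)
      min(max(v, lower[nm]), upper[nm])
    }, numeric(1))
    starts <- rbind(par0, starts)
  }

  # screen every start by its initial chi-squared, then polish the most
  # promising ones; the derivative step is kept well above the ODE noise
  # floor so the numeric Jacobian is informative
  screen <- apply(starts, 1, function(p) sum(resid_fn(p)^2))
  polish <- order(screen)[seq_len(spec$n_polish)]

  best <- NULL
  log_rows <- vector("list", length(polish))
  for (k in seq_along(polish)) {
    i <- polish[k]
    fitres <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = spec$maxiter, epsfcn = 1e-8)),
      error = function(e) NULL)
    if (is.null(fitres)) {
      log_rows[[k]] <- data.frame(start = i, chi2_start = screen[i],
                                  chi2 = Inf, info = NA_integer_)
      next
    }
    chi2_i <- sum(fitres$fvec^2)
    log_rows[[k]] <- data.frame(start = i, chi2_start = screen[i],
                                chi2 = chi2_i, info = fitres$info)
    if (is.null(best) || chi2_i < best$chi2)
      best <- list(fit = fitres, chi2 = chi2_i)
    if (best$chi2 <= spec$chi2_stop) break
  }
  start_log <- do.call(rbind, log_rows[!vapply(log_rows, is.null,
                                               logical(1))])

  max_vm <- max(data$v_mother_um3, na.rm = TRUE)
  max_vb <- if (all(is.na(data$v_bud_um3))) NA_real_ else
    max(data$v_bud_um3, na.rm = TRUE)

  if (is.null(best) || !is.finite(best$chi2)) {
    out <- list(params = setNames(rep(NA_real_, 6),
                                  c("k_uptake", "k_uc", "phi_mother", "q",
                                    "r_0", "t_budstart")),
                chi2 = Inf, converged = FALSE, retained = FALSE,
                residuals = NULL, max_v_mother = max_vm,
                max_v_bud = max_vb, starts = start_log)
    class(out) <- "scgm_fit"
    return(out)
  }

  theta <- to_theta(best$fit$par)
  theta <- theta[c("k_uptake", "k_uc", "phi_mother", "q", "r_0",
                   "t_budstart")]
  out <- list(params = theta, chi2 = best$chi2,
              converged = best$fit$info %in% 1:4,
              retained = theta[["k_uc"]] >= 1 && best$chi2 <= 50,
              residuals = best$fit$fvec,
              max_v_mother = max_vm, max_v_bud = max_vb,
              starts = start_log)
  class(out) <- "scgm_fit"
  out
}

#' @export
print.scgm_fit <- function(x, ...) {
  cat(sprintf("Coupled-model fit: chi2 = %.4g, converged = %s, retained = %s\n",
              x$chi2, x$converged, x$retained))
  print(signif(x$params, 4))
  invisible(x)
}

#' Post-fit filtering
#'
#' Retains exactly the fits with `k_uc >= 1` um and `chi2 <= 50` (both
#' thresholds inclusive on the keep side). Idempotent.
#'
#' @param results list of `scgm_fit` objects.
#' @return the retained sublist.
#' @export
filter_fits <- function(results) {
  keep <- vapply(results, function(f) {
    is.finite(f$chi2) && !is.na(f$params[["k_uc"]]) &&
      f$params[["k_uc"]] >= 1 && f$chi2 <= 50
  }, logical(1))
  results[keep]
}

#' Cohort summary of retained fits
#'
#' Per-parameter median and interquartile range, plus the Pearson
#' correlation matrix of the fitted parameters together with the maximal
#' observed mother and bud volumes (read from the data, not the model).
#' Correlations that are undefined (zero variance) are reported as `NA`.
#'
#' @param results list of at least two `scgm_fit` objects.
#' @return list with `medians`, `iqr` (named vectors) and `correlations`
#'   (matrix over parameters and `max_v_mother`, `max_v_bud`).
#' @export
summarize_fits <- function(results) {
  if (length(results) < 2)
    stop("insufficient data: need at least 2 fits to summarize")
  mat <- t(vapply(results, function(f) {
    c(f$params, max_v_mother = f$max_v_mother, max_v_bud = f$max_v_bud)
  }, numeric(8)))
  param_cols <- colnames(mat)[1:6]
  meds <- apply(mat[, param_cols, drop = FALSE], 2, median)
  iqr <- apply(mat[, param_cols, drop = FALSE], 2, function(v)
    unname(diff(quantile(v, c(0.25, 0.75)))))
  cors <- suppressWarnings(cor(mat, use = "pairwise.complete.obs"))
  sds <- apply(mat, 2, stats::sd)
  cors[sds == 0, ] <- NA
  cors[, sds == 0] <- NA
  diag(cors) <- 1
  list(medians = meds, iqr = iqr, correlations = cors)
}
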