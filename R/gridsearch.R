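#' Evaluate one point of the (C, rho, mean delay) grid
#'
#' Runs the full forward pipeline at one parameter combination: homeostatic
#' stabilisation, a plasticity-off recording, the hemodynamic transform and
#' band-pass, then the fit metrics against the supplied reference FC/FCD plus
#' the dynamical readouts (synchrony, metastability, criticality k).
#'
#' @param cfg a [wc_config()] carrying the point's `C`, `rho`, `mean_delay`.
#' @param c a [connectome()].
#' @param ref_fc,ref_fcd reference FC and FCD matrices (same parcellation).
#' @param record_s recording duration, s.
#' @param max_stab_s stabilisation cap, s.
#' @param hemo a [hemo_config()].
#' @param seed RNG seed.
#' @return one-row data frame: `C`, `rho`, `mean_delay`, `corr`, `mse`, `ks`,
#'   `synchrony`, `metastability`, `k`, `converged`.
#' @export
evaluate_point <- function(cfg, c, ref_fc, ref_fcd, record_s = 180,
                           max_stab_s = 1800, hemo = hemo_config(),
                           seed = cfg$seed) {
  st <- stabilize(cfg, c, max_duration_s = max_stab_s,
                  seed = derive_seed(seed, 1))
  sim <- simulate_wc(cfg, c, record_s, plasticity = FALSE, init = st$state,
                     discard_s = 10, seed = derive_seed(seed, 2))
  bold <- bold_bandpass(bold_transform(sim, hemo), hemo)
  fc <- static_fc(bold)
  fcd <- fcd_matrix(bold)
  fm <- fit_metrics(fc, ref_fc, fcd, ref_fcd)
  sm <- synchrony_metastability(kuramoto_series(bold))
  k <- criticality_k(detect_avalanches(sim))
  data.frame(C = cfg$C, rho = cfg$rho, mean_delay = cfg$mean_delay,
             corr = fm[["corr"]], mse = fm[["mse"]], ks = fm[["ks"]],
             synchrony = sm[["synchrony"]], metastability = sm[["metastability"]],
             k = k, converged = st$converged, row.names = NULL)
}

#' Grid search over coupling, target rate and mean delay
#'
#' Evaluates [evaluate_point()] at every combination of the supplied
#' parameter values. The full-scale protocol uses 25 log-spaced couplings in
#' `[0.1, 14]`, target rates `0.05..0.30` in steps of 0.01 and mean delays
#' `0..15` ms; any sub-grid can be run.
#'
#' @param c a [connectome()].
#' @param ref_fc,ref_fcd reference FC / FCD.
#' @param C_values,rho_values,delay_values grid axes.
#' @param base_cfg template [wc_config()] supplying all other parameters.
#' @param seed master seed (each point gets a derived seed).
#' @param ... passed to [evaluate_point()].
#' @return data frame of class `wc_grid`, one row per grid point.
#' @export
grid_search <- function(c, ref_fc, ref_fcd,
                        C_values = exp(seq(log(0.1), log(14), length.out = 25)),
                        rho_values = seq(0.05, 0.3, by = 0.01),
                        delay_values = 0:15,
                        base_cfg = wc_config(), seed = 1, ...) {
  grid <- expand.grid(C = C_values, rho = rho_values, mean_delay = delay_values)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- wc_config(C = grid$C[i], rho = grid$rho[i],
                     mean_delay = grid$mean_delay[i],
                     tau_E = base_cfg$tau_E, tau_I = base_cfg$tau_I,
                     c_EE = base_cfg$c_EE, c_IE = base_cfg$c_IE,
                     P = base_cfg$P, mu = base_cfg$mu, sigma = base_cfg$sigma,
                     tau_homeo = base_cfg$tau_homeo,
                     noise_var = base_cfg$noise_var, dt = base_cfg$dt,
                     record_dt = base_cfg$record_dt)
    evaluate_point(cfg, c, ref_fc, ref_fcd, seed = derive_seed(seed, i), ...)
  })
  out <- do.call(rbind, res)
  class(out) <- c("wc_grid", class(out))
  out
}

#' Select the working point from grid results
#'
#' Applies the admissibility thresholds (FC correlation >= `corr_min`, MSE <=
#' `mse_max`, FCD KS distance <= `ks_max`), then picks the admissible point
#' with maximal correlation, ties broken by minimal KS. If no point is
#' admissible, returns the best-correlation point with a warning.
#'
#' @param grid a `wc_grid` (or compatible data frame).
#' @param corr_min,mse_max,ks_max admissibility thresholds
#'   (0.45 / 0.1 / 0.15).
#' @return list `chosen` (one-row data frame), `admissible` (data frame of
#'   all passing points), `any_admissible` (logical).
#' @export
select_working_point <- function(grid, corr_min = 0.45, mse_max = 0.1,
                                 ks_max = 0.15) {
  stopifnot(nrow(grid) > 0)
  ok <- grid$corr >= corr_min & grid$mse <= mse_max & grid$ks <= ks_max
  ok[is.na(ok)] <- FALSE
  pool <- if (any(ok)) grid[ok, , drop = FALSE] else grid
  if (!any(ok))
    warning("no grid point satisfies all thresholds; returning best correlation")
  pick <- order(-pool$corr, pool$ks)[1]
  list(chosen = pool[pick, , drop = FALSE],
       admissible = grid[ok, , drop = FALSE],
       any_admissible = any(ok))
}
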