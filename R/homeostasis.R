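#' One homeostatic scaling update of the inhibitory weights
#'
#' The synaptic-scaling rule for the local inhibitory-to-excitatory weights:
#' `c_EI,i <- c_EI,i + dt * rI_i * (rE_i - rho) / tau_homeo`, clamped below at
#' `cei_floor`. Excitatory activity above the target rate `rho` strengthens
#' inhibition; below-target activity weakens it; `rE = rho` is the fixed
#' point. This R-level function applies the update for given rates; inside
#' the compiled integrator the same update runs every Euler step, with the
#' rates sensed through the slow moving average set by `tau_sense` in
#' [wc_config()] (see there for why).
#'
#' @param cei current inhibitory weights (vector).
#' @param rE,rI current excitatory and inhibitory rates.
#' @param rho target excitatory rate.
#' @param dt step, ms.
#' @param tau_homeo homeostatic time constant, ms.
#' @param cei_floor lower clamp (default 0).
#' @return updated weight vector.
#' @export
plasticity_step <- function(cei, rE, rI, rho, dt = 0.2, tau_homeo = 2500,
                            cei_floor = 0) {
  pmax(cei + dt * rI * (rE - rho) / tau_homeo, cei_floor)
}

#' Detect a steady state in the sampled inhibitory-weight trajectory
#'
#' The trajectory is considered converged at the first sliding window of
#' `window` consecutive samples in which, for every node, the within-window
#' range of `c_EI,i` relative to `max(|mean c_EI,i|, scale_floor)` falls below
#' `tol`. The criterion is scale-free per node and robust to noise-driven
#' jitter.
#'
#' @param cei_series N x S matrix of weights sampled every `sample_period_s`
#'   seconds (a numeric vector is treated as one node).
#' @param window number of consecutive samples per test window (default 10).
#' @param tol relative tolerance (default 0.02). Under input noise the
#'   converged weights keep wandering on the percent scale with the network's
#'   slow state fluctuations; the default detects that quasi-steady plateau
#'   rather than a fully frozen trajectory.
#' @param scale_floor lower bound on the normalising scale (default 0.1), so
#'   near-zero weights are judged on an absolute scale.
#' @param sample_period_s sampling period of the series, s (default 10).
#' @return list with `converged` (logical), `index` (last sample index of the
#'   first converged window, `NA` if none) and `time_s` (corresponding
#'   simulated time).
#' @export
detect_steady_state <- function(cei_series, window = 10, tol = 0.02,
                                scale_floor = 0.1, sample_period_s = 10) {
  if (is.vector(cei_series)) cei_series <- matrix(cei_series, nrow = 1)
  S <- ncol(cei_series)
  if (S < max(2, window))
    return(list(converged = FALSE, index = NA_integer_, time_s = NA_real_))
  for (s in 1:(S - window + 1)) {
    win <- cei_series[, s:(s + window - 1), drop = FALSE]
    rng <- apply(win, 1, function(v) max(v) - min(v))
    scl <- pmax(abs(rowMeans(win)), scale_floor)
    if (max(rng / scl) < tol) {
      idx <- s + window - 1L
      return(list(converged = TRUE, index = idx, time_s = idx * sample_period_s))
    }
  }
  list(converged = FALSE, index = NA_integer_, time_s = NA_real_)
}

#' Run the network with plasticity until the inhibitory weights converge
#'
#' Integrates the network with homeostatic scaling enabled, sampling the
#' inhibitory weights every `cfg$cei_sample_s` seconds, until
#' [detect_steady_state()] triggers or `max_duration_s` of simulated time is
#' reached. The steady state is invariant (within noise) to `tau_homeo` and to
#' the weight initialisation; those invariances are part of the test suite.
#'
#' @param cfg a [wc_config()].
#' @param c a [connectome()].
#' @param init_cei initial inhibitory weights (scalar or vector; default
#'   `cfg$init_cei`), or a full state list to continue from (e.g. the
#'   post-lesion state).
#' @param max_duration_s cap on simulated time, s (default 500 minutes).
#' @param window,tol steady-state criterion, see [detect_steady_state()].
#'   `window = NULL` (default) scales the window with the plasticity speed:
#'   it spans 40 tau_homeo of simulated time (10 samples at the default
#'   tau_homeo = 2.5 s), so slow plasticity is not mistaken for a plateau.
#' @param detect run convergence detection (default). With `detect = FALSE`
#'   the network simply runs with plasticity for `max_duration_s`; useful to
#'   settle on and average around the steady state.
#' @param chunk_s chunk length between convergence checks, s.
#' @param seed RNG seed (default `cfg$seed`); `NULL` continues the current
#'   stream.
#' @return list of class `wc_steady`: `cei` (steady-state weight vector),
#'   `converged`, `time_s` (simulated time to convergence, `NA` if capped),
#'   `cei_series` (full sampled trajectory), `state` (final network state for
#'   subsequent recordings).
#' @export
stabilize <- function(cfg, c, init_cei = NULL, max_duration_s = 500 * 60,
                      window = NULL, tol = 0.02, chunk_s = 100,
                      detect = TRUE, seed = cfg$seed) {
  stopifnot(inherits(cfg, "wc_config"), inherits(c, "connectome"))
  if (is.null(window))
    window <- max(10, ceiling(0.04 * cfg$tau_homeo / cfg$cei_sample_s))
  delay_steps <- build_delay_steps(c, cfg$mean_delay, cfg$dt)
  el <- edge_list(c, delay_steps)
  state <- if (is.list(init_cei) && !is.null(init_cei$buf)) init_cei
           else init_state(cfg, c, delay_steps, cei = init_cei)
  run <- function() {
    cei_series <- NULL
    elapsed <- 0
    res <- NULL
    while (elapsed < max_duration_s) {
      step_s <- min(chunk_s, max_duration_s - elapsed)
      r <- run_chunk(cfg, c, el, state, step_s, plasticity = TRUE,
                     record = FALSE, cei_sample = TRUE)
      state <<- r$state
      cei_series <- cbind(cei_series, r$cei)
      elapsed <- elapsed + step_s
      if (detect) {
        det <- detect_steady_state(cei_series, window = window, tol = tol,
                                   sample_period_s = cfg$cei_sample_s)
        if (det$converged) {
          return(list(cei_series = cei_series, det = det))
        }
      }
    }
    list(cei_series = cei_series,
         det = list(converged = FALSE, index = NA_integer_, time_s = NA_real_))
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  if (detect && !out$det$converged)
    warning("inhibitory weights did not converge within ",
            max_duration_s / 60, " simulated minutes")
  structure(list(cei = state$cei, converged = out$det$converged,
                 time_s = out$det$time_s, cei_series = out$cei_series,
                 state = state, n = c$n),
            class = "wc_steady")
}

#' @export
print.wc_steady <- function(x, ...) {
  cat("Homeostatic stabilization:",
      if (x$converged) sprintf("converged at %.0f s simulated time", x$time_s)
      else "NOT converged (capped)", "\n")
  cat(sprintf("  steady-state c_EI: mean %.4f, range %.4f - %.4f over %d nodes\n",
              mean(x$cei), min(x$cei), max(x$cei), x$n))
  invisible(x)
}
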