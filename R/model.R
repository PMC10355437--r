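#' Model configuration for the Wilson-Cowan network
#'
#' Collects every fixed and free parameter of the coupled excitatory (E) /
#' inhibitory (I) neural-mass network, its homeostatic plasticity rule and the
#' integration/recording settings. Defaults are the model's standard fixed
#' values: E/I time constants chosen so an isolated mass oscillates in the
#' gamma range (~40 Hz), and an intrinsic excitability `P` that poises the
#' isolated mass just below its Hopf bifurcation, so oscillations are driven
#' by network coupling.
#'
#' @param C global coupling scaling the connectome weights (free parameter,
#'   explored in `[0.1, 14]`; default is the working point 4.07).
#' @param mean_delay mean conduction delay over connected pairs, ms (free
#'   parameter in `[0, 15]`; default 4).
#' @param rho homeostatic target excitatory rate (free parameter in
#'   `[0.05, 0.3]`; default 0.2).
#' @param tau_E,tau_I E and I population time constants, ms (2.5 / 5).
#' @param c_EE recurrent E-to-E coupling (3.5).
#' @param c_IE E-to-I coupling (3.75).
#' @param P intrinsic excitability of each mass (0.31).
#' @param mu,sigma sigmoid threshold and sensitivity (1 / 0.25).
#' @param tau_homeo homeostatic time constant, ms (2500). The steady state is
#'   invariant to this value provided it is slow compared with the node
#'   dynamics; it only sets the adaptation speed.
#' @param tau_sense time constant, ms, of the exponential moving average
#'   through which the plasticity rule senses the rates (default 1000).
#'   Homeostatic scaling integrates activity over timescales much longer than
#'   an oscillation cycle; sensing the slow-averaged rates makes the rule
#'   control the time-mean excitatory rate. Setting 0 uses the instantaneous
#'   rates, which instead controls the inhibition-weighted mean (biased below
#'   the target by the rate covariance when the network oscillates).
#' @param noise_var variance of the additive Gaussian input noise (0.01). The
#'   draw is injected inside the sigmoid argument, independently per node,
#'   population and Euler step, and is not scaled by `sqrt(dt)` (discrete
#'   input-fluctuation convention).
#' @param dt Euler integration step, ms (0.2, i.e. 5 kHz).
#' @param cei_floor lower clamp for the inhibitory weights (0; inhibition
#'   cannot become negative).
#' @param record_dt decimation period of recorded rate series, ms (1 ms keeps
#'   the ~40 Hz content with margin).
#' @param cei_sample_s sampling period of the slow inhibitory-weight
#'   trajectory, s (10).
#' @param init_rate deterministic initial E and I rate (0.1).
#' @param init_cei initial inhibitory-to-excitatory weight (1).
#' @param seed default RNG seed for simulations.
#' @return an object of class `wc_config` (a validated list).
#' @export
wc_config <- function(C = 4.07, mean_delay = 4, rho = 0.2,
                      tau_E = 2.5, tau_I = 5, c_EE = 3.5, c_IE = 3.75,
                      P = 0.31, mu = 1, sigma = 0.25, tau_homeo = 2500,
                      tau_sense = 1000, noise_var = 0.01, dt = 0.2,
                      cei_floor = 0, record_dt = 1, cei_sample_s = 10,
                      init_rate = 0.1, init_cei = 1, seed = 1) {
  cfg <- list(C = C, mean_delay = mean_delay, rho = rho, tau_E = tau_E,
              tau_I = tau_I, c_EE = c_EE, c_IE = c_IE, P = P, mu = mu,
              sigma = sigma, tau_homeo = tau_homeo, tau_sense = tau_sense,
              noise_var = noise_var,
              dt = dt, cei_floor = cei_floor, record_dt = record_dt,
              cei_sample_s = cei_sample_s, init_rate = init_rate,
              init_cei = init_cei, seed = seed)
  if (any(vapply(cfg, length, 1L) != 1L)) stop("all parameters must be scalars")
  with(cfg, {
    if (tau_E <= 0 || tau_I <= 0 || tau_homeo <= 0 || dt <= 0 || sigma <= 0)
      stop("time constants, dt and sigma must be positive")
    if (noise_var < 0) stop("noise_var must be >= 0")
    if (tau_sense < 0) stop("tau_sense must be >= 0")
    if (mean_delay < 0) stop("mean_delay must be >= 0")
    if (record_dt < dt) stop("record_dt must be >= dt")
  })
  structure(cfg, class = "wc_config")
}

#' @export
print.wc_config <- function(x, ...) {
  cat("Wilson-Cowan network configuration\n")
  cat(sprintf("  coupling C = %.3g, mean delay = %.3g ms, target rate rho = %.3g\n",
              x$C, x$mean_delay, x$rho))
  cat(sprintf("  tau_E/tau_I = %.3g/%.3g ms, c_EE = %.3g, c_IE = %.3g, P = %.3g\n",
              x$tau_E, x$tau_I, x$c_EE, x$c_IE, x$P))
  cat(sprintf("  sigmoid mu = %.3g, sigma = %.3g; noise variance %.3g\n",
              x$mu, x$sigma, x$noise_var))
  cat(sprintf("  tau_homeo = %.3g ms; dt = %.3g ms; record every %.3g ms\n",
              x$tau_homeo, x$dt, x$record_dt))
  invisible(x)
}

#' Neural-mass activation function
#'
#' The sigmoid response of a population to its summed input,
#' `F(x) = 1 / (1 + exp(-(x - mu) / sigma))`: strictly increasing with range
#' (0, 1), value 1/2 at the threshold `mu`.
#'
#' @param x input (any numeric array).
#' @param mu threshold.
#' @param sigma sensitivity (> 0).
#' @return rates in (0, 1), same shape as `x`.
#' @export
wc_sigmoid <- function(x, mu = 1, sigma = 0.25) {
  stopifnot(sigma > 0)
  1 / (1 + exp(-(x - mu) / sigma))
}

#' Integer step delays from tract lengths
#'
#' Chooses the conduction speed so that the mean delay `L_ij / v` over
#' connected pairs equals `mean_delay`, then rounds each delay to the nearest
#' integer multiple of `dt` (minimum one step for connected pairs when
#' `mean_delay > 0`; all zeros when `mean_delay = 0`).
#'
#' @param c a `connectome`.
#' @param mean_delay target mean conduction delay, ms.
#' @param dt integration step, ms.
#' @return integer N x N matrix of step delays.
#' @export
build_delay_steps <- function(c, mean_delay, dt = 0.2) {
  stopifnot(inherits(c, "connectome"), mean_delay >= 0, dt > 0)
  conn <- c$W > 0
  steps <- matrix(0L, c$n, c$n)
  if (mean_delay == 0) return(steps)
  if (!any(conn)) stop("connectome has no connected pairs")
  mL <- mean(c$L[conn])
  tau <- c$L * mean_delay / mL        # ms, so that mean over edges = mean_delay
  st <- as.integer(round(tau / dt))
  steps[conn] <- pmax(1L, st[conn])
  steps
}

# directed edge list (0-based, for the C++ core) from a connectome + delays
edge_list <- function(c, delay_steps) {
  idx <- which(c$W > 0, arr.ind = TRUE)   # receiver i = row, source j = col
  list(from = as.integer(idx[, 2] - 1L),
       to = as.integer(idx[, 1] - 1L),
       w = c$W[idx],
       delay = as.integer(delay_steps[idx]))
}

# fresh network state: deterministic rates, delay buffer filled with them
init_state <- function(cfg, c, delay_steps, cei = NULL) {
  depth <- max(delay_steps) + 1L
  rE <- rep(cfg$init_rate, c$n)
  if (is.null(cei)) cei <- rep(cfg$init_cei, c$n)
  if (length(cei) == 1L) cei <- rep(cei, c$n)
  stopifnot(length(cei) == c$n)
  list(rE = rE, rI = rep(cfg$init_rate, c$n), cei = as.double(cei),
       rEf = rE, rIf = rep(cfg$init_rate, c$n),
       buf = matrix(rE, c$n, depth), buf_pos = 0L)
}

# low-level chunk runner shared by simulate_wc() and stabilize()
run_chunk <- function(cfg, c, el, state, duration_s, plasticity,
                      record = TRUE, record_rI = FALSE, cei_sample = TRUE) {
  res <- .wc_sim_cpp(el$from, el$to, el$w, el$delay, c$n,
                     cfg$tau_E, cfg$tau_I, cfg$c_EE, cfg$c_IE, cfg$P,
                     cfg$mu, cfg$sigma, cfg$C,
                     sqrt(cfg$noise_var), cfg$dt,
                     state$rE, state$rI, state$cei,
                     state$buf, state$buf_pos,
                     duration_s * 1000,
                     plasticity, cfg$rho, cfg$tau_homeo, cfg$cei_floor,
                     cfg$tau_sense, state$rEf, state$rIf,
                     if (record) as.integer(round(cfg$record_dt / cfg$dt)) else 0L,
                     record_rI,
                     if (cei_sample) as.integer(round(cfg$cei_sample_s * 1000 / cfg$dt)) else 0L)
  res$state <- list(rE = res$rE_end, rI = res$rI_end, cei = res$cei_end,
                    rEf = res$rEf_end, rIf = res$rIf_end,
                    buf = res$buf, buf_pos = res$buf_pos)
  res
}

#' Simulate the Wilson-Cowan network on a connectome
#'
#' Integrates the delayed, noise-driven network with the Euler method at
#' `cfg$dt` (default 0.2 ms), optionally applying the homeostatic inhibitory
#' scaling rule at every step, and records the decimated excitatory rate
#' series together with the slow inhibitory-weight trajectory. Runs with the
#' same seed are bit-identical.
#'
#' @param cfg a [wc_config()].
#' @param c a [connectome()].
#' @param duration_s recorded duration in seconds (excludes `discard_s`).
#' @param plasticity logical; apply the homeostatic update each step.
#' @param init either `NULL` (fresh deterministic state), a numeric vector of
#'   initial inhibitory weights, or a state list returned in a previous
#'   record's `$state` (to continue a run).
#' @param discard_s initial transient simulated and discarded before
#'   recording starts (default 10 s).
#' @param record_rI also record the inhibitory rate series.
#' @param seed RNG seed (default `cfg$seed`); `NULL` to continue the current
#'   RNG stream.
#' @return an object of class `wc_sim`: `rE` (and optionally `rI`) as regions
#'   x time matrices at `cfg$record_dt` ms, `cei_series` sampled every
#'   `cfg$cei_sample_s` s, `dt_effective` (ms), `duration_s`, and the final
#'   `state` for continuation.
#' @export
simulate_wc <- function(cfg, c, duration_s, plasticity = FALSE, init = NULL,
                        discard_s = 10, record_rI = FALSE, seed = cfg$seed) {
  stopifnot(inherits(cfg, "wc_config"), inherits(c, "connectome"),
            duration_s > 0, discard_s >= 0)
  delay_steps <- build_delay_steps(c, cfg$mean_delay, cfg$dt)
  el <- edge_list(c, delay_steps)
  state <- if (is.list(init) && !is.null(init$buf)) init
           else init_state(cfg, c, delay_steps, cei = init)
  run <- function() {
    if (discard_s > 0) {
      r0 <- run_chunk(cfg, c, el, state, discard_s, plasticity,
                      record = FALSE, cei_sample = FALSE)
      state <<- r0$state
    }
    run_chunk(cfg, c, el, state, duration_s, plasticity,
              record = TRUE, record_rI = record_rI)
  }
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  out <- list(rE = res$rE,
              rI = if (record_rI) res$rI else NULL,
              cei_series = res$cei,
              cei = res$state$cei,
              dt_effective = cfg$record_dt,
              duration_s = duration_s,
              discard_s = discard_s,
              plasticity = plasticity,
              state = res$state,
              n = c$n)
  class(out) <- "wc_sim"
  out
}

#' @export
print.wc_sim <- function(x, ...) {
  cat("Wilson-Cowan simulation record:", x$n, "regions,",
      sprintf("%.1f s at %.3g ms (%d samples)", x$duration_s,
              x$dt_effective, ncol(x$rE)), "\n")
  cat(sprintf("  plasticity %s; mean rE = %.4f (range %.4f - %.4f across nodes)\n",
              if (x$plasticity) "on" else "off", mean(x$rE),
              min(rowMeans(x$rE)), max(rowMeans(x$rE))))
  invisible(x)
}

#' Simulate one isolated neural mass
#'
#' Convenience wrapper: a single uncoupled node (`C = 0`), e.g. to inspect
#' its fixed point or limit cycle. With the default time constants the
#' oscillatory regime sits in the gamma band (~40 Hz).
#'
#' @param P intrinsic excitability (raise above the bifurcation for
#'   oscillations).
#' @param cei fixed inhibitory weight of the node.
#' @param duration_s,discard_s recorded / discarded durations (s).
#' @param noise_var input noise variance (0 for deterministic dynamics).
#' @param ... further arguments to [wc_config()].
#' @return a `wc_sim` (single-row rate matrices).
#' @export
single_node_sim <- function(P = 0.4, cei = 1, duration_s = 10, discard_s = 1,
                            noise_var = 0, ...) {
  cfg <- wc_config(C = 0, mean_delay = 0, P = P, noise_var = noise_var,
                   init_cei = cei, ...)
  reg <- data.frame(label = "node_1_R", hemisphere = "R", x = 0, y = 0, z = 0,
                    homotope_label = NA_character_, stringsAsFactors = FALSE)
  c1 <- connectome(matrix(0, 1, 1), matrix(0, 1, 1), reg)
  simulate_wc(cfg, c1, duration_s, discard_s = discard_s)
}

#' Fixed point of the isolated two-population mass
#'
#' Solves the noise-free, uncoupled steady-state equations
#' `rE = F(c_EE rE - cei rI + P)`, `rI = F(c_IE rE)` by damped fixed-point
#' iteration. Useful as a reference for sub-bifurcation dynamics.
#'
#' @param cfg a [wc_config()].
#' @param cei inhibitory weight (scalar).
#' @param start starting rates.
#' @param tol convergence tolerance on the update.
#' @return c(rE, rI) at the fixed point (of the attracting branch reached
#'   from `start`).
#' @export
isolated_fixed_point <- function(cfg, cei = cfg$init_cei,
                                 start = c(0.1, 0.1), tol = 1e-12) {
  x <- start
  for (i in 1:200000) {
    fE <- wc_sigmoid(cfg$c_EE * x[1] - cei * x[2] + cfg$P, cfg$mu, cfg$sigma)
    fI <- wc_sigmoid(cfg$c_IE * x[1], cfg$mu, cfg$sigma)
    xn <- x + 0.2 * (c(fE, fI) - x)
    if (max(abs(xn - x)) < tol) return(xn)
    x <- xn
  }
  warning("fixed-point iteration did not converge (oscillatory regime?)")
  x
}

#' Power-spectrum peak frequency
#'
#' Frequency (Hz) of the maximum of the periodogram of a demeaned series,
#' excluding DC.
#'
#' @param x numeric series.
#' @param fs sampling frequency in Hz.
#' @return peak frequency in Hz.
#' @export
spectral_peak <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- 2:floor(n / 2)
  freqs <- (half - 1) * fs / n
  freqs[which.max(p[half])]
}
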