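#' Hemodynamic (balloon-Windkessel) configuration
#'
#' Parameters of the forward model coupling excitatory firing rate to the
#' BOLD signal: vasodilatory signal decay `kappa` (1/s), flow-dependent
#' elimination `gamma` (1/s), hemodynamic transit time `tau_h` (s), Grubb
#' exponent `alpha`, resting oxygen extraction fraction `rho_h`, and resting
#' venous volume fraction `V0`. Defaults are the standard set of the
#' balloon-model lineage.
#'
#' @param kappa signal decay rate, 1/s.
#' @param gamma flow-dependent elimination rate, 1/s.
#' @param tau_h hemodynamic transit time, s.
#' @param alpha Grubb vessel-stiffness exponent, in (0, 1).
#' @param rho_h resting oxygen extraction fraction.
#' @param V0 resting venous blood volume fraction.
#' @param TR_out output sampling period, s (0.72, the HCP resting-state TR).
#' @param band band-pass edges in Hz applied by [bold_bandpass()]
#'   (c(0.01, 0.1), the standard resting-state band).
#' @param drive_scale multiplier on the rate before it drives the balloon
#'   model (default 1: the excitatory rate is used directly).
#' @param discard_samples BOLD samples dropped at the start to remove the
#'   hemodynamic onset transient (default 10).
#' @return an object of class `hemo_config`.
#' @export
hemo_config <- function(kappa = 0.65, gamma = 0.41, tau_h = 0.98,
                        alpha = 0.32, rho_h = 0.34, V0 = 0.02,
                        TR_out = 0.72, band = c(0.01, 0.1),
                        drive_scale = 1, discard_samples = 10) {
  stopifnot(kappa > 0, gamma > 0, tau_h > 0, alpha > 0, alpha < 1,
            rho_h > 0, rho_h < 1, V0 > 0, TR_out > 0,
            length(band) == 2, band[1] > 0, band[2] > band[1])
  structure(list(kappa = kappa, gamma = gamma, tau_h = tau_h, alpha = alpha,
                 rho_h = rho_h, V0 = V0, TR_out = TR_out, band = band,
                 drive_scale = drive_scale, discard_samples = discard_samples),
            class = "hemo_config")
}

#' BOLD record container
#'
#' @param series regions x samples numeric matrix.
#' @param TR sampling period in seconds.
#' @param filtered logical, whether [bold_bandpass()] has been applied.
#' @return an object of class `bold_record`.
#' @export
bold_record <- function(series, TR, filtered = FALSE) {
  series <- as.matrix(series)
  if (any(!is.finite(series))) stop("non-finite BOLD values")
  structure(list(series = series, TR = TR, filtered = filtered),
            class = "bold_record")
}

#' @export
print.bold_record <- function(x, ...) {
  cat(sprintf("BOLD record: %d regions x %d samples at TR = %.3g s (%s)\n",
              nrow(x$series), ncol(x$series), x$TR,
              if (x$filtered) "band-passed" else "unfiltered"))
  invisible(x)
}

#' Transform excitatory rates to BOLD
#'
#' Integrates the balloon-Windkessel system driven by the excitatory rate
#' series (Euler, at the rate-series decimation step), evaluates the BOLD
#' observation equation, downsamples to `cfg$TR_out` and discards the onset
#' transient. At the resting state (zero drive, flow = volume =
#' deoxyhemoglobin = 1) the output is exactly zero.
#'
#' @param sim a `wc_sim` (its `rE` at `dt_effective` ms is used) or a regions
#'   x samples rate matrix.
#' @param cfg a [hemo_config()].
#' @param dt_ms sampling period of the rate series in ms (taken from the
#'   `wc_sim` when available).
#' @return an unfiltered [bold_record()] at TR `cfg$TR_out`.
#' @export
bold_transform <- function(sim, cfg = hemo_config(), dt_ms = NULL) {
  if (inherits(sim, "wc_sim")) {
    r <- sim$rE
    dt_ms <- sim$dt_effective
  } else {
    r <- as.matrix(sim)
    if (is.null(dt_ms)) stop("dt_ms required for a bare rate matrix")
  }
  dt_s <- dt_ms / 1000
  y <- .balloon_cpp(r * cfg$drive_scale, dt_s, cfg$kappa, cfg$gamma,
                    cfg$tau_h, cfg$alpha, cfg$rho_h, cfg$V0)
  dec <- cfg$TR_out / dt_s
  if (abs(dec - round(dec)) > 1e-9)
    stop("TR_out must be an integer multiple of the rate sampling period")
  dec <- as.integer(round(dec))
  idx <- seq(dec, ncol(y), by = dec)
  if (cfg$discard_samples > 0) {
    if (length(idx) <= cfg$discard_samples)
      stop("series too short: nothing left after discarding the onset transient")
    idx <- idx[-seq_len(cfg$discard_samples)]
  }
  bold_record(y[, idx, drop = FALSE], TR = cfg$TR_out, filtered = FALSE)
}

#' Zero-phase band-pass filter for BOLD series
#'
#' Demeans each region's series and applies a 2nd-order Butterworth band-pass
#' forwards and backwards (zero phase) in the configured band.
#'
#' @param b a [bold_record()].
#' @param cfg a [hemo_config()] (its `band` is used).
#' @return a filtered [bold_record()].
#' @export
bold_bandpass <- function(b, cfg = hemo_config()) {
  stopifnot(inherits(b, "bold_record"))
  fs <- 1 / b$TR
  nyq <- fs / 2
  if (cfg$band[2] >= nyq) stop("upper band edge at or above Nyquist (", nyq, " Hz)")
  bf <- signal::butter(2, cfg$band / nyq, type = "pass")
  x <- b$series
  x <- x - rowMeans(x)
  filt <- t(apply(x, 1, function(v) signal::filtfilt(bf, v)))
  bold_record(filt, TR = b$TR, filtered = TRUE)
}
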