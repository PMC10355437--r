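# analytic signal via FFT (one-sided spectrum doubling); returns complex series
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Kuramoto order parameter time series
#'
#' Measures instantaneous phase synchrony across regions:
#' `R(t) = |mean_n exp(i theta_n(t))|`, with `theta_n` the Hilbert
#' (analytic-signal) phase of each demeaned regional series. `R = 1` for
#' identical signals; phases evenly spread on the circle give `R = 0`. Input
#' should be narrowband (e.g. band-passed BOLD). Edge samples, where the
#' analytic phase is unreliable, are trimmed.
#'
#' @param signals a [bold_record()] or regions x samples matrix
#'   (narrowband).
#' @param trim number of samples dropped at each end (default 10, capped at
#'   a quarter of the series).
#' @return numeric vector `R(t)` in `[0, 1]`.
#' @export
kuramoto_series <- function(signals, trim = 10) {
  x <- if (inherits(signals, "bold_record")) signals$series else as.matrix(signals)
  if (nrow(x) < 2) stop("need at least 2 regions")
  if (any(apply(x, 1, stats::sd) == 0))
    stop("constant signal: instantaneous phase undefined")
  x <- x - rowMeans(x)
  ph <- t(apply(x, 1, function(v) Arg(analytic_signal(v))))
  R <- Mod(colMeans(exp(1i * ph)))
  trim <- min(trim, floor(length(R) / 4))
  if (trim > 0) R <- R[(trim + 1):(length(R) - trim)]
  R
}

#' Synchrony and metastability
#'
#' The time mean and time standard deviation of the Kuramoto order parameter:
#' mean synchrony measures overall phase coupling; its temporal variability
#' (metastability) measures flexible switching between synchronised and
#' desynchronised episodes.
#'
#' @param R a Kuramoto order-parameter series (from [kuramoto_series()]).
#' @return named vector `c(synchrony, metastability)`.
#' @export
synchrony_metastability <- function(R) {
  stopifnot(length(R) > 0)
  c(synchrony = mean(R),
    metastability = if (length(R) > 1) stats::sd(R) else 0)
}

#' Detect neuronal avalanches in regional rate series
#'
#' Each region's series is Z-scored against its own mean and SD; an event is
#' the first sample of every excursion beyond `|z| > z_threshold`; an
#' avalanche is a maximal run of consecutive samples in which at least one
#' event occurs anywhere in the network. Size counts all events in the run;
#' duration counts its samples.
#'
#' @param rates a `wc_sim` (its `rE` is used) or regions x samples matrix.
#' @param z_threshold threshold in SD units (default 2.3, i.e. excursions
#'   distinct from Gaussian noise at p < 0.01).
#' @return object of class `avalanche_set`: `sizes`, `durations`, `n_nodes`,
#'   `n_samples`.
#' @export
detect_avalanches <- function(rates, z_threshold = 2.3) {
  x <- if (inherits(rates, "wc_sim")) rates$rE else as.matrix(rates)
  sds <- apply(x, 1, stats::sd)
  if (all(sds == 0)) stop("all series constant: no events definable")
  z <- (x - rowMeans(x)) / ifelse(sds == 0, Inf, sds)
  # event = first sample of each excursion; excursions beyond +threshold and
  # beyond -threshold are distinct events even when back-to-back
  up <- z > z_threshold
  dn <- z < -z_threshold
  first <- function(o) o & !cbind(FALSE, o[, -ncol(o), drop = FALSE])
  ev <- first(up) | first(dn)
  counts <- colSums(ev)
  active <- counts > 0
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  sizes <- vapply(runs, function(k) sum(counts[starts[k]:ends[k]]), numeric(1))
  structure(list(sizes = as.numeric(sizes),
                 durations = as.numeric(r$lengths[runs]),
                 n_nodes = nrow(x), n_samples = ncol(x)),
            class = "avalanche_set")
}

#' @export
print.avalanche_set <- function(x, ...) {
  cat(sprintf("Avalanche set: %d avalanches over %d nodes x %d samples\n",
              length(x$sizes), x$n_nodes, x$n_samples))
  if (length(x$sizes))
    cat(sprintf("  sizes: median %.0f, max %.0f; durations: median %.0f, max %.0f\n",
                stats::median(x$sizes), max(x$sizes),
                stats::median(x$durations), max(x$durations)))
  invisible(x)
}

# CDF of the discrete power law p(s) ~ s^(-1.5), s = 1..s_max
truncated_powerlaw_cdf <- function(beta, s_max, exponent = -1.5) {
  p <- (1:s_max)^exponent
  p <- p / sum(p)
  cdf <- cumsum(p)
  idx <- pmin(pmax(floor(beta), 0), s_max)
  ifelse(idx < 1, 0, cdf[pmax(idx, 1)]) * (idx >= 1)
}

#' Sample avalanche sizes from the truncated power law
#'
#' Draws from the discrete distribution `p(s) ~ s^(-1.5)` for
#' `s = 1..s_max`, the reference size distribution of a critical system whose
#' largest avalanche spans the network.
#'
#' @param n number of draws.
#' @param s_max truncation (network size; default 78).
#' @param exponent power-law exponent (default -1.5).
#' @param seed RNG seed (`NULL` uses the current stream).
#' @return integer vector of sizes.
#' @export
rpowerlaw_sizes <- function(n, s_max = 78, exponent = -1.5, seed = NULL) {
  p <- (1:s_max)^exponent
  draw <- function() sample.int(s_max, n, replace = TRUE, prob = p)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Criticality statistic k
#'
#' Compares the empirical avalanche-size CDF with the CDF of a power law with
#' exponent -1.5 truncated at the network size:
#' `k = 1 + (1/m) * sum_n (F_PL(beta_n) - F_NA(beta_n))` over `m`
#' logarithmically spaced points between the minimum and maximum observed
#' sizes. `k ~ 1` at criticality; an excess of small avalanches (empirical
#' CDF above the power law) gives `k < 1` (subcritical), a heavy tail of
#' system-size events gives `k > 1` (supercritical).
#'
#' Note on orientation: the difference is taken as `F_PL - F_NA` so that
#' subcritical systems score below 1 and supercritical above 1, matching the
#' statistic's standard reading.
#'
#' @param av an `avalanche_set` (from [detect_avalanches()]) or a numeric
#'   vector of sizes.
#' @param m number of log-spaced evaluation points (default 10).
#' @param s_max truncation of the reference power law; defaults to the
#'   avalanche set's `n_nodes` (78 for the full-scale cortical network).
#' @param exponent reference exponent (default -1.5).
#' @return scalar k.
#' @export
criticality_k <- function(av, m = 10, s_max = NULL, exponent = -1.5) {
  sizes <- if (inherits(av, "avalanche_set")) av$sizes else as.numeric(av)
  if (length(sizes) == 0) stop("empty avalanche set")
  if (is.null(s_max)) {
    s_max <- if (inherits(av, "avalanche_set")) av$n_nodes else 78L
  }
  if (length(unique(sizes)) < 2)
    warning("fewer than 2 distinct avalanche sizes; k is degenerate")
  beta <- exp(seq(log(min(sizes)), log(max(sizes)), length.out = m))
  Fna <- stats::ecdf(sizes)(beta)                       # right-continuous
  Fpl <- truncated_powerlaw_cdf(beta, s_max = s_max, exponent = exponent)
  1 + mean(Fpl - Fna)
}
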