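#' Long-term excitability change map
#'
#' Percentage change of each region's inhibitory weight between the pre-lesion
#' baseline and the chronic steady state:
#' `100 * (c_EI(T2) - c_EI(T0)) / c_EI(T0)`. Negative values mean inhibition
#' decreased, i.e. local excitability increased. The lesioned region's own
#' entry is marked missing (its weight is meaningless once isolated).
#'
#' @param exp a `lesion_experiment`, or `NULL` if `cei_T0`/`cei_T2` are given.
#' @param cei_T0,cei_T2 weight vectors (ignored when `exp` is supplied).
#' @param lesioned_node lesioned index (taken from `exp` when supplied).
#' @return object of class `excitability_map`: data frame with `region`,
#'   `delta_cei_pct`, plus attributes `lesioned_node` and `mirrored`.
#' @export
delta_cei <- function(exp = NULL, cei_T0 = NULL, cei_T2 = NULL,
                      lesioned_node = NULL) {
  if (!is.null(exp)) {
    stopifnot(inherits(exp, "lesion_experiment"))
    cei_T0 <- exp$cei_T0
    cei_T2 <- exp$cei_T2
    lesioned_node <- exp$node
    labels <- exp$connectome_intact$regions$label
  } else {
    labels <- names(cei_T0)
    if (is.null(labels)) labels <- paste0("region_", seq_along(cei_T0))
  }
  if (any(cei_T0 <= 0)) stop("baseline c_EI must be positive everywhere")
  pct <- 100 * (cei_T2 - cei_T0) / cei_T0
  if (!is.null(lesioned_node)) pct[lesioned_node] <- NA_real_
  structure(data.frame(region = labels, delta_cei_pct = pct,
                       stringsAsFactors = FALSE),
            lesioned_node = lesioned_node, mirrored = FALSE,
            class = c("excitability_map", "data.frame"))
}

#' Exponential-distance fit of an excitability map
#'
#' Least-squares fit of `delta_cei_pct = a * exp(-d / lambda) + c` against
#' each region's Euclidean distance to the lesion, with an additive offset
#' `c` so distant regions may plateau near zero. Reports the amplitude, the
#' length constant and the coefficient of determination.
#'
#' @param map an `excitability_map` (or numeric vector of values).
#' @param distances per-region Euclidean distance (mm) to the lesioned
#'   region.
#' @return list `amplitude`, `length_constant`, `offset`, `r_squared`,
#'   `converged`, `fit` (the `nls` object or `NULL`).
#' @export
exp_distance_fit <- function(map, distances) {
  y <- if (inherits(map, "excitability_map")) map$delta_cei_pct else as.numeric(map)
  keep <- is.finite(y) & is.finite(distances)
  y <- y[keep]
  d <- distances[keep]
  if (length(y) < 4) stop("need at least 4 non-missing regions")
  a0 <- y[which.min(d)]
  if (!is.finite(a0) || a0 == 0) a0 <- min(y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-d / lambda) + cc,
                      start = list(a = a0, lambda = max(diff(range(d)) / 3, 1),
                                   cc = 0),
                      lower = c(-Inf, 1e-3, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(amplitude = NA_real_, length_constant = NA_real_,
                offset = NA_real_, r_squared = NA_real_,
                converged = FALSE, fit = NULL))
  }
  res <- stats::resid(fit)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  cf <- stats::coef(fit)
  list(amplitude = unname(cf["a"]), length_constant = unname(cf["lambda"]),
       offset = unname(cf["cc"]), r_squared = r2, converged = TRUE, fit = fit)
}

#' Asymmetry index of a homotopic region pair
#'
#' Relative change in the right/left ratio of inhibitory weights between
#' baseline and the chronic state:
#' `(c_R(T2)/c_L(T2)) / (c_R(T0)/c_L(T0)) - 1`. Zero if both sides change by
#' the same factor; negative when excitability rose more on the right
#' (inhibition fell more on the right than the left).
#'
#' @param cei_T0,cei_T2 per-region weight vectors.
#' @param left,right indices of the homotopic pair (e.g. left and right
#'   motor cortex).
#' @return scalar index.
#' @export
asymmetry_index <- function(cei_T0, cei_T2, left, right) {
  w <- c(cei_T0[left], cei_T0[right], cei_T2[left], cei_T2[right])
  if (any(w <= 0)) stop("all four weights must be positive")
  unname((cei_T2[right] / cei_T2[left]) / (cei_T0[right] / cei_T0[left]) - 1)
}

#' Correlations between excitability changes and lesion structure
#'
#' Across a lesion sweep: (i) pooled Pearson correlation of per-region
#' `delta c_EI (%)` with the structural weight connecting that region to the
#' lesioned node, and (ii) correlation of each lesion's mean
#' `delta c_EI (%)` with the lesioned node's strength. Significance by the
#' F-test of the correlation (as in `cor.test`).
#'
#' @param sweep a `lesion_sweep` (failed entries skipped).
#' @param c the intact [connectome()].
#' @return list `pooled` (r, p, n over region-lesion pairs) and `by_lesion`
#'   (r, p, n over lesions).
#' @export
lesion_correlations <- function(sweep, c) {
  exps <- Filter(function(e) inherits(e, "lesion_experiment"), sweep)
  if (length(exps) < 3) stop("need at least 3 completed lesions")
  dce <- lapply(exps, delta_cei)
  w_to_lesion <- unlist(lapply(exps, function(e) c$W[, e$node]))
  d_all <- unlist(lapply(dce, function(m) m$delta_cei_pct))
  keep <- is.finite(d_all)
  ct1 <- stats::cor.test(d_all[keep], w_to_lesion[keep])
  s <- node_strength(c)
  mean_d <- vapply(dce, function(m) mean(m$delta_cei_pct, na.rm = TRUE), numeric(1))
  lesion_strength <- vapply(exps, function(e) s[e$node], numeric(1))
  ct2 <- stats::cor.test(mean_d, lesion_strength)
  list(pooled = list(r = unname(ct1$estimate), p = ct1$p.value, n = sum(keep)),
       by_lesion = list(r = unname(ct2$estimate), p = ct2$p.value,
                        n = length(exps)))
}

#' Average excitability map across lesions, mirrored
#'
#' Mirrors maps from left-hemisphere lesions so the ipsilesional hemisphere
#' is always on the right, then averages across lesions, reporting the mean,
#' SD and SEM per region. Missing entries (the lesioned nodes themselves) are
#' dropped per region.
#'
#' @param sweep a `lesion_sweep` or list of `lesion_experiment`s.
#' @param c the intact [connectome()].
#' @return data frame `region`, `mean`, `sd`, `sem`, `n`.
#' @export
sweep_average_map <- function(sweep, c) {
  exps <- Filter(function(e) inherits(e, "lesion_experiment"), sweep)
  stopifnot(length(exps) >= 1)
  vals <- vapply(exps, function(e)
    mirror_to_ipsilesional(delta_cei(e)$delta_cei_pct, e$node, c),
    numeric(c$n))
  vals <- matrix(vals, nrow = c$n)
  n <- rowSums(is.finite(vals))
  m <- rowMeans(vals, na.rm = TRUE)
  s <- apply(vals, 1, stats::sd, na.rm = TRUE)
  data.frame(region = c$regions$label, mean = m, sd = s,
             sem = s / sqrt(pmax(n, 1)), n = n, stringsAsFactors = FALSE)
}
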