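#' Generate a synthetic mirror-symmetric connectome
#'
#' Emulates the statistical structure of cortical structural connectivity that
#' the analysis pipeline assumes, so every stage runs without external data:
#' regions are placed mirror-symmetrically in two hemispheric point clouds,
#' connection weight decays exponentially with Euclidean distance
#' (`W ~ exp(-d / decay_length)`) under multiplicative lognormal jitter,
#' homotopic (mirror-pair) connections are boosted, the edge set is
#' thresholded to a target density, and tract lengths equal the Euclidean
#' distances. Weights are scaled so the mean node strength is 1, making the
#' global coupling `C` comparable across fixture sizes and densities.
#'
#' Coordinates are drawn in two 60 mm-radius hemispheric shells whose centres
#' are 80 mm apart, giving inter-regional distances in the empirical cortical
#' range so that delay arithmetic is realistic.
#'
#' @param n_regions even number of regions (half per hemisphere).
#' @param decay_length exponential length constant in mm.
#' @param homotopic_boost multiplicative factor on mirror-pair weights.
#' @param density fraction of possible edges retained (0 < density <= 1).
#'   Homotopic pairs are always retained.
#' @param jitter_sd standard deviation of the lognormal weight jitter on the
#'   log scale; 0 disables jitter.
#' @param seed RNG seed; the same seed reproduces the connectome exactly.
#' @return a [connectome()] object.
#' @export
synth_connectome <- function(n_regions = 16, decay_length = 40,
                             homotopic_boost = 3, density = 0.5,
                             jitter_sd = 0.5, seed = 1) {
  if (n_regions %% 2 != 0) stop("n_regions must be even (hemispheric mirroring)")
  if (decay_length <= 0) stop("decay_length must be positive")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  nh <- n_regions / 2L
  with_seed(seed, {
    # right-hemisphere cloud: uniform in a half-ball of radius 60 mm centred
    # at x = +40; left hemisphere is its mirror image through x = 0
    pts <- matrix(NA_real_, nh, 3)
    k <- 0
    while (k < nh) {
      p <- stats::runif(3, -60, 60)
      if (sum(p^2) <= 60^2 && p[1] >= 0) {
        k <- k + 1
        pts[k, ] <- p + c(40, 0, 0)
      }
    }
    coords <- rbind(pts, cbind(-pts[, 1], pts[, 2:3]))
    hemi <- rep(c("R", "L"), each = nh)
    lab <- c(paste0("region_", seq_len(nh), "_R"),
             paste0("region_", seq_len(nh), "_L"))
    regions <- data.frame(label = lab, hemisphere = hemi,
                          x = coords[, 1], y = coords[, 2], z = coords[, 3],
                          homotope_label = c(paste0("region_", seq_len(nh), "_L"),
                                             paste0("region_", seq_len(nh), "_R")),
                          stringsAsFactors = FALSE)
    d <- as.matrix(stats::dist(coords))
    W <- exp(-d / decay_length)
    if (jitter_sd > 0) {
      J <- matrix(0, n_regions, n_regions)
      J[upper.tri(J)] <- stats::rnorm(sum(upper.tri(J)), 0, jitter_sd)
      J <- J + t(J)
      W <- W * exp(J)
    }
    homo <- cbind(seq_len(nh), nh + seq_len(nh))
    W[homo] <- W[homo] * homotopic_boost
    W[homo[, 2:1]] <- W[homo]
    diag(W) <- 0
    # density threshold on the upper triangle; homotopic edges always kept
    ut <- which(upper.tri(W))
    n_keep <- max(1L, round(density * length(ut)))
    ord <- ut[order(W[ut], decreasing = TRUE)]
    keep <- ord[seq_len(n_keep)]
    keep <- union(keep, homo[, 1] + (homo[, 2] - 1L) * n_regions)
    mask <- matrix(FALSE, n_regions, n_regions)
    mask[keep] <- TRUE
    mask <- mask | t(mask)
    W[!mask] <- 0
    W <- W / mean(colSums(W))   # unit mean node strength
    g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
    if (!igraph::is_connected(g))
      warning("requested density leaves the synthetic connectome disconnected")
    connectome(W, d, regions)
  })
}

#' Generate reference BOLD-like signals with planted community structure
#'
#' Correlated Gaussian series at the resting-state fMRI sampling period,
#' with a block (community) covariance structure: regions in the same
#' community share a latent signal. Used as a stand-in reference for the
#' model-fitting metrics, consensus clustering and modularity.
#'
#' @param n_regions number of regions.
#' @param n_samples number of time points.
#' @param n_communities number of planted communities (<= n_regions).
#' @param within_cor target correlation between regions sharing a community.
#' @param TR sampling period in seconds (default 0.72).
#' @param seed RNG seed.
#' @return a [bold_record()] with attribute `communities` (the planted
#'   assignment).
#' @export
synth_reference_signals <- function(n_regions = 16, n_samples = 400,
                                    n_communities = 4, within_cor = 0.7,
                                    TR = 0.72, seed = 1) {
  if (n_communities > n_regions) stop("n_communities must be <= n_regions")
  stopifnot(within_cor >= 0, within_cor < 1)
  with_seed(seed, {
    comm <- rep_len(seq_len(n_communities), n_regions)
    comm <- sort(comm)
    a <- sqrt(within_cor)           # loading on the shared community signal
    latent <- matrix(stats::rnorm(n_communities * n_samples), n_communities)
    noise <- matrix(stats::rnorm(n_regions * n_samples), n_regions)
    series <- a * latent[comm, , drop = FALSE] + sqrt(1 - a^2) * noise
    b <- bold_record(series, TR = TR, filtered = FALSE)
    attr(b, "communities") <- comm
    b
  })
}
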