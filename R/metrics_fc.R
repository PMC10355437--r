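#' Static functional connectivity
#'
#' Pairwise Pearson correlation matrix between regional BOLD series.
#' Zero-variance regions yield `NA` rows/columns (with a warning).
#'
#' @param b a [bold_record()] or a regions x samples matrix.
#' @return N x N correlation matrix (class `fc_matrix`): symmetric, unit
#'   diagonal.
#' @export
static_fc <- function(b) {
  x <- if (inherits(b, "bold_record")) b$series else as.matrix(b)
  if (ncol(x) < 2) stop("need at least 2 samples")
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) warning("zero-variance region(s): undefined FC entries")
  fc <- suppressWarnings(stats::cor(t(x)))
  diag(fc) <- 1
  class(fc) <- c("fc_matrix", class(fc))
  fc
}

#' Functional connectivity dynamics (FCD)
#'
#' FC is computed in sliding windows of `window` samples advanced by
#' `window * (1 - overlap)` samples; the FCD matrix holds the Pearson
#' correlation between the upper-triangular FC patterns of every window pair.
#' Its off-diagonal value distribution characterises how much FC fluctuates
#' over time.
#'
#' @param b a [bold_record()] or regions x samples matrix.
#' @param window window length in samples (default 80).
#' @param overlap fractional overlap between consecutive windows (default
#'   0.8, i.e. a step of 16 samples).
#' @return n_win x n_win matrix of class `fcd_matrix`.
#' @export
fcd_matrix <- function(b, window = 80, overlap = 0.8) {
  x <- if (inherits(b, "bold_record")) b$series else as.matrix(b)
  T <- ncol(x)
  if (T < window) stop("series shorter than one FCD window (", window, " samples)")
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  starts <- seq(1L, T - window + 1L, by = step)
  pats <- vapply(starts, function(s) {
    fc <- suppressWarnings(stats::cor(t(x[, s:(s + window - 1), drop = FALSE])))
    upper_tri_vec(fc)
  }, numeric(nrow(x) * (nrow(x) - 1) / 2))
  fcd <- stats::cor(pats)
  diag(fcd) <- 1
  class(fcd) <- c("fcd_matrix", class(fcd))
  fcd
}

#' Fit metrics between model and reference FC/FCD
#'
#' Pearson correlation and mean squared error between the upper triangles of
#' the model and reference FC matrices, plus the Kolmogorov-Smirnov statistic
#' between the distributions of off-diagonal values of the two FCD matrices.
#'
#' @param model_fc,ref_fc N x N FC matrices (same parcellation).
#' @param model_fcd,ref_fcd FCD matrices (any sizes).
#' @return named numeric vector `c(corr, mse, ks)`.
#' @export
fit_metrics <- function(model_fc, ref_fc, model_fcd, ref_fcd) {
  if (!all(dim(model_fc) == dim(ref_fc))) stop("FC size mismatch")
  a <- upper_tri_vec(unclass(model_fc))
  b <- upper_tri_vec(unclass(ref_fc))
  ks <- suppressWarnings(
    stats::ks.test(upper_tri_vec(unclass(model_fcd)),
                   upper_tri_vec(unclass(ref_fcd)))$statistic)
  c(corr = stats::cor(a, b), mse = mean((a - b)^2), ks = unname(ks))
}

#' FC distance (Frobenius norm of the difference)
#'
#' `sqrt(sum((A - B)^2))` over all entries: a true metric on FC matrices
#' (symmetric, zero iff equal, triangle inequality).
#'
#' @param a,b equally sized matrices.
#' @param exclude optional indices of regions removed before comparison
#'   (e.g. the lesioned node).
#' @return scalar distance.
#' @export
fc_distance <- function(a, b, exclude = NULL) {
  a <- unclass(a); b <- unclass(b)
  if (!all(dim(a) == dim(b))) stop("size mismatch")
  if (!is.null(exclude)) {
    a <- a[-exclude, -exclude, drop = FALSE]
    b <- b[-exclude, -exclude, drop = FALSE]
  }
  sqrt(sum((a - b)^2))
}

#' Correlation between functional and structural connectivity
#'
#' Pearson correlation between the upper triangles of an FC matrix and the
#' connectome weight matrix; its post-lesion drop and recovery is a
#' structural-functional decoupling biomarker.
#'
#' @param fc an FC matrix.
#' @param c a [connectome()] (or a weight matrix).
#' @param exclude optional region indices removed before the correlation.
#' @return scalar Pearson r.
#' @export
fc_sc_correlation <- function(fc, c, exclude = NULL) {
  W <- if (inherits(c, "connectome")) c$W else as.matrix(c)
  fc <- unclass(fc)
  if (!all(dim(fc) == dim(W))) stop("parcellation mismatch")
  if (!is.null(exclude)) {
    fc <- fc[-exclude, -exclude, drop = FALSE]
    W <- W[-exclude, -exclude, drop = FALSE]
  }
  w <- upper_tri_vec(W)
  if (stats::sd(w) == 0) stop("constant structural weights: correlation undefined")
  stats::cor(upper_tri_vec(fc), w)
}
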