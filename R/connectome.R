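#' Construct a structural connectome object
#'
#' Bundles a non-negative connection weight matrix, a matching tract-length
#' matrix (mm) and region metadata into a validated `connectome` object, the
#' substrate every simulation and lesion acts on.
#'
#' Both matrices must be square, of the same size as the region table,
#' symmetric (up to `tol`, symmetrized by averaging), with zero diagonal.
#' Tract lengths must be positive wherever a connection weight is positive.
#'
#' @param W numeric N x N matrix of connection weights (dimensionless, >= 0).
#' @param L numeric N x N matrix of tract lengths in mm.
#' @param regions data frame with columns `label`, `hemisphere` ("L"/"R"),
#'   `x`, `y`, `z` (mm) and optionally `homotope_label` (label of the
#'   mirror-hemisphere partner, `NA` if none).
#' @param tol relative tolerance for accepting (and averaging away) asymmetry.
#' @return An object of class `connectome` with elements `W`, `L`, `regions`,
#'   `homotope` (integer index of each region's mirror partner, `NA` if none)
#'   and `n`.
#' @seealso [load_connectome()], [synth_connectome()], [node_strength()]
#' @export
connectome <- function(W, L, regions, tol = 1e-8) {
  W <- as.matrix(W)
  L <- as.matrix(L)
  n <- nrow(W)
  if (ncol(W) != n || nrow(L) != n || ncol(L) != n)
    stop("W and L must be square matrices of identical size")
  if (!is.data.frame(regions) || nrow(regions) != n)
    stop("region table must have one row per matrix row (", n, ")")
  req <- c("label", "hemisphere", "x", "y", "z")
  miss <- setdiff(req, names(regions))
  if (length(miss)) stop("region table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(regions$label)) stop("region labels must be unique")
  if (!all(regions$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'")
  if (any(!is.finite(W)) || any(!is.finite(L))) stop("non-finite matrix entries")
  if (any(W < 0)) stop("negative connection weights")

  asym <- function(M) {
    s <- max(abs(M))
    if (s == 0) 0 else max(abs(M - t(M))) / s
  }
  if (asym(W) > tol || asym(L) > tol)
    stop("matrix asymmetry exceeds tolerance (", tol, "); refusing to symmetrize")
  W <- (W + t(W)) / 2
  L <- (L + t(L)) / 2
  diag(W) <- 0
  diag(L) <- 0
  if (any(L[W > 0] <= 0)) stop("zero or negative tract length on a connected pair")

  homotope <- rep(NA_integer_, n)
  if ("homotope_label" %in% names(regions)) {
    hl <- as.character(regions$homotope_label)
    has <- !is.na(hl) & nzchar(hl)
    homotope[has] <- match(hl[has], regions$label)
    if (any(has & is.na(homotope)))
      stop("homotope_label refers to an unknown region label")
    for (i in which(!is.na(homotope))) {
      j <- homotope[i]
      if (regions$hemisphere[j] == regions$hemisphere[i])
        stop("homotope of '", regions$label[i], "' lies in the same hemisphere")
      if (is.na(homotope[j]) || homotope[j] != i)
        stop("homotopy is not symmetric at region '", regions$label[i], "'")
    }
  }
  rownames(W) <- colnames(W) <- regions$label
  rownames(L) <- colnames(L) <- regions$label
  structure(list(W = W, L = L, regions = regions, homotope = homotope, n = n),
            class = "connectome")
}

#' Load a connectome from plain-text files
#'
#' Reads square CSV weight and tract-length matrices (no header) plus a CSV
#' region table (`label,hemisphere,x,y,z[,homotope_label]`) and validates them
#' via [connectome()].
#'
#' @param weights_path,lengths_path paths to CSV square numeric matrices.
#' @param regions_path path to the CSV region table (with header).
#' @param tol asymmetry tolerance passed to [connectome()].
#' @param normalize optional weight normalization: `"none"` (default, use
#'   weights as loaded), `"mean_strength"` (scale so the mean node strength
#'   is 1, the convention under which the default global coupling was
#'   characterised), or `"max"` (scale the largest weight to 1).
#' @return a `connectome` object.
#' @export
load_connectome <- function(weights_path, lengths_path, regions_path,
                            tol = 1e-8,
                            normalize = c("none", "mean_strength", "max")) {
  normalize <- match.arg(normalize)
  W <- as.matrix(utils::read.csv(weights_path, header = FALSE))
  L <- as.matrix(utils::read.csv(lengths_path, header = FALSE))
  regions <- utils::read.csv(regions_path, header = TRUE,
                             stringsAsFactors = FALSE)
  dimnames(W) <- NULL
  dimnames(L) <- NULL
  c <- connectome(W, L, regions, tol = tol)
  if (normalize == "mean_strength" && mean(colSums(c$W)) > 0)
    c$W <- c$W / mean(colSums(c$W))
  else if (normalize == "max" && max(c$W) > 0)
    c$W <- c$W / max(c$W)
  c
}

#' Write a connectome to plain-text files
#'
#' Inverse of [load_connectome()]: writes `weights.csv`, `lengths.csv` and
#' `regions.csv` under `dir`.
#'
#' @param c a `connectome`.
#' @param dir output directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
save_connectome <- function(c, dir) {
  stopifnot(inherits(c, "connectome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pw <- file.path(dir, "weights.csv")
  pl <- file.path(dir, "lengths.csv")
  pr <- file.path(dir, "regions.csv")
  utils::write.table(c$W, pw, sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(c$L, pl, sep = ",", row.names = FALSE, col.names = FALSE)
  reg <- c$regions
  if (!"homotope_label" %in% names(reg)) {
    reg$homotope_label <- ifelse(is.na(c$homotope), "",
                                 reg$label[c$homotope])
  }
  utils::write.csv(reg, pr, row.names = FALSE)
  invisible(c(weights = pw, lengths = pl, regions = pr))
}

#' Node strength
#'
#' Sum of connection weights incident on each region, the "lesion strength"
#' used to rank lesions by severity.
#'
#' @param c a `connectome`.
#' @return named numeric vector of length N.
#' @export
node_strength <- function(c) {
  stopifnot(inherits(c, "connectome"))
  colSums(c$W)
}

#' Euclidean distances between region centroids
#'
#' @param regions a region data frame (as in [connectome()]) or a
#'   `connectome`.
#' @return symmetric N x N matrix of distances in mm, zero diagonal.
#' @export
euclidean_distances <- function(regions) {
  if (inherits(regions, "connectome")) regions <- regions$regions
  if (!all(c("x", "y", "z") %in% names(regions)))
    stop("region coordinates (x, y, z) are required")
  xyz <- as.matrix(regions[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("missing region coordinates")
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- list(regions$label, regions$label)
  d
}

#' Remove all connections of one region (in-silico stroke)
#'
#' Zeroes row and column `node` of the weight matrix, leaving tract lengths
#' and all other entries untouched. The region stays in the network as an
#' isolated, noise-driven node.
#'
#' @param c a `connectome`.
#' @param node region index (1-based) or label.
#' @return a new `connectome` with the lesion applied.
#' @export
apply_lesion <- function(c, node) {
  stopifnot(inherits(c, "connectome"))
  node <- resolve_region(c, node)
  W <- c$W
  W[node, ] <- 0
  W[, node] <- 0
  c$W <- W
  c
}

# map a label or index to a validated 1-based region index
resolve_region <- function(c, node) {
  if (is.character(node)) {
    i <- match(node, c$regions$label)
    if (is.na(i)) stop("unknown region label '", node, "'")
    return(i)
  }
  node <- as.integer(node)
  if (is.na(node) || node < 1L || node > c$n)
    stop("region index out of range 1..", c$n)
  node
}

#' @export
print.connectome <- function(x, ...) {
  ne <- sum(x$W[upper.tri(x$W)] > 0)
  cat("Structural connectome: ", x$n, " regions, ", ne, " edges (density ",
      sprintf("%.2f", ne / (x$n * (x$n - 1) / 2)), ")\n", sep = "")
  cat("  hemispheres: L =", sum(x$regions$hemisphere == "L"),
      ", R =", sum(x$regions$hemisphere == "R"),
      "; homotopic pairs =", sum(!is.na(x$homotope)) / 2, "\n")
  cat("  node strength: median", sprintf("%.3f", stats::median(node_strength(x))),
      "range", paste(sprintf("%.3f", range(node_strength(x))), collapse = " - "), "\n")
  invisible(x)
}

#' @export
summary.connectome <- function(object, ...) {
  s <- node_strength(object)
  d <- euclidean_distances(object$regions)
  edges <- object$W[upper.tri(object$W)]
  out <- list(
    n = object$n,
    n_edges = sum(edges > 0),
    density = mean(edges > 0),
    strength = summary(s),
    weight_range = range(edges[edges > 0]),
    distance_range = range(d[upper.tri(d)])
  )
  class(out) <- "summary.connectome"
  out
}

#' @export
print.summary.connectome <- function(x, ...) {
  cat("Connectome with", x$n, "regions,", x$n_edges,
      sprintf("edges (density %.2f)\n", x$density))
  cat("Node strength:\n")
  print(x$strength)
  cat(sprintf("Nonzero weights in [%.4g, %.4g]; distances in [%.1f, %.1f] mm\n",
              x$weight_range[1], x$weight_range[2],
              x$distance_range[1], x$distance_range[2]))
  invisible(x)
}
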