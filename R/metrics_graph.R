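#' Density-threshold an FC matrix into a binary graph
#'
#' Keeps the top `density` fraction of off-diagonal upper-triangle values as
#' undirected edges. Ties at the cutoff are broken by a stable sort on
#' (value, row, column) so results are deterministic across platforms.
#'
#' @param fc an FC (or any symmetric) matrix.
#' @param density fraction of possible edges retained, in (0, 1].
#' @return object of class `binary_graph`: `adjacency` (0/1 symmetric, zero
#'   diagonal), `density` (requested), `n_edges`.
#' @export
threshold_graph <- function(fc, density) {
  stopifnot(density > 0, density <= 1)
  fc <- unclass(fc)
  n <- nrow(fc)
  ut <- which(upper.tri(fc))
  n_keep <- round(density * length(ut))
  A <- matrix(0L, n, n)
  if (n_keep > 0) {
    rows <- ((ut - 1) %% n) + 1
    cols <- ((ut - 1) %/% n) + 1
    ord <- order(-fc[ut], rows, cols)
    keep <- ut[ord[seq_len(n_keep)]]
    A[keep] <- 1L
    A <- A + t(A)
  }
  dimnames(A) <- dimnames(fc)
  structure(list(adjacency = A, density = density, n_edges = n_keep),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("Binary graph: %d nodes, %d edges (density %.2f)\n",
              nrow(x$adjacency), x$n_edges, x$density))
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
}

#' Consensus module partition by repeated k-means
#'
#' Runs k-means on the rows of the FC matrix `runs` times with random
#' initialisations, accumulates an association (co-assignment) matrix
#' counting how often each pair of regions lands in the same cluster, then
#' clusters the association matrix once with k-means to obtain the final
#' partition. Modules fixed this way a priori avoid biasing modularity by
#' optimising community structure on each compared network.
#'
#' @param fc an FC matrix.
#' @param k number of modules (default 6).
#' @param runs number of k-means repetitions (default 200).
#' @param seed RNG seed for reproducibility.
#' @return object of class `module_partition`: `assignment` (integer module
#'   id per region), `k`, `association` (N x N co-assignment fractions).
#' @export
consensus_modules <- function(fc, k = 6, runs = 200, seed = 1) {
  fc <- unclass(fc)
  n <- nrow(fc)
  if (n < k) stop("need at least k regions")
  if (n == k) {
    # each region its own module (stats::kmeans needs k < n)
    return(structure(list(assignment = seq_len(n), k = k,
                          association = diag(n)),
                     class = "module_partition"))
  }
  with_seed(seed, {
    assoc <- matrix(0, n, n)
    for (r in seq_len(runs)) {
      cl <- stats::kmeans(fc, centers = k, nstart = 1)$cluster
      assoc <- assoc + outer(cl, cl, "==")
    }
    assoc <- assoc / runs
    final <- stats::kmeans(assoc, centers = k, nstart = 10)$cluster
    structure(list(assignment = as.integer(final), k = k, association = assoc),
              class = "module_partition")
  })
}

#' @export
print.module_partition <- function(x, ...) {
  cat("Module partition: k =", x$k, "modules over", length(x$assignment),
      "regions; sizes:", paste(tabulate(x$assignment, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Modularity of a binary graph under a fixed partition
#'
#' `Q = sum_u (e_uu - a_u^2)`, where `e_uu` is the fraction of edges inside
#' module `u` and `a_u` the fraction of edge ends attached to module `u`
#' (within-module edges counted once, plus half of each between-module edge
#' fraction), so that the `e_uv` fractions sum to 1. `Q = 0` for a single
#' all-covering module; positive Q means denser-than-expected within-module
#' connectivity.
#'
#' @param g a [threshold_graph()] result (or 0/1 adjacency matrix).
#' @param partition a `module_partition` or an integer assignment vector.
#' @param weights optional symmetric non-negative weight matrix: computes the
#'   weighted variant on it instead of the binary adjacency.
#' @return scalar Q in `[-1, 1]`.
#' @export
modularity_q <- function(g, partition, weights = NULL) {
  A <- if (!is.null(weights)) as.matrix(weights)
       else if (inherits(g, "binary_graph")) g$adjacency
       else as.matrix(g)
  mod <- if (inherits(partition, "module_partition")) partition$assignment
         else as.integer(partition)
  stopifnot(length(mod) == nrow(A))
  tw <- sum(A) # 2E for undirected
  if (tw == 0) stop("edgeless graph: modularity undefined")
  ids <- sort(unique(mod))
  Q <- 0
  for (u in ids) {
    in_u <- mod == u
    e_uu <- sum(A[in_u, in_u]) / tw
    a_u <- sum(A[in_u, ]) / tw
    Q <- Q + e_uu - a_u^2
  }
  Q
}

#' Small-world coefficient
#'
#' `SW = (C / C_rand) / (L / L_rand)`, with `C` the average (local)
#' clustering coefficient and `L` the characteristic path length of the
#' graph, normalised by the means over `n_random` Erdos-Renyi G(n, m) graphs
#' with the same node and edge count (resampled until connected, up to 1000
#' attempts each). Requires a connected input graph.
#'
#' @param g a [threshold_graph()] result or 0/1 adjacency matrix.
#' @param n_random number of reference random graphs (default 100).
#' @param seed RNG seed.
#' @return scalar SW (> 1 indicates small-world organisation).
#' @export
small_world <- function(g, n_random = 100, seed = 1) {
  A <- if (inherits(g, "binary_graph")) g$adjacency else as.matrix(g)
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  if (!igraph::is_connected(ig))
    stop("graph is disconnected: characteristic path length undefined")
  n <- igraph::vcount(ig)
  m <- igraph::ecount(ig)
  C <- igraph::transitivity(ig, type = "localaverage", isolates = "zero")
  L <- igraph::mean_distance(ig)
  with_seed(seed, {
    Cr <- Lr <- numeric(n_random)
    for (i in seq_len(n_random)) {
      for (att in 1:1000) {
        rg <- igraph::sample_gnm(n, m)
        if (igraph::is_connected(rg)) break
        if (att == 1000) stop("could not sample a connected random graph")
      }
      Cr[i] <- igraph::transitivity(rg, type = "localaverage", isolates = "zero")
      Lr[i] <- igraph::mean_distance(rg)
    }
    (C / mean(Cr)) / (L / mean(Lr))
  })
}

#' Graph metrics of an FC matrix across density thresholds
#'
#' Removes the lesioned region (if any) from the FC matrix, thresholds at
#' each requested edge density and computes modularity (under the supplied
#' fixed partition) and, over a typically narrower range where thresholded
#' graphs stay connected, the small-world coefficient. Densities where the
#' graph is disconnected yield `NA` for SW.
#'
#' @param fc an FC matrix.
#' @param partition a `module_partition` or assignment vector over all
#'   regions (the lesioned entry is dropped internally).
#' @param lesioned_node optional region index removed before thresholding.
#' @param q_densities densities for modularity (default `seq(0.04, 0.40, 0.02)`).
#' @param sw_densities densities for small-world (default `seq(0.20, 0.40, 0.02)`).
#' @param n_random,seed passed to [small_world()].
#' @param weighted also compute the weighted-modularity variant on `|FC|` at
#'   full density (single value, `NA` densities ignored).
#' @return list with data frames `q` (density, Q) and `sw` (density, SW) plus
#'   `mean_q`, `mean_sw` (across-density means, NA-removed).
#' @export
lesion_graph_metrics <- function(fc, partition, lesioned_node = NULL,
                                 q_densities = seq(0.04, 0.40, by = 0.02),
                                 sw_densities = seq(0.20, 0.40, by = 0.02),
                                 n_random = 100, seed = 1, weighted = FALSE) {
  fc <- unclass(fc)
  mod <- if (inherits(partition, "module_partition")) partition$assignment
         else as.integer(partition)
  stopifnot(length(mod) == nrow(fc))
  if (!is.null(lesioned_node)) {
    fc <- fc[-lesioned_node, -lesioned_node, drop = FALSE]
    mod <- mod[-lesioned_node]
  }
  q <- vapply(q_densities, function(d)
    modularity_q(threshold_graph(fc, d), mod), numeric(1))
  sw <- vapply(seq_along(sw_densities), function(i) {
    g <- threshold_graph(fc, sw_densities[i])
    ig <- as_igraph(g)
    if (!igraph::is_connected(ig)) return(NA_real_)
    small_world(g, n_random = n_random, seed = derive_seed(seed, i))
  }, numeric(1))
  out <- list(q = data.frame(density = q_densities, Q = q),
              sw = data.frame(density = sw_densities, SW = sw),
              mean_q = mean(q), mean_sw = mean(sw, na.rm = TRUE))
  if (weighted)
    out$weighted_q <- modularity_q(NULL, mod, weights = abs(fc) - diag(nrow(fc)))
  out
}
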