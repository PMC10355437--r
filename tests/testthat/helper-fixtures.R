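# small deterministic fixtures shared across tests

region_table <- function(n, hemi = rep(c("R", "L"), length.out = n),
                         coords = NULL) {
  if (is.null(coords)) coords <- matrix(seq_len(3 * n), n, 3)
  data.frame(label = paste0("r", seq_len(n)), hemisphere = hemi,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             stringsAsFactors = FALSE)
}

toy_connectome <- function(W, L = NULL, coords = NULL) {
  n <- nrow(W)
  if (is.null(L)) {
    L <- matrix(10, n, n)
    diag(L) <- 0
  }
  connectome(W, L, region_table(n, coords = coords))
}

# two coupled nodes, unit weight
pair_connectome <- function(w = 1) {
  toy_connectome(matrix(c(0, w, w, 0), 2))
}

# brute-force modularity: explicit edge iteration over the Newman definition
brute_modularity <- function(A, mod) {
  edges <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  E <- nrow(edges)
  ids <- sort(unique(mod))
  e <- matrix(0, length(ids), length(ids))
  for (k in seq_len(E)) {
    u <- match(mod[edges[k, 1]], ids)
    v <- match(mod[edges[k, 2]], ids)
    if (u == v) e[u, u] <- e[u, u] + 1 / E
    else {
      e[u, v] <- e[u, v] + 0.5 / E
      e[v, u] <- e[v, u] + 0.5 / E
    }
  }
  sum(diag(e)) - sum(rowSums(e)^2)
}

# brute-force clustering coefficient and characteristic path length (BFS)
brute_clustering <- function(A) {
  n <- nrow(A)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) { cc[i] <- 0; next }
    links <- sum(A[nb, nb]) / 2
    cc[i] <- links / (k * (k - 1) / 2)
  }
  mean(cc)
}

brute_path_length <- function(A) {
  n <- nrow(A)
  total <- 0; count <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in which(A[u, ] > 0)) {
        if (is.infinite(dist[v])) {
          dist[v] <- dist[u] + 1
          queue <- c(queue, v)
        }
      }
    }
    total <- total + sum(dist[-s])
    count <- count + (n - 1)
  }
  total / count
}

# brute-force avalanche detection: literal per-sample trace of the rule
brute_avalanches <- function(x, z_threshold = 2.3) {
  z <- t(scale(t(x)))
  n <- nrow(x); T <- ncol(x)
  ev <- matrix(FALSE, n, T)
  for (i in seq_len(n)) {
    above <- FALSE; below <- FALSE
    for (t in seq_len(T)) {
      up <- z[i, t] > z_threshold
      dn <- z[i, t] < -z_threshold
      if ((up && !above) || (dn && !below)) ev[i, t] <- TRUE
      above <- up; below <- dn
    }
  }
  active <- colSums(ev) > 0
  sizes <- c(); durations <- c()
  t <- 1
  while (t <= T) {
    if (active[t]) {
      t2 <- t
      while (t2 < T && active[t2 + 1]) t2 <- t2 + 1
      sizes <- c(sizes, sum(ev[, t:t2]))
      durations <- c(durations, t2 - t + 1)
      t <- t2 + 1
    } else t <- t + 1
  }
  list(sizes = sizes, durations = durations)
}
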