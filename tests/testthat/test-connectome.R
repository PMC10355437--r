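test_that("node strength sums incident weights", {
  c0 <- toy_connectome(matrix(0, 2, 2))
  expect_equal(unname(node_strength(c0)), c(0, 0))

  c1 <- pair_connectome(1)
  expect_equal(unname(node_strength(c1)), c(1, 1))

  # 3-node chain
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 2
  W[2, 3] <- W[3, 2] <- 3
  expect_equal(unname(node_strength(toy_connectome(W))), c(2, 5, 3))
})

test_that("node strength of a symmetric matrix equals row and column sums", {
  set.seed(42)
  W <- matrix(runif(64), 8)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  c8 <- toy_connectome(W)
  expect_equal(node_strength(c8), rowSums(c8$W), ignore_attr = TRUE)
  expect_equal(node_strength(c8), colSums(c8$W), ignore_attr = TRUE)
})

test_that("connectome validation rejects malformed input", {
  reg <- region_table(2)
  expect_error(connectome(matrix(0, 2, 3), matrix(0, 2, 2), reg), "square")
  expect_error(connectome(matrix(0, 3, 3), matrix(0, 3, 3), reg), "one row")
  W <- matrix(c(0, -1, -1, 0), 2)
  expect_error(connectome(W, matrix(10, 2, 2), reg), "negative")
  W <- matrix(c(0, 1, 2, 0), 2)   # asymmetric beyond tolerance
  expect_error(connectome(W, matrix(10, 2, 2), reg), "asymmetry")
  # connected pair with zero tract length
  W <- matrix(c(0, 1, 1, 0), 2)
  expect_error(connectome(W, matrix(0, 2, 2), reg), "tract length")
})

test_that("self-connections are zeroed on construction", {
  W <- matrix(c(5, 1, 1, 5), 2)
  c2 <- toy_connectome(W)
  expect_equal(diag(c2$W), c(0, 0), ignore_attr = TRUE)
})

test_that("homotopy must be mutual and cross-hemispheric", {
  reg <- region_table(2)
  reg$homotope_label <- c("r2", "r1")
  W <- matrix(c(0, 1, 1, 0), 2)
  c2 <- connectome(W, matrix(10, 2, 2), reg)
  expect_equal(c2$homotope, c(2L, 1L))

  reg_bad <- reg
  reg_bad$hemisphere <- c("R", "R")
  expect_error(connectome(W, matrix(10, 2, 2), reg_bad), "hemisphere")

  reg_asym <- region_table(3, hemi = c("R", "L", "L"))
  reg_asym$homotope_label <- c("r2", NA, "r1")   # r1 -> r2 but r2 -> none
  W3 <- matrix(0, 3, 3)
  expect_error(connectome(W3, matrix(0, 3, 3), reg_asym), "not symmetric")
})

test_that("save/load round-trips a synthetic connectome", {
  c16 <- synth_connectome(16, seed = 3)
  dir <- tempfile("conn")
  paths <- save_connectome(c16, dir)
  c2 <- load_connectome(paths["weights"], paths["lengths"], paths["regions"])
  expect_equal(c2$W, c16$W, tolerance = 1e-12)
  expect_equal(c2$L, c16$L, tolerance = 1e-12)
  expect_equal(c2$regions$label, c16$regions$label)
  expect_equal(c2$homotope, c16$homotope)
  # and a second round-trip is the identity
  dir2 <- tempfile("conn")
  paths2 <- save_connectome(c2, dir2)
  c3 <- load_connectome(paths2["weights"], paths2["lengths"], paths2["regions"])
  expect_identical(c3$W, c2$W)
})

test_that("optional weight normalization on load", {
  c16 <- synth_connectome(16, seed = 3)
  c16$W <- c16$W * 7          # arbitrary scale
  dir <- tempfile("conn")
  paths <- save_connectome(c16, dir)
  asis <- load_connectome(paths["weights"], paths["lengths"], paths["regions"])
  expect_equal(mean(node_strength(asis)), 7)
  ms <- load_connectome(paths["weights"], paths["lengths"], paths["regions"],
                        normalize = "mean_strength")
  expect_equal(mean(node_strength(ms)), 1)
  mx <- load_connectome(paths["weights"], paths["lengths"], paths["regions"],
                        normalize = "max")
  expect_equal(max(mx$W), 1)
})

test_that("euclidean distances are metric", {
  reg <- region_table(2, coords = rbind(c(0, 0, 0), c(3, 4, 0)))
  d <- euclidean_distances(reg)
  expect_equal(d[1, 2], 5)
  expect_equal(diag(d), c(0, 0), ignore_attr = TRUE)

  reg_same <- region_table(2, coords = rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(euclidean_distances(reg_same)[1, 2], 0)

  set.seed(7)
  for (rep in 1:5) {
    reg <- region_table(6, coords = matrix(rnorm(18, sd = 20), 6))
    d <- euclidean_distances(reg)
    expect_equal(d, t(d))
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("lesioning zeroes exactly one node's connections", {
  c16 <- synth_connectome(16, seed = 5)
  les <- apply_lesion(c16, 4)
  expect_equal(unname(node_strength(les))[4], 0)
  expect_equal(les$W[-4, -4], c16$W[-4, -4])
  expect_equal(les$L, c16$L)            # lengths untouched
  expect_equal(apply_lesion(les, 4)$W, les$W)  # idempotent
  # lesioning by label works
  lab <- c16$regions$label[4]
  expect_equal(apply_lesion(c16, lab)$W, les$W)
  expect_error(apply_lesion(c16, 99), "out of range")
})
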