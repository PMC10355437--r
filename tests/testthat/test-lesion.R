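test_that("mirroring to the ipsilesional convention is a hemisphere swap", {
  c16 <- synth_connectome(16, seed = 3)
  vals <- seq_len(16) / 16
  right <- which(c16$regions$hemisphere == "R")[1]
  left <- c16$homotope[right]

  # right-side lesion: identity
  expect_identical(mirror_to_ipsilesional(vals, right, c16), vals)

  m <- mirror_to_ipsilesional(vals, left, c16)
  # involution (the swap map does not depend on which left node is lesioned)
  expect_identical(mirror_to_ipsilesional(m, left, c16), vals)
  # values moved to the homotopic partner
  expect_equal(m, vals[c16$homotope])

  # mirror-symmetric data: left-lesion pattern equals the right-lesion one
  sym <- vals[pmin(seq_len(16), c16$homotope)]   # equal within each pair
  expect_identical(mirror_to_ipsilesional(sym, left, c16), sym)

  # a region without a homotope keeps its value
  c2 <- connectome(matrix(c(0, 1, 1, 0), 2), matrix(10, 2, 2) - diag(10, 2),
                   region_table(2, hemi = c("L", "R")))
  expect_identical(mirror_to_ipsilesional(c(5, 7), 1, c2), c(5, 7))
})

test_that("excitability maps report percentage change with the lesion masked", {
  cei0 <- c(2, 2, 4, 1)
  names(cei0) <- paste0("r", 1:4)
  m0 <- delta_cei(cei_T0 = cei0, cei_T2 = cei0)
  expect_equal(m0$delta_cei_pct, rep(0, 4))

  cei2 <- c(1, 2, 4, 1)   # halved at region 1 -> -50%
  m <- delta_cei(cei_T0 = cei0, cei_T2 = cei2, lesioned_node = 3)
  expect_equal(m$delta_cei_pct[1], -50)
  expect_true(is.na(m$delta_cei_pct[3]))
  expect_error(delta_cei(cei_T0 = c(0, 1), cei_T2 = c(1, 1)), "positive")
})

test_that("asymmetry index reflects relative right/left change", {
  cei0 <- c(L = 2, R = 2)
  expect_equal(asymmetry_index(cei0, cei0, "L", "R"), 0)
  # right weight halves, left constant
  expect_equal(asymmetry_index(cei0, c(L = 2, R = 1), "L", "R"), -0.5)
  # both sides scaled identically: ratio invariant
  expect_equal(asymmetry_index(cei0, cei0 * 3.3, "L", "R"), 0)
  expect_error(asymmetry_index(c(L = 0, R = 1), cei0, "L", "R"), "positive")
})

test_that("exponential-distance fits recover generative parameters", {
  set.seed(40)
  d <- runif(30, 5, 150)
  y <- -8 * exp(-d / 35) + 0.5
  fit <- exp_distance_fit(y, d)
  expect_true(fit$converged)
  expect_equal(fit$amplitude, -8, tolerance = 0.1 * 8)
  expect_equal(fit$length_constant, 35, tolerance = 0.1 * 35)
  expect_gt(fit$r_squared, 0.999)

  # spatial shuffling destroys the relationship
  r2s <- replicate(20, exp_distance_fit(sample(y), d)$r_squared)
  expect_lt(stats::median(r2s, na.rm = TRUE), 0.2)
  expect_error(exp_distance_fit(y[1:3], d[1:3]), "4 non-missing")
})

test_that("sweep-level correlations recover a planted structural dependence", {
  c16 <- synth_connectome(16, seed = 6)
  s <- node_strength(c16)
  nodes <- order(s, decreasing = TRUE)[c(1, 4, 8, 12, 16)]
  fake_exp <- function(node) {
    cei0 <- rep(3, 16)
    # excitability rises (cei falls) in proportion to connectivity to lesion
    cei2 <- cei0 * (1 - 2 * c16$W[, node] / max(c16$W))
    structure(list(node = node, cei_T0 = cei0, cei_T2 = pmax(cei2, 0.1),
                   connectome_intact = c16),
              class = "lesion_experiment")
  }
  sweep <- lapply(nodes, fake_exp)
  class(sweep) <- "lesion_sweep"
  lc <- lesion_correlations(sweep, c16)
  expect_lt(lc$pooled$r, -0.5)
  expect_lt(lc$pooled$p, 0.01)
  expect_lt(lc$by_lesion$r, 0)

  avg <- sweep_average_map(sweep, c16)
  expect_equal(nrow(avg), 16)
  expect_true(all(avg$mean <= 0))
  expect_error(lesion_correlations(sweep[1:2], c16), "at least 3")
})

test_that("the three-phase protocol produces a coherent experiment object", {
  c8 <- synth_connectome(8, seed = 8)
  cfg <- wc_config(seed = 9)
  base <- stabilize(cfg, c8, max_duration_s = 1500)
  node <- unname(which.max(node_strength(c8)))
  exp <- suppressWarnings(
    run_protocol(cfg, c8, node, base, record_s = 60, max_stab_s = 600))

  expect_s3_class(exp, "lesion_experiment")
  expect_equal(exp$node, node)
  # lesioned connectome really is lesioned; the original is untouched
  expect_equal(unname(node_strength(exp$connectome))[node], 0)
  expect_gt(node_strength(exp$connectome_intact)[node], 0)
  # T0 weights are the baseline weights; T2 weights are re-converged
  expect_identical(exp$cei_T0, base$cei)
  expect_true(all(exp$cei_T2 >= 0))
  # the lesioned node loses excitation, so its chronic inhibition must drop
  expect_lt(exp$cei_T2[node], exp$cei_T0[node])
  for (tp in c("T0", "T1", "T2")) {
    expect_s3_class(exp$records[[tp]]$bold, "bold_record")
    expect_true(exp$records[[tp]]$bold$filtered)
    expect_equal(nrow(exp$records[[tp]]$rates), 8)
  }
  # intact nodes return to the setpoint at T2
  intact <- setdiff(1:8, node)
  expect_lt(max(abs(exp$records$T2$mean_rE[intact] - cfg$rho)) / cfg$rho, 0.15)

  # an isolated node's lesion leaves the network statistically unchanged:
  # FC distance T1 vs T0 below the two-seed noise floor for a null lesion
  s <- summary(exp, n_random = 5)
  expect_s3_class(s, "data.frame")
  expect_true(is.finite(s$fc_dist_T1) && is.finite(s$fc_dist_T2))
  expect_true(is.finite(s$q_T0) && is.finite(s$k_T0))
})
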