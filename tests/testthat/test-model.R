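test_that("activation function matches its closed form", {
  expect_equal(wc_sigmoid(1, mu = 1, sigma = 0.25), 0.5)
  expect_equal(wc_sigmoid(1.25, mu = 1, sigma = 0.25), 1 / (1 + exp(-1)))
  expect_equal(wc_sigmoid(1e6), 1)
  expect_equal(wc_sigmoid(-1e6), 0)
  x <- seq(-3, 3, by = 0.01)
  expect_true(all(diff(wc_sigmoid(x)) > 0))
  expect_true(all(wc_sigmoid(x) > 0 & wc_sigmoid(x) < 1))
  expect_error(wc_sigmoid(0, sigma = 0), "sigma")
})

test_that("delay steps scale tract lengths to the requested mean", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  W[1, 3] <- W[3, 1] <- 1
  L <- matrix(0, 3, 3)
  L[1, 2] <- L[2, 1] <- 10
  L[2, 3] <- L[3, 2] <- 20
  L[1, 3] <- L[3, 1] <- 30
  c3 <- connectome(W, L, region_table(3))

  expect_equal(build_delay_steps(c3, 0), matrix(0L, 3, 3))

  st <- build_delay_steps(c3, 4, dt = 0.2)
  # mean length 20 mm at 4 ms mean delay: raw delays 2, 4, 6 ms = 10, 20, 30 steps
  expect_equal(st[1, 2], 10L)
  expect_equal(st[2, 3], 20L)
  expect_equal(st[1, 3], 30L)
  expect_equal(mean(st[c3$W > 0]) * 0.2, 4)

  # uniform lengths: every connected delay equals the mean
  cu <- toy_connectome(W, L = matrix(15, 3, 3) - diag(15, 3))
  stu <- build_delay_steps(cu, 6, dt = 0.2)
  expect_true(all(stu[cu$W > 0] == 30L))

  # connected pairs never get delay zero when a mean delay is requested
  Lshort <- L; Lshort[1, 2] <- Lshort[2, 1] <- 0.01
  cs <- connectome(W, Lshort, region_table(3))
  sts <- build_delay_steps(cs, 4, dt = 0.2)
  expect_gte(min(sts[cs$W > 0]), 1L)
})

test_that("seeded simulations are bit-identical and symmetric nodes stay identical", {
  c2 <- pair_connectome(0.5)
  cfg <- wc_config(C = 1, mean_delay = 2, seed = 5)
  a <- simulate_wc(cfg, c2, duration_s = 2, discard_s = 0.5)
  b <- simulate_wc(cfg, c2, duration_s = 2, discard_s = 0.5)
  expect_identical(a$rE, b$rE)
  expect_identical(a$state$cei, b$state$cei)

  # deterministic symmetric pair: identical trajectories
  cfg0 <- wc_config(C = 1, mean_delay = 2, noise_var = 0, P = 0.4,
                    init_cei = 2.5)
  s <- simulate_wc(cfg0, c2, duration_s = 3, discard_s = 0)
  expect_equal(s$rE[1, ], s$rE[2, ], tolerance = 1e-14)
})

test_that("rates stay inside the unit interval", {
  c16 <- synth_connectome(16, seed = 1)
  for (C in c(0.5, 4)) {
    sim <- simulate_wc(wc_config(C = C, seed = 2), c16, duration_s = 5,
                       discard_s = 0, record_rI = TRUE)
    expect_true(all(sim$rE > 0 & sim$rE < 1))
    expect_true(all(sim$rI > 0 & sim$rI < 1))
  }
})

test_that("noise-free uncoupled nodes settle on the solver's fixed point", {
  skip_if_not_installed("pracma")
  cfg <- wc_config(C = 0, noise_var = 0, P = 0.31, init_cei = 1)
  sim <- single_node_sim(P = 0.31, cei = 1, duration_s = 3, discard_s = 5)
  end <- sim$state$rE
  # independent oracle: nonlinear root of the 2-D steady-state equations
  f <- function(x) c(
    -x[1] + wc_sigmoid(cfg$c_EE * x[1] - 1 * x[2] + cfg$P, cfg$mu, cfg$sigma),
    -x[2] + wc_sigmoid(cfg$c_IE * x[1], cfg$mu, cfg$sigma))
  root <- pracma::fsolve(f, c(end, sim$state$rI))$x
  expect_equal(c(end, sim$state$rI), root, tolerance = 1e-8)
  # and the damped-iteration helper lands on the same branch
  fp <- isolated_fixed_point(cfg, cei = 1, start = root[1:2])
  expect_equal(fp, root, tolerance = 1e-6)
})

test_that("the isolated mass crosses a Hopf bifurcation as excitability rises", {
  # below onset: converges to a fixed point; above: sustained limit cycle
  low <- single_node_sim(P = 0.25, cei = 2.5, duration_s = 4, discard_s = 4)
  expect_lt(diff(range(low$rE[1, 2000:4000])), 1e-4)
  high <- single_node_sim(P = 0.5, cei = 2.5, duration_s = 4, discard_s = 4)
  expect_gt(diff(range(high$rE[1, 2000:4000])), 0.1)
  expect_lt(mean(low$rE), mean(high$rE))
})

test_that("the oscillatory regime peaks in the gamma band", {
  sim <- single_node_sim(P = 0.4, cei = 2.5, duration_s = 6, discard_s = 2)
  f <- spectral_peak(sim$rE[1, ], fs = 1000)
  expect_gt(f, 35)
  expect_lt(f, 45)
})

test_that("halving the integration step leaves trajectories nearly unchanged", {
  # convergent (sub-bifurcation) regime: on a limit cycle the Euler
  # frequency shift accumulates phase drift, so trajectory-level RMS
  # comparisons are only meaningful where the flow contracts
  c2 <- pair_connectome(0.5)
  run <- function(dt) {
    cfg <- wc_config(C = 0.5, mean_delay = 2, noise_var = 0, P = 0.2,
                     init_cei = 3, dt = dt, record_dt = 1)
    simulate_wc(cfg, c2, duration_s = 10, discard_s = 0)$rE
  }
  a <- run(0.2)
  b <- run(0.1)
  rms <- sqrt(mean((a - b)^2)) / sqrt(mean(a^2))
  expect_lt(rms, 0.01)
})

test_that("simulation state continues seamlessly across chunks", {
  c2 <- pair_connectome(0.8)
  cfg <- wc_config(C = 1, mean_delay = 3, noise_var = 0, P = 0.35,
                   init_cei = 2.5)
  whole <- simulate_wc(cfg, c2, duration_s = 4, discard_s = 0)
  first <- simulate_wc(cfg, c2, duration_s = 2, discard_s = 0)
  second <- simulate_wc(cfg, c2, duration_s = 2, discard_s = 0,
                        init = first$state, seed = NULL)
  expect_equal(cbind(first$rE, second$rE), whole$rE, tolerance = 1e-12)
})
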