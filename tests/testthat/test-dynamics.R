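test_that("sigmoid has the midpoint, asymptotes and closed-form values", {
  expect_equal(sigmoid(0.5, K = 10, phi = 0.5), 0.5)
  expect_equal(sigmoid(1e6, K = 10, phi = 0.5), 1)
  expect_equal(sigmoid(-1e6, K = 10, phi = 0.5), 0)
  ## 1 / (1 + exp(-ln 3)) = 3/4
  expect_equal(sigmoid(log(3), K = 1, phi = 0), 0.75)
  ## strictly increasing
  x <- seq(-3, 3, length.out = 50)
  expect_true(all(diff(sigmoid(x, K = 7, phi = 0.3)) > 0))
})

test_that("a quiescent unit stays quiescent and activity is bounded", {
  p <- list(K = 10, phi = 0.8, K_i = 10, phi_i = 0.5, wie = 0.15, wei = 0.6,
            delta = 0.5, rho = 1)
  E <- 0; I <- 0
  for (i in 1:200) {
    up <- wc_step(E, I, -p$wie * I, p$wei * E, p, 0.1)
    E <- up$E; I <- up$I
  }
  expect_lt(E, 0.01)

  ## boundedness under arbitrary finite inputs (random weights and drives)
  set.seed(42)
  for (rep in 1:20) {
    p2 <- list(K = runif(1, 1, 40), phi = runif(1, -1, 1), K_i = 10,
               phi_i = 0.5, wie = runif(1, 0, 2), wei = runif(1, 0, 2),
               delta = runif(1, 0.05, 1), rho = runif(1, 0.1, 1))
    E <- runif(5); I <- runif(5)
    for (i in 1:100) {
      drive <- rnorm(5, 0, 10)
      up <- wc_step(E, I, drive - p2$wie * I, p2$wei * E + rnorm(5, 0, 3),
                    p2, 0.1)
      E <- up$E; I <- up$I
      expect_true(all(E >= 0 & E <= 1 & I >= 0 & I <= 1))
    }
  }
})

test_that("a constant-input unit converges to the scalar fixed point", {
  ## oracle: solve sigmoid(c)(1-E) = delta E for E
  p <- list(K = 8, phi = 0.55, K_i = 10, phi_i = 0.5, wie = 0, wei = 0,
            delta = 0.5, rho = 1)
  for (c_in in c(0.3, 0.6, 0.9, 1.5)) {
    s <- sigmoid(c_in, p$K, p$phi)
    oracle <- uniroot(function(E) s * (1 - E) - p$delta * E, c(0, 1))$root
    E <- 0; I <- 0
    for (i in 1:round(10 / p$delta / 0.1)) {
      up <- wc_step(E, I, c_in, 0, p, 0.1)
      E <- up$E; I <- up$I
    }
    expect_lt(abs(E - oracle), 1e-3)
  }
})

test_that("coarse and fine Euler steps agree on a 1 s trajectory", {
  p <- list(K = 4, phi = 0.8, K_i = 10, phi_i = 0.5, wie = 0.15, wei = 0.6,
            delta = 0.5, rho = 1)
  drive <- function(t_ms) 0.3 + 0.45 * (1 + sin(t_ms / 150))
  run_at <- function(dt_ms) {
    E <- 0; I <- 0
    n <- round(1000 / dt_ms)
    out <- numeric(0)
    for (i in 1:n) {
      t <- i * dt_ms
      up <- wc_step(E, I, drive(t) - p$wie * I, p$wei * E, p, dt_ms / 50)
      E <- up$E; I <- up$I
      if (t %% 5 == 0) out <- c(out, E)
    }
    out
  }
  fine <- run_at(0.05)
  ## first-order convergence: halving the step roughly halves the divergence,
  ## and the half-step trajectory is within 1e-2 of the fine-step reference
  err5 <- max(abs(run_at(5) - fine))
  err2.5 <- max(abs(run_at(2.5) - fine))
  expect_lt(err2.5, 1e-2)
  expect_lt(err5, 2.5e-2)
  expect_lt(err5 / err2.5, 3)
})

test_that("run length, determinism and the role of noise are as specified", {
  cfg <- quiet_cfg()
  net <- build_network(cfg)
  run <- simulate_network(net, 1000, seed = 1)
  expect_equal(run$n_steps, 200)            # 1000 ms at dt = 5 ms
  expect_error(simulate_network(net, 1003), "multiple")

  ## after the settling transient a noise-free run is near-still; with input
  ## noise the same statistic fluctuates at least an order of magnitude more
  tail_idx <- 150:200
  cfg2 <- default_config()
  net2 <- build_network(cfg2)
  run2 <- simulate_network(net2, 1000, seed = 1)
  expect_gt(var(diff(run2$summary[tail_idx, "ST"])),
            10 * var(diff(run$summary[tail_idx, "ST"])))

  ## bit-identical repetition under the same seed and config
  run3 <- simulate_network(net2, 1000, seed = 1)
  expect_identical(run2$summary, run3$summary)
  expect_identical(run2$syn, run3$syn)
})

test_that("full recording exposes per-unit series and synaptic input series", {
  cfg <- quiet_cfg()
  net <- build_network(cfg)
  run <- simulate_network(net, 500, aud = test_contour(), endo_a = 0.3,
                          seed = 1, record = "full")
  expect_equal(dim(run$E$ST), c(100, 81))
  expect_equal(dim(run$E$aINS_a), c(100, 1))
  expect_true(all(run$syn >= 0))
  df <- as_activity_df(run, modules = c("A1_up", "ST"))
  expect_named(df, c("time_ms", "module", "submodule", "unit_row",
                     "unit_col", "E", "I"))
  expect_equal(nrow(df), 100 * 81 * 2)
})
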