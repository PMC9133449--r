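test_that("synaptic integration is exact on constructed inputs", {
  mods <- c("A1_up", "A1_down", "ST")
  rmap <- list(A1 = c("A1_up", "A1_down"), ST = "ST")
  zero <- matrix(0, 40, 3, dimnames = list(NULL, mods))
  u0 <- integrate_synaptic(zero, dt_ms = 5, region_map = rmap, bin_ms = 50)
  expect_true(all(u0 == 0))
  expect_equal(dim(u0), c(4, 2))           # 200 ms / 50 ms bins

  const <- matrix(rep(c(1, 2, 3), each = 40), 40, 3,
                  dimnames = list(NULL, mods))
  u <- integrate_synaptic(const, dt_ms = 5, region_map = rmap, bin_ms = 50)
  expect_true(all(u[, "A1"] == (1 + 2) * 10))   # 10 steps per bin
  expect_true(all(u[, "ST"] == 3 * 10))
  ## homogeneity
  u2 <- integrate_synaptic(2 * const, dt_ms = 5, region_map = rmap, bin_ms = 50)
  expect_equal(unclass(u2), unclass(2 * u), ignore_attr = TRUE)

  expect_error(integrate_synaptic(const, 5, region_map = list(A1 = "A1_up")),
               "without a region")
  expect_error(integrate_synaptic(const, 5,
                                  region_map = list(A = mods, B = "ST")),
               "more than one region")
})

test_that("the balloon model rests at zero and rejects negative input", {
  u <- rep(0, 100)
  b <- balloon_bold(u, balloon_params())
  expect_equal(length(b), 5)               # 100 bins x 50 ms = 5 s at TR 1 s
  expect_true(all(abs(b) < 1e-12))
  expect_error(balloon_bold(c(0.1, -0.2)), "nonnegative")
})

test_that("a brief input pulse gives a 3-8 s peak and an undershoot", {
  p <- balloon_params()
  u <- rep(0, 600)                         # 30 s at 50 ms bins
  u[21:30] <- 1                            # 500 ms pulse at t = 1 s
  b <- balloon_bold(u, p)
  peak_t <- which.max(b)                   # TR index = seconds
  expect_gte(peak_t - 1, 3)
  expect_lte(peak_t - 1, 8)
  expect_lt(min(b[peak_t:length(b)]), 0)   # post-peak undershoot
  expect_lt(abs(b[length(b)]), 0.05)       # back near baseline

  ## independent stiff-solver oracle on the same input
  uf <- stats::approxfun(seq(0.025, by = 0.05, length.out = length(u)), u,
                         method = "constant", rule = 2)
  deriv <- function(t, y, parms) {
    s <- y[1]; f <- y[2]; v <- y[3]; q <- y[4]
    Ef <- 1 - (1 - p$E0)^(1 / f)
    list(c(uf(t) - p$kappa * s - p$gamma * (f - 1), s,
           (f - v^(1 / p$alpha)) / p$tau,
           (f * Ef / p$E0 - v^(1 / p$alpha) * q / v) / p$tau))
  }
  sol <- deSolve::lsoda(c(0, 1, 1, 1), seq(0, 30, by = 0.01), deriv, NULL)
  bold_o <- 100 * p$V0 * (p$k1 * (1 - sol[, 5]) + p$k2 * (1 - sol[, 5] / sol[, 4]) +
                            p$k3 * (1 - sol[, 4]))
  oracle_tr <- vapply(1:30, function(t) mean(bold_o[sol[, 1] > t - 1 & sol[, 1] <= t]),
                      numeric(1))
  ## the oracle confirms the peak latency and the undershoot, and the Euler
  ## waveform stays within 2% of it on this sharp transient
  expect_equal(which.max(b), which.max(oracle_tr))
  expect_lt(min(oracle_tr[which.max(oracle_tr):30]), 0)
  expect_lt(max(abs(b - oracle_tr)), 0.02 * max(abs(oracle_tr)))
})

test_that("a sustained step converges to the algebraic steady state", {
  p <- balloon_params()
  u0 <- 0.4
  u <- rep(u0, 2400)                       # 120 s step
  b <- balloon_bold(u, p)
  ## steady state: s = 0, f* = 1 + u/gamma, v* = f*^alpha,
  ## q* = f* E(f*)/E0 * v*/v*^(1/alpha)
  fs <- 1 + u0 / p$gamma
  vs <- fs^p$alpha
  qs <- fs * (1 - (1 - p$E0)^(1 / fs)) / p$E0 * vs / vs^(1 / p$alpha)
  bold_s <- 100 * p$V0 * (p$k1 * (1 - qs) + p$k2 * (1 - qs / vs) + p$k3 * (1 - vs))
  expect_equal(b[length(b)], bold_s, tolerance = 1e-3)
})

test_that("Euler integration tracks the stiff-solver oracle within 1%", {
  p <- balloon_params()
  set.seed(8)
  u <- pmax(stats::filter(runif(400, 0, 0.6), rep(1 / 8, 8), sides = 1), 0)
  u[is.na(u)] <- 0
  b <- balloon_bold(u, p)
  uf <- stats::approxfun(seq(0.025, by = 0.05, length.out = length(u)), u,
                         method = "constant", rule = 2)
  deriv <- function(t, y, parms) {
    s <- y[1]; f <- y[2]; v <- y[3]; q <- y[4]
    Ef <- 1 - (1 - p$E0)^(1 / f)
    list(c(uf(t) - p$kappa * s - p$gamma * (f - 1), s,
           (f - v^(1 / p$alpha)) / p$tau,
           (f * Ef / p$E0 - v^(1 / p$alpha) * q / v) / p$tau))
  }
  sol <- deSolve::lsoda(c(0, 1, 1, 1), seq(0, 20, by = 0.005), deriv, NULL)
  bold_o <- 100 * p$V0 * (p$k1 * (1 - sol[, 5]) + p$k2 * (1 - sol[, 5] / sol[, 4]) +
                            p$k3 * (1 - sol[, 4]))
  oracle_tr <- vapply(seq_len(length(b)), function(t)
    mean(bold_o[sol[, 1] > t - 1 & sol[, 1] <= t]), numeric(1))
  expect_lt(max(abs(b - oracle_tr)), 0.01 * max(abs(oracle_tr)))
})

test_that("design assembly produces labeled block and event runs", {
  cfg <- default_config()
  net <- build_network(cfg)
  expect_error(assemble_design(net, n_cycles = 0), "at least one")
  bd <- assemble_design(net, task = "dms_aud", design = "block",
                        n_cycles = 1, seed = 4)
  expect_true(all(c("task", "control") %in% bd$labels))
  expect_equal(ncol(bd$bold), length(default_region_map()))
  ## equal task and control trial counts by construction
  expect_equal(sum(rle(bd$labels)$values == "task"),
               sum(rle(bd$labels)$values == "control"))

  ev <- assemble_design(net, task = "dms_aud", design = "event",
                        n_cycles = 2, seed = 4)
  onsets <- which(ev$labels == "task" & c("rest", utils::head(ev$labels, -1)) != "task")
  expect_gte(diff(onsets), 25)             # 25 s between trial onsets
})
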