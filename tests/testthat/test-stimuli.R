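test_that("tonal contour invariants are enforced", {
  expect_error(make_tonal_contour(data.frame(
    direction = "up", start_channel = 0, end_channel = 30,
    duration_ms = 250)), "1, 81")
  expect_error(make_tonal_contour(data.frame(
    direction = "down", start_channel = 10, end_channel = 30,
    duration_ms = 250)), "direction")
  expect_error(make_tonal_contour(data.frame(
    direction = c("up", "up"), start_channel = c(10, 50),
    end_channel = c(30, 60), duration_ms = c(100, 100))), "continuous")

  set.seed(1)
  for (i in 1:25) {
    ct <- random_contour(seed = 100 + i)
    expect_gte(ct$duration_ms, 200)
    expect_lte(ct$duration_ms, 300)
    expect_true(all(ct$segments$start_channel %in% 1:81))
    expect_true(all(ct$segments$end_channel %in% 1:81))
  }
})

test_that("a single up-sweep renders a strictly increasing peak channel", {
  ct <- make_tonal_contour(data.frame(
    direction = "up", start_channel = 10, end_channel = 30,
    duration_ms = 250))
  r <- render_stimulus(ct, dt_ms = 5)
  expect_equal(r$steps, 50)               # 250 ms at dt = 5 ms
  peaks <- apply(r$up, 1, which.max)
  expect_true(all(diff(peaks) >= 0))
  expect_gt(peaks[50], peaks[1])
  expect_true(all(r$down == 0))
})

test_that("a direction reversal drives the contour-selective units", {
  cfg <- quiet_cfg()
  net <- build_network(cfg)
  run <- simulate_network(net, 600, aud = test_contour(), endo_a = 0.05,
                          seed = 1, record = "full")
  expect_gt(max(run$E$A2_contour), 0.2)
  ## a pure one-direction sweep barely drives them
  mono <- make_tonal_contour(data.frame(
    direction = "up", start_channel = 20, end_channel = 45,
    duration_ms = 250))
  run2 <- simulate_network(net, 600, aud = mono, endo_a = 0.05,
                           seed = 1, record = "full")
  expect_lt(max(run2$E$A2_contour), max(run$E$A2_contour) / 2)
})

test_that("probes obey the match/nonmatch contract and are reproducible", {
  cfg <- default_config()
  tgt <- random_contour(seed = 7, cfg = cfg)
  expect_identical(make_probe(tgt, TRUE), tgt)
  p1 <- make_probe(tgt, FALSE, seed = 11, cfg = cfg)
  p2 <- make_probe(tgt, FALSE, seed = 11, cfg = cfg)
  expect_identical(p1, p2)
  ov <- sum(stimulus_pattern(p1) & stimulus_pattern(tgt)) /
    sum(stimulus_pattern(p1) | stimulus_pattern(tgt))
  expect_lte(ov, cfg$stimuli$overlap_max)
  expect_false(identical(stimulus_pattern(p1), stimulus_pattern(tgt)))
})

test_that("saliency validates its range and scales the sensory response", {
  cfg <- quiet_cfg()
  expect_error(apply_saliency(test_contour(), 1.2), "0, 1")
  expect_error(random_contour(seed = 1, saliency = -0.1), "0, 1")
  ## s = 0 silences the drive
  r0 <- render_stimulus(test_contour(0), dt_ms = 5)
  expect_true(all(r0$up == 0) && all(r0$down == 0))
  ## monotone: weaker saliency, weaker A1 response
  net <- build_network(cfg)
  peak_a1 <- function(s) {
    run <- simulate_network(net, 400, aud = test_contour(s), seed = 1)
    max(run$summary[, "A1"])
  }
  expect_lt(peak_a1(0.5), peak_a1(0.9))
})

test_that("control stimuli match the object's input energy within 10%", {
  cfg <- default_config()
  set.seed(3)
  for (i in 1:5) {
    obj <- random_contour(seed = 200 + i, cfg = cfg)
    ctl <- make_control(obj, seed = 300 + i, cfg = cfg)
    e_obj <- sum(render_stimulus(obj, 5)$up + render_stimulus(obj, 5)$down)
    r <- render_stimulus(ctl, 5)
    e_ctl <- sum(r$up + r$down)
    expect_lt(abs(e_ctl - e_obj) / e_obj, 0.10)
    sh <- random_shape(seed = 400 + i, cfg = cfg)
    dg <- make_control(sh, seed = 500 + i, cfg = cfg)
    expect_equal(sum(dg$frame > 0), sum(sh$frame > 0))
  }
})

test_that("distinct objects produce distinct ST representations", {
  cfg <- quiet_cfg()
  net <- build_network(cfg)
  st_pattern <- function(seed) {
    ct <- random_contour(seed = seed, cfg = cfg)
    run <- simulate_network(net, 500, aud = ct, endo_a = 0.05, seed = 1,
                            record = "full")
    run$E$ST[100, ]
  }
  a <- st_pattern(21); b <- st_pattern(57)
  expect_lt(cor(a, b), 0.8)
})
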