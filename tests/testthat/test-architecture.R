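test_that("the module roster matches the published shapes", {
  r <- module_roster()
  a1a2 <- r$name %in% c("A1_up", "A1_down", "A2_up", "A2_down", "A2_contour")
  expect_true(all(r$rows[a1a2] == 1 & r$cols[a1a2] == 81))
  nine <- r$name %in% c("ST", "MTL", "FS_a", "R_a", "V1", "V4", "IT", "EC",
                        "FS_v", "R_v", paste0("D1_a", 1:3), paste0("D2_a", 1:3),
                        paste0("D1_v", 1:3), paste0("D2_v", 1:3))
  expect_true(all(r$rows[nine] == 9 & r$cols[nine] == 9))
  expect_equal(sum(r$name %in% c("aINS_a", "aINS_v")), 2)
  expect_equal(nrow(r), 29)
  expect_true(all(nchar(r$talairach) > 0))
})

test_that("network construction validates its edge list", {
  expect_error(build_network(edges = default_edges()[0, ]), "edge list")
  bad <- default_edges()
  bad$source[3] <- "NOPE"
  expect_error(build_network(edges = bad), "unknown module")
  net <- build_network(quiet_cfg())
  expect_error(remove_edges(net, "D2->XYZ"), "no such edge")
  remove_edges(net, c("D2_v->IT", "D2_v->V4", "D2_a->ST", "D2_a->A2"))
  expect_true(all(net$W[c("D2_v->IT", "D2_v->V4", "D2_a->ST", "D2_a->A2")] == 0))
  ## the ablated network still runs
  run <- simulate_network(net, 300, seed = 1)
  expect_equal(run$n_steps, 60)
})

test_that("gating stores sequential items in distinct slots, once each", {
  cfg <- default_config()
  net <- build_network(cfg)
  items <- avwm:::draw_trial_stimuli("sternberg", cfg, 4242)
  tr <- run_sternberg_trial(net, items, items[[1]], TRUE, seed = 77)
  run <- tr$run
  ps <- run$epochs$start_step[run$epochs$label == "probe"]
  slots <- run$summary[ps - 1, c("D2a1", "D2a2", "D2a3")]
  thr <- cfg$readout$retention_threshold
  expect_equal(sum(net$gate$aud$used), 3)
  expect_gte(sum(slots > thr), 2)   # at least two clean stores under noise

  ## a single presented stimulus consumes exactly one group
  net2 <- build_network(cfg)
  ep <- function(lab, dur, aud = NULL)
    list(label = lab, dur_ms = dur, endo_a = 0.3, endo_v = 0.05, aud = aud)
  run_schedule(net2, list(ep("lead", 250), ep("stim", 250, aud = items[[1]]),
                          ep("delay", 750)), seed = 3)
  expect_equal(sum(net2$gate$aud$used), 1)
})

test_that("a fourth stimulus finds no free slot (three-item capacity)", {
  cfg <- default_config()
  net <- build_network(cfg)
  ep <- function(lab, dur, aud = NULL)
    list(label = lab, dur_ms = dur, endo_a = 0.3, endo_v = 0.05, aud = aud)
  set.seed(9)
  items <- lapply(1:4, function(i) random_contour(seed = 600 + i, cfg = cfg))
  sched <- list(ep("lead", 250))
  for (s in items) sched <- c(sched, list(ep("stim", 250, aud = s), ep("isi", 400)))
  run <- run_schedule(net, sched, seed = 12, record = "full")
  expect_error(run_sternberg_trial(net, items, items[[1]], TRUE), "capacity")
  ## all three groups consumed by the first three items
  expect_equal(sum(net$gate$aud$used), 3)
  ## channels unique to the fourth item are not represented in any slot
  p4 <- stimulus_pattern(items[[4]])
  earlier <- Reduce(`|`, lapply(items[1:3], stimulus_pattern))
  only4 <- p4 & !earlier
  d2sum <- run$E$D2_a1[run$n_steps, ] + run$E$D2_a2[run$n_steps, ] +
    run$E$D2_a3[run$n_steps, ]
  if (any(only4)) expect_lt(max(d2sum[only4]), 0.3)
})

test_that("slot protection: a later stimulus never erases stored items", {
  cfg <- default_config()
  net <- build_network(cfg)
  items <- avwm:::draw_trial_stimuli("sternberg", cfg, 777)
  ep <- function(lab, dur, aud = NULL)
    list(label = lab, dur_ms = dur, endo_a = 0.3, endo_v = 0.05, aud = aud)
  sched <- list(ep("lead", 250),
                ep("stim", 250, aud = items[[1]]), ep("isi", 400),
                ep("stim", 250, aud = items[[2]]), ep("isi", 400),
                ep("mark", 5),
                ep("stim", 250, aud = items[[3]]), ep("post", 400))
  run <- run_schedule(net, sched, seed = 31)
  mark <- run$epochs$start_step[run$epochs$label == "mark"]
  stored_before <- run$summary[mark, c("D2a1", "D2a2")] >
    cfg$readout$retention_threshold
  final <- run$summary[run$n_steps, c("D2a1", "D2a2")]
  expect_true(all(final[stored_before] > cfg$readout$retention_threshold))
})

test_that("the salience pair is symmetric, quiet at rest and competitive", {
  cfg <- quiet_cfg()
  cfg$exo$gain_a <- cfg$exo$gain_v   # symmetric readout for the symmetry check
  eq <- compute_exogenous(0.8, 0.8, cfg = cfg, duration_ms = 800)
  expect_equal(eq$exo_v, eq$exo_a, tolerance = 1e-10)
  rest <- compute_exogenous(0, 0, cfg = cfg, duration_ms = 800)
  expect_lt(rest$exo_v, 0.02)
  expect_lt(rest$exo_a, 0.02)
  ## rising visual drive with fixed auditory input shifts the balance
  lo <- compute_exogenous(0.5, 0.8, cfg = cfg, duration_ms = 800)
  hi <- compute_exogenous(1.1, 0.8, cfg = cfg, duration_ms = 800)
  expect_gt(hi$exo_v, lo$exo_v)
  expect_lt(hi$exo_a, lo$exo_a)
  ## bounded total
  expect_lt(hi$exo_v + hi$exo_a, 2 * cfg$exo$cap + 1e-9)
})

test_that("attention combination clips at the configured ceiling", {
  cfg <- default_config()
  expect_equal(combine_attention(0.3, 0, cfg), 0.3)
  expect_equal(combine_attention(0.3, 0.3, cfg), cfg$att$max)
  expect_equal(combine_attention(0, 0, cfg), 0)
})

test_that("delay activity is retained at high attention and lost at low", {
  ## a moderately salient stimulus: salience-driven (exogenous) capture alone
  ## must not ignite the slot, so retention is governed by the task set
  cfg <- default_config()
  net <- build_network(cfg)
  stim <- test_contour(saliency = 0.75)
  thr <- cfg$readout$retention_threshold
  hi <- run_schedule(net, mini_dms_schedule(cfg, stim, stim, endo = 0.3), seed = 2)
  delay_end <- max(avwm:::epoch_steps(hi, "delay"))
  expect_gt(hi$summary[delay_end, "D2a1"], thr)
  lo <- run_schedule(net, mini_dms_schedule(cfg, stim, stim, endo = 0.05), seed = 2)
  expect_lt(lo$summary[max(avwm:::epoch_steps(lo, "delay")), "D2a1"], thr)
})
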