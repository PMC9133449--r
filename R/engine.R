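## Time-stepping engine: Wilson-Cowan microcircuit update, the synchronous
## whole-network step, and schedule-driven simulation runs.

#' Sigmoid activation of a Wilson-Cowan element
#'
#' \eqn{1 / (1 + \exp(-K (x - \phi)))}; strictly increasing in `x`,
#' overflow-safe for large `|x|`.
#'
#' @param x summed input
#' @param K gain (> 0)
#' @param phi threshold
#' @export
sigmoid <- function(x, K = 10, phi = 0.5) {
  stopifnot(K > 0)
  stats::plogis(K * (x - phi))
}

#' One forward-Euler step of a Wilson-Cowan microcircuit array
#'
#' The excitatory and inhibitory populations follow
#' \eqn{E \leftarrow E + \rho\,\Delta t\,[S(in_E)(1-E) - \delta E]} (and
#' likewise for I), clamped to \[0, 1\]. `in_E` already contains afferent
#' excitation, the local \eqn{-w_{IE} I} term, any attention bias and noise;
#' `in_I` contains the local \eqn{w_{EI} E} term and inter-module inhibitory
#' afferents.
#'
#' @param E,I current activity vectors
#' @param in_E,in_I summed inputs
#' @param p parameter list with K, phi, K_i, phi_i, delta, rho
#' @param dt integration step in unit-time (dt_ms / tau_ms)
#' @return list with updated `E` and `I`
#' @export
wc_step <- function(E, I, in_E, in_I, p, dt) {
  sE <- stats::plogis(p$K * (in_E - p$phi))
  sI <- stats::plogis(p$K_i * (in_I - p$phi_i))
  rdt <- (p$rho %||% 1) * dt
  list(E = clamp01(E + rdt * (sE * (1 - E) - p$delta * E)),
       I = clamp01(I + rdt * (sI * (1 - I) - p$delta * I)))
}

band_means <- function(x, ng) {
  n <- length(x) %/% ng
  out <- numeric(ng)
  for (k in seq_len(ng)) out[k] <- sum(x[((k - 1L) * n + 1L):(k * n)]) / n
  out
}

## Names of the per-step summary columns recorded by run_schedule()
SUMMARY_COLS <- c("R_a", "R_v", "ST", "IT", "A1", "V1", "exo_a", "exo_v",
                  "att_a", "att_v", "D2a1", "D2a2", "D2a3",
                  "D2v1", "D2v2", "D2v3")

## One synchronous update of every module. Inputs are computed from the
## current state, then all modules advance together. Returns c(syn, summary).
step_core <- function(net, d_up, d_down, d_v, endo_a, endo_v, step_idx) {
  cfg <- net$cfg; W <- net$W; P <- net$P
  E <- net$E; I <- net$I
  dt <- cfg$dt_ms / cfg$tau_ms
  nsd <- cfg$noise_sd
  g <- cfg$gating
  ng <- g$n_groups
  E2 <- E; I2 <- I
  syn <- numeric(length(E))
  im <- net$imod  # name -> index lookup

  Pm <- net$Pm  # per-module parameter matrix (rows = modules)
  ## For dt <= tau and delta*dt <= 1 the Euler update cannot leave [0, 1]
  ## (the shunting term caps growth at 1, linear decay cannot cross 0), so no
  ## explicit clamp is needed in the hot loop; wc_step() clamps for generality.
  upd <- function(j, exc, inh_extra = 0) {
    p <- Pm[j, ]
    Ev <- E[[j]]; Iv <- I[[j]]
    in_E <- exc - p[6L] * Iv
    if (nsd > 0) in_E <- in_E + stats::rnorm(length(Ev), 0, nsd)
    in_I <- p[7L] * Ev + inh_extra
    if (anyNA(in_E) || anyNA(in_I)) {
      stop(sprintf("non-finite input to module %s at step %d",
                   names(E)[j], step_idx))
    }
    sE <- 1 / (1 + exp(p[1L] * (p[2L] - in_E)))
    sI <- 1 / (1 + exp(p[4L] * (p[5L] - in_I)))
    rdt <- p[3L] * dt
    E2[[j]] <<- Ev + rdt * (sE * (1 - Ev) - p[8L] * Ev)
    I2[[j]] <<- Iv + rdt * (sI * (1 - Iv) - p[8L] * Iv)
    ## integrated absolute synaptic input (noise excluded): all excitatory
    ## afferent terms are nonnegative, inhibition enters via |w_IE I| and in_I
    syn[j] <<- sum(exc) + p[6L] * sum(Iv) + sum(in_I)
  }

  ## ---- auditory stream ----
  upd(im["A1_up"], W[["stim_a->A1"]] * d_up)
  upd(im["A1_down"], W[["stim_a->A1"]] * d_down)
  lam_c <- cfg$dt_ms / 100
  net$ctr_trace_up <- net$ctr_trace_up + lam_c * (E[[im["A1_up"]]] - net$ctr_trace_up)
  net$ctr_trace_down <- net$ctr_trace_down + lam_c * (E[[im["A1_down"]]] - net$ctr_trace_down)
  d2sum_a <- E[[im["D2_a1"]]] + E[[im["D2_a2"]]] + E[[im["D2_a3"]]]
  fb_a2 <- W[["D2_a->A2"]] * d2sum_a
  upd(im["A2_up"], W[["A1_up->A2_up"]] * E[[im["A1_up"]]] + fb_a2)
  upd(im["A2_down"], W[["A1_down->A2_down"]] * E[[im["A1_down"]]] + fb_a2)
  upd(im["A2_contour"], W[["A1->A2_contour"]] * net$ctr_trace_up * net$ctr_trace_down)
  upd(im["ST"], W[["A2_up->ST"]] * E[[im["A2_up"]]] +
        W[["A2_down->ST"]] * E[[im["A2_down"]]] +
        W[["A2_contour->ST"]] * E[[im["A2_contour"]]] +
        W[["D2_a->ST"]] * d2sum_a)

  ## ---- auditory gating (MTL winner-take-all over unused groups) ----
  lam_g <- cfg$dt_ms / g$trace_ms
  mst <- sum(E[[im["ST"]]]) / 81
  ## gating onsets are detected on the phasic, feedback-free A2 stage, so a
  ## new stimulus is visible against any working-memory-driven ST background
  ma2 <- (sum(E[[im["A2_up"]]]) + sum(E[[im["A2_down"]]])) / 162
  ga <- net$gate$aud
  onset_a <- max(ma2 - ga$st_trace - g$onset_floor, 0)
  if (ga$refract > 0) {
    onset_a <- 0
    net$gate$aud$refract <- ga$refract - 1L
  }
  net$gate$aud$st_trace <- ga$st_trace + lam_g * (ma2 - ga$st_trace)
  bm_a <- band_means(E[[im["MTL"]]], ng)
  live_a <- !ga$used
  band_in <- (W[["ST->MTL"]] * onset_a + g$tie_bias * (ng:1) / ng) * live_a
  ## consumed groups are silenced through their interneurons (prefrontal
  ## confirmation feedback); live groups inhibit one another (winner-take-all)
  cross_a <- W[["MTL<->MTL"]] * (sum(bm_a) - bm_a) - g$used_bias * ga$used
  nb <- 81 %/% ng
  upd(im["MTL"], rep(band_in, each = nb), inh_extra = rep(cross_a, each = nb))
  ## winner-take-all readout: only the most active unused group passes the
  ## stimulus through to its slot; exact ties go to the lowest group index
  gate_a <- pmin(pmax(bm_a - g$out_thresh, 0) * g$out_gain, 1) * live_a
  win_a <- which.max(bm_a + g$tie_bias * (ng:1) / ng - 10 * ga$used)
  gate_a[-win_a] <- 0
  if (net$gate$aud$refract > 0) gate_a[] <- 0

  if (!is.null(net$gate_log)) {
    net$gate_log[[length(net$gate_log) + 1]] <-
      c(step_idx, onset_a, bm_a, gate_a, net$gate$aud$refract)
  }

  ## ---- auditory prefrontal ----
  upd(im["FS_a"], W[["ST->FS_a"]] * E[[im["ST"]]])
  att_a <- clamp(endo_a + net$exo_a, 0, cfg$att$max) * W[["ATT_a->D2_a"]]
  st_now <- E[[im["ST"]]]
  id1a <- net$idx$d1a; id2a <- net$idx$d2a
  for (k in 1:ng) {
    j1 <- id1a[k]; j2 <- id2a[k]
    upd(j1, W[["D2_a->D1_a"]] * E[[j2]] + W[["ST->D1_a"]] * gate_a[k] * st_now)
    upd(j2, W[["D1_a->D2_a"]] * E[[j1]] + W[["D2_a->D2_a"]] * E[[j2]] + att_a)
  }
  upd(im["R_a"], W[["FSxD2_a->R_a"]] * E[[im["FS_a"]]] * d2sum_a)

  ## ---- visual stream ----
  upd(im["V1"], W[["stim_v->V1"]] * d_v)
  d2sum_v <- E[[im["D2_v1"]]] + E[[im["D2_v2"]]] + E[[im["D2_v3"]]]
  upd(im["V4"], W[["V1->V4"]] * E[[im["V1"]]] + W[["D2_v->V4"]] * d2sum_v)
  upd(im["IT"], W[["V4->IT"]] * E[[im["V4"]]] + W[["D2_v->IT"]] * d2sum_v)

  mit <- sum(E[[im["IT"]]]) / 81
  mv4 <- sum(E[[im["V4"]]]) / 81
  gv <- net$gate$vis
  onset_v <- max(mv4 - gv$st_trace - g$onset_floor, 0)
  if (gv$refract > 0) {
    onset_v <- 0
    net$gate$vis$refract <- gv$refract - 1L
  }
  net$gate$vis$st_trace <- gv$st_trace + lam_g * (mv4 - gv$st_trace)
  bm_v <- band_means(E[[im["EC"]]], ng)
  live_v <- !gv$used
  band_in_v <- (W[["IT->EC"]] * onset_v + g$tie_bias * (ng:1) / ng) * live_v
  cross_v <- W[["EC<->EC"]] * (sum(bm_v) - bm_v) - g$used_bias * gv$used
  upd(im["EC"], rep(band_in_v, each = nb), inh_extra = rep(cross_v, each = nb))
  gate_v <- pmin(pmax(bm_v - g$out_thresh, 0) * g$out_gain, 1) * live_v
  win_v <- which.max(bm_v + g$tie_bias * (ng:1) / ng - 10 * gv$used)
  gate_v[-win_v] <- 0
  if (net$gate$vis$refract > 0) gate_v[] <- 0

  if (!is.null(net$gate_log_v)) {
    net$gate_log_v[[length(net$gate_log_v) + 1]] <-
      c(step_idx, mv4, onset_v, bm_v, gate_v, net$gate$vis$refract)
  }

  upd(im["FS_v"], W[["IT->FS_v"]] * E[[im["IT"]]])
  att_v <- clamp(endo_v + net$exo_v, 0, cfg$att$max) * W[["ATT_v->D2_v"]]
  it_now <- E[[im["IT"]]]
  id1v <- net$idx$d1v; id2v <- net$idx$d2v
  for (k in 1:ng) {
    j1 <- id1v[k]; j2 <- id2v[k]
    upd(j1, W[["D2_v->D1_v"]] * E[[j2]] + W[["IT->D1_v"]] * gate_v[k] * it_now)
    upd(j2, W[["D1_v->D2_v"]] * E[[j1]] + W[["D2_v->D2_v"]] * E[[j2]] + att_v)
  }
  upd(im["R_v"], W[["FSxD2_v->R_v"]] * E[[im["FS_v"]]] * d2sum_v)

  ## ---- anterior insula competition ----
  upd(im["aINS_a"], W[["ST->aINS_a"]] * mst,
      inh_extra = W[["aINS_v->aINS_a"]] * E[[im["aINS_v"]]])
  upd(im["aINS_v"], W[["IT->aINS_v"]] * mit,
      inh_extra = W[["aINS_a->aINS_v"]] * E[[im["aINS_a"]]])

  ## commit state
  net$E <- E2; net$I <- I2

  ## store-confirmation: a slot crossing the confirmation strength consumes
  ## its gating group (inhibitory feedback suppresses the active gate)
  refract_steps <- as.integer(g$refractory_ms / cfg$dt_ms)
  ss_a <- numeric(ng); ss_v <- numeric(ng)
  for (k in 1:ng) {
    ss_a[k] <- slot_strength(E2[[id2a[k]]], g$conf_top)
    ss_v[k] <- slot_strength(E2[[id2v[k]]], g$conf_top)
    if (!net$gate$aud$used[k] && ss_a[k] > g$conf_thresh) {
      net$gate$aud$used[k] <- TRUE
      net$gate$aud$refract <- refract_steps
    }
    if (!net$gate$vis$used[k] && ss_v[k] > g$conf_thresh) {
      net$gate$vis$used[k] <- TRUE
      net$gate$vis$refract <- refract_steps
    }
  }

  ## exogenous attention: affine map of aINS output, 50 ms moving average
  ex <- cfg$exo
  nbuf <- length(net$exo_buf_a)
  ptr <- net$exo_ptr %% nbuf + 1L
  net$exo_buf_a[ptr] <- clamp(ex$gain_a * (E2[[im["aINS_a"]]] - ex$baseline), 0, ex$cap)
  net$exo_buf_v[ptr] <- clamp(ex$gain_v * (E2[[im["aINS_v"]]] - ex$baseline), 0, ex$cap)
  net$exo_ptr <- ptr
  net$exo_a <- mean(net$exo_buf_a)
  net$exo_v <- mean(net$exo_buf_v)

  mn <- function(nm) sum(E2[[im[nm]]]) / length(E2[[im[nm]]])
  c(syn,
    mn("R_a"), mn("R_v"),
    mn("ST"), mn("IT"),
    (mn("A1_up") + mn("A1_down")) / 2,
    mn("V1"),
    net$exo_a, net$exo_v, att_a, att_v,
    ss_a, ss_v)
}

#' Run a network through an epoch schedule
#'
#' Epochs are lists with fields `label`, `dur_ms`, `endo_a`, `endo_v` and
#' optional stimuli `aud` and `vis` (presented from epoch onset). The network
#' is reset to rest, the RNG is seeded, and the whole schedule is integrated
#' at `cfg$dt_ms`. Identical seed and configuration give bit-identical output.
#'
#' @param net an `avwm_network`
#' @param schedule list of epoch lists
#' @param seed integer seed for the input noise
#' @param record `"summary"` (per-step module summaries and synaptic series)
#'   or `"full"` (additionally every unit's E and I trajectory)
#' @param reset reset the network state first (default TRUE)
#' @return an object of class `avwm_run`: epoch table, per-step summary matrix,
#'   per-step per-module integrated synaptic input, and (optionally) full unit
#'   activity
#' @export
run_schedule <- function(net, schedule, seed = 1,
                         record = c("summary", "full"), reset = TRUE) {
  record <- match.arg(record)
  cfg <- net$cfg
  if (reset) reset_network(net)
  if (!is.null(seed)) set.seed(seed)
  net$imod <- stats::setNames(seq_along(net$E), names(net$E))
  ng <- cfg$gating$n_groups
  net$idx <- list(d1a = net$imod[paste0("D1_a", 1:ng)],
                  d2a = net$imod[paste0("D2_a", 1:ng)],
                  d1v = net$imod[paste0("D1_v", 1:ng)],
                  d2v = net$imod[paste0("D2_v", 1:ng)])

  steps_per <- vapply(schedule, function(ep) {
    if (ep$dur_ms %% cfg$dt_ms != 0)
      stop("epoch duration must be a multiple of dt_ms")
    as.integer(ep$dur_ms / cfg$dt_ms)
  }, integer(1))
  n_steps <- sum(steps_per)
  nmod <- length(net$E)
  out <- matrix(0, n_steps, nmod + length(SUMMARY_COLS))
  full <- NULL
  if (record == "full") {
    full <- lapply(net$E, function(v) matrix(0, n_steps, length(v)))
    full_I <- lapply(net$I, function(v) matrix(0, n_steps, length(v)))
  }
  zero81 <- numeric(81)
  sidx <- 0L
  for (ei in seq_along(schedule)) {
    ep <- schedule[[ei]]
    r_a <- if (!is.null(ep$aud)) render_stimulus(ep$aud, cfg$dt_ms, cfg) else NULL
    r_v <- if (!is.null(ep$vis)) render_stimulus(ep$vis, cfg$dt_ms, cfg) else NULL
    for (s in seq_len(steps_per[ei])) {
      sidx <- sidx + 1L
      d_up <- if (!is.null(r_a) && s <= r_a$steps) r_a$up[s, ] else zero81
      d_down <- if (!is.null(r_a) && s <= r_a$steps) r_a$down[s, ] else zero81
      d_v <- if (!is.null(r_v) && s <= r_v$steps) r_v$frame[s, ] else zero81
      out[sidx, ] <- step_core(net, d_up, d_down, d_v,
                               ep$endo_a %||% 0, ep$endo_v %||% 0, sidx)
      if (record == "full") {
        for (j in seq_len(nmod)) {
          full[[j]][sidx, ] <- net$E[[j]]
          full_I[[j]][sidx, ] <- net$I[[j]]
        }
      }
    }
  }
  ends <- cumsum(steps_per)
  epochs <- data.frame(
    label = vapply(schedule, function(e) e$label, character(1)),
    start_step = c(1L, utils::head(ends, -1) + 1L),
    end_step = ends,
    endo_a = vapply(schedule, function(e) e$endo_a %||% 0, numeric(1)),
    endo_v = vapply(schedule, function(e) e$endo_v %||% 0, numeric(1)),
    stringsAsFactors = FALSE)
  syn <- out[, seq_len(nmod), drop = FALSE]
  colnames(syn) <- names(net$E)
  summary <- out[, nmod + seq_along(SUMMARY_COLS), drop = FALSE]
  colnames(summary) <- SUMMARY_COLS
  res <- list(dt_ms = cfg$dt_ms, n_steps = n_steps, epochs = epochs,
              summary = summary, syn = syn, cfg = cfg)
  if (record == "full") { res$E <- full; res$I <- full_I }
  class(res) <- "avwm_run"
  res
}

#' Simulate the network for a fixed duration
#'
#' A thin wrapper over [run_schedule()] for spontaneous or single-stimulus
#' runs: one epoch of `duration_ms` (which must be a multiple of `dt_ms`) with
#' optional auditory/visual stimuli presented at onset.
#'
#' @inheritParams run_schedule
#' @param duration_ms run length in ms
#' @param aud,vis optional stimuli
#' @param endo_a,endo_v endogenous attention levels
#' @return an `avwm_run`
#' @export
simulate_network <- function(net, duration_ms, aud = NULL, vis = NULL,
                             endo_a = 0, endo_v = 0, seed = 1,
                             record = "summary") {
  if (duration_ms %% net$cfg$dt_ms != 0)
    stop("duration_ms must be a multiple of dt_ms")
  run_schedule(net, list(list(label = "run", dur_ms = duration_ms,
                              endo_a = endo_a, endo_v = endo_v,
                              aud = aud, vis = vis)),
               seed = seed, record = record)
}

#' Combine endogenous and exogenous attention
#'
#' The task-set (endogenous) level and the salience-driven (exogenous) level
#' add, clipped to the configured ceiling; the result is the uniform bias
#' injected into the corresponding D2 submodules.
#'
#' @param endo endogenous level
#' @param exo exogenous level
#' @param cfg configuration list
#' @export
combine_attention <- function(endo, exo, cfg = default_config()) {
  clamp(endo + exo, 0, cfg$att$max)
}

#' Stand-alone anterior-insula competition
#'
#' Integrates just the mutually inhibitory aINS unit pair under constant
#' visual/auditory drives (module-mean IT and ST activity, already scaled by
#' stimulus salience) and returns the smoothed exogenous attention pair.
#'
#' @param it_drive,st_drive constant scalar drives
#' @param cfg configuration list
#' @param duration_ms integration time
#' @param seed RNG seed (noise-free if `cfg$noise_sd` is 0)
#' @return list with `exo_v`, `exo_a` (final smoothed values) and the per-step
#'   `trace` matrix
#' @export
compute_exogenous <- function(it_drive, st_drive, cfg = default_config(),
                              duration_ms = 1000, seed = 1) {
  if (!is.null(seed)) set.seed(seed)
  uc0 <- cfg$unit_common
  p <- cfg$units$AINS
  uc <- list(K_i = p$K_i %||% uc0$K_i, phi_i = p$phi_i %||% uc0$phi_i,
             wie = p$wie %||% uc0$wie, wei = p$wei %||% uc0$wei)
  dt <- cfg$dt_ms / cfg$tau_ms
  n <- round(duration_ms / cfg$dt_ms)
  Ev <- Ea <- Iv <- Ia <- 0
  nbuf <- max(1L, round(cfg$exo$smooth_ms / cfg$dt_ms))
  bv <- ba <- numeric(nbuf)
  tr <- matrix(0, n, 2, dimnames = list(NULL, c("exo_v", "exo_a")))
  wx <- cfg$w$ains_x; ex <- cfg$exo
  par <- list(K = p$K, phi = p$phi, rho = p$rho, K_i = uc$K_i, phi_i = uc$phi_i,
              delta = cfg$delta)
  for (s in seq_len(n)) {
    nz <- if (cfg$noise_sd > 0) stats::rnorm(2, 0, cfg$noise_sd) else c(0, 0)
    up_v <- wc_step(Ev, Iv, it_drive - uc$wie * Iv + nz[1],
                    uc$wei * Ev + wx * Ea, par, dt)
    up_a <- wc_step(Ea, Ia, st_drive - uc$wie * Ia + nz[2],
                    uc$wei * Ea + wx * Ev, par, dt)
    Ev <- up_v$E; Iv <- up_v$I; Ea <- up_a$E; Ia <- up_a$I
    ptr <- (s - 1L) %% nbuf + 1L
    bv[ptr] <- clamp(ex$gain_v * (Ev - ex$baseline), 0, ex$cap)
    ba[ptr] <- clamp(ex$gain_a * (Ea - ex$baseline), 0, ex$cap)
    tr[s, ] <- c(mean(bv), mean(ba))
  }
  list(exo_v = mean(bv), exo_a = mean(ba), trace = tr)
}

#' Long-format activity table of a full-record run
#'
#' @param run an `avwm_run` recorded with `record = "full"`
#' @param modules optional subset of module names
#' @return data.frame (time_ms, module, submodule, unit_row, unit_col, E, I)
#' @export
as_activity_df <- function(run, modules = NULL) {
  if (is.null(run$E)) stop("run was not recorded with record = 'full'")
  roster <- module_roster()
  nms <- names(run$E)
  if (!is.null(modules)) nms <- intersect(nms, modules)
  out <- lapply(nms, function(nm) {
    m <- run$E[[nm]]
    ri <- roster[roster$name == nm, ]
    n <- ncol(m)
    rows <- rep(rep(seq_len(ri$rows), times = ri$cols), each = nrow(m))
    cols <- rep(rep(seq_len(ri$cols), each = ri$rows), each = nrow(m))
    data.frame(time_ms = rep((seq_len(nrow(m)) - 1) * run$dt_ms, n),
               module = ri$region, submodule = nm,
               unit_row = rows, unit_col = cols,
               E = as.vector(m), I = as.vector(run$I[[nm]]))
  })
  do.call(rbind, out)
}

#' @rdname as_activity_df
#' @param path output CSV path
#' @export
write_activity_csv <- function(run, path, modules = NULL) {
  utils::write.csv(as_activity_df(run, modules), path, row.names = FALSE)
  invisible(path)
}
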