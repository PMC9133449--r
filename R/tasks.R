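## Trial schedules and behavioral scoring for the five simulated experiments.

epoch <- function(label, dur_ms, endo_a = 0.05, endo_v = 0.05,
                  aud = NULL, vis = NULL) {
  list(label = label, dur_ms = dur_ms, endo_a = endo_a, endo_v = endo_v,
       aud = aud, vis = vis)
}

epoch_steps <- function(run, label) {
  ep <- run$epochs[run$epochs$label == label, ]
  unlist(lapply(seq_len(nrow(ep)), function(i) ep$start_step[i]:ep$end_step[i]))
}

## mean of a summary column over an epoch
epoch_mean <- function(run, label, col) {
  mean(run$summary[epoch_steps(run, label), col])
}

score_outcome <- function(run, match, cfg, r_col = "R_a") {
  ## response statistic: mean R activity over the probe epoch plus a short
  ## tail (the sensory chain lags the probe by 150-250 ms), baseline-corrected
  ## by the preceding 100 ms so only the probe-evoked response counts
  ps <- epoch_steps(run, "probe")
  extra <- round((cfg$readout$response_window_extra_ms %||% 0) / run$dt_ms)
  win <- ps[1]:min(max(ps) + extra, run$n_steps)
  base <- max(1, ps[1] - round(100 / run$dt_ms)):(ps[1] - 1)
  stat <- mean(run$summary[win, r_col]) - mean(run$summary[base, r_col])
  responded <- stat > cfg$readout$response_threshold
  list(responded = responded, correct = responded == match, probe_stat = stat)
}

#' Run a single delayed match-to-sample trial
#'
#' Stimulus, delay, probe; the task-set (endogenous) attention for the task
#' modality is high (0.3) throughout. The outcome is scored from the mean
#' response-module activity during the probe epoch.
#'
#' @param net an `avwm_network`
#' @param stimulus,probe stimulus objects (same modality)
#' @param match logical ground truth (probe matches the stimulus)
#' @param seed integer seed
#' @param modality `"aud"` or `"vis"`
#' @param endo endogenous attention during the trial (default: configured high)
#' @return an `avwm_trial`: outcome (responded/correct), probe statistic,
#'   slot strengths and the underlying run record
#' @export
run_dms_trial <- function(net, stimulus, probe, match, seed = 1,
                          modality = c("aud", "vis"), endo = NULL) {
  modality <- match.arg(modality)
  cfg <- net$cfg; ep <- cfg$epochs
  hi <- endo %||% cfg$att$high
  lo <- cfg$att$low
  ea <- function(x) if (modality == "aud") x else lo
  ev <- function(x) if (modality == "vis") x else lo
  aud <- function(s) if (modality == "aud") s else NULL
  vis <- function(s) if (modality == "vis") s else NULL
  sched <- list(
    epoch("lead", ep$lead_ms, ea(hi), ev(hi)),
    epoch("stim", ep$stim_ms, ea(hi), ev(hi), aud = aud(stimulus), vis = vis(stimulus)),
    epoch("delay", ep$delay_ms, ea(hi), ev(hi)),
    epoch("probe", ep$probe_ms, ea(hi), ev(hi), aud = aud(probe), vis = vis(probe)),
    epoch("iti", ep$iti_ms, lo, lo))
  run <- run_schedule(net, sched, seed = seed)
  out <- score_outcome(run, match, cfg, if (modality == "aud") "R_a" else "R_v")
  trial_record(run, out, match, task = "dms")
}

trial_record <- function(run, out, match, task, extra = list()) {
  structure(c(list(task = task, match = match, responded = out$responded,
                   correct = out$correct, probe_stat = out$probe_stat,
                   run = run), extra),
            class = "avwm_trial")
}

#' @export
print.avwm_trial <- function(x, ...) {
  cat(sprintf("%s trial: %s (probe %s, R stat %.4f)\n", x$task,
              if (x$correct) "correct" else "error",
              if (x$match) "match" else "nonmatch", x$probe_stat))
  invisible(x)
}

#' Run a DMS trial with two intervening distractors
#'
#' The target is presented under high endogenous attention; two distractors
#' (same or other modality) follow; attention drops to the low level after the
#' distractors and is re-engaged at the probe. Distractors evoke working-memory
#' activity but must not overwrite the target.
#'
#' @inheritParams run_dms_trial
#' @param distractors list of two stimuli
#' @export
run_distractor_trial <- function(net, stimulus, distractors, probe, match,
                                 seed = 1, modality = c("aud", "vis")) {
  modality <- match.arg(modality)
  stopifnot(length(distractors) == 2)
  cfg <- net$cfg; ep <- cfg$epochs
  hi <- cfg$att$high; lo <- cfg$att$low
  ea <- function(x) if (modality == "aud") x else lo
  ev <- function(x) if (modality == "vis") x else lo
  put <- function(s) {
    if (inherits(s, "avwm_contour") || inherits(s, "avwm_noise")) {
      list(aud = s, vis = NULL)
    } else list(aud = NULL, vis = s)
  }
  d1 <- put(distractors[[1]]); d2 <- put(distractors[[2]])
  tgt <- put(stimulus); prb <- put(probe)
  ## endogenous attention is high through target encoding and the first delay,
  ## drops to low once the distractors arrive, and re-engages at the probe
  sched <- list(
    epoch("lead", ep$lead_ms, ea(hi), ev(hi)),
    epoch("stim", ep$stim_ms, ea(hi), ev(hi), aud = tgt$aud, vis = tgt$vis),
    epoch("delay", 400, ea(hi), ev(hi)),
    epoch("distractor", ep$stim_ms, lo, lo, aud = d1$aud, vis = d1$vis),
    epoch("gap", ep$distractor_gap_ms, lo, lo),
    epoch("distractor", ep$stim_ms, lo, lo, aud = d2$aud, vis = d2$vis),
    epoch("post", ep$post_distractor_ms, lo, lo),
    epoch("probe", ep$probe_ms, ea(hi), ev(hi), aud = prb$aud, vis = prb$vis),
    epoch("iti", ep$iti_ms, lo, lo))
  run <- run_schedule(net, sched, seed = seed)
  out <- score_outcome(run, match, cfg, if (modality == "aud") "R_a" else "R_v")
  trial_record(run, out, match, task = "dms_distractors")
}

#' Run a Sternberg recognition trial
#'
#' A list of up to three stimuli is presented sequentially, each routed to its
#' own working-memory slot by the gating module; after a delay, the model
#' responds if the probe matches any stored item.
#'
#' @inheritParams run_dms_trial
#' @param stimuli list of stimuli (length <= slot capacity)
#' @param match logical: probe matches some list item
#' @export
run_sternberg_trial <- function(net, stimuli, probe, match, seed = 1,
                                modality = c("aud", "vis")) {
  modality <- match.arg(modality)
  if (length(stimuli) > net$n_slots)
    stop("list length exceeds working-memory capacity (", net$n_slots, ")")
  cfg <- net$cfg; ep <- cfg$epochs
  hi <- cfg$att$high; lo <- cfg$att$low
  ea <- function(x) if (modality == "aud") x else lo
  ev <- function(x) if (modality == "vis") x else lo
  aud <- function(s) if (modality == "aud") s else NULL
  vis <- function(s) if (modality == "vis") s else NULL
  sched <- list(epoch("lead", ep$lead_ms, ea(hi), ev(hi)))
  for (i in seq_along(stimuli)) {
    sched <- c(sched, list(
      epoch("stim", ep$stim_ms, ea(hi), ev(hi),
            aud = aud(stimuli[[i]]), vis = vis(stimuli[[i]])),
      epoch("isi", ep$isi_ms, ea(hi), ev(hi))))
  }
  sched <- c(sched, list(
    epoch("delay", ep$delay_ms, ea(hi), ev(hi)),
    epoch("probe", ep$probe_ms, ea(hi), ev(hi), aud = aud(probe), vis = vis(probe)),
    epoch("iti", ep$iti_ms, lo, lo)))
  run <- run_schedule(net, sched, seed = seed)
  out <- score_outcome(run, match, cfg, if (modality == "aud") "R_a" else "R_v")
  trial_record(run, out, match, task = "sternberg")
}

#' Run a bimodal competition trial
#'
#' Auditory and visual stimuli are presented simultaneously with their own
#' saliency levels; the anterior-insula pair allocates exogenous attention and
#' the more salient (or endogenously favored) modality encodes its stimulus.
#'
#' @inheritParams run_dms_trial
#' @param aud_stim,vis_stim stimuli (carrying their saliency)
#' @param endo_a,endo_v endogenous attention levels (default: low bimodal 0.1)
#' @return an `avwm_trial` with per-modality encoding flags and mean exogenous
#'   attention during the stimulus epoch
#' @export
run_bimodal_trial <- function(net, aud_stim, vis_stim, seed = 1,
                              endo_a = NULL, endo_v = NULL) {
  cfg <- net$cfg; ep <- cfg$epochs
  ea <- endo_a %||% cfg$att$bimodal
  ev <- endo_v %||% cfg$att$bimodal
  sched <- list(
    epoch("lead", ep$lead_ms, ea, ev),
    epoch("stim", ep$stim_ms, ea, ev, aud = aud_stim, vis = vis_stim),
    epoch("delay", ep$delay_ms, ea, ev))
  run <- run_schedule(net, sched, seed = seed)
  enc_a <- max(run$summary[run$n_steps, c("D2a1", "D2a2", "D2a3")])
  enc_v <- max(run$summary[run$n_steps, c("D2v1", "D2v2", "D2v3")])
  thr <- cfg$readout$retention_threshold
  ## attention window: stimulus epoch plus the rise time of the salience
  ## circuit (the anterior insula lags the sensory integrators by ~200 ms)
  ss <- epoch_steps(run, "stim")
  win <- ss[1]:min(max(ss) + round(250 / run$dt_ms), run$n_steps)
  structure(list(task = "bimodal",
                 exo_a = mean(run$summary[win, "exo_a"]),
                 exo_v = mean(run$summary[win, "exo_v"]),
                 encoded_a = enc_a > thr, encoded_v = enc_v > thr,
                 run = run),
            class = "avwm_trial")
}

#' Run a working-memory load trial
#'
#' One to three visual items are encoded under visual task-set attention; a
#' salient auditory distractor is presented before the visual probe. Returns
#' the two distractor-epoch summary measures (mean exogenous auditory
#' attention and mean ST activity) together with the behavioral outcome.
#'
#' @inheritParams run_dms_trial
#' @param vis_items list of 1-3 visual shapes
#' @param aud_distractor auditory stimulus (tonal contour)
#' @param probe visual probe
#' @param match logical: probe matches a stored item
#' @export
run_load_trial <- function(net, vis_items, aud_distractor, probe, match,
                           seed = 1) {
  if (length(vis_items) > net$n_slots)
    stop("visual load exceeds working-memory capacity (", net$n_slots, ")")
  cfg <- net$cfg; ep <- cfg$epochs
  hi <- cfg$att$high; lo <- cfg$att$low
  ## pad the lead so every load reaches the distractor at the same elapsed
  ## time: the load contrast must not ride on the network's settling transient
  isi <- ep$load_isi_ms %||% ep$isi_ms
  pad <- (net$n_slots - length(vis_items)) * (ep$stim_ms + isi)
  sched <- list(epoch("lead", ep$lead_ms + pad, lo, hi))
  for (i in seq_along(vis_items)) {
    sched <- c(sched, list(
      epoch("stim", ep$stim_ms, lo, hi, vis = vis_items[[i]]),
      epoch("isi", isi, lo, hi)))
  }
  sched <- c(sched, list(
    epoch("predelay", 300, lo, hi),
    epoch("distractor", ep$stim_ms, lo, hi, aud = aud_distractor),
    epoch("post", ep$post_distractor_ms, lo, hi),
    epoch("probe", ep$probe_ms, lo, hi, vis = probe),
    epoch("iti", ep$iti_ms, lo, lo)))
  run <- run_schedule(net, sched, seed = seed)
  out <- score_outcome(run, match, cfg, "R_v")
  ## distractor-epoch measures outlast the 250 ms sound: the salience circuit
  ## (smoothed aINS output) rises and decays within ~500 ms of onset, while the
  ## ST response carries the distractor's memory-trace feedback for ~700 ms
  ds <- epoch_steps(run, "distractor")
  win_att <- ds[1]:min(max(ds) + round(500 / run$dt_ms), run$n_steps)
  win_st <- ds[1]:min(max(ds) + round(700 / run$dt_ms), run$n_steps)
  pre <- max(1, ds[1] - round(250 / run$dt_ms)):(ds[1] - 1)
  trial_record(run, out, match, task = "load",
               extra = list(load = length(vis_items),
                            exo_a_distractor = mean(run$summary[win_att, "exo_a"]),
                            exo_v_distractor = mean(run$summary[win_att, "exo_v"]),
                            st_distractor = mean(run$summary[win_st, "ST"]) -
                              mean(run$summary[pre, "ST"])))
}

#' Percent correct of a set of trial outcomes
#'
#' @param outcomes list of `avwm_trial` objects (or logical vector of
#'   per-trial correctness)
#' @return percent correct (0-100)
#' @export
score_accuracy <- function(outcomes) {
  if (length(outcomes) == 0) stop("no outcomes to score")
  ok <- if (is.logical(outcomes)) outcomes
        else vapply(outcomes, function(t) isTRUE(t$correct), logical(1))
  100 * mean(ok)
}
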