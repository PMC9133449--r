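## Synaptic-to-BOLD forward model: 50 ms integrated synaptic activity per
## region, balloon hemodynamics, and block / event-related designs.

#' Integrate synaptic activity over regions and 50 ms bins
#'
#' Sums the per-step absolute synaptic input of every module in a region and
#' over consecutive time bins (50 ms by default).
#'
#' @param syn matrix (steps x modules) of per-step summed absolute synaptic
#'   input, as produced by [run_schedule()] (`run$syn`)
#' @param dt_ms integration step of the series
#' @param region_map named list: region -> character vector of module names.
#'   Every module column must belong to exactly one region.
#' @param bin_ms bin width (must be a multiple of `dt_ms`)
#' @return matrix (bins x regions) of class `avwm_synaptic`
#' @export
integrate_synaptic <- function(syn, dt_ms, region_map = default_region_map(),
                               bin_ms = 50) {
  stopifnot(bin_ms %% dt_ms == 0)
  mods <- colnames(syn)
  assigned <- unlist(region_map, use.names = FALSE)
  if (anyDuplicated(assigned)) stop("a module is assigned to more than one region")
  missing <- setdiff(mods, assigned)
  if (length(missing)) stop("modules without a region: ",
                            paste(missing, collapse = ", "))
  steps_per_bin <- bin_ms / dt_ms
  nbin <- floor(nrow(syn) / steps_per_bin)
  bin_of <- rep(seq_len(nbin), each = steps_per_bin)
  out <- vapply(region_map, function(ms) {
    ms <- intersect(ms, mods)
    v <- if (length(ms) == 1) syn[, ms] else rowSums(syn[, ms, drop = FALSE])
    as.vector(rowsum(v[seq_along(bin_of)], bin_of))
  }, numeric(nbin))
  structure(out, bin_ms = bin_ms, class = c("avwm_synaptic", class(out)))
}

#' Default region map (Talairach-labeled ROIs)
#'
#' Groups the module arrays into the regions of interest used for simulated
#' fMRI: working-memory slot replicas collapse into one D1/D2 region per
#' modality, and the two A1 (three A2) submodules into one region each.
#' @export
default_region_map <- function() {
  list(A1 = c("A1_up", "A1_down"),
       A2 = c("A2_up", "A2_down", "A2_contour"),
       ST = "ST", MTL = "MTL",
       FS_a = "FS_a", D1_a = paste0("D1_a", 1:3), D2_a = paste0("D2_a", 1:3),
       R_a = "R_a",
       V1 = "V1", V4 = "V4", IT = "IT", EC = "EC",
       FS_v = "FS_v", D1_v = paste0("D1_v", 1:3), D2_v = paste0("D2_v", 1:3),
       R_v = "R_v",
       aINS = c("aINS_a", "aINS_v"))
}

#' Balloon-model parameters
#'
#' Standard hemodynamic constants: signal decay `kappa` (1/s), flow feedback
#' `gamma` (1/s), mean transit time `tau` (s), vessel stiffness `alpha`,
#' resting oxygen extraction `E0`, resting venous volume fraction `V0`, and
#' the BOLD coefficients k1 = 7 E0, k2, k3 = 2 E0 - 0.2.
#'
#' @param ... overrides of the defaults
#' @export
balloon_params <- function(...) {
  p <- default_config()$balloon
  over <- list(...)
  p[names(over)] <- over
  p$k1 <- 7 * p$E0
  p$k3 <- 2 * p$E0 - 0.2
  p
}

balloon_deriv <- function(state, u, p) {
  s <- state[1]; f <- state[2]; v <- state[3]; q <- state[4]
  Ef <- 1 - (1 - p$E0)^(1 / f)
  c(u - p$kappa * s - p$gamma * (f - 1),
    s,
    (f - v^(1 / p$alpha)) / p$tau,
    (f * Ef / p$E0 - v^(1 / p$alpha) * q / v) / p$tau)
}

#' Balloon-model BOLD from a neural input series
#'
#' Integrates the vasodilatory-signal / inflow / volume / deoxyhemoglobin
#' system with forward Euler at `p$dt_ms`, holding each input bin constant,
#' and returns the percent BOLD signal resampled at the repetition time.
#' The rest state (s, f, v, q) = (0, 1, 1, 1) is a fixed point under zero
#' input, so a zero series returns a zero BOLD series.
#'
#' @param u nonnegative neural input series (one value per `bin_ms` bin); a
#'   matrix is processed column-wise
#' @param params balloon parameters, see [balloon_params()]
#' @param bin_ms input bin width in ms
#' @param tr_s repetition time in s
#' @return BOLD series (percent signal), length `floor(duration / tr_s)`;
#'   matrix input gives a matrix with the same column names
#' @export
balloon_bold <- function(u, params = balloon_params(), bin_ms = 50, tr_s = 1) {
  if (is.matrix(u)) {
    out <- apply(u, 2, balloon_bold, params = params, bin_ms = bin_ms,
                 tr_s = tr_s)
    return(out)
  }
  if (any(u < 0)) stop("balloon input must be nonnegative")
  p <- params
  dt_s <- p$dt_ms / 1000
  sub <- bin_ms / p$dt_ms
  stopifnot(sub == round(sub))
  state <- c(0, 1, 1, 1)
  total_s <- length(u) * bin_ms / 1000
  n_tr <- floor(total_s / tr_s)
  bold_fine <- numeric(length(u) * sub)
  k <- 0L
  for (i in seq_along(u)) {
    for (j in seq_len(sub)) {
      state <- state + dt_s * balloon_deriv(state, u[i], p)
      state[2:4] <- pmax(state[2:4], 1e-6)
      k <- k + 1L
      v <- state[3]; q <- state[4]
      bold_fine[k] <- 100 * p$V0 *
        (p$k1 * (1 - q) + p$k2 * (1 - q / v) + p$k3 * (1 - v))
    }
  }
  per_tr <- tr_s * 1000 / p$dt_ms
  vapply(seq_len(n_tr), function(t)
    mean(bold_fine[((t - 1) * per_tr + 1):(t * per_tr)]), numeric(1))
}

#' Scale integrated synaptic activity to balloon input
#'
#' Affine map normalizing the resting level to zero: positive deviations of
#' the integrated synaptic activity from rest, relative to rest, times a gain
#' calibrated for percent-level peak signal change.
#'
#' @param u bins x regions matrix from [integrate_synaptic()]
#' @param rest resting level per region; by default the per-region minimum of
#'   the series (the quietest bin)
#' @param gain scalar gain
#' @export
scale_synaptic <- function(u, rest = NULL, gain = 1) {
  if (is.null(rest)) rest <- apply(u, 2, function(x) max(min(x), 1e-9))
  sweep2 <- sweep(u, 2, rest, "/") - 1
  gain * pmax(sweep2, 0)
}

#' Simulate an fMRI experiment (block or event-related design)
#'
#' Block design: alternating blocks of 3 task trials and 3 control trials
#' (passive perception of degraded shapes / auditory noise patterns at low
#' attention), 1 s delay periods. Event-related design: each trial lasts 2 s
#' (stimulus, short delay, probe within the trial window is replaced by an
#' extended 20 s delay to expose the full response curve), with 25 s between
#' trial onsets.
#'
#' @param net an `avwm_network`
#' @param task `"dms_aud"`, `"dms_vis"` or `"bimodal"` (no-instruction
#'   attention capture; event-related only)
#' @param design `"block"` or `"event"`
#' @param n_cycles task/control block pairs (block design) or trials (event)
#' @param seed integer seed
#' @return list of class `avwm_bold`: `bold` (TR x region matrix), `labels`
#'   (per-TR `"task"`/`"control"`/`"rest"`), `syn`, `design`
#' @export
assemble_design <- function(net, task = c("dms_aud", "dms_vis", "bimodal"),
                            design = c("block", "event"), n_cycles = 4,
                            seed = 1) {
  task <- match.arg(task)
  design <- match.arg(design)
  if (n_cycles < 1) stop("need at least one trial block")
  cfg <- net$cfg; ep <- cfg$epochs
  hi <- cfg$att$high; lo <- cfg$att$low
  modality <- if (task == "dms_vis") "vis" else "aud"
  ea <- function(x) if (modality == "aud") x else lo
  ev <- function(x) if (modality == "vis") x else lo
  draw_stim <- function() {
    if (modality == "aud") random_contour(cfg = cfg) else random_shape(cfg = cfg)
  }
  set.seed(seed)
  sched <- list(epoch("rest", 2000, lo, lo))
  if (design == "block") {
    one_trial <- function(kind) {
      s <- draw_stim()
      if (kind == "task") {
        m <- stats::runif(1) < 0.5
        p <- make_probe(s, m, cfg = cfg)
        list(epoch("task", ep$stim_ms, ea(hi), ev(hi),
                   aud = if (modality == "aud") s else NULL,
                   vis = if (modality == "vis") s else NULL),
             epoch("task", 1000, ea(hi), ev(hi)),
             epoch("task", ep$probe_ms, ea(hi), ev(hi),
                   aud = if (modality == "aud") p else NULL,
                   vis = if (modality == "vis") p else NULL))
      } else {
        ctl <- make_control(s, cfg = cfg)
        list(epoch("control", ep$stim_ms, lo, lo,
                   aud = if (modality == "aud") ctl else NULL,
                   vis = if (modality == "vis") ctl else NULL),
             epoch("control", 1000, lo, lo),
             epoch("control", ep$probe_ms, lo, lo,
                   aud = if (modality == "aud") make_control(s, cfg = cfg) else NULL,
                   vis = if (modality == "vis") make_control(s, cfg = cfg) else NULL))
      }
    }
    for (cy in seq_len(n_cycles)) {
      for (tr in 1:3) sched <- c(sched, one_trial("task"))
      for (tr in 1:3) sched <- c(sched, one_trial("control"))
    }
  } else {
    for (tr in seq_len(n_cycles)) {
      if (task == "bimodal") {
        sal <- if (tr == 1) c(v = 1.0, a = 0.4) else c(v = 0.4, a = 1.0)
        sched <- c(sched, list(
          epoch("task", 2000, lo, lo,
                aud = random_contour(cfg = cfg, saliency = sal["a"]),
                vis = random_shape(cfg = cfg, saliency = sal["v"]))))
      } else {
        s <- draw_stim()
        sched <- c(sched, list(
          epoch("task", 2000, ea(hi), ev(hi),
                aud = if (modality == "aud") s else NULL,
                vis = if (modality == "vis") s else NULL)))
      }
      sched <- c(sched, list(epoch("rest", ep$event_delay_ms, lo, lo),
                             epoch("rest", ep$event_iti_ms - ep$event_delay_ms - 2000,
                                   lo, lo)))
    }
  }
  run <- run_schedule(net, sched, seed = seed)
  u <- integrate_synaptic(run$syn, cfg$dt_ms, bin_ms = cfg$fmri$bin_ms)
  z <- scale_synaptic(u, gain = cfg$fmri$gain)
  bold <- balloon_bold(z, balloon_params(), bin_ms = cfg$fmri$bin_ms,
                       tr_s = cfg$fmri$tr_s)
  ## per-TR design label from the epoch schedule
  step_label <- rep(run$epochs$label,
                    run$epochs$end_step - run$epochs$start_step + 1)
  per_tr <- cfg$fmri$tr_s * 1000 / cfg$dt_ms
  labels <- vapply(seq_len(nrow(bold)), function(t) {
    lab <- step_label[((t - 1) * per_tr + 1):min(t * per_tr, length(step_label))]
    names(sort(table(lab), decreasing = TRUE))[1]
  }, character(1))
  structure(list(bold = bold, labels = labels, syn = u, design = design,
                 task = task, tr_s = cfg$fmri$tr_s),
            class = "avwm_bold")
}

#' Task-vs-control BOLD contrast per region
#'
#' Mean BOLD during task-labeled TRs minus mean during control-labeled TRs,
#' with the labels shifted by a hemodynamic lag.
#'
#' @param x an `avwm_bold` from a block design
#' @param lag_s label shift (s) accounting for hemodynamic delay
#' @export
bold_contrast <- function(x, lag_s = 3) {
  lag <- round(lag_s / x$tr_s)
  lab <- c(rep("rest", lag), utils::head(x$labels, -lag))
  task <- lab == "task"; ctrl <- lab == "control"
  if (!any(task) || !any(ctrl)) stop("design has no task/control TRs")
  colMeans(x$bold[task, , drop = FALSE]) - colMeans(x$bold[ctrl, , drop = FALSE])
}

#' Write a BOLD record to CSV (+ JSON sidecar with design labels)
#' @param x an `avwm_bold`
#' @param path CSV path; the sidecar is written next to it as `.json`
#' @export
write_bold_csv <- function(x, path) {
  df <- data.frame(tr = seq_len(nrow(x$bold)), x$bold)
  utils::write.csv(df, path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(design = x$design, task = x$task, tr_s = x$tr_s,
                            labels = x$labels),
                       side, auto_unbox = TRUE)
  invisible(path)
}
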