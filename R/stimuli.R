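## Stimulus generation: auditory tonal contours (frequency-sweep patterns on an
## 81-channel tonotopic axis), 9x9 visual shapes, and energy-matched controls.

#' Construct an auditory tonal contour
#'
#' A tonal contour is an ordered list of frequency sweeps (segments), each
#' moving the instantaneous peak channel up or down the 81-channel tonotopic
#' axis. Adjacent segments are channel-continuous; the total duration is that
#' of a single syllable-length sound (roughly 200-300 ms).
#'
#' @param segments data.frame with columns `direction` ("up"/"down"),
#'   `start_channel`, `end_channel`, `duration_ms`.
#' @param saliency scalar in \[0, 1\]; loudness analog, scales the input drive.
#' @return an object of class `avwm_contour`
#' @export
make_tonal_contour <- function(segments, saliency = 1) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1)
  if (any(segments$start_channel < 1 | segments$start_channel > 81 |
          segments$end_channel < 1 | segments$end_channel > 81)) {
    stop("contour channels must lie in [1, 81]")
  }
  dirs <- ifelse(segments$end_channel >= segments$start_channel, "up", "down")
  if (!all(segments$direction == dirs)) {
    stop("segment direction must agree with its channel ramp")
  }
  if (nrow(segments) > 1) {
    if (any(segments$start_channel[-1] != segments$end_channel[-nrow(segments)])) {
      stop("adjacent segments must be channel-continuous")
    }
  }
  structure(list(kind = "contour", segments = segments,
                 duration_ms = sum(segments$duration_ms),
                 saliency = check_saliency(saliency)),
            class = c("avwm_contour", "avwm_stimulus"))
}

check_saliency <- function(s) {
  if (!is.numeric(s) || length(s) != 1 || is.na(s) || s < 0 || s > 1) {
    stop("saliency must be a scalar in [0, 1]")
  }
  s
}

#' Draw a random tonal contour
#'
#' Segments alternate sweep direction; the starting channel, sweep extents and
#' per-segment durations are drawn uniformly within the generator settings so
#' that the contour invariants (duration 200-300 ms, channels within 1..81)
#' always hold.
#'
#' @param seed integer RNG seed
#' @param cfg configuration list (stimulus settings are read from `cfg$stimuli`)
#' @param saliency scalar in \[0, 1\]
#' @return an `avwm_contour`
#' @export
random_contour <- function(seed = NULL, cfg = default_config(), saliency = 1) {
  if (!is.null(seed)) set.seed(seed)
  sc <- cfg$stimuli
  nseg <- sample(sc$n_segments, 1)
  total <- round(stats::runif(1, sc$dur_range_ms[1], sc$dur_range_ms[2]))
  durs <- rep(floor(total / nseg), nseg)
  durs[1] <- durs[1] + total - sum(durs)
  dir1 <- sample(c("up", "down"), 1)
  ext <- round(stats::runif(nseg, sc$sweep_extent[1], sc$sweep_extent[2]))
  segs <- vector("list", nseg)
  ch <- sample(15:67, 1)
  d <- dir1
  for (i in seq_len(nseg)) {
    step <- if (d == "up") ext[i] else -ext[i]
    end <- clamp(ch + step, 3, 79)
    if (end == ch) end <- clamp(ch + sign(step) * 3, 3, 79)
    segs[[i]] <- data.frame(direction = if (end >= ch) "up" else "down",
                            start_channel = ch, end_channel = end,
                            duration_ms = durs[i])
    ch <- end
    d <- if (d == "up") "down" else "up"
  }
  make_tonal_contour(do.call(rbind, segs), saliency = saliency)
}

#' Construct / draw a visual shape stimulus
#'
#' Shapes are 9x9 activity patterns; the random generator unions a few
#' horizontal, vertical or diagonal strokes, giving simple connected figures.
#'
#' @param frame 9x9 numeric matrix in \[0, 1\] with at least one active element
#' @param duration_ms presentation duration
#' @param saliency scalar in \[0, 1\]; luminance analog
#' @return an object of class `avwm_shape`
#' @export
make_visual_shape <- function(frame, duration_ms = 250, saliency = 1) {
  stopifnot(is.matrix(frame), all(dim(frame) == c(9, 9)))
  if (any(frame < 0 | frame > 1)) stop("frame values must lie in [0, 1]")
  if (all(frame == 0)) stop("a non-blank shape needs at least one active element")
  structure(list(kind = "shape", frame = frame, duration_ms = duration_ms,
                 saliency = check_saliency(saliency)),
            class = c("avwm_shape", "avwm_stimulus"))
}

#' @rdname make_visual_shape
#' @param seed integer RNG seed
#' @param cfg configuration list
#' @export
random_shape <- function(seed = NULL, cfg = default_config(), saliency = 1,
                         duration_ms = 250) {
  if (!is.null(seed)) set.seed(seed)
  n_strokes <- sample(cfg$stimuli$shape_strokes, 1)
  repeat {
  fr <- matrix(0, 9, 9)
  r0 <- sample(3:7, 1); c0 <- sample(3:7, 1)
  for (i in seq_len(n_strokes)) {
    ## redraw orientation/length/direction until the whole stroke fits the grid
    repeat {
      ori <- sample(c("h", "v", "d1", "d2"), 1)
      len <- sample(5:7, 1)
      dr <- switch(ori, h = 0, v = 1, d1 = 1, d2 = 1)
      dc <- switch(ori, h = 1, v = 0, d1 = 1, d2 = -1)
      sgn <- sample(c(-1, 1), 1)
      r1 <- r0 + sgn * (len - 1) * dr
      c1 <- c0 + sgn * (len - 1) * dc
      if (r1 >= 1 && r1 <= 9 && c1 >= 1 && c1 <= 9) break
    }
    for (k in 0:(len - 1)) fr[r0 + sgn * k * dr, c0 + sgn * k * dc] <- 1
    # next stroke starts somewhere on the current figure
    on <- which(fr > 0, arr.ind = TRUE)
    p <- on[sample(nrow(on), 1), ]
    r0 <- p[1]; c0 <- p[2]
  }
  ## constrain figure size to a narrow band: heavily self-overlapping stroke
  ## sets are too faint to gate, sprawling ones dominate the salience drive
  if (sum(fr > 0) >= 11 && sum(fr > 0) <= 14) break
  }
  make_visual_shape(fr, duration_ms = duration_ms, saliency = saliency)
}

#' Control stimuli: auditory noise and degraded shapes
#'
#' Controls have the same geometry and (within 10 percent) the same mean input
#' energy as their object counterpart, but none of its spectrotemporal or
#' figural structure: the auditory control scatters short tone bursts over
#' random channels and sweep directions; the visual control scatters the same
#' number of active elements over random positions.
#'
#' @param counterpart the object stimulus to match
#' @param seed integer RNG seed
#' @param cfg configuration list
#' @return an `avwm_noise` or degraded `avwm_shape` with attribute `control`
#' @export
make_control <- function(counterpart, seed = NULL, cfg = default_config()) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(counterpart, "avwm_contour")) {
    seg_ms <- cfg$stimuli$noise_segment_ms
    n <- max(1L, round(counterpart$duration_ms / seg_ms))
    out <- structure(list(kind = "aud_noise",
                          channels = sample(5:77, n, replace = TRUE),
                          dirs = sample(c("up", "down"), n, replace = TRUE),
                          segment_ms = seg_ms,
                          duration_ms = counterpart$duration_ms,
                          saliency = counterpart$saliency),
                     class = c("avwm_noise", "avwm_stimulus"))
  } else {
    fr <- counterpart$frame
    n_on <- sum(fr > 0)
    new <- matrix(0, 9, 9)
    keep <- sample(which(fr > 0), ceiling(n_on / 2))
    new[keep] <- fr[keep]
    scatter <- sample(which(new == 0), n_on - length(keep))
    new[scatter] <- 1
    out <- make_visual_shape(new, duration_ms = counterpart$duration_ms,
                             saliency = counterpart$saliency)
    out$kind <- "degraded_shape"
  }
  attr(out, "control") <- TRUE
  out
}

#' Set the saliency of a stimulus
#'
#' Saliency (loudness/luminance analog) multiplies the rendered input drive;
#' the map is the identity on \[0, 1\].
#'
#' @param stim a stimulus object
#' @param s scalar in \[0, 1\]
#' @export
apply_saliency <- function(stim, s) {
  stim$saliency <- check_saliency(s)
  stim
}

#' Binary feature pattern of a stimulus
#'
#' For a contour, the set of tonotopic channels the sweeps visit; for a shape,
#' the set of active pixels. Used for probe overlap control and match checks.
#'
#' @param stim a stimulus object
#' @return logical vector of length 81
#' @export
stimulus_pattern <- function(stim) {
  if (inherits(stim, "avwm_contour")) {
    on <- rep(FALSE, 81)
    for (i in seq_len(nrow(stim$segments))) {
      s <- stim$segments[i, ]
      on[seq(s$start_channel, s$end_channel)] <- TRUE
    }
    on
  } else if (inherits(stim, "avwm_noise")) {
    on <- rep(FALSE, 81); on[stim$channels] <- TRUE; on
  } else {
    as.vector(stim$frame > 0)
  }
}

pattern_overlap <- function(a, b) {
  pa <- stimulus_pattern(a); pb <- stimulus_pattern(b)
  sum(pa & pb) / sum(pa | pb)
}

#' Draw a probe stimulus for a match/nonmatch trial
#'
#' A match probe is the target itself; a nonmatch probe is a fresh random
#' stimulus of the same kind redrawn until its pattern overlap (Jaccard) with
#' the target — and with any other stimuli in `avoid` — is below the configured
#' ceiling. Nonmatch probes are lures: they must share at least `lure_min`
#' overlap with the target, as in standard delayed-match designs where the
#' foil resembles the sample.
#'
#' @param target target stimulus
#' @param match logical
#' @param seed integer RNG seed
#' @param cfg configuration list
#' @param avoid optional list of further stimuli the probe must not resemble
#' @param lure draw the nonmatch probe as a lure (minimum target overlap);
#'   list-memory (Sternberg) foils are drawn without the lure constraint
#' @export
make_probe <- function(target, match, seed = NULL, cfg = default_config(),
                       avoid = list(), lure = TRUE) {
  if (match) return(target)
  if (!is.null(seed)) set.seed(seed)
  refs <- c(list(target), avoid)
  lure_min <- if (lure) cfg$stimuli$lure_min %||% 0 else 0
  best <- NULL; best_ov <- -1
  for (i in 1:200) {
    cand <- if (inherits(target, "avwm_contour")) {
      random_contour(cfg = cfg, saliency = target$saliency)
    } else {
      random_shape(cfg = cfg, saliency = target$saliency,
                   duration_ms = target$duration_ms)
    }
    ov <- vapply(refs, function(r) pattern_overlap(cand, r), numeric(1))
    if (all(ov <= cfg$stimuli$overlap_max)) {
      if (ov[1] >= lure_min) return(cand)
      if (ov[1] > best_ov) { best <- cand; best_ov <- ov[1] }
    }
  }
  if (!is.null(best)) return(best)
  stop("could not draw a nonmatch probe below the overlap ceiling")
}

#' Render a stimulus as a time-by-channel input drive
#'
#' Auditory stimuli become two (steps x 81) matrices driving the upward- and
#' downward-sweep selective A1 submodules: a Gaussian bump around the
#' instantaneous peak channel, amplitude = saliency, assigned to the submodule
#' matching the current sweep direction. Visual stimuli become a (steps x 81)
#' matrix repeating the flattened frame times saliency.
#'
#' @param stim a stimulus object
#' @param dt_ms integration step
#' @param cfg configuration list
#' @return list with elements `up`, `down` (auditory) or `frame` (visual), and
#'   `steps`
#' @export
render_stimulus <- function(stim, dt_ms = 5, cfg = default_config()) {
  if (inherits(stim, "avwm_contour")) {
    bump_sd <- cfg$stimuli$bump_sd
    steps_total <- max(1L, round(stim$duration_ms / dt_ms))
    up <- matrix(0, steps_total, 81); down <- matrix(0, steps_total, 81)
    t0 <- 0
    ch_axis <- 1:81
    for (i in seq_len(nrow(stim$segments))) {
      s <- stim$segments[i, ]
      nst <- max(1L, round(s$duration_ms / dt_ms))
      idx <- pmin(t0 + seq_len(nst), steps_total)
      peaks <- s$start_channel + (s$end_channel - s$start_channel) *
        (seq_len(nst) - 0.5) / nst
      m <- if (s$direction == "up") "up" else "down"
      for (k in seq_len(nst)) {
        bump <- stim$saliency * exp(-(ch_axis - peaks[k])^2 / (2 * bump_sd^2))
        if (m == "up") up[idx[k], ] <- up[idx[k], ] + bump
        else down[idx[k], ] <- down[idx[k], ] + bump
      }
      t0 <- t0 + nst
    }
    list(up = up, down = down, steps = steps_total)
  } else if (inherits(stim, "avwm_noise")) {
    steps_total <- max(1L, round(stim$duration_ms / dt_ms))
    seg_steps <- max(1L, round(stim$segment_ms / dt_ms))
    up <- matrix(0, steps_total, 81); down <- matrix(0, steps_total, 81)
    ch_axis <- 1:81
    bump_sd <- cfg$stimuli$bump_sd
    for (j in seq_along(stim$channels)) {
      rows <- ((j - 1) * seg_steps + 1):min(j * seg_steps, steps_total)
      if (rows[1] > steps_total) break
      bump <- stim$saliency * exp(-(ch_axis - stim$channels[j])^2 / (2 * bump_sd^2))
      if (stim$dirs[j] == "up") up[rows, ] <- rep(bump, each = length(rows))
      else down[rows, ] <- rep(bump, each = length(rows))
    }
    list(up = up, down = down, steps = steps_total)
  } else {
    steps_total <- max(1L, round(stim$duration_ms / dt_ms))
    v <- as.vector(stim$frame) * stim$saliency
    list(frame = matrix(rep(v, each = steps_total), steps_total, 81),
         steps = steps_total)
  }
}

#' Serialize a rendered stimulus to CSV (time x channel)
#' @param stim stimulus object
#' @param path output file
#' @param dt_ms integration step used for rendering
#' @export
write_stimulus_csv <- function(stim, path, dt_ms = 5) {
  r <- render_stimulus(stim, dt_ms = dt_ms)
  m <- if (!is.null(r$frame)) r$frame else r$up + r$down
  df <- data.frame(time_ms = (seq_len(nrow(m)) - 1) * dt_ms, m)
  names(df) <- c("time_ms", paste0("ch", 1:81))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
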