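#' Default model configuration
#'
#' Returns the full parameter set of the combined auditory-visual network:
#' integration step, Wilson-Cowan unit constants per module class, inter-module
#' connection weights, gating constants, attention/salience mapping, task epoch
#' durations, stimulus generator settings, cohort settings and hemodynamic
#' (balloon) constants. All rate constants are dimensionless per unit time
#' (one unit time = \code{tau_ms}); \code{dt_ms} is the Euler step.
#'
#' The constants were calibrated once against the behavioral operating points
#' the model is meant to reproduce (delayed match-to-sample accuracy in the
#' mid-80s, attention capture of a maximally salient lone stimulus at roughly
#' 0.25 exogenous attention) and are not meant to be tuned per run.
#'
#' @return a named list; see the methods vignette for the meaning and units of
#'   each group.
#' @export
default_config <- function() {
  list(
    dt_ms = 5,          # Euler step (ms)
    tau_ms = 50,        # unit time constant (ms); dt = dt_ms / tau_ms
    delta = 0.5,        # activity decay rate per unit time
    noise_sd = 0.06,    # sd of i.i.d. Gaussian noise on excitatory inputs

    ## Wilson-Cowan sigmoid/decay constants per module class.
    ## K: gain, phi: threshold; *_i: the inhibitory element; wie: I->E weight,
    ## wei: E->I weight within a microcircuit; rho: rate multiplier (<1 = slow).
    ## A class may override the common interneuron constants (the salience pair
    ## uses cross-driven interneurons: wei = 0, shallow K_i, strong wie).
    units = list(
      A1   = list(K = 4,  phi = 0.95, rho = 1.0),
      A2   = list(K = 6,  phi = 0.85, rho = 0.6),
      A2C  = list(K = 8,  phi = 0.50, rho = 1.0),
      ST   = list(K = 8,  phi = 0.70, rho = 0.45),
      GATE = list(K = 10, phi = 0.50, rho = 0.6),
      FS   = list(K = 12, phi = 0.74, rho = 1.0),
      D1   = list(K = 14, phi = 0.68, rho = 1.0),
      D2   = list(K = 30, phi = 0.72, rho = 1.0),
      R    = list(K = 10, phi = 0.50, rho = 1.0),
      V1   = list(K = 4,  phi = 0.95, rho = 1.0),
      V4   = list(K = 6,  phi = 0.85, rho = 1.0),
      IT   = list(K = 8,  phi = 0.70, rho = 0.45),
      AINS = list(K = 4,  phi = 0.50, rho = 1.0,
                  wie = 0.5, wei = 0, K_i = 2, phi_i = 0.85)
    ),
    unit_common = list(K_i = 10, phi_i = 0.5, wie = 0.15, wei = 0.6),

    ## Inter-module connection gains (the edge table in default_edges() maps
    ## each anatomical edge to one of these named scalars).
    w = list(
      in_a    = 2.0,   # stimulus drive -> A1
      a1a2    = 2.6,   # A1 -> A2 (topographic, per sweep direction)
      a1ctr   = 14,    # A1 up x down traces -> A2 contour units
      a2st    = 2.2,   # A2 sweep submodules -> ST
      ctrst   = 0.6,   # A2 contour -> ST
      gate_a  = 140,    # ST onset signal -> MTL gating groups
      gatex_a = 2.0,   # MTL cross-group inhibition
      enc_a   = 1.6,   # gated ST -> D1 (encoding)
      fs_a    = 1.3,   # ST -> FS
      d1d2_a  = 0.55,  # D1 -> D2
      d2d2_a  = 0.60,  # D2 self-excitation (delay attractor)
      d2d1_a  = 1.44,  # D2 -> D1
      r_a     = 2.8,   # FS x D2 (match detection) -> R
      fb_st   = 0.3,   # D2 -> ST feedback
      fb_a2   = 0.05,  # D2 -> A2 feedback
      ains_a  = 9.8,     # mean ST -> aINS (auditory salience drive)
      att_a   = 1.0,   # attention bias -> D2 (auditory)
      in_v    = 1.42,
      v1v4    = 1.3,
      v4it    = 2.2,
      gate_v  = 140,
      gatex_v = 2.0,
      enc_v   = 1.6,
      fs_v    = 1.3,
      d1d2_v  = 0.55,
      d2d2_v  = 0.60,
      d2d1_v  = 1.44,
      r_v     = 2.8,
      fb_it   = 0.5,   # D2 -> IT feedback
      fb_v4   = 0.05,  # D2 -> V4 feedback
      ains_v  = 20.0,
      att_v   = 1.0,
      ains_x  = 2.5    # aINS mutual inhibition
    ),

    gating = list(
      n_groups     = 3,     # working-memory slots per modality
      trace_ms     = 150,   # time constant of the onset differentiator
      onset_floor  = 0.004,  # onset signal below this does not recruit a gate
      refractory_ms = 350,  # gating pause after a storage confirmation
      tie_bias     = 0.02,  # small fixed bias: lowest group index wins ties
      used_bias    = -5,    # clamp on consumed groups
      out_thresh   = 0.35,  # gate activity below this passes nothing
      out_gain     = 3.5,
      conf_thresh  = 0.55,  # slot strength confirming storage (top-unit mean)
      conf_top     = 9      # slot strength = mean of the top-k E values
    ),

    att = list(high = 0.3, low = 0.05, bimodal = 0.1, max = 0.4),
    exo = list(gain_v = 1.0, gain_a = 0.72, baseline = 0.27, cap = 0.5,
               smooth_ms = 50),

    readout = list(response_threshold = 0.026, retention_threshold = 0.30,
                   response_window_extra_ms = 200),

    epochs = list(lead_ms = 250, stim_ms = 250, delay_ms = 1000, probe_ms = 250,
                  iti_ms = 250, isi_ms = 340, load_isi_ms = 550, distractor_gap_ms = 100,
                  post_distractor_ms = 700, event_delay_ms = 20000,
                  event_iti_ms = 25000),

    stimuli = list(channels = 81, dur_range_ms = c(200, 300), bump_sd = 1.5,
                   n_segments = 2:3, sweep_extent = c(6, 20),
                   overlap_max = 0.5, lure_min = 0.25, task_distractor_saliency = 0.8,
                   shape_strokes = 2:3,
                   noise_segment_ms = 25),

    bimodal = list(aud_saliency = 0.65, distractor_saliency = 1.0),

    cohort = list(n_subjects = 10, n_trials = 20, sigma = 0.04),

    balloon = list(kappa = 0.65, gamma = 0.41, tau = 0.98, alpha = 0.32,
                   E0 = 0.34, V0 = 0.02, k2 = 2, dt_ms = 10),
    fmri = list(bin_ms = 50, tr_s = 1, gain = 1.0)
  )
}

#' Read / write a model configuration as YAML
#'
#' @param path file path
#' @param cfg configuration list (as from [default_config()])
#' @return `read_config` returns a configuration list with defaults filled in
#'   for any field the file omits.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}
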