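## shared fixtures: a quiet configuration for deterministic dynamics checks
quiet_cfg <- function() {
  cfg <- default_config()
  cfg$noise_sd <- 0
  cfg
}

## a short auditory DMS schedule used by several tests
mini_dms_schedule <- function(cfg, stim, probe, endo = cfg$att$high) {
  list(
    list(label = "lead", dur_ms = 250, endo_a = endo, endo_v = 0.05),
    list(label = "stim", dur_ms = 250, endo_a = endo, endo_v = 0.05, aud = stim),
    list(label = "delay", dur_ms = 1000, endo_a = endo, endo_v = 0.05),
    list(label = "probe", dur_ms = 250, endo_a = endo, endo_v = 0.05, aud = probe))
}

## a fixed, mid-sized test contour
test_contour <- function(saliency = 1) {
  make_tonal_contour(data.frame(
    direction = c("up", "down"),
    start_channel = c(25, 40), end_channel = c(40, 28),
    duration_ms = c(125, 125)), saliency = saliency)
}
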