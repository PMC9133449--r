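## Network construction: module roster (shapes, Talairach metadata), edge
## table, and the mutable network object holding unit state.

#' Module roster of the combined auditory-visual network
#'
#' One row per module array: the two sweep-direction A1 submodules and three A2
#' submodules are 1 x 81 (tonotopic axis); every other module is a 9 x 9 array;
#' the two anterior-insula salience units are single microcircuits. The
#' prefrontal delay submodules D1/D2 come in `n_slots` replicas per modality
#' (the working-memory slots). Talairach labels are carried as metadata only.
#'
#' @param n_slots number of working-memory slots per modality
#' @return data.frame with columns name, class, stream, region, rows, cols,
#'   talairach
#' @export
module_roster <- function(n_slots = 3) {
  row <- function(name, class, stream, region, rows, cols, tal) {
    data.frame(name = name, class = class, stream = stream, region = region,
               rows = rows, cols = cols, talairach = tal,
               stringsAsFactors = FALSE)
  }
  slots_a <- do.call(rbind, lapply(seq_len(n_slots), function(k) rbind(
    row(paste0("D1_a", k), "D1", "aud", "D1_a", 9, 9, "(51, 12, 10)"),
    row(paste0("D2_a", k), "D2", "aud", "D2_a", 9, 9, "(32, 29, 8)"))))
  slots_v <- do.call(rbind, lapply(seq_len(n_slots), function(k) rbind(
    row(paste0("D1_v", k), "D1", "vis", "D1_v", 9, 9, "(43, 29, 21)"),
    row(paste0("D2_v", k), "D2", "vis", "D2_v", 9, 9, "(42, 39, 2)"))))
  rbind(
    row("A1_up",      "A1",   "aud", "A1",   1, 81, "(51, -24, 8)"),
    row("A1_down",    "A1",   "aud", "A1",   1, 81, "(51, -24, 8)"),
    row("A2_up",      "A2",   "aud", "A2",   1, 81, "(61, -36, 12)"),
    row("A2_down",    "A2",   "aud", "A2",   1, 81, "(61, -36, 12)"),
    row("A2_contour", "A2C",  "aud", "A2",   1, 81, "(61, -36, 12)"),
    row("ST",         "ST",   "aud", "ST",   9, 9,  "(59, -20, 1)"),
    row("MTL",        "GATE", "aud", "MTL",  9, 9,  "(22, -30, -12)"),
    row("FS_a",       "FS",   "aud", "FS_a", 9, 9,  "(47, 19, 9)"),
    slots_a,
    row("R_a",        "R",    "aud", "R_a",  9, 9,  "(29, 25, 40)"),
    row("V1",         "V1",   "vis", "V1",   9, 9,  "(14, -86, 7)"),
    row("V4",         "V4",   "vis", "V4",   9, 9,  "(30, -70, -7)"),
    row("IT",         "IT",   "vis", "IT",   9, 9,  "(31, -39, -6)"),
    row("EC",         "GATE", "vis", "EC",   9, 9,  "(25, -12, -25)"),
    row("FS_v",       "FS",   "vis", "FS_v", 9, 9,  "(35, 19, 13)"),
    slots_v,
    row("R_v",        "R",    "vis", "R_v",  9, 9,  "(33, 13, 28)"),
    row("aINS_a",     "AINS", "aud", "aINS", 1, 1,  "(48, 12, 4)"),
    row("aINS_v",     "AINS", "vis", "aINS", 1, 1,  "(48, 12, 4)")
  )
}

#' Edge table of the network
#'
#' Every inter-module connection, with its sign (inhibitory edges synapse onto
#' the receiving module's inhibitory interneurons), projection pattern and the
#' name of the scalar gain in `cfg$w` that carries its weight. The four
#' prefrontal feedback edges (`D2_v->IT`, `D2_v->V4`, `D2_a->ST`, `D2_a->A2`)
#' are individually removable for ablation experiments.
#'
#' @param n_slots number of working-memory slots per modality
#' @return data.frame with columns name, source, target, sign, pattern, w
#' @export
default_edges <- function(n_slots = 3) {
  e <- function(name, source, target, sign, pattern, w) {
    data.frame(name = name, source = source, target = target, sign = sign,
               pattern = pattern, w = w, stringsAsFactors = FALSE)
  }
  rbind(
    e("stim_a->A1",    "stim_a", "A1",     "excitatory", "topographic", "in_a"),
    e("A1_up->A2_up",  "A1_up",  "A2_up",  "excitatory", "topographic", "a1a2"),
    e("A1_down->A2_down", "A1_down", "A2_down", "excitatory", "topographic", "a1a2"),
    e("A1->A2_contour", "A1_up",  "A2_contour", "excitatory", "sigma-pi", "a1ctr"),
    e("A2_up->ST",     "A2_up",  "ST",     "excitatory", "topographic", "a2st"),
    e("A2_down->ST",   "A2_down","ST",     "excitatory", "topographic", "a2st"),
    e("A2_contour->ST","A2_contour", "ST", "excitatory", "topographic", "ctrst"),
    e("ST->MTL",       "ST",     "MTL",    "excitatory", "diffuse",     "gate_a"),
    e("MTL<->MTL",     "MTL",    "MTL",    "inhibitory", "cross-group", "gatex_a"),
    e("ST->D1_a",      "ST",     "D1_a",   "excitatory", "gated",       "enc_a"),
    e("ST->FS_a",      "ST",     "FS_a",   "excitatory", "topographic", "fs_a"),
    e("D1_a->D2_a",    "D1_a",   "D2_a",   "excitatory", "topographic", "d1d2_a"),
    e("D2_a->D2_a",    "D2_a",   "D2_a",   "excitatory", "topographic", "d2d2_a"),
    e("D2_a->D1_a",    "D2_a",   "D1_a",   "excitatory", "topographic", "d2d1_a"),
    e("FSxD2_a->R_a",  "FS_a",   "R_a",    "excitatory", "sigma-pi",    "r_a"),
    e("D2_a->MTL",     "D2_a",   "MTL",    "inhibitory", "gating-reset", "gatex_a"),
    e("D2_a->ST",      "D2_a",   "ST",     "excitatory", "topographic", "fb_st"),
    e("D2_a->A2",      "D2_a",   "A2_up",  "excitatory", "topographic", "fb_a2"),
    e("ST->aINS_a",    "ST",     "aINS_a", "excitatory", "diffuse",     "ains_a"),
    e("ATT_a->D2_a",   "ATT_a",  "D2_a",   "excitatory", "diffuse",     "att_a"),
    e("stim_v->V1",    "stim_v", "V1",     "excitatory", "topographic", "in_v"),
    e("V1->V4",        "V1",     "V4",     "excitatory", "topographic", "v1v4"),
    e("V4->IT",        "V4",     "IT",     "excitatory", "topographic", "v4it"),
    e("IT->EC",        "IT",     "EC",     "excitatory", "diffuse",     "gate_v"),
    e("EC<->EC",       "EC",     "EC",     "inhibitory", "cross-group", "gatex_v"),
    e("IT->D1_v",      "IT",     "D1_v",   "excitatory", "gated",       "enc_v"),
    e("IT->FS_v",      "IT",     "FS_v",   "excitatory", "topographic", "fs_v"),
    e("D1_v->D2_v",    "D1_v",   "D2_v",   "excitatory", "topographic", "d1d2_v"),
    e("D2_v->D2_v",    "D2_v",   "D2_v",   "excitatory", "topographic", "d2d2_v"),
    e("D2_v->D1_v",    "D2_v",   "D1_v",   "excitatory", "topographic", "d2d1_v"),
    e("FSxD2_v->R_v",  "FS_v",   "R_v",    "excitatory", "sigma-pi",    "r_v"),
    e("D2_v->EC",      "D2_v",   "EC",     "inhibitory", "gating-reset", "gatex_v"),
    e("D2_v->IT",      "D2_v",   "IT",     "excitatory", "topographic", "fb_it"),
    e("D2_v->V4",      "D2_v",   "V4",     "excitatory", "topographic", "fb_v4"),
    e("IT->aINS_v",    "IT",     "aINS_v", "excitatory", "diffuse",     "ains_v"),
    e("aINS_v->aINS_a","aINS_v", "aINS_a", "inhibitory", "topographic", "ains_x"),
    e("aINS_a->aINS_v","aINS_a", "aINS_v", "inhibitory", "topographic", "ains_x"),
    e("ATT_v->D2_v",   "ATT_v",  "D2_v",   "excitatory", "diffuse",     "att_v")
  )
}

#' Build a wired network
#'
#' Creates the mutable simulation object: unit state (E and I activity per
#' module), resolved edge weights, gating state for the MTL/EC winner-take-all
#' groups, and the exogenous-attention smoothing buffers.
#'
#' @param cfg configuration list, see [default_config()]
#' @param edges edge table; defaults to [default_edges()]. An empty edge table
#'   is an error.
#' @param n_slots number of working-memory slots per modality
#' @return an environment of class `avwm_network`
#' @export
build_network <- function(cfg = default_config(), edges = default_edges(),
                          n_slots = 3) {
  if (is.null(edges) || nrow(edges) == 0) stop("the network needs a non-empty edge list")
  roster <- module_roster(n_slots)
  known <- c(roster$name, "A1", "A2_up", "stim_a", "stim_v", "ATT_a", "ATT_v",
             "D1_a", "D2_a", "D1_v", "D2_v")
  bad <- setdiff(unique(c(edges$source, edges$target)), known)
  if (length(bad)) stop("unknown module name in edge list: ", paste(bad, collapse = ", "))
  missing_w <- setdiff(edges$w, names(cfg$w))
  if (length(missing_w)) stop("edge weight keys missing from cfg$w: ",
                              paste(missing_w, collapse = ", "))

  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  net$roster <- roster
  net$edges <- edges
  net$n_slots <- n_slots
  ## resolved weight of every edge (possibly subject-perturbed or ablated)
  w <- unlist(cfg$w[edges$w])
  names(w) <- edges$name
  net$W <- w
  ## per-module unit parameters resolved once
  uc <- cfg$unit_common
  net$P <- lapply(seq_len(nrow(roster)), function(i) {
    cl <- cfg$units[[roster$class[i]]]
    list(K = cl$K, phi = cl$phi, rho = cl$rho,
         K_i = cl$K_i %||% uc$K_i, phi_i = cl$phi_i %||% uc$phi_i,
         wie = cl$wie %||% uc$wie, wei = cl$wei %||% uc$wei,
         delta = cfg$delta)
  })
  names(net$P) <- roster$name
  net$Pm <- do.call(rbind, lapply(net$P, function(p)
    c(K = p$K, phi = p$phi, rho = p$rho, K_i = p$K_i, phi_i = p$phi_i,
      wie = p$wie, wei = p$wei, delta = p$delta)))
  reset_network(net)
  class(net) <- "avwm_network"
  net
}

#' Reset a network to its rest state
#'
#' Zeroes all unit activity, clears the gating groups' used flags, the onset
#' differentiator traces, the contour coincidence traces and the
#' exogenous-attention smoothing buffers.
#'
#' @param net an `avwm_network`
#' @export
reset_network <- function(net) {
  net$E <- lapply(seq_len(nrow(net$roster)), function(i)
    numeric(net$roster$rows[i] * net$roster$cols[i]))
  names(net$E) <- net$roster$name
  net$I <- net$E
  ng <- net$cfg$gating$n_groups
  net$gate <- list(
    aud = list(used = rep(FALSE, ng), st_trace = 0, refract = 0L),
    vis = list(used = rep(FALSE, ng), st_trace = 0, refract = 0L))
  net$ctr_trace_up <- numeric(81)
  net$ctr_trace_down <- numeric(81)
  nbuf <- max(1L, round(net$cfg$exo$smooth_ms / net$cfg$dt_ms))
  net$exo_buf_a <- numeric(nbuf)
  net$exo_buf_v <- numeric(nbuf)
  net$exo_ptr <- 0L
  net$exo_a <- 0
  net$exo_v <- 0
  invisible(net)
}

#' Remove (ablate) edges from a network
#'
#' Sets the named edges' weights to zero. Used for the feedback-ablation
#' experiment (removing `D2_v->IT`, `D2_v->V4`, `D2_a->ST`, `D2_a->A2`).
#'
#' @param net an `avwm_network`
#' @param names character vector of edge names (see [default_edges()])
#' @export
remove_edges <- function(net, names) {
  bad <- setdiff(names, names(net$W))
  if (length(bad)) stop("no such edge: ", paste(bad, collapse = ", "))
  net$W[names] <- 0
  invisible(net)
}

#' @export
print.avwm_network <- function(x, ...) {
  cat("Auditory-visual working-memory network\n")
  cat("  modules:", nrow(x$roster), " units:",
      sum(x$roster$rows * x$roster$cols), "\n")
  cat("  edges:", nrow(x$edges),
      " (", sum(x$W == 0), "ablated )\n")
  cat("  slots per modality:", x$n_slots, "\n")
  invisible(x)
}

## strength of a working-memory slot: mean of the top-k unit activities
slot_strength <- function(E, top = 9) {
  n <- length(E)
  if (n <= top) return(sum(E) / n)
  s <- sort.int(E, partial = n - top + 1L)
  sum(s[(n - top + 1L):n]) / top
}
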