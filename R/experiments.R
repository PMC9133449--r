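## Cohort generation and the full simulated experiments: task accuracies,
## the working-memory load effect, the saliency switch threshold, and the
## feedback-ablation control.

#' Create a cohort of simulated subjects
#'
#' Subjects differ by a small Gaussian multiplicative perturbation of every
#' inter-module connection weight (intra-microcircuit weights are untouched).
#' Perturbed weights are kept positive. Each subject carries its own derived
#' seed so any subject (and any trial within a subject) is re-runnable in
#' isolation.
#'
#' @param cfg base configuration
#' @param n_subjects number of subjects
#' @param sigma relative sd of the weight perturbation (>= 0)
#' @param master_seed master RNG seed
#' @return object of class `avwm_cohort`: list of per-subject weight vectors
#'   and seeds
#' @export
make_subjects <- function(cfg = default_config(),
                          n_subjects = cfg$cohort$n_subjects,
                          sigma = cfg$cohort$sigma, master_seed = 1) {
  if (sigma < 0) stop("sigma must be nonnegative")
  edges <- default_edges()
  base_w <- unlist(cfg$w[edges$w])
  names(base_w) <- edges$name
  subjects <- lapply(seq_len(n_subjects), function(s) {
    seed <- derive_seed(master_seed, s)
    set.seed(seed)
    w <- base_w * (1 + stats::rnorm(length(base_w), 0, sigma))
    w <- pmax(w, 0.05 * base_w)
    list(id = s, seed = seed, W = w)
  })
  structure(list(cfg = cfg, sigma = sigma, master_seed = master_seed,
                 subjects = subjects),
            class = "avwm_cohort")
}

subject_network <- function(cohort, s, ablate = NULL) {
  net <- build_network(cohort$cfg)
  net$W[names(cohort$subjects[[s]]$W)] <- cohort$subjects[[s]]$W
  if (!is.null(ablate)) remove_edges(net, ablate)
  net
}

#' @export
print.avwm_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d subjects, weight jitter sigma = %.3f\n",
              length(x$subjects), x$sigma))
  invisible(x)
}

draw_trial_stimuli <- function(task, cfg, seed, modality = "aud") {
  set.seed(seed)
  draw <- function() if (modality == "aud") random_contour(cfg = cfg)
                     else random_shape(cfg = cfg)
  if (task == "sternberg") {
    items <- list(draw(), draw(), draw())
    ## redraw overlapping list items so the three representations are distinct
    for (i in 2:3) {
      for (tries in 1:50) {
        ok <- all(vapply(items[seq_len(i - 1)], function(p)
          pattern_overlap(items[[i]], p) <= cfg$stimuli$overlap_max, logical(1)))
        if (ok) break
        items[[i]] <- draw()
      }
    }
    items
  } else if (task == "dms_distractors") {
    tgt <- draw()
    ## task-irrelevant distractors are somewhat less salient than the target
    dsal <- cfg$stimuli$task_distractor_saliency %||% 1
    d <- list(apply_saliency(draw(), dsal), apply_saliency(draw(), dsal))
    ## distractors share little with the target so the match detector is not
    ## already half-driven when the probe arrives
    for (j in 1:2) {
      for (tries in 1:50) {
        if (pattern_overlap(d[[j]], tgt) <= min(cfg$stimuli$overlap_max, 0.15)) break
        d[[j]] <- draw()
      }
    }
    list(target = tgt, distractors = d)
  } else {
    draw()
  }
}

run_one_trial <- function(task, net, cfg, trial_seed, match) {
  if (task == "dms") {
    s <- draw_trial_stimuli("dms", cfg, trial_seed)
    p <- make_probe(s, match, seed = trial_seed + 1L, cfg = cfg)
    run_dms_trial(net, s, p, match, seed = trial_seed + 2L)
  } else if (task == "dms_distractors") {
    d <- draw_trial_stimuli("dms_distractors", cfg, trial_seed)
    p <- make_probe(d$target, match, seed = trial_seed + 1L, cfg = cfg,
                    avoid = d$distractors)
    run_distractor_trial(net, d$target, d$distractors, p, match,
                         seed = trial_seed + 2L)
  } else if (task == "sternberg") {
    items <- draw_trial_stimuli("sternberg", cfg, trial_seed)
    p <- if (match) items[[sample(3, 1)]]
         else make_probe(items[[1]], FALSE, seed = trial_seed + 1L, cfg = cfg,
                         avoid = items[-1], lure = FALSE)
    run_sternberg_trial(net, items, p, match, seed = trial_seed + 2L)
  } else stop("unknown task: ", task)
}

#' Run a simulated experiment over a cohort
#'
#' For the three auditory short-term-memory tasks (`"dms"`,
#' `"dms_distractors"`, `"sternberg"`): `n_trials` per subject, half match /
#' half nonmatch in shuffled order, accuracy scored from the response module.
#' For `"load"`: `n_trials` runs per subject, each run executing the
#' visual-memory + auditory-distractor trial at loads 1, 2 and 3 with shared
#' stimuli and noise seed (a matched within-run comparison).
#'
#' @param task one of `"dms"`, `"dms_distractors"`, `"sternberg"`, `"load"`
#' @param cohort an `avwm_cohort`
#' @param n_trials trials (or load-runs) per subject
#' @param ablate optional character vector of edges removed from every subject
#' @return object of class `avwm_experiment`: per-trial table and aggregates
#' @export
run_experiment <- function(task, cohort, n_trials = cohort$cfg$cohort$n_trials,
                           ablate = NULL) {
  cfg <- cohort$cfg
  rows <- list()
  for (s in seq_along(cohort$subjects)) {
    net <- subject_network(cohort, s, ablate = ablate)
    sseed <- cohort$subjects[[s]]$seed
    if (task == "load") {
      for (r in seq_len(n_trials)) {
        tseed <- derive_seed(sseed, r)
        set.seed(tseed)
        items <- list(random_shape(cfg = cfg), random_shape(cfg = cfg),
                      random_shape(cfg = cfg))
        distractor <- random_contour(cfg = cfg,
                                     saliency = cfg$bimodal$distractor_saliency)
        match <- r %% 2 == 0
        probe <- make_probe(items[[1]], match, seed = tseed + 1L, cfg = cfg,
                            avoid = items[-1])
        for (load in 1:3) {
          tr <- run_load_trial(net, items[seq_len(load)], distractor, probe,
                               match, seed = tseed + 2L)
          rows[[length(rows) + 1]] <- data.frame(
            subject = s, trial = r, load = load, match = match,
            responded = tr$responded, correct = tr$correct,
            probe_stat = tr$probe_stat,
            exo_a = tr$exo_a_distractor, exo_v = tr$exo_v_distractor,
            st = tr$st_distractor)
        }
      }
    } else {
      set.seed(derive_seed(sseed, 0L))
      matches <- sample(rep(c(TRUE, FALSE), length.out = n_trials))
      for (r in seq_len(n_trials)) {
        tseed <- derive_seed(sseed, r)
        tr <- run_one_trial(task, net, cfg, tseed, matches[r])
        rows[[length(rows) + 1]] <- data.frame(
          subject = s, trial = r, match = matches[r],
          responded = tr$responded, correct = tr$correct,
          probe_stat = tr$probe_stat)
      }
    }
  }
  trials <- do.call(rbind, rows)
  res <- list(task = task, trials = trials, n_subjects = length(cohort$subjects),
              n_trials = n_trials, ablated = ablate)
  if (task != "load") {
    per_subject <- tapply(trials$correct, trials$subject, function(x) 100 * mean(x))
    res$accuracy_mean <- mean(per_subject)
    res$accuracy_sd <- stats::sd(per_subject)
    res$per_subject <- as.vector(per_subject)
  }
  class(res) <- "avwm_experiment"
  res
}

#' @export
print.avwm_experiment <- function(x, ...) {
  cat("Simulated experiment:", x$task, "\n")
  cat(sprintf("  %d subjects x %d trials\n", x$n_subjects, x$n_trials))
  if (!is.null(x$accuracy_mean)) {
    cat(sprintf("  accuracy %.1f%% (SD %.2f across subjects)\n",
                x$accuracy_mean, x$accuracy_sd))
  }
  if (!is.null(x$ablated)) cat("  ablated edges:", paste(x$ablated, collapse = ", "), "\n")
  invisible(x)
}

#' Working-memory load-effect statistics
#'
#' From a `"load"` experiment: per subject, the distractor-epoch exogenous
#' auditory attention and ST activity are averaged over runs at each load;
#' the statistics are the percent changes at loads 2 and 3 relative to load 1,
#' tested against zero with a one-tailed one-sample t-test (df = subjects - 1;
#' the hypothesized direction is a reduction).
#'
#' @param result an `avwm_experiment` from `run_experiment("load", ...)`
#' @return data.frame with columns measure, contrast, mean, sd, t, df, p
#' @export
load_effect_stats <- function(result) {
  tr <- result$trials
  if (length(unique(tr$subject)) < 2) stop("need at least two subjects")
  per <- stats::aggregate(cbind(exo_a, st) ~ subject + load, tr, mean)
  stats_for <- function(col) {
    w <- stats::reshape(per[, c("subject", "load", col)], idvar = "subject",
                        timevar = "load", direction = "wide")
    base <- w[[paste0(col, ".1")]]
    do.call(rbind, lapply(2:3, function(L) {
      chg <- 100 * (w[[paste0(col, ".", L)]] - base) / base
      m <- mean(chg); s <- stats::sd(chg); n <- length(chg)
      tv <- if (s > 0) m / (s / sqrt(n)) else 0
      data.frame(measure = if (col == "exo_a") "auditory_attention" else "st_activity",
                 contrast = paste0(L, "v1"), mean = m, sd = s,
                 t = tv, df = n - 1,
                 p = if (s > 0) stats::pt(tv, n - 1) else 0.5)
    }))
  }
  rbind(stats_for("exo_a"), stats_for("st"))
}

#' Find the intersensory attention-switch threshold
#'
#' With endogenous attention set to the auditory modality (high) and visual
#' attention low, bimodal trials are run with fixed auditory saliency and
#' visual saliency scanned over a grid. The switch point is the smallest
#' visual saliency at which mean exogenous visual attention exceeds auditory
#' during the stimulus epoch AND the visual working memory encodes the
#' stimulus. Returns `Inf` when no grid value switches.
#'
#' @param net an `avwm_network` (a single representative subject)
#' @param grid visual saliency grid
#' @param seed integer seed
#' @param n_reps trials averaged per grid point
#' @return list with `threshold` and the per-grid-point summary table
#' @export
find_switch_threshold <- function(net, grid = seq(0.1, 1.0, by = 0.1),
                                  seed = 1, n_reps = 3) {
  cfg <- net$cfg
  rows <- lapply(seq_along(grid), function(i) {
    svis <- grid[i]
    reps <- lapply(seq_len(n_reps), function(r) {
      tseed <- derive_seed(seed, i * 100 + r)
      set.seed(tseed)
      ## mid-sized reference contours: the competition is about saliency, so
      ## keep the auditory object's spectral extent in a narrow band
      repeat {
        aud <- random_contour(cfg = cfg, saliency = cfg$bimodal$aud_saliency)
        if (sum(stimulus_pattern(aud)) %in% 12:16) break
      }
      vis <- random_shape(cfg = cfg, saliency = svis)
      run_bimodal_trial(net, aud, vis, seed = tseed + 1L,
                        endo_a = cfg$att$high, endo_v = cfg$att$low)
    })
    data.frame(saliency = svis,
               exo_v = mean(vapply(reps, `[[`, numeric(1), "exo_v")),
               exo_a = mean(vapply(reps, `[[`, numeric(1), "exo_a")),
               encoded_v = mean(vapply(reps, function(x) x$encoded_v, logical(1))),
               encoded_a = mean(vapply(reps, function(x) x$encoded_a, logical(1))))
  })
  tab <- do.call(rbind, rows)
  switched <- tab$exo_v > tab$exo_a & tab$encoded_v >= 0.4
  thr <- if (any(switched)) tab$saliency[which(switched)[1]] else Inf
  list(threshold = thr, table = tab)
}

#' Ablate prefrontal feedback and re-run the load experiment
#'
#' Removes the feedback edges from the working-memory modules to the sensory
#' hierarchy (`D2_v->IT`, `D2_v->V4`, `D2_a->ST`, `D2_a->A2`) in every subject
#' and re-runs the load experiment; used to show that the load-dependent
#' reduction of intersensory distraction depends on those feedback paths.
#'
#' @param cohort an `avwm_cohort`
#' @param edges edges to remove
#' @param n_trials runs per subject
#' @return an `avwm_experiment` (task `"load"`, with `ablated` set)
#' @export
ablate_and_rerun <- function(cohort,
                             edges = c("D2_v->IT", "D2_v->V4",
                                       "D2_a->ST", "D2_a->A2"),
                             n_trials = cohort$cfg$cohort$n_trials) {
  known <- default_edges()$name
  bad <- setdiff(edges, known)
  if (length(bad)) stop("no such edge: ", paste(bad, collapse = ", "))
  run_experiment("load", cohort, n_trials = n_trials, ablate = edges)
}
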