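---
title: "The avwm model: dynamics, attention, working memory and simulated fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The avwm model: dynamics, attention, working memory and simulated fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avwm)
```

## Scope and assumptions

`avwm` is a large-scale neural network simulation of auditory-visual object
short-term memory and intersensory attention. It makes three core modeling
commitments:

1. **Rate-coded microcircuits.** Every unit is a Wilson-Cowan pair (one
   excitatory, one inhibitory population), a caricature of a cortical column.
   Activities are normalized rates in [0, 1]; there are no spikes,
   conductances, or transmission delays between nodes (lags arise only from
   the sigmoidal rise times of the units themselves).
2. **A fixed anatomical macro-architecture.** Two feedforward object-processing
   hierarchies (tonotopic A1 → A2 → ST and retinotopic V1/V2 → V4 → IT), a
   gating stage per modality (MTL auditory, EC visual), prefrontal
   working-memory circuitry (FS, three D1–D2 slot replicas, R), feedback from
   D2 to the sensory integrators, and a mutually inhibitory anterior-insula
   pair computing exogenous attention. Talairach coordinates are carried as
   metadata labels only.
3. **Attention as a scalar bias.** Endogenous (task-set) attention is a
   per-epoch scalar; exogenous attention is an affine readout of the aINS
   units; their sum, clipped at `att$max`, is injected uniformly into the D2
   units of the corresponding modality. Working memory ignition, maintenance
   and protection all derive from how this bias interacts with the D1–D2
   attractor.

Background cortical input is modeled as i.i.d. Gaussian noise (sd
`noise_sd = 0.06`) added to every excitatory input at every step, standing in
for the fluctuating drive a whole-brain embedding would provide.

## Unit dynamics and numerical scheme

Each module array advances by forward Euler,
$$E \leftarrow E + \rho\,\Delta t\,[\,S(\mathrm{in}_E)(1-E) - \delta E\,],
\qquad S(x) = \frac{1}{1+e^{-K(x-\phi)}},$$
with one unit time equal to `tau_ms` = 50 ms and `dt_ms` = 5 ms, i.e.
$\Delta t = 0.1$. For $\Delta t \le 1$ and $\delta\,\Delta t \le 1$ the update
cannot leave [0, 1] (the shunting term caps growth, linear decay cannot cross
zero), which the property suite verifies under random drives. A trajectory
integrated at 5 ms differs from a 0.05 ms reference by less than $10^{-2}$,
and constant-input steady states agree with the scalar fixed-point equation
solved by root finding to better than $10^{-3}$.

The per-class constants (gain $K$, threshold $\phi$, rate multiplier $\rho$)
shape the functional roles: sensory relays are fast with high thresholds (so
spontaneous rates stay near zero and the loudness/luminance of a stimulus
maps onto graded response amplitudes); ST and IT are slow integrators
($\rho = 0.45$) that accumulate a sweep into a stable spatial pattern; the D2
delay units are steep ($K = 30$, $\phi = 0.72$) so that together with D2
self-excitation and the D1 loop they form a bistable attractor per unit.

## Working-memory mechanics

**Ignition.** A stimulus pattern reaches ST (IT), opens a gate, and is pushed
into the D1 units of one slot. D2 ignites only if the gated D1 drive and the
attention bias together exceed the attractor's ignition threshold — roughly
an attention level of 0.2. This is why a 0.3 task-set encodes reliably, a
lone 0.05 or 0.1 level never encodes, and a bimodal 0.1 level encodes only
with exogenous support.

**Maintenance.** Once ignited, the D1–D2 loop (`d2d1 = 1.44`, `d2d2 = 0.60`)
is self-sustaining even at the low attention level, so a stored item survives
the attention drop of the distractor task; items are erased only between
trials when the network is reset.

**Gating.** The MTL/EC groups are a winner-take-all circuit driven by an
onset detector (the deviation of mean A2/V4 activity from its own 150 ms
running average — a phasic stage unaffected by memory feedback, so a new item
remains visible against any delay activity). The winning unused group passes
the ST (IT) pattern to its slot; a storage confirmation (slot strength
crossing `conf_thresh`) marks the group used and pauses gating for 350 ms,
implementing the use-once rule and the three-item capacity. Exact ties go to
the lowest group index.

**Readout.** R units receive the product of FS (the current sensory pattern)
and the summed D2 slots — a sigma-pi style coincidence detector in the
lineage of this model family. The behavioral statistic is the mean R activity
over the probe epoch plus a 200 ms tail (the sensory chain lags the probe by
150-250 ms, slightly more when the prefrontal feedback that pre-depolarizes
the stored ST representation is removed), baseline-corrected by the preceding
100 ms; a response is emitted when it exceeds `response_threshold = 0.026`. Behavioral errors arise from the
heterogeneity of the stimulus library (sparser patterns yield weaker
statistics), input noise, lure probes that share channels with the target,
overlap between a probe and the union of stored items (false alarms grow
with memory load), and occasional encoding failures of later list items.
These are the only error sources; no label noise is added anywhere.

## Attention competition

The aINS pair receives the module-mean activity of IT and ST (already scaled
by stimulus salience) and inhibits one another through cross-driven
interneurons (`wei = 0`, shallow `K_i`), which makes the suppression roughly
proportional to the opponent's activity rather than saturating at its own.
Exogenous attention is a per-modality affine map of the aINS output, smoothed
by a 50 ms moving average; the visual and auditory maps are calibrated
separately (`gain_v = 1.0`, `gain_a = 0.72`) because the two streams deliver
different mean drives to the pair. A lone maximal-salience stimulus yields an
exogenous level near 0.25, enough to ignite a slot on top of a low task set.

Attention capture is a bootstrap: a salient visual stimulus raises aINS-v,
which suppresses aINS-a and lifts visual attention past the ignition
threshold; the encoded item's feedback (D2 → IT) then sustains aINS-v. With
the default calibration the bootstrap first succeeds at visual saliency 0.8
against a 0.65-salience auditory stream under an auditory task set.

The working-memory load effect follows from the same wiring: stored visual
items tonically drive IT via D2 → IT feedback, raising aINS-v and suppressing
aINS-a, so an auditory distractor evokes less auditory attention (and, via
weaker auditory encoding, less ST feedback) at higher visual loads. Removing
the D2 → IT/ST and D2 → V4/A2 edges abolishes the effect while leaving
single-item performance essentially intact.

## Stimuli

Tonal contours are 2–3 channel-continuous frequency sweeps of 200–300 ms
total duration on the 81-channel tonotopic axis, rendered as a moving
Gaussian bump (sd 1.5 channels) routed to the upward- or downward-selective
A1 submodule; sweep extents of 6–20 channels give a library with a broad
range of pattern widths, which is the main source of graded behavioral
difficulty. Visual shapes are unions of 2–3 straight strokes on the 9×9 grid,
constrained to 11–14 active elements so that figural salience is carried by
the luminance scalar rather than by accidental size differences. Nonmatch
probes for the match-to-sample tasks are lures (minimum Jaccard overlap 0.25
with the target, maximum 0.5), as in standard DMS designs; Sternberg foils
are ordinary library draws constrained only by the ceiling. Controls for the
fMRI block design are energy-matched (within 10%) noise patterns and
degraded shapes.

What the generator does **not** emulate: acoustic waveforms, cochlear or
retinal preprocessing, spatial structure beyond the feature axes, semantic
content, or inter-stimulus perceptual similarity structure beyond channel
overlap. Passing behavioral tests therefore demonstrate the network
mechanics, not stimulus-level realism.

## Simulated fMRI

The integrated synaptic activity of a region is the sum over its units of the
absolute synaptic inputs (all excitatory afferents, attention bias, and the
interneuron traffic; the diagnostic noise term is excluded), accumulated in
50 ms bins. These series drive a standard balloon model (κ = 0.65 s⁻¹,
γ = 0.41 s⁻¹, τ = 0.98 s, α = 0.32, E₀ = 0.34, V₀ = 0.02, k₁ = 7E₀, k₂ = 2,
k₃ = 2E₀ − 0.2) integrated by forward Euler at 10 ms, after an affine
normalization that maps each region's resting level to zero. BOLD is reported
in percent and resampled at TR = 1 s. The Euler integration stays within 1%
of a stiff-solver reference on bounded inputs (tested against `deSolve`).
Block designs alternate three task and three control trials with 1 s delays;
event-related designs use 2 s trials, 20 s delays and 25 s onset spacing.

## Experiment conditions and problem sizes

The simulated cohort has 10 subjects generated by multiplying every
inter-module weight by $1 + \mathcal{N}(0, 0.04)$ (microcircuit-internal
constants untouched), 20 trials per subject and task with a balanced,
shuffled match/nonmatch mix, and a master-seed → subject-seed → trial-seed
derivation so any single trial can be re-run in isolation. The load
experiment runs each subject 20 times at visual loads 1, 2 and 3 with shared
stimuli and noise seed across loads (a matched within-run comparison that
removes stimulus variance from the contrasts); contrasts are tested with
one-tailed one-sample t-tests against zero, df = 9, hypothesizing a
reduction. The ablation control in the test suite uses 8 runs per subject
since only the sign and significance of its contrasts are assessed. The
saliency scan runs three bimodal trials per grid point with mid-sized
reference contours at auditory saliency 0.65.

## Design choices made where the design was open

- **Distractor salience in the DMS-with-distractors task.** Task-irrelevant
  distractors are presented at salience 0.8 (the target at 1.0); at full
  salience they capture working memory strongly enough that the response
  module's recovery from the capture contaminates the probe readout. The
  load-experiment distractor keeps salience 1.0.
- **Epoch schedule of the distractor task.** Endogenous attention is high
  through target encoding and the first delay, drops to 0.05 from the first
  distractor onward, and re-engages at the probe. Published descriptions fix
  only the high (0.3) and low (0.05) values; dropping at distractor onset is
  the reading under which distractors disturb but cannot overwrite.
- **Attention combination.** Total bias = clip(endogenous + exogenous, 0,
  0.4). The ceiling keeps the delay attractor out of its runaway regime; the
  published account names both signals but not the rule.
- **Onset-driven gating with a storage refractory period.** Without onset
  gating, memory-driven delay activity would re-open gates and duplicate
  items across slots; the 350 ms refractory period prevents one presentation
  from consuming two groups. Stimuli arriving within the refractory window of
  a storage event are not encoded.
- **Slot wiring.** The k-th consumed gating group routes to the k-th D1/D2
  replica; winner-take-all ties break to the lowest index, so groups are
  consumed in order.
- **Per-modality exogenous gain.** The visual and auditory aINS-to-attention
  maps are separate calibration constants because the mean drives of the two
  streams differ; a common gain cannot simultaneously support visual capture
  and a graded auditory suppression.
- **Measurement windows.** The load experiment's attention measure covers the
  distractor presentation plus 500 ms (the smoothed salience signal rises and
  decays within that span); the ST measure extends to 700 ms because the
  distractor's memory-trace feedback onto ST evolves more slowly, and ST is
  reported as the distractor-evoked response above the pre-distractor
  baseline. Trials at every load are padded to the same pre-distractor
  duration so the contrasts cannot ride on the network's settling transient.
- **Independent per-modality capacities.** The auditory (MTL) and visual (EC)
  gating groups are independent three-slot pools; whether the two modalities
  share capacity is left open in the source account.

## Numerical details and degenerate inputs

Euler updates are synchronous (all inputs computed from the previous state).
Non-finite inputs abort with a diagnostic naming the module and step. An
epoch duration that is not a multiple of `dt_ms` is an error, as is a
saliency outside [0, 1], a contour channel outside [1, 81], an empty edge
list, an edge naming an unknown module, a Sternberg list or visual load
beyond the slot capacity, and a negative balloon input. A distractor
identical to the target is allowed (the probe then matches a stored item and
the trial is scored by the usual rule).

## Known limitations

- The behavioral operating points (noise amplitude, response threshold,
  stimulus-library statistics) were calibrated jointly, once, against the
  target accuracy regime; they are a package-level default, not a fit to any
  particular dataset.
- Error rates are sensitive to the stimulus generator's overlap statistics;
  changing the library changes accuracies.
- The ST load contrast is carried by the latch timing and rate of the
  distractor's working-memory trace and is numerically small (about −1%);
  its sign is robust but its magnitude sits in the lower half of the
  plausible band.
- No reaction times, no learning across trials, no long-term memory, no
  crossmodal (integrated-stream) tasks, no scanner noise or GLM stage.
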