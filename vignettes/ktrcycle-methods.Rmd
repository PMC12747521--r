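---
title: "Methods: single-cell cell-cycle analysis from KTR imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell cell-cycle analysis from KTR imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

`ktrcycle` measures cell-cycle behaviour of single cells from multichannel
time-lapse fluorescence microscopy. The cells carry four genetically encoded
reporters:

* **H2B** (nuclear marker) — segmentation and tracking;
* **CDK4/6 KTR** and **CDK2 KTR** — kinase translocation reporters whose
  phosphorylation state sets their nucleo-cytoplasmic partitioning, so the
  cytoplasm-to-nucleus (C/N) median-intensity ratio reads out kinase
  activity;
* a **Cdt1 degron** (high in G1, degraded during S, re-accumulating in G2)
  or a **Geminin degron** (APC/C substrate accumulating from G1/S), marking
  phase transitions.

The pipeline is: segmentation → cytoplasmic rings → frame linking →
mitosis detection → activity/degron traces → fate classification and phase
calling → summary statistics. A companion fixed-cell arm covers Hoechst
segmentation, EdU and phospho-Rb gating, RNA FISH puncta counting, and
live-to-fixed registration. An IC50 helper fits dose–response of S-phase
fractions.

Because no public imaging dataset accompanies the method, every stage is
validated against the package's own synthetic-data generator, which
produces traces, movies, and fixed fields with exact ground truth.

## The synthetic-data generator

`simulate_traces()` draws a lineage in which each cell is one cell-cycle
generation. Defaults are chosen to emulate asynchronously cycling breast
cancer epithelial cells imaged every 12 minutes for 48 hours:

* **Phase durations.** G1 is lognormal (mean 8 h, CV 0.3 for the parental
  preset) — the lognormal captures the long right tail characteristic of
  G1; S (8 h) and G2/M (5 h) are normal truncated at zero with small CV,
  reflecting that these phases are tightly controlled. The
  `resistant_drug_maintained` preset triples G1 (mean 24 h, CV 0.4) and
  drops the proliferating fraction to 0.9, mimicking chronic CDK4/6
  inhibition; these presets are fixed properties of the generator, not
  tuning knobs.
* **Activities.** CDK2 follows a canonical post-mitotic reset
  (C/N ≈ 0.25) with a sigmoidal rise through 1 late in G1 and a plateau
  near 2.2 before mitosis. Quiescent cells drift below 0.9. CDK4/6
  activates rapidly after mitosis and stays high. These are
  piecewise-smooth canonical curves, not a mechanistic ODE model: the
  pipeline needs controllable shapes with known boundaries, not biology.
* **Bleed-through.** The rendered raw CDK4/6 reporter equals true CDK4/6
  activity plus `alpha` x CDK2 activity (default 0.41, the MCF-7
  calibration; 0.35 is the MDA-MB-231 value), because the CDK4/6 sensor
  carries a degenerate CDK2 site and partially reports CDK2 in S/G2.
* **Divisions.** Each daughter receives a uniform fraction of the mother's
  integrated H2B drawn from 0.45–0.55; the two fractions are drawn
  independently and renormalised to sum to at most 1. Daughter nuclear
  radii are drawn around the population radius divided by sqrt(2) (nuclei
  regrow over the cycle, so sizes do not shrink generation over
  generation), and the daughter's per-pixel H2B level is set so its
  integrated signal is exactly the drawn fraction of the mother's.
  Per-cell H2B levels are otherwise static, so integrated H2B halves each
  generation rather than recovering through synthesis as it would in real
  cells — a deliberate simplification that keeps the 45–55% rule exact at
  every division while leaving later generations dimmer (a realistic
  stress on the segmenter).
* **Motion.** Cells perform a reflected random walk (per-axis step SD
  1.5 µm/frame) with excluded volume: nuclei cannot interpenetrate, and
  overlapping pairs are relaxed apart each frame. Without excluded volume
  the renderer produces physically impossible merged nuclei whose later
  separation is indistinguishable from a division — real interphase nuclei
  do not overlap at the confluencies this kind of experiment uses.
* **Optics.** Rendering uses hard-disk nuclei and a cytoplasmic annulus
  whose per-pixel level is the nuclear level times the true activity, so
  the ring-median/nuclear-median ratio of an isolated cell equals the
  prescribed activity up to discretisation. Image formation is
  `(signal + background_offset) x bias + noise`, with the illumination
  bias a low-order radial polynomial (matching what flat-field correction
  assumes) and i.i.d. Gaussian read noise.

What the generator does **not** emulate: apoptosis and cell loss, focus
drift, photobleaching, segmentation-adversarial nuclear shapes (all nuclei
are discs), autofluorescence structure, or mechanistic Rb/E2F coupling
between the reporters. Passing the synthetic acceptance suite therefore
demonstrates correctness of the measurement pipeline under the stated
optical model, not robustness to every pathology of real microscopy.

## Segmentation choices

* **Live (H2B):** scale-normalised Laplacian-of-Gaussian blob detection
  over nuclear radii 4–15 µm (three scales, FFT-based with cached kernel
  spectra), and marker-based watershed (`EBImage::propagate`) from the blob
  maxima. The foreground threshold on the background-corrected frame is the
  frame median plus 6 MAD: background pixels dominate and sit near zero, so
  this keeps any nucleus bright enough to quantify, whereas a two-class
  (Otsu-style) split loses dim nuclei whenever a bright sub-population
  dominates the variance — which happens as soon as H2B expression varies
  across the population. Maxima closer than 1.5x the
  smallest admissible radius are non-maximum-suppressed: two seeds that
  close cannot be distinct nuclei, and without suppression noise ripples
  on the blob-response plateau shatter nuclei into fragments. Objects
  outside 30–400 µm² are removed. The area bounds and scale range are
  package defaults (the method's description names no values).
* **Fixed (Hoechst):** the histogram-curvature threshold is
  operationalised as the maximum of the discrete second difference of the
  Gaussian-smoothed log10 histogram, taken on a log-count scale, beyond
  the background mode. On log counts a Gaussian-like background peak is a
  parabola of constant curvature, so the curvature maximum falls where
  the tail meets the empty valley floor — the foot of the background
  peak — instead of partway down the shoulder, keeping essentially all
  background pixels below threshold. The exact curvature definition in
  the original method is not published; this stand-in is documented and
  the smoothing bandwidth configurable. A flat or unimodal histogram
  (negligible mass above the candidate threshold) falls back to a
  quantile threshold with a warning. Touching nuclei are split by
  distance-transform watershed.
* **Background:** subtract the 50th percentile of non-nuclear pixels.
  Negative values are retained — downstream summaries are medians and
  clipping would bias ratios.
* **Rings:** cytoplasmic signal is the median in an annulus 0.65–3.25 µm
  outside the nuclear boundary (Euclidean distance transform, computed in
  per-cell crops). Rings exclude all nuclear pixels of every cell; cells
  whose rings share pixels are excluded from ratio quantification, as are
  border-truncated cells (the border rule is a package decision).

## Tracking and mitosis detection

Linking is greedy nearest-neighbour on the distance to each track's
velocity-predicted position, gated at `max_step_um`, followed by a
deflection-resolution pass that reassigns detections when a swap lowers
the total cost. Ties break by smaller displacement then smaller label id,
making runs reproducible. Track fragments separated by at most
`max_gap_frames` are bridged with interpolated centroids (`gap_filled`
flag; intensities stay missing).

Mitoses use the daughter H2B-intensity rule: a mother ending at frame *t*
with exactly two tracks starting at *t*+1 within 25 µm (configurable;
"adjacent" is not quantified in the method description), each carrying
45–55% of the mother's integrated H2B (area x median — robust to daughter
size asymmetry). Because a nearest-neighbour linker frequently walks the
mother track straight into one daughter, a first pass splits tracks whose
integrated H2B halves between consecutive frames while a second
daughter-like track appears alongside. Measured fractions are compared
with a small tolerance (`fraction_tol = 0.02`) beyond the configured
range, sized a priori to the discretisation error of pixel-counted areas
(1–2% per nucleus); the biological rule itself stays 45–55%.

## Fate classification and phase calling

A cell is **proliferating** (or a **persister** under drug combinations)
when CDK2 exceeds 1 continuously for strictly more than 2 h within the
30–48 h window. "Sustained" is read literally: a run of k frames counts
as k x 12 min (so at least 11 frames), a single sub-threshold frame breaks
the run, and gap-filled frames join a run only when both measured flanks
are above threshold. The threshold applies to raw traces by default;
3-frame median smoothing is available but off, since the rule's published
form does not mention smoothing. Cells whose traces do not cover the
window are unclassified rather than quiescent.

Phase boundaries come from the degron: sustained degradation is
established when the trace falls below `f_drop = 0.5` of its running
pre-drop maximum for at least `k = 3` frames, and the G1/S boundary is
then placed at the degradation onset — the last frame still within 10% of
the pre-drop maximum. S/G2 is the analogous re-accumulation onset after a
sustained rise above `r_rise = 2` x the running trough. The deep-crossing
/ onset split makes the call robust to noise while keeping the boundary
at the kinetic transition; the constants are package defaults (none are
published) and all are exposed. Durations follow from the boundaries and
the next anaphase, so G1 + S + G2/M equals the intermitotic time by
construction wherever all are defined.

## Fixed-cell arm

EdU and p-Rb classification threshold at the valley between the two
dominant modes of a fixed-bandwidth (Silverman) KDE of the log10 intensity
(p-Rb is first normalised to total Rb). Candidate modes below 5% of the
dominant mode's density, or valleys shallower than 20% of the smaller
mode, are treated as KDE ripples: such distributions are an error
instructing a manual threshold rather than a silently arbitrary split. FISH puncta are isolated by a white
top-hat with a 4 µm circular kernel — which also cancels any additive
offset — thresholded at 5x the MAD of the filtered image (the kernel is
published, the threshold is a package default), and counted per cell
within the nucleus dilated by 50 µm; cells whose dilated territories touch
are excluded. FISH z-stacks are assumed maximum-projected upstream.
Live-to-fixed registration maximises FFT cross-correlation of the nuclear
channels with quadratic sub-pixel refinement; cells match by mutual
nearest centroids within 10 µm (the matching radius is a package default).

## IC50

`ic50_from_sphase()` fits a four-parameter logistic to the S-phase
fraction relative to the drug-naive control with `minpack.lm::nlsLM` and
reports the inflection dose as the half-maximal inhibitory concentration,
with its standard error and a normal 95% CI. A response that does not
decrease is an explicit error, not a fit.

## Numerical and degenerate-input policy

* All automatic thresholds (foreground MAD, histogram curvature, KDE
  valley, puncta MAD) are echoed or returned so analyses are auditable.
* Ratios are missing — never infinite — when the nuclear median is at or
  below the signal floor, or when the ring is overlap/border-flagged.
* Empty frames segment to empty label maps; empty groups are dropped from
  summaries with warnings; a single-cell group reports an undefined CI.
* 95% CIs are mean ± 1.96 SE throughout (the normal approximation).
* Determinism: the generator consumes only its `rng_seed`; identical
  configurations are bit-identical. Assignment ties in tracking break by
  displacement, then id.

## Problem sizes used in validation

The test-suite and acceptance script sizes were chosen as the smallest
cohorts at which the Monte-Carlo error of each check is comfortably below
its tolerance: 10,000 random traces for the classification oracle; 500
cycling cells for boundary recovery; a 100-founder, 241-frame (48 h at
12 min) movie for tracking; two image-level conditions of 120 and 140
founders (analysed cells born early enough that a 30 h observation window
guarantees uncensored G1 measurement) for the threefold-G1 recovery; 1000
cells for each bimodal classifier. The acceptance script runs the same
computations at moderately reduced movie sizes.

## Known limitations

* The deflection-bridging tracker reimplements the described behaviour
  (bridging plus deflection resolution); it is not a port of the original
  implementation, whose exact cost function is unpublished.
* The histogram-curvature threshold and the degron boundary constants are
  documented stand-ins for unpublished specifics.
* The C/N "activity unit" is taken as ratio = 1; no biochemical
  calibration is implied.
* Phase durations from a finite movie are right-censored; analyses here
  restrict to cells with a guaranteed observation window, and users of
  real data should do likewise or model the censoring.
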