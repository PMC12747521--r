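# ktrcycle

Single-cell cell-cycle analysis from kinase-translocation-reporter (KTR)
time-lapse imaging.

## The problem

CDK4/6 inhibitors (e.g. palbociclib) are standard of care in HR+/HER2−
breast cancer, and a central question in studying resistance is not just
*whether* resistant cells proliferate under drug, but *how fast they move
through each cell-cycle phase* and *what fraction commit to the cycle at
all*. Answering that requires following thousands of individual cells
through mitosis and reading out kinase activity and phase transitions
cell by cell. `ktrcycle` implements that measurement pipeline for the
standard four-reporter design:

* **H2B** nuclear marker — segmentation, tracking, mitosis detection;
* **CDK4/6 KTR** and **CDK2 KTR** — kinase activity as the
  cytoplasm/nucleus (C/N) median-intensity ratio; the CDK4/6 reporter is
  corrected for CDK2 bleed-through,
  `CDK4/6 activity = (CDK4/6 reporter) − α · (CDK2 reporter)`
  with α = 0.41 (MCF-7) or 0.35 (MDA-MB-231);
* **Cdt1 or Geminin degron** — G1/S and S/G2 boundaries, hence G1, S,
  G2/M durations and the intermitotic time (IMT = G1 + S + G2/M).

Cells are classified **proliferating** (or **persister** under drug
combinations) when CDK2 > 1 continuously for > 2 h within the 30–48 h
analysis window. A fixed-cell arm adds Hoechst segmentation
(histogram-curvature threshold), EdU S-phase gating, p-Rb/total-Rb
classification, RNA FISH puncta counting (4 µm top-hat, 50 µm whole-cell
dilation with neighbour exclusion), live-to-fixed registration, and 4PL
IC50 fitting of S-phase dose–response.

Since no public imaging dataset accompanies the method, the package ships
a first-class synthetic-data module (`simulate_traces()`,
`render_movie()`, `render_fixed_field()`) producing movies and traces
with exact ground truth, against which every stage is tested.

## Worked example

Simulate a small movie, run the full pipeline, and summarise phase
durations:

```r
library(ktrcycle)

cfg <- sim_config(n_cells = 12, duration_hours = 30,
                  field_um = c(300, 300), condition = "parental",
                  rng_seed = 11)
st  <- simulate_traces(cfg)

res <- process_movie(
  frame_fn = function(fr) render_frame(st$truth, fr, cfg,
                                       channels = c("h2b", "cdk2", "degron")),
  n_frames = max(st$truth$frames$frame),
  pixel_size_um = cfg$pixel_size_um,
  frame_interval_min = cfg$frame_interval_min,
  ring_channels = "cdk2", max_step_um = 18)

nrow(res$events)
#> [1] 21

ann <- annotate_cycle(res, cfg$frame_interval_min, degron_kind = "cdt1")
duration_stats(ann$annotations)
#>   group metric  n      mean median        sd     ci_lo     ci_hi
#> 1   all   g1_h 23  7.634783    7.4 1.9113557  6.853634  8.415931
#> 2   all    s_h 17  7.929412    7.8 0.6202466  7.634565  8.224258
#> 3   all  g2m_h  9  5.266667    5.2 0.5291503  4.920955  5.612378
#> 4   all  imt_h  9 20.622222   20.2 1.6261748 19.559788 21.684656
```

Twenty-one mitoses are detected in the 30 h movie. The recovered means —
G1 7.6 h, S 7.9 h, G2/M 5.3 h, intermitotic time 20.6 h — match the
generator's parental programme (8, 8, 5, hence IMT 21 h) within the
sampling error of these small counts; `n` differs per metric because each
duration needs its own pair of observed boundaries, so later boundaries
are measurable in fewer cells. `classify_fate(res$traces)` labels each trace
proliferating/quiescent by the sustained-CDK2 rule; `plot_trace_heatmap()`
and `plot_aligned_mean()` reproduce the standard heatmap and
anaphase-aligned cohort-trace figures.

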