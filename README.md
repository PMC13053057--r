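# tocstamp

Quantitative analysis of tumor-on-chip (ToC) time-lapse videos: how fast do
cancer cells die under chemotherapy, and does early proximity to
cancer-associated fibroblasts (CAFs) predict which cells survive?

The package is aimed at groups running microfluidic cocultures of
red-prestained tumor cells and CAFs in collagen gels, imaged for up to 72 h
with a caspase-3/7 apoptosis reporter (green) and a transmission channel at
higher cadence. It implements a static-cell variant of the STAMP
(Spatio-Temporal Apoptosis MaPper) video analysis, windowed death-kinetics
statistics, pluggable CAF segmentation, and per-cell tumor–CAF proximity
metrics correlated with late cell fate. A seeded synthetic-video generator
with full ground truth makes the whole chain testable without microscope
data.

## The method in brief

**Detection (red channel).** Per-frame adaptive Bradley thresholding — pixel
foreground iff intensity exceeds the local mean over a window of side
`min(rows, cols)/8` times `1 + s` (default `s = 0.05`), computed exactly via
summed-area tables — followed by a temporal-persistence mask: a pixel is
tumor iff foreground in ≥ 95% of frames. 8-connected components become cell
records with centroid `C_i`; each cell's background ring is its dilation by
`r_dilate = √area ⁄ 3` minus itself.

**Apoptosis (green channel).** Cells are static, so fixed masks transpose to
every green frame. Corrected signal = foreground mean − ring mean; an event
is called when it exceeds `median + 5·MAD` of the pre-event baseline for 3
consecutive frames. Windowed statistics over 10-h windows:

    survival(tₙ)  = (N₀ − #events in (t₀, tₙ]) / N₀ × 100
    rate(tₙ)      = #events in (tₙ, tₙ+10] / alive(tₙ) × 100

Conditions are compared per window with the exact matched-pair Wilcoxon
signed-rank (sign-flip) test.

**Proximity (transmission channel).** Against per-frame CAF masks (classical
texture backend, or imported CNN masks): contacts (frames with a CAF pixel
strictly closer than 18 µm to `C_i`), minimum centroid-to-CAF-boundary
distance (recorded when not in contact), and IOU between the CAF mask and
the 82-µm disc around `C_i`. Early-window (0–8 h) measurements are
stratified by fate at 72 h (dead/alive) and compared with a two-sample
Kolmogorov–Smirnov statistic whose p-value comes from a cell-level
permutation null (see the methods vignette for why the iid KS p is invalid
here).

## Worked example

```r
library(tocstamp)

cfg <- sim_config(seed = 7, field_size_px = c(256L, 256L), duration_h = 24,
                  n_cancer = 30L, n_caf = 9L, lambda0_per_h = 0.06,
                  rho = 0.5, dt_trans_min = 15)
video <- generate_toc_video(cfg)
video
#> <toc_video> 30 cancer cells, 9 CAFs, 24 h (seed 7)
#>   apoptosis events: 17/30
#> <toc_stack> 256 x 256 px, 1.3 um/px
#>   red     49 frames, 0.0-24.0 h
#>   green   49 frames, 0.0-24.0 h
#>   trans   97 frames, 0.0-24.0 h

cells  <- detect_tumor_cells(video$stack)    # 30 cells recovered
traces <- extract_green_traces(video$stack, cells)
events <- call_apoptosis_events(traces)
kinetics_table(events, n_alive_t0 = nrow(cells), duration_h = 24)
#>   condition video   t_n alive survival_pct events_in_window rate_pct
#> 1 <NA>      <NA>      0    30        100                  9    30
#> 2 <NA>      <NA>     10    21         70                  5    23.8
#> 3 <NA>      <NA>     20    16         53.3                1     6.25
```

Survival drops from 100% to 53.3% by the 20-h window: of 30 cells, 9 died in
the first window (rate 30%), 5 of the 21 still alive at 10 h died in the
second (23.8%), and so on — the two printed formulas applied verbatim.

```r
cafs  <- segment_cafs(video$stack, tumor_mask = attr(cells, "tumor_mask"))
prox  <- proximity_records(cells, cafs, window_h = c(0, 8))
fates <- fate_table(cells, events, horizon_h = 24)
set.seed(1)
tidy(stratify_by_fate(prox, fates, n_perm = 499))
#>   parameter   n_alive n_dead  ks_D p_value direction
#> 1 contacts         15     15 0.533   0.022    14
#> 2 iou             495    357 0.272   0.214     0.0165
#> 3 min_dist_um     289    304 0.249   0.272   -12.7
```

This video was generated with a planted protective effect (`rho = 0.5`:
cells within 50 µm of a CAF in the first 8 h die at half the rate). The
direction columns point the right way — surviving cells had more early
contacts (+14 frames), larger CAF coverage (IOU +0.017) and shorter minimum
distances (−12.7 µm) — and with only 30 cells the cell-level permutation
test reaches p = 0.022 for contacts while the distance metrics stay
non-significant; power at realistic cell counts is characterised in the
test suite. `autoplot()` on the stratification and `plot_kinetics()` on
kinetics tables give the standard ggplot2 views.

The full pipeline (simulate → detect → cafseg → apoptosis → proximity →
report, with a checksummed manifest) runs as

```r
run_toc_pipeline(list(sim = list(seed = 1)), "out/",
                 conditions = list(coculture = list(rho = 0.5),
                                   monoculture = list(rho = 1)),
                 videos_per_condition = 3)
```

or from a shell via the thin wrapper `inst/cli/toc`
(`toc simulate|detect|cafseg|apoptosis|proximity|run`).

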