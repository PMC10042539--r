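# mitomass

Macrophages occasionally hand whole mitochondria to breast-cancer cells, and
the recipient cells grow measurably faster. **mitomass** quantifies the
population-level consequences of this rare event and provides the label-free
imaging analysis used to measure it at the single-cell level. It is aimed at
quantitative cell biologists working with quantitative phase imaging (QPI)
of co-cultures, and at modelers asking how a small, transient subpopulation
with a growth advantage shifts tumor growth.

The package has two halves:

1. **An agent-based growth model.** Each cell agent carries a dry mass *m*
   that grows per time step Δt as

   *m* ← *m* (1 + *k* Δt),

   with *k* = *k*₀ for ordinary cells and *k* = *k*₀ *r* for cells carrying
   transferred mitochondria. Per step, each non-carrier becomes a carrier
   with probability *f* Δt/*T*d, where *f* is the fraction of the population
   gaining mitochondria per doubling time *T*d. A cell that exceeds twice
   its birth mass divides into two half-mass daughters, and exactly one
   daughter of a carrier keeps the mitochondria (and the growth advantage).
   The population mass *m*P = Σ *m* is compared against pure exponential
   growth, *m*B = *m*₀ e^(d ln 2), after *d* doublings. With the measured
   inputs — *f* = 5%, *r* = 1.15, *T*d ≈ 40 h — the model predicts a ≈15%
   increase in population mass over baseline by 20 doublings, despite only
   5% of cells carrying mitochondria at any instant.

2. **A QPI dry-mass pipeline.** Phase-shift images (fractions of a
   wavelength) are background-corrected by a robust sixth-order polynomial
   surface fit and converted to dry mass per pixel via *m* = φ λ A / α
   (λ = 0.623 µm, α = 0.185 µm³/pg, A = 0.36 µm²/px). Cells are segmented
   by Sobel edge detection (Otsu threshold, closing, hole filling, watershed
   splitting of touching cells), tracked by nearest-centroid linking with
   explicit division detection, and each track gets a *specific growth
   rate*: the least-squares slope of mass versus time divided by mean mass
   (1/h). Donor-mitochondria fluorescence is separated into bulk network
   signal and small punctae by a rolling-ball (grayscale opening) filter,
   and cells are classified by intensity gates: recipient-marker ≥ 1.5×
   background → cancer cell; donor channel ≥ 2× background → macrophage;
   cancer cell with donor punctae → recipient. Cytokinesis and
   daughter-lineage utilities, ΔΔCT percent-knockdown and ERK-KTR ratio
   helpers round out the toolkit.

A synthetic time-lapse generator (`generate_timelapse()`) renders movies
with exact ground truth (true masses, divisions, recipient flags) so every
stage — and the end-to-end recovery of the 15% growth advantage — is
testable without any experimental data.

## Worked example

```r
library(mitomass)

# --- agent-based model at the study conditions ---
params <- abm_params(n0 = 1000, f = 0.05, r = 1.15, d_target = 20)
res <- replicate_increase(params, seeds = 1:10)
attr(res, "summary")
#>      mean        sd
#> 14.420115  0.589981
```

With 5% of cells transiently carrying mitochondria that confer a 15% growth
advantage, population mass after 20 doublings is ~14.4% above the pure
exponential baseline — the model's headline prediction.

```r
# --- synthetic movie through the full imaging pipeline ---
mv <- generate_timelapse(synth_params("fast", seed = 3))
mv
#> <synth_movie> 41 frames (10 h at 0.25 h), 192x192 px, 8 cells (1 recipients)

an <- analyze_timelapse(mv$phase, mv$times, mv$rfp, mv$donor)
an
#> <qpi_analysis> 41 frames, 8 tracks, 1 lineages
#>   classes: cancer: 7, recipient_cancer: 1
#>   mean specific growth rate: recipients 0.01993/h vs non-recipients 0.01756/h (+13.5%)
```

The pipeline segments and tracks every cell, finds the one division, flags
the single recipient from its donor punctae, and recovers its growth
advantage (true multiplier here: 1.15, i.e. +15%; the non-recipient rate
corresponds to the 40 h doubling time, ln 2 / 40 ≈ 0.0173/h).

```r
percent_knockdown(1.8)   # ddCT of 1.8 cycles
#> [1] 71.28254
```

## Command line

A thin CLI over the same functions lives at
`inst/scripts/mitomass-cli.R` with subcommands `simulate`, `synth`,
`analyze`, and `report`:

```sh
Rscript inst/scripts/mitomass-cli.R simulate --f 0.05 --r 1.15 \
    --doublings 20 --n0 1000 --dt-frac 0.01 --seed 1 --reps 10 --out traj.csv
Rscript inst/scripts/mitomass-cli.R synth --preset paper --seed 1 --out movie/
Rscript inst/scripts/mitomass-cli.R analyze --dir movie/ --out tracks.csv
Rscript inst/scripts/mitomass-cli.R report --tracks tracks.csv
```

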