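---
title: "Models and methods behind mitomass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitomass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomass)
```

mitomass quantifies how rare macrophage-to-cancer-cell mitochondrial
transfer changes tumor population growth, and implements the quantitative
phase imaging (QPI) analysis that measures the underlying single-cell
growth rates. This vignette documents the models, the tunable parameters,
the numerical choices, and what the synthetic-data validation does and does
not demonstrate.

## 1. The agent-based transfer model

Each cell agent carries a dry mass $m$ (pg), its mass at birth $m_b$, and a
flag for transferred mitochondria. Per time step $\Delta t$:

1. **Growth** (Euler form of exponential growth):
   $m \leftarrow m\,(1 + k\,\Delta t)$, with $k = k_0$ for non-carriers and
   $k = k_0 r$ for carriers ($r \ge 1$).
2. **Transfer**: each non-carrier becomes a carrier with probability
   $f\,\Delta t / T_d$, so that a fraction $f$ of the population gains
   mitochondria per doubling time $T_d$. Carriers cannot gain again
   (a no-op), which keeps $f$ interpretable as the fraction of the
   population receiving mitochondria.
3. **Division**: an agent with $m > 2 m_b$ splits into two daughters of
   exactly half its mass; each daughter's $m_b$ is reset to its birth mass,
   so the next division requires another full doubling. For a carrier
   parent exactly one daughter keeps the flag — QPI lineage observations
   show that typically a single daughter inherits the transferred
   mitochondria — so half the carrier population loses the advantage per
   division. A Bernoulli(1/2)-per-daughter variant is available
   (`divide_loss = "bernoulli"`).

The population mass $m_P(t)$ is the sum over agents; the comparator is pure
exponential growth, $m_B = m_0\,e^{d \ln 2}$ after $d$ doublings
(`baseline_mass()`), and the reported quantity is
$100\,(m_P(d\,T_d)/m_B - 1)$ (`relative_increase()`).

### Defaults and why

| parameter | default | meaning |
|---|---|---|
| `f` | 0.05 | fraction of the population gaining mitochondria per $T_d$, the transfer rate measured in vivo |
| `r` | 1.15 | growth-rate multiplier of carriers, from single-cell QPI growth rates |
| `Td` | 40 h | cell doubling time for this line |
| `dt` | $T_d/100$ | keeps the Euler discretization error far below the 15% effect |
| `n0` | 1000 | agents simulated; the model is mass-homogeneous, so the relative increase does not depend on $n_0$ beyond Monte-Carlo noise |
| `m0` | 250 pg | initial mass per agent (typical epithelial cancer cell); cancels in all relative quantities |

### Numerical choices

* **Growth-constant calibration.** With $k_0 = \ln 2 / T_d$ the discrete
  update $(1 + k_0\Delta t)^{T_d/\Delta t}$ falls slightly short of 2 per
  $T_d$. The default therefore calibrates $k_0 = (2^{\Delta t/T_d} -
  1)/\Delta t$, which makes one doubling take exactly $T_d$ at the discrete
  level, so "$d$ doublings" and "elapsed time $d\,T_d$" coincide for the
  baseline. The continuous-time constant is available via
  `growth_calibration = "continuous"`.
* **Evaluation epoch.** "After $d$ doublings" is evaluated at elapsed time
  $d \cdot T_d$ — the epoch at which the *baseline* population has doubled
  $d$ times — because the comparator $m_B$ is time-parameterized.
* **Population control.** Twenty doublings of 1000 agents would be $10^9$
  agents; when the count exceeds `agent_cap` (default $2 n_0$) the
  population is uniformly subsampled back to $n_0$ and a bookkeeping scale
  factor preserves the recorded total mass exactly (the carrier fraction is
  preserved without bias; its sampling noise is part of the Monte-Carlo
  error). With `f = 0` the entire simulation is deterministic and matches
  $2^d$ to within floating-point accumulation.

With the defaults the model predicts a mean mass increase over baseline of
about 14–15% at 20 doublings (SD ≈ 0.6 percentage points over seeds) —
i.e. a 5% standing subpopulation with a 15% growth advantage inflates the
whole population by roughly the same 15% after 20 doublings, because
carriers continually arise, divide faster, and decay back into the
non-carrier pool.

## 2. QPI dry-mass measurement

Phase shift $\varphi$ (fractions of a wavelength) relates to dry mass
through the specific refractive increment:
$m_{px} = \varphi\,\lambda\,A/\alpha$ per pixel, with defaults
$\lambda = 0.623$ µm, $\alpha = 0.185$ µm³/pg, $A = 0.36$ µm²/pixel
(`optical_constants()`, `phase_to_mass()`). Total cell mass is the pixel
sum over the segmented region.

**Background correction** (`correct_background()`) fits a sixth-order 2-D
polynomial surface to the image background and subtracts it. Background
pixels are not known in advance, so the fit is made robust: fit to all
pixels (on a deterministic regular subsample of at most 10,000 for speed),
discard pixels more than 2 SD *above* the surface (cells only add phase),
refit, three iterations. Coordinates are normalized to $[-1, 1]$ for
conditioning, and the fitted surface is evaluated on the full grid by
separable matrix products.

**Segmentation** (`segment_cells()`) is edge-based: Sobel gradient
magnitude → Otsu threshold on the gradient → morphological closing (disc,
radius 3 px) → hole filling → a 2 px mask dilation → watershed splitting on
the distance transform (tolerance 1 px) → connected components → regions
under `min_area` (200 px) dropped. Two details matter and were set against
generator ground truth:

* the small dilation recovers the faint outer tail of the cell's mass
  distribution that lies beyond the steepest gradient (mass capture
  improves from ~89% to ~99% for dim cells);
* watershed splitting is essential in confluent fields — plain connected
  components merge touching cells (notably newborn sister cells), which
  corrupts both masses and downstream classification.

**Tracking** (`track_cells()`) links regions across frames by greedy
nearest-centroid assignment in physical units (default limit 20 µm/frame at
15-min intervals). Division is detected when two regions in the next frame
both lie nearest to the same vanished parent, their summed mass is within
20% of the parent's, and each holds 25–75% of it; the parent track closes
with fate `divided` and two linked daughter tracks open. A link implying
more than a 30% mass change in one frame is refused: dry mass changes well
under 1% per 15 min, so such a jump is a segmentation artifact (usually a
transient merge), and absorbing it poisons the growth-rate fit. Tracks
ending before the last frame are `left_frame` when the last centroid is
within `border_margin` of the edge, otherwise censored, as are tracks
alive at the end.

**Specific growth rate** (`specific_growth_rate()`) is the least-squares
slope of mass versus time divided by the track's mean mass. For a linear
series this equals slope/mean exactly; for an exponential observed over
$kT \lesssim 0.3$ it recovers $k$ within 2%. Group means are computed over
tracks observed for at least 32 frames (8 h, `growth$min_track_frames`):
slope/mean over shorter noisy windows is numerically unstable, and the few
corrupted short fragments otherwise dominate a group mean.

**Cytokinesis fraction** (`cytokinesis_fraction()`): a track counts as a
divider if it divides within 40 h; non-dividers enter the denominator only
if observed at least 30 h (cells leaving the frame earlier are omitted).

## 3. Fluorescence overlay and recipient classification

Fluorescence frames are bilinearly resized to the QPI grid
(`resize_to_match()`), and per-cell intensity is the integrated intensity
over the segmented region divided by area (`per_cell_intensity()`).
Channel background is the median over non-cell pixels — robust to bright
punctae.

**Punctae separation** (`extract_punctae()`): a rolling-ball filter —
grayscale opening with a flat disc, default diameter 6 µm, within the
4.8–9 µm range that sits just above typical punctae size — estimates the
low-spatial-frequency network signal; the residual (input − opening,
clipped at 0) contains the punctae. Two implementation notes:

* grayscale morphology is computed on intensities rescaled to $[0,1]$
  (opening commutes with increasing affine maps) with replicate-padded
  borders, so image edges produce no artifacts;
* the opening of a *noisy* flat field tracks local minima and sits a
  couple of noise SDs below the mean, so the residual carries a positive
  offset everywhere. Detection therefore thresholds the residual relative
  to its median, at `punctae_min_intensity` (default 5) robust (MAD) SDs.

**Gates** (`classify_population()`): recipient-marker intensity ≥ 1.5×
background → cancer cell; whole-cell donor intensity ≥ 2× background →
macrophage; a cancer cell that is not a macrophage and has detected donor
punctae → recipient. Cells passing both whole-cell gates are treated as
cancer/macrophage fusions and excluded (`other`), mirroring how
flow-cytometry analyses remove the double-positive population. The 1.5×
gate is read as ≥1.5× background (parallel to "double that of background"
for the donor channel). At the track level, a cell is punctae-positive
only when punctae are detected in at least two consecutive frames
(suppresses single-frame noise blips); daughter punctae inheritance is
read from the first three post-division frames.

## 4. The synthetic-movie generator

`generate_timelapse()` renders ground-truthed movies that emulate the
imaging regime the analysis targets: frames every 15 min for 48 h, ~40 h
doubling time, a 5% recipient subpopulation growing 15% faster and
carrying 1–3 donor punctae (1.5 µm discs at 10× donor background) that
pass to exactly one daughter at division.

* Cells are smooth truncated-Gaussian phase profiles (radius 8 µm,
  SD = radius/2.5) whose integrated mass equals the requested mass to
  floating-point accuracy — real cells are irregular, but mass integrals
  do not depend on shape, which is what the pipeline measures.
* True masses follow $m(t) = m_b e^{kt}$ exactly between divisions;
  division halves mass exactly; founders start at random points of their
  mass cycle so divisions spread over the movie.
* The phase background is a fixed degree-3 polynomial surface of amplitude
  comparable to the cell signal; noise is additive Gaussian with SD 2% of
  a nominal cell's peak phase. No shot noise, phase wrapping, optical PSF,
  or irregular morphology is modeled.
* Founders sit on a jittered grid with random-walk motility
  (0.3 µm/frame), chosen for tracker solvability; real motility and
  density statistics are not reproduced.
* The recipient count is `round(recipient_fraction * n_cells)` (minimum 1
  when the fraction is positive) rather than a Bernoulli draw: with 5%
  and ~30-cell fields, a binomial draw frequently yields zero recipients,
  which would make the recipient/non-recipient comparison undefined in a
  single field.

Consequently, passing the end-to-end tests shows that the pipeline's
operators are correct and that the growth-advantage readout is unbiased
under the stated imaging regime — it does not show robustness to
irregular cell shapes, uneven illumination beyond polynomial order 6,
phase wrapping, or dense tissue-like confluency.

### End-to-end validation

On full-scale synthetic movies (384×384 px, 193 frames, 30 founders, 5%
recipients at $r = 1.15$, noise on), the pipeline recovers a mean
specific-growth-rate difference between recipient and non-recipient cells
of 14.4–15.0% across generator seeds (true value 15%), with
recipient-classification accuracy of 98–100% against ground truth. The
acceptance test runs one such movie; the package test suite also verifies
every operator against closed forms and brute-force oracles (per-pixel
mass summation, double-loop grayscale opening, binomial transfer counts).

## 5. Reporter utilities

`percent_knockdown()` implements the Livak relative quantification:
$\Delta CT = CT_{target} - CT_{reference}$ per condition (technical
replicates averaged first, per sample), $\Delta\Delta CT =
\Delta CT_{treated} - \Delta CT_{control}$, and
$\%\,knockdown = (1 - 2^{-\Delta\Delta CT}) \times 100$. Descriptions of
ΔCT direction in lab protocols are often garbled; this package follows the
standard Livak convention, which matches the formula above. Negative
values (up-regulation) are reported as-is.

`ktr_ratio_series()` computes the kinase-translocation-reporter readout:
cytoplasmic:nuclear mean intensity per time point, normalized to exactly 1
at $t_0$; it is invariant to common rescaling of both channels.

## 6. Known limitations

* The tracker is greedy and nearest-centroid; it is adequate for the
  sparse-to-moderate densities generated here, not for dense tissue.
* Segmentation assumes cells brighter than background in phase; debris and
  overlapping cells beyond what watershed separates are not handled.
* The ABM has no spatial structure, cell death, or contact dependence of
  transfer, and the mechanistic link (ROS/ERK signaling) is outside its
  scope; it translates measured single-cell rates into population mass.
* Equivalence with any particular microscope vendor's or lab's original
  processing chain is not claimed — only the behavior specified and tested
  here.

## Problem sizes used in the shipped checks

The test suite exercises the ABM at $n_0 \le 1000$ for up to 20 doublings
(seconds per run) and one full-scale synthetic movie (~1 minute of
analysis); smaller presets (`synth_params("fast")`) cover the remaining
pipeline tests. These sizes were chosen as the smallest at which the
Monte-Carlo and measurement noise are far below the tested tolerances.
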