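---
title: "Quantifying senescent cells from per-cell image stacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying senescent cells from per-cell image stacks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senescan)
library(dplyr)
```

## The measurement problem

Senescence-associated beta-galactosidase (SA-β-gal) activity, revealed by
X-gal staining, is the standard marker of cellular senescence, but on a
microscope slide it is scored by eye, cell by cell. Imaging flow cytometry
removes that bottleneck: every cell in suspension is photographed in a
bright-field (BF) channel and several fluorescence channels, and scoring
becomes a gating problem over per-cell image features. X-gal precipitate
makes senescent cells *dark* in bright field, so the discriminating feature
is the mean background-subtracted BF pixel value inside the cell mask —
strongly negative for stained cells, near zero for unstained ones.
Fluorescence channels add nuclear damage foci (γH2AX), loss of nuclear
markers (HMGB1, Ki67), proliferation labels (BrdU), cell-type markers
(CD45, pan-cytokeratin, GFP) and a viability dye, so senescence can be
quantified per cell type inside dissociated tissues.

`senescan` implements that measurement chain end to end: mask derivation
and feature extraction per cell, hierarchical control-referenced gating,
population statistics, and a synthetic image generator that renders
populations with known ground truth so every stage can be validated without
instrument data.

## Per-cell features

Each cell record carries one small 2-D image per channel, all the same
size, with a physical pixel scale (`pixel_size_um`, default 0.5 µm/px).
The commercial analysis software that ships with imaging flow cytometers
does not publish its mask or feature definitions, so each operator here is
a transparent reconstruction from standard image-processing primitives:

* **Cell mask** — absolute deviation from the estimated background (median
  of the image border), Gaussian smoothing, Otsu threshold, morphological
  closing (disc, r = 2 px), hole filling, largest connected component.
  Using the *unsigned* deviation makes one recipe work for both dark
  (stained) and rim-contrast (unstained) cells. A guard rejects frames
  where the Otsu threshold fails to clear the smoothed background noise
  ("no cell detected").
* **Background** — per cell and per channel, the median of pixels outside
  the mask dilated by 3 px; robust to outliers and illumination drift
  between frames. `mean_pixel`, `max_pixel` and `total_intensity` are
  computed on background-subtracted pixels inside the mask.
* **Area and aspect ratio** — mask pixel count × `pixel_size_um`²; the
  aspect ratio is minor/major axis of the equal-second-moment ellipse.
  Both drive the bright-field singlet gate.
* **Focus metrics** — RMS of the central-difference gradient magnitude over
  the mask, and the robust contrast (p95 − p5)/(p95 + p5 + ε) of raw mask
  pixels.
* **Nuclear focus count** — white top-hat (disc r = 3 px) of the focus
  channel, thresholded at `k` × the robust noise scale (1.4826 × MAD of
  the top-hat response inside the nucleus), connected components of ≥ 2 px.
  Detection is restricted to the nucleus eroded by 1 px, which drops the
  soft nuclear rim (whose top-hat residue would enter the noise estimate)
  without shrinking the core — a stronger erosion clips boundary foci and
  lets crowded foci corrupt the MAD scale. Touching foci count
  as one spot — there is deliberately no watershed splitting, which keeps
  the count deterministic; the cost is occasional under-counting in
  crowded nuclei (see limitations).
* **DAPI totals** — the DAPI *foreground* area and integrated intensity
  over every detected component, not just the largest. A two-nuclei event
  then shows roughly twice the area and twice the intensity, which is what
  the dissociated-tissue singlet gate keys on, while nuclear markers are
  still measured on the single largest nucleus.

### Numerical choices

The smoothing sigma of the mask recipe defaults to 1 px. This was
calibrated on analytic disc renders: with σ = 2 px the Otsu threshold on
the smoothed deviation image sits well below the half-height of small
bright objects and the mask inherits the smoothing halo (about +15–20%
area for an 8-px-radius nucleus), while σ = 1 px keeps rendered discs of
radius ≥ 8 px within 5% of πr². The spot threshold multiplier defaults to
`k = 5`, the smallest value at which ground-truth focus counts 0–8 are
recovered in ≥ 99% of calibration nuclei (at `k = 4` rare 2-px noise
clumps create false single foci). Quantiles everywhere use the
linear-interpolation definition so control thresholds are bit-reproducible.

## Gating

Gates are named predicates over feature columns arranged in a tree;
membership is evaluated in topological order and a cell belongs to a gate
only if it also belongs to the parent, so hierarchy containment holds by
construction. Predicates are 1-D thresholds, intervals, 2-D rectangles and
boolean combinations (AND/OR/NOT) of earlier gates. Cells with missing
features for a gate (for example `spot_count` in a cell without a DAPI
channel) drop out of that gate and are reported in a per-gate "ungated"
tally rather than aborting the run.

Marker positivity is **control-referenced**: the cutoff is a quantile of
an unstained reference sample, evaluated among control cells inside the
parent gate. Defaults are the 0.99 quantile for "positive above"
(fluorescence) and the 0.01 quantile for "positive below" (SA-β-gal
darkness on `bf_mean_pixel`). This mirrors reference gating against
unstained cells and makes the false-positive rate explicit: gating the
control with its own threshold marks (1 − q) of it positive by
construction, so a q = 0.99 gate carries a ≈ 1-percentage-point additive
background. That floor is negligible against the ~90% in-vitro
prevalences but dominates the 0.2–16% in-vivo ones and contaminates
statistics conditioned on the SA⁺ gate, so the dissociated-tissue presets
place the dark-side cutoff at quantile 0.001 instead of 0.01: the stained
and unstained bright-field distributions are separated by roughly 15
standard deviations, so moving the cutoff deeper into the valley costs no
sensitivity — the quantitative analogue of verifying the gate by visual
inspection of stained cells. Every preset states its quantile, and a fixed
`cutoff:` can replace it for manual gates.

Structural gates:

* **Bright-field singlets** — aspect ratio ≥ 0.6 and area within
  50–5000 µm²; tangent same-size doublets have aspect ratio ≈ 0.45 and
  fall out.
* **DAPI singlets** (dissociated tissue) — a rectangle on total DAPI
  foreground area and integrated intensity, placed relative to the
  dataset's median nucleus: a wide area window (0.3–3.5×, nuclei of
  different cell types differ several-fold in area) and a tight intensity
  window (0.5–1.55×, DNA content is ~2N for every singlet, so doublets sit
  near 2×).
* **Focus gate** — gradient RMS ≥ 9 and contrast ≥ 0.015, frozen from the
  percentiles of in-focus vs σ = 6 px defocused synthetic renders. On BF
  images with a ~600-count baseline the contrast feature barely separates
  (the baseline dominates both percentiles), so the gradient-RMS cut does
  the work; the read-noise gradient floor is ≈ 8, crisp renders sit at
  ≥ 9.3.

Population statistics are per-sample percent-of-parent (with any ancestor
usable as the denominator, e.g. "% SA⁺ among pCK⁺ epithelial cells"),
mean ± SEM across samples, mean cell area inside vs outside a gate, and
the classic pooled-variance two-tailed t-test as the reporting primitive.

## The synthetic generator

The generator is first-class, tested code: it draws ground-truth labels per
cell (`sample_phenotypes()`) and renders the image stack per cell
(`render_cell()`), with one root seed and per-cell child seeds derived by
counter so datasets are bit-reproducible and could be rendered in any
order. What it emulates, per channel:

* **BF** — background (600 counts) minus (intrinsic contrast 45 + X-gal
  darkness) over a soft-edged ellipse, plus a darker cell rim just inside
  the boundary (amplitude 15, centred at 0.9 of the radius so faint-cell
  masks are not inflated by the rim halo). Stained cells draw darkness
  from N(150, 25²), unstained from |N(0, 6²)|; read noise is N(0, 8²)
  everywhere.
* **DAPI** — a nuclear disc (radius 0.5 of the cell radius, strictly
  inside) with constant *integrated* intensity (150 000 counts, CV 0.1),
  i.e. DNA content, not stain density, is conserved across cell sizes.
* **γH2AX** — Gaussian puncta (σ 1.0 px, amplitude 250) at ≥ 4.5 px mutual
  separation inside the nucleus, on a faint nuclear base. Focus-positive
  cells carry 4–8 foci, negative cells 0–2, so the spot-count ≥ 3 gate
  has a one-focus safety margin against merge losses.
* **Nuclear markers / type channels / viability dye** — nuclear disc or
  cell body scaled by a lognormal level, high for positive cells
  (mean 350–400) and autofluorescence-low otherwise (12–15).
* **Artefacts** — a doublet fraction (second tangent cell; the frame
  auto-grows to contain the pair), a defocus fraction (whole-stack
  Gaussian blur, σ 6 px), and dead cells bright in the viability channel.

Cell sizes are lognormal with the configured mean area and CV, truncated
at ±2.75 log-SD (mean shift < 0.1%) so cells always fit their frame;
aspect ratios are drawn in [0.8, 1]. Marker and focus positivity can be
specified per phenotype (`sen`/`nonsen`), per staining status
(`stained`/`unstained` — used to inject printed joint statistics such as
"% of SA⁺ cells that are Ki67⁻"), per cell type, or as one scalar.

Staining is conditional on senescence with configurable sensitivity and
false-positive rate, so "% SA⁺" in a sample is an injected quantity the
pipeline must recover through rendering, masking, feature extraction and
control-referenced gating — classification error, mask bias and threshold
leakage all land in the recovered number. The packaged presets
(`recipes()`) encode five scenarios — etoposide-senescent vs growing
fibroblasts, a damage time course with marker combinations, tumor
regression with GFP⁺/CD45⁺ compartments and a viability gate, bleomycin
lung fibrosis with pCK⁺/CD45⁺ compartments and proliferation markers, and
young-vs-old tissue panels — with prevalences, marker rates and mean areas
set to the corresponding published population values, 2000 cells per
sample, and an unstained control sample in every scenario.

What the generator does **not** emulate: real X-gal granularity and
perinuclear localisation, autofluorescence spillover between channels,
shape irregularity beyond mild eccentricity, segmentation-relevant debris,
or staining-duration effects. Passing recovery tests therefore shows the
measurement chain is unbiased under this generative model, not that any
particular instrument's masks are reproduced.

## Problem sizes and validation

The test suite validates operators against brute-force oracles on random
8×8 patches, focus counting against 200 rendered calibration nuclei
(≥ 99% exact recovery of counts 0–8), control self-consistency
(≈ (1 − q) × 100% of a control gated positive by its own threshold, within
binomial error), and end-to-end recovery on 1000-cell-per-sample runs of
the fibroblast scenarios: injected percent-positive recovered within ±3
percentage points and mean areas within ±5%. The acceptance script
(`scripts/acceptance.R`) repeats the recovery runs at the presets' full
2000 cells per sample across all five scenarios. These sizes were chosen
so the whole validation runs comfortably on a laptop-class single core.

## Known limitations

* Strongly stained, defocused cells can pass the focus gate (their
  interior contrast and edge gradients survive σ = 6 px blur); at the
  default 3% defocus fraction this moves percentages by well under one
  point.
* Mask areas of small (r ≈ 10 px) faint soft-edged cells read ~10% high;
  absolute areas are only reported for the large in-vitro fibroblasts,
  and in-vivo size results are relative (SA⁺ vs SA⁻ within a tissue).
* Touching foci merge; exact spot counts in crowded small nuclei can
  under-read by one, which is why positivity uses a ≥ 3 threshold with
  foci injected at ≥ 4.
* The control-referenced threshold adds its (1 − q) false-positive rate
  to every recovered percentage; at q = 0.99 this is ≈ +1 point, visible
  when the true prevalence is of the same order. The in-vivo presets
  mitigate it with the 0.001 valley cutoff described above.
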