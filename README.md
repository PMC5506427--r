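# senescan

Quantitative, cell-type-specific identification of senescent cells from
per-cell multi-channel image stacks, as produced by imaging flow
cytometers. `senescan` is for researchers who score senescence by
SA-β-gal staining and want the scoring to be a reproducible, per-cell
computation instead of a by-eye count: it extracts image features per
cell, gates populations hierarchically against unstained controls, and
reports percent-positive and cell-size statistics per sample and per cell
type — plus a seeded synthetic image generator with ground-truth labels so
the whole chain can be validated without instrument data.

## The measurement

X-gal precipitate renders SA-β-gal–positive cells dark in bright field
(BF). For each cell with mask *M* and local background *b* (median outside
the dilated mask), the discriminating feature is the mean background-
subtracted pixel

  `bf_mean_pixel = mean_{p ∈ M} I(p) − b`

which is strongly negative for stained cells. Positivity cutoffs are
control-referenced quantiles: a cell is SA⁺ if `bf_mean_pixel` falls below
the q = 0.01 quantile of an unstained reference sample (fluorescence
markers use q = 0.99 upward). Upstream, cells pass a singlet gate (area
and aspect ratio of the BF mask, or DAPI foreground area and integrated
intensity for dissociated tissue) and a focus gate (gradient RMS and
contrast). Nuclear γH2AX foci are counted by a white top-hat filter
thresholded at 5 × the robust noise scale inside the nucleus; boolean
gates combine markers (e.g. SA⁺ ∧ HMGB1⁻). Population output is percent of
a parent gate per sample, mean ± SEM across samples, mean area inside vs
outside a gate, and pooled-variance two-tailed t-tests.

## Worked example

Simulate the senescent-vs-growing fibroblast scenario (89.6% of the
damage-induced senescent sample stained, 4.8% of growing cells spuriously
stained, mean areas 668.9 vs 461 µm², plus an unstained control), run the
full pipeline and read off the recovered statistics:

```r
library(senescan)

run <- run_pipeline(recipe("dis_fibroblasts", seed = 42, n_per_sample = 300))
percent_positive(run$result, "sa_pos")
#> # A tibble: 3 × 5
#>   sample_id gate   n_parent n_in_gate percent
#>   <chr>     <chr>     <int>     <int>   <dbl>
#> 1 dis       sa_pos      293       252   86.0
#> 2 growing   sa_pos      290        18    6.21
#> 3 unstained sa_pos      287         3    1.05
```

The DIS sample reads 86.0% SA⁺ against 89.6% injected (binomial noise at
n ≈ 300 is ±2 points), growing cells 6.2% against 4.8% injected plus the
≈1-point false-positive floor of the q = 0.99 control threshold — which is
exactly what the unstained row shows (1.05%). The full per-gate report,
including mean areas (667 µm² for DIS vs 463 µm² for growing cells here),
comes from `tidy(run)`; `autoplot(run)` draws it. Presets for the other
study designs — a damage time course with γH2AX/HMGB1/Ki67 marker
combinations, dissociated tumors (GFP⁺ tumor vs CD45⁺ immune cells with a
viability gate), fibrotic lung (pCK⁺ epithelial vs CD45⁺ immune
compartments, BrdU/Ki67 overlap) and young-vs-old tissue panels — are
listed by `recipes()`.

A thin CLI wraps the same functions:

```sh
exec/senescan run --recipe dis_fibroblasts --out results/ --seed 1 --n 500
exec/senescan simulate --config sim.yaml --out data/ --seed 1
exec/senescan features --manifest data/manifest.csv --out features.csv
exec/senescan gate --features features.csv --gates gates.yaml --controls unstained --out report.csv
```

Datasets on disk are one multi-page uint16 TIFF per cell (pages =
channels) plus a `manifest.csv`; feature tables and reports are CSV;
gating trees and simulation configs are YAML.

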