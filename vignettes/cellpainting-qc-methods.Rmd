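---
title: "Methods: quality control and reproducibility metrics for Cell Painting profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality control and reproducibility metrics for Cell Painting profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(paintqc)
```

## The problem

A Cell Painting screen images cells stained in six compartments after
compound treatment and summarizes each segmented cell as a vector of
morphological features. Between those single-cell tables and any biological
conclusion sits a long chain of statistical housekeeping: cleaning the
single-cell population, collapsing it to well-level profiles, normalizing
plates against their vehicle controls, pruning the feature set, deciding
which compounds are even worth analyzing (neither cytotoxic nor inert), and
quantifying whether the surviving profiles are reproducible enough to trust.
`paintqc` implements that chain for 384-well screens in which test compounds
occupy columns 1--22 and the controls — DMSO vehicle, plus nocodazole and
tetrandrine as strong-phenotype positive controls — occupy columns 23--24.

Every stage is a pure function of its inputs and a configuration object, so
the whole pipeline is reproducible from one seed, and a synthetic generator
provides inputs with known ground truth at any scale.

## Single-cell cleaning

Cells with any missing or non-finite feature value are removed row-wise
(`drop_invalid_cells()`). The remaining population of a plate is ranked by a
histogram-based outlier score (HBOS): per feature, an equal-width histogram
with `n_bins = 10` bins over the observed min–max, heights normalized so the
tallest bin is 1; a cell's score is

$$\mathrm{HBOS}(x) = \sum_f \log \frac{1}{h_f(x_f) + \alpha},$$

with smoothing `alpha = 0.1`. High scores mean the cell sits in sparse bins
of many features — segmentation artifacts, debris, dying cells. The filter
removes the `ceiling(contamination * n)` highest-scoring cells with
`contamination = 0.1`.

Three boundary rules are deliberate and tested:

* a value up to `tol = 0.5` bin-widths outside the fitted range is clamped
  to the nearest edge bin; anything farther gets the feature's minimal bin
  height (scoring such samples as maximally surprising for that feature);
* a constant feature occupies one degenerate bin of height 1 and therefore
  contributes the same constant to every score;
* ties at the removal cut are broken by (score descending, plate, well,
  object id descending), so results are order-independent.

The implementation is validated against a brute-force oracle (explicit
per-sample bin lookup and log-sum) to within 1e-9, not against any external
library.

Dead cells are classified separately by the small-and-round rule — area
strictly below 1000 μm² *and* width/length ratio strictly above 0.83 — and
reported per treatment as a half-even-rounded percentage at one decimal.
Cleaned cells aggregate to one row per well: feature medians over all
remaining cells (up to nine fields pooled) plus the remaining cell count;
wells left with zero cells are omitted and reported.

## Normalization and feature selection

Profiles are normalized per *physical* plate — one (library plate,
replicate) combination, since each replicate is a separately seeded and
imaged plate with its own controls — against that plate's DMSO wells:

$$x' = \frac{x - \mathrm{median}_{\mathrm{DMSO}}}{\mathrm{MAD}_{\mathrm{DMSO}} + \varepsilon},
\qquad \varepsilon = 10^{-6}.$$

The MAD is the raw median absolute deviation without the 1.4826 normal
consistency factor; the convention is switchable
(`normalization$mad_consistency`) because downstream correlation metrics are
scale-invariant but the induction filter is not, and the raw form is the
default in the profiling tools this pipeline follows.

Feature selection runs four fixed stages, each recorded in a report that
partitions the feature set: (1) drop features with any missing value;
(2) near-zero-variance screening — drop when the most-common/second-most-
common frequency ratio exceeds `1/freq_cut = 10` *and* the unique-value
fraction is below `unique_cut = 0.1`, with zero-variance features always
dropped; (3) drop features whose maximum absolute normalized value exceeds
`outlier_cutoff = 100`; (4) iteratively resolve correlated pairs above
`corr_threshold = 0.9`, at each step taking the pair with the largest |r|
and dropping the member with the larger mean absolute correlation to all
remaining features (lexicographically later name on ties). After selection
the code asserts both post-conditions: no surviving |value| above 100 and no
surviving pair above |r| = 0.9.

Consensus profiles are element-wise medians over a compound's replicate
wells (median cell count likewise); missing replicates are tolerated.

## Compound filters

**Toxicity.** A compound is toxic when its consensus cell count is strictly
below `median - 2.5 * SD` of the test-compound consensus counts (population
SD, denominator n; controls excluded by default, switchable). Compounds with
no surviving cells anywhere are toxic by construction.

**Activity (induction).** In normalized space the DMSO center is 0 and the
robust scale 1, so a feature "responds" when `|z| > 3`; the induction score
is the responding fraction of selected features, and a compound is
low-active when that fraction is strictly below 0.05. Filters apply
sequentially (toxicity first), so the categories in the accounting table are
disjoint and `retained = total - toxic - low_active - non_replicating`, with
integer percentages rounded half-even.

## Reproducibility metrics

All four metrics share one construction: a per-item correlation score, a
permutation null of 10,000 random non-matching groups, and a strict pass
rule at the 95th percentile of the null (linear-interpolation quantile,
type 7). Null draws are independent across samples and without replacement
within a sample.

* **Percent replicating** — item: compound; score: median pairwise Pearson
  correlation of its replicate well profiles; null: quadruplets of wells
  from four distinct compounds.
* **Percent matching** — item: MOA (each annotation counted separately,
  at least 3 member compounds); score: median pairwise correlation among
  member consensus profiles; null: random same-size compound groups, one
  null distribution per distinct group size.
* **Percent pairing** — item: compound shared by two datasets, on the
  intersection of their selected features; score: Pearson correlation of
  its two consensus vectors; null: random non-matching cross-dataset pairs.
* **Percent matching across datasets** — as matching, but scores use
  cross-dataset member pairs only and an MOA must reach the membership
  minimum in both datasets.

Null sampling for matching draws members uniformly from all compounds
(same-MOA coincidences are not excluded; at realistic annotation densities
the coincidence probability is negligible, and the construction is recorded
in each result's descriptor).

## The synthetic generator

`synthetic_config()` defaults describe the screen the pipeline is sized
for: 2,464 compounds on seven 384-well plates, four replicates, 2,000
seeded cells per well (Hep G2-like; 700 for a U-2 OS-like density).
Compound effects are sparse (10% of features), additive, and expressed in
DMSO-MAD units — `effect_scale_active = 5` puts affected features well past
the induction threshold of 3, `effect_scale_low = 1` inside it. Toxic
compounds (5%) multiply expected counts by 0.2; counts are negative-binomial
(size 20) to match the overdispersion of real well counts. Plates carry
smooth row/column drift (amplitude 0.2 raw units) and an additive rim
offset (0.5) on edge wells for the first 10% of features. Single-cell
tables add dead cells (small, round, bright nucleus — satisfying the
dead-cell classifier by construction), outlier cells shifted 8 noise-SDs in
a quarter of the features, and a 1% fraction of invalid values. All label
counts are `round(fraction * n)` exactly, and per-plate substreams derive
from the one global seed.

What the generator does **not** emulate: correlated feature blocks (real
morphological features are heavily collinear — which is why the correlation
stage of feature selection drops little on synthetic data but ~75% of real
features), non-Gaussian feature marginals, segmentation-error structure
beyond the outlier mechanism, batch effects between sites beyond
independent noise, and dose–response. Passing tests therefore demonstrate
the statistical machinery, not feature-extraction realism.

## Calibration, and two design points worth recording

*Calibration inputs must actually satisfy the null.* The calibration tests
require the permutation metrics to pass ~5% of items on null data. Plate
artifacts (rim, drift) are position-linked signal shared by a compound's
replicates — and, across paired datasets, shared between sites — so
"effect-free" data with artifacts on is *not* null, and the metrics
correctly report elevated rates on it. Calibration therefore runs on
effect-free, artifact-free (exchangeable) input.

*Finite control wells make the normalized pipeline slightly conservative.*
Normalizing each physical plate against its 16 DMSO wells subtracts an
estimated median whose error is shared by all wells of that plate. Null
groups occasionally combine wells of one physical plate (sharing that
error) while replicate wells never do (replicates live on different
physical plates), so under a global null the threshold sits slightly high
and percent replicating comes out at roughly 1–3 points below nominal at
desk scale. This is an inherent property of control-based normalization,
not of the null construction; the calibration tests isolate the latter.

## Problem sizes

The test suite and the acceptance analyses run at desk scale, chosen as the
smallest sizes at which the statistical claims are meaningful: 500
compounds on two plates (100–200 features) for calibration and recovery,
1,540 compounds on five plates for MOA matching (500 MOA groups of 3), and
10,000-sample nulls throughout — the same null size used at full scale. The
worked-example tables (filter accounting, dead-cell percentages) are exact
arithmetic and run at their published sizes.

## Known limitations

* Percent-matching null construction is declared, not harmonized with any
  external implementation; alternative group-resampling granularities exist.
* The induction filter inherits its 3-MAD / 5% thresholds from U-2 OS-tuned
  screens; on weakly responding cell lines it labels most compounds
  low-active (as the accounting tables reproduce), and should be re-tuned
  for other assays rather than read as a biological constant.
* Toxicity is a cell-count proxy, not a viability assay.
* The control-well pattern within columns 23--24 (column 23 DMSO, column 24
  alternating nocodazole/tetrandrine by row) is a fixed convention recorded
  in the layout output; real screens vary here, and the layout reader
  accepts any assignment.
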