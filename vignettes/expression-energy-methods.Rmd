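---
title: "Methods: expression energy, synthetic histology, and profile comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression energy, synthetic histology, and profile comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crequant)
```

`crequant` quantifies whole-brain ISH image series of transgenic mouse
lines into per-structure expression profiles and compares those profiles
across datasets. This vignette is the package's account of the model
behind each stage, the parameters that matter, what the synthetic data do
and do not emulate, and the design choices that were genuinely open.

## The atlas model

The reference atlas is modelled as a hierarchical ontology (a tree with a
single root) plus a 3D integer label volume in which every nonzero voxel
carries a leaf structure id. Three levels matter downstream:

* **divisions** — 12 major brain divisions (isocortex, olfactory areas,
  hippocampal formation, cortical subplate, striatum, pallidum, thalamus,
  hypothalamus, midbrain, pons, medulla, cerebellum) used for coarse
  summaries;
* **mid-level structures** — an antichain of the tree whose leaf sets
  disjointly cover the brain. All quantification is unionized to this
  level, mirroring the mid-ontology tier of non-overlapping structures
  that production atlases use for profile tables;
* **leaves** — the voxel labels.

`validate_ontology()` enforces the invariants that make unionization
well-defined: unique ids and acronyms, one root, acyclic connected parent
links, the antichain property, and exactly one mid-level
ancestor-or-self per leaf. Violations are classed errors, not warnings,
because every downstream table silently depends on them.

The toy geometry places divisions as rostro-caudal slabs and mid-level
structures as dorso-ventral slabs within each division, with optional
±1-voxel boundary jitter. Axis-aligned blocks keep every structure volume
exactly countable, which the Poisson placement tests rely on. The default
volume is 80 × 44 × 192 voxels at 50 μm (4.0 × 2.2 × 9.6 mm, one
hemisphere). Two considerations fixed these numbers: the rostro-caudal
extent should be mouse-brain-like so a 200 μm series yields a realistic
section count (48), and each mid-level slab should span several 200 μm
grid rows (~500 μm here) so centre-point grid assignment is only mildly
diluted at slab boundaries, as it is for real mid-level structures that
are large relative to the grid.

## The synthetic-histology forward model

The generator's recoverable truth is a density λ_s of expressing cells
per mm³ for every mid-level structure. Six qualitative pattern
categories are encoded as density templates relative to a base density
λ0 (default 5000 cells/mm³): *restricted* (λ0 in the target, 0
elsewhere), *restricted-but-sparse* (0.1 λ0), *enriched* (λ0 in the
target, 0.2 λ0 in its division siblings), and *widespread* / *scattered*
/ *sparse* (1, 0.3, 0.05 λ0 across the whole division). The multipliers
are package defaults encoding the categories' qualitative density
ordering; no published density scale exists for them, so they are
configuration, not fact. λ0 = 5000/mm³ corresponds to a few percent of
neurons in a structure expressing, a plausible mid-range for a
cell-type-selective driver.

Cells are realised as a Poisson process: count ~ Poisson(λ_s · V_s) with
V_s the annotated volume, positions uniform within the structure's
voxels, per-cell amplitudes Gaussian (mean 150, sd 30, truncated to
0–255). Sectioning takes 25 μm slabs every 200 μm along the rostro-caudal
(coronal) or medio-lateral (sagittal) axis, starting at half a thickness
so the first slab is fully interior; the section count is
⌊(extent − thickness)/spacing⌋ + 1. Each section renders its slab's cells
as peak-normalised Gaussian blobs (radius ≈ 10 μm) at 10 μm pixels on an
in-tissue background b0 = 20 with Gaussian texture σ = 5, clipped to
0–255. Images store *signal* intensity (higher = more ISH product); real
colorimetric scans are dark-field inverses of this and are assumed
inverted by upstream loaders.

Gene/Cre dataset pairs follow three faithfulness categories: (1) the Cre
truth equals the gene truth; (2) the Cre truth adds ectopic structures
(by default half of the zero-density structures, at the line's maximum
density); (3) the Cre truth keeps a strict subset (dropping half of the
positive structures). The fractions are defaults chosen to make the
categories clearly distinct while keeping category-3 lines non-empty.

What the generator does **not** emulate: optical blur beyond the blob
kernel, staining artifacts, tissue tears, registration error (the
pixel→atlas transform is exact by construction), hemispheric symmetry,
and within-structure expression gradients (laminar patterns are
represented only as whole-slab densities). Passing recovery tests
therefore demonstrate that the informatics is correct and well
conditioned, not that it is robust to registration failure or histology
artifacts — on real data those failure modes dominate, which is why
production workflows pair such tables with visual inspection.

## Segmentation

The upstream stage of real pipelines — a proprietary trained detector —
is specified only as "signal above background". `crequant` implements a
documented, parameterized robust threshold in its place: per section, the
background is the median of in-tissue intensities and the spread the
MAD scaled by 1.4826; a pixel is detected iff it is in-tissue and
brighter than b + k·max(s, s_min), with k = 3 and s_min = 2 intensity
units. The MAD floor keeps the rule meaningful on noiseless sections
where the MAD collapses to zero. The threshold is global per section
(slide-level variation is real, so background is not pooled across a
series), the mask is a pure pointwise function (no morphological
cleanup), and equivalence with any production detector is not claimed —
the stage is deliberately swappable behind the `detect_expression()`
surface.

## Gridding and expression energy

Masked sections are tiled with half-open 200 μm grid cells in pixel space
(the grid must be an integer multiple of the pixel size; there is no
resampling). Per cell, three sums are kept: detected intensity, detected
count, in-tissue pixel count. Each cell is assigned to the mid-level
structure under its centre after mapping through the section transform;
centres over background or outside the volume leave the cell unassigned
and excluded downstream. Centre-point assignment (rather than per-voxel
majority vote) matches the one-assignment-per-grid granularity of the
production statistic and is exactly testable against a brute-force
oracle.

Expression energy pools over all grids of a series assigned to s:
E_s = Σ detected intensity / Σ in-tissue pixels. Two readings of the
denominator were possible; the tissue-restricted one is used (off-tissue
pixels of boundary grids never count), since background glass carries no
expression information and would dilute boundary structures
asymmetrically. Three exact invariants pin the implementation down:
detected intensity and pixel counts are conserved from grids to
structures; whole-brain energy equals the pixel-weighted mean of
structure energies; and refining the grid leaves E_s unchanged when
structure boundaries align with both grids.

Structures never sampled by a series are reported as **missing**, not
zero. A coronal series can legitimately miss a small structure;
conflating that with "not expressed" would inject spurious ties at the
bottom of every rank correlation.

## Profile comparison

Spearman rank correlation (average ranks for ties) is computed over the
structures present in both vectors, requiring ≥ 3 complete pairs and
nonzero rank variance — degenerate cases raise a classed condition rather
than returning a silent 0. Per line, all cross pairs of replicates that
share the plane of sectioning are correlated and the coefficients
averaged (1–6 replicates per dataset); averaging pairwise ρ rather than
correlating averaged vectors keeps single-replicate and multi-replicate
lines on the same footing. Both the signed mean ρ and the mean of ρ² are
reported. Published characterizations label the averaged coefficient
"r²" while also quoting negative values, which a squared quantity cannot
produce; emitting both statistics side-steps the ambiguity, and ordering
and binning use the signed mean.

The replicate baseline is the unweighted mean over lines of the
within-line mean pairwise replicate ρ — each line counts once regardless
of replicate count. Per-line correlations are binned by quartiles
(inclusive linear-interpolation thresholds, `stats::quantile` type 7)
with ties at a threshold assigned upward: value = Q3 → high, = median →
mid, = Q1 → low.

Enrichment is the fold change F_s = E_s / W against the line's
whole-brain energy, with no expression floor before the ratio —
deliberately, because energy scales differ across lines and series; the
cost is that near-zero energies can produce large F, so rankings should
be read alongside the energies themselves. Within a structure, lines are
ranked by descending F, missing values last, ties broken lexically by
line id for determinism. Group comparisons (e.g. knock-in vs transgenic
correlation means) use two-tailed t-tests: paired as a one-sample test on
differences, unpaired as Welch's unequal-variance test — the safer
default when only "unpaired t-test" is specified; zero-variance
degenerate inputs return t = 0, p = 1 instead of erroring. No
multiple-testing correction is applied, matching the descriptive use of
these comparisons.

## Validation studies and problem sizes

Three simulation studies double as acceptance checks and as the package's
calibration record (`recovery_study()`, `enrichment_study()`,
`faithfulness_study()`; `scripts/acceptance.R` re-runs them):

* **Recovery** — densities log-spaced over three orders of magnitude
  (10² to 10⁵ cells/mm³) across the default atlas's 48 structures,
  shuffled against position, rendered noiselessly and quantified;
  Spearman ρ between E_s and λ_s is ≥ 0.9 (typically ≥ 0.95). The lower
  end of the density range was set so the sampled slab volume of a
  structure still contains a handful of expected cells — below that,
  Poisson sampling of the *truth*, not the pipeline, caps the attainable
  correlation.
* **Enrichment mining** — 20 cohorts of 5 lines on a compact 6 × 3 atlas,
  one line designed "restricted" in a rotating target structure; fold
  change ranking recovers the designed line at rank 1 in ≥ 90% of
  noiseless and ≥ 75% of default-noise cohorts (observed: 100%).
* **Faithfulness ordering** — 10 line pairs per category, 2 replicates
  per dataset, default noise. Mean correlation of faithful pairs exceeds
  both unfaithful categories, and sits at or above the all-lines
  replicate baseline minus 0.05. The baseline pools weakly patterned
  lines whose replicate correlations are intrinsically lower, so the
  faithful group can legitimately exceed it — the check is one-sided by
  design.

The compact cohort atlas (40 × 26 × 48 voxels) keeps each study's
simulated image volume proportionate to what a rank-correlation study of
18 structures needs; the default atlas is used where per-structure
resolution matters. All studies derive every random stream from a single
seed via a stable FNV-style hash (`derive_seed()`), so replicates differ
while runs reproduce bit-identically — the property the pipeline's
checksummed manifest asserts.

## Known limitations

* Grid cells straddling structure boundaries are wholly credited to the
  centre's structure; energies of thin structures adjacent to dense ones
  are biased upward. Real mid-level structures are large relative to
  200 μm, which bounds the effect, but it is the dominant error term in
  the toy recovery studies.
* The segmentation stage is a stand-in by design; its recall/false-positive
  guarantees are stated only for the synthetic blob-and-texture imaging
  model.
* Sagittal and coronal series of the same brain sample different voxels;
  correlations across planes are refused rather than corrected.
* The six pattern categories drive only the simulator. Automated
  classification of rendered images into those categories is out of
  scope, as is any claim about reproducing published correlation values,
  which depend on real image data.
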