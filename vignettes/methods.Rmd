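---
title: "Methods: per-cell quantification, membrane profiling and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-cell quantification, membrane profiling and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streakquant)
```

# The measurement model

`streakquant` quantifies multichannel immunofluorescence of differentiating
hPSC cultures at the single-cell level. Its inputs are co-registered intensity
channels (DAPI, nuclear fate markers, membrane cadherins, and for live imaging
a CAAX membrane reporter) plus an integer nuclear label mask. Segmentation is
deliberately external: label masks typically come from a trained pixel
classifier (e.g. ilastik probability maps, consumed by
`probmap_to_labels()`); `fallback_segment_nuclei()` is a plain
threshold-plus-watershed convenience so the pipeline runs end to end without
one, not a substitute for trained classification on real data.

All coordinates are (row, col), 1-based, origin at the top-left pixel, rows
increasing downwards. Ray angle 0 points along +col and angles increase
towards +row. These conventions are arbitrary but fixed, and every centroid,
shift and angle in the package uses them.

## Nuclear quantification

A z-stack is first reduced by maximum-intensity projection (per channel,
elementwise max over slices). Nuclear expression of a marker in cell $i$ is
the arithmetic mean of the channel over the cell's labelled pixels. Because
staining and illumination vary across fields, nuclear markers are optionally
reported relative to the same cell's DAPI mean
($\mathrm{marker}_i / \mathrm{DAPI}_i$); cells with a nonpositive DAPI mean
cannot be normalized and are flagged (`qc_zero_dapi`) and excluded from
normalized readouts with a warning.

## Directional membrane profiling

Membrane markers concentrate on a thin ring around each cell, so a mask-mean
is the wrong statistic; instead each cell's membrane signal is measured by
directional profiling. From the nuclear centroid, intensities are sampled
along $n$ equally spaced rays at unit steps $d = 1..L$ pixels (bilinear
interpolation at the continuous sample points; samples falling outside the
image are discarded). Per ray, the top $\lceil q\,m \rceil$ of the $m$
retained samples are averaged — the ray crosses the membrane somewhere inside
the window, and the top fraction picks up that crossing without requiring a
membrane segmentation — and the cell's signal is the mean of the per-ray
values over rays with at least one retained sample.

Tunables (`quant_config()`), all in pixels or proportions:

| parameter | default | meaning |
|---|---|---|
| `n_directions` | 6 | rays per cell |
| `ray_length` | 25 | sampling window along each ray, px |
| `top_fraction` | 0.20 | fraction of retained samples averaged per ray |
| `ray_origin` | `"centroid"` | where the window starts (see below) |
| `sample_step` | 1 | spacing of samples along a ray, px |

The defaults are the standard settings for this assay (six rays, top 20%
within 25 px). Two readings of "within 25 pixels from the nucleus" are
possible: a window starting at the nuclear *centroid* (the default — the rays
are anchored there) or at the nuclear *boundary* along each ray
(`ray_origin = "edge"`, which first walks out of the cell's own label and
then samples the next `ray_length` steps). Both are implemented; the choice
matters when nuclear radii are comparable to the window.

Numerical choices worth stating:

* **Bilinear sampling, not pixel walking.** Unit-step bilinear interpolation
  makes the operator rotation-robust (tested: rotating a symmetric cell's
  neighbourhood by 60° moves the signal by < 2%, interpolation error only).
* **Top-$k$ count.** $k = \lceil q\,m \rceil$ computed as
  `ceiling(q * m - 1e-12)`; the subtraction guards against binary
  floating-point excess in products like $0.2 \times m$. Ties in intensity
  are handled by taking the $k$ largest values after a decreasing sort, so
  the result is deterministic and order-independent.
* **Border cells.** Samples outside the image are discarded per ray
  (partial windows are averaged over what remains); a cell whose rays are
  *all* fully out of bounds is flagged `NA` and reported in a warning.
* **No neighbour masking.** Samples inside the cell's own nucleus or inside
  neighbouring cells are *not* excluded. At confluent densities a ray can
  therefore read a neighbour's membrane; this is a documented limitation of
  the operator, and the package's recovery benchmarks use isolated-cell
  geometry (below) where the operator's assumptions hold.

## Live-imaging branch

Chromatic offsets between channels are static, so the inter-channel shift is
estimated once per position (at the first timepoint) and reused: exhaustive
search over integer shifts $|dy|,|dx| \le$ `max_shift`, scoring each by the
Pearson correlation of the two channels over their overlap region. Ties are
broken by smallest $|dy|+|dx|$, then row-major order; constant inputs are an
error (nothing to correlate). Registration is integer-pixel only — no
subpixel refinement.

Background is the median intensity over the complement of all cell masks
(median for robustness to bright debris); it is subtracted and the result
clipped at zero. The per-image readout per timepoint and channel is then

$$ R(t) = \frac{\text{mean intensity over membrane mask}}
               {\text{mean intensity over non-membrane cell mask}} $$

with disjoint, nonempty masks required and a nonpositive denominator flagged
`NA`. Quantification is per image, not per tracked cell; single-cell tracking
is out of scope. When several positions are available the pipeline emits both
per-position series and a mean ± SEM aggregate, since either may be the
quantity of interest.

## Population statistics

Per-cell values are collapsed to one number per image — the median by default
— so that images, not cells, are the units of inference (cells within an
image are not independent replicates). The median of an even count is the
midpoint of the two central order statistics. Group comparisons use Welch's
unequal-variance $t$-test on these per-image medians with Welch–Satterthwaite
degrees of freedom and two-sided p-values (sidedness is a convention choice;
two-sided matches the usual significance brackets), Bonferroni-adjusted as
$\min(1, p \cdot m)$ where $m$ is the number of comparisons *declared in the
config* — panels define their own comparison families, so $m$ is never
auto-inferred from the data. Stars: \*p<0.05, \*\*p<0.01, \*\*\*p<0.001,
\*\*\*\*p<0.0001. Error bars use the standard error of the mean
($s/\sqrt{n}$, $n-1$ denominator).

Quadrant gating uses manually defined thresholds (an Otsu-based suggestion
utility exists but is explicitly a convenience, not the reference procedure).
A value exactly at a threshold counts **positive**; one convention had to be
picked, and this one is tested.

# The synthetic-data generator

Real imaging data for this assay are not redistributable, so the package
generates its own: fields of circular nuclei (DAPI disks), nuclear marker
channels constant over each nucleus with per-cell levels drawn from Gaussian
mixture populations, membrane channels as annuli of stated radius and width
with per-cell amplitudes, additive background, and i.i.d. Gaussian pixel
noise truncated at zero. Nuclei are placed by rejection sampling (10,000
attempts per cell, then an error naming the density). For live mode the same
geometry is rendered per timepoint with the ring amplitude following a
supplied trajectory, a cytoplasmic level inside each cell, fresh noise per
frame, and known integer shifts applied to non-reference channels.

Design choices:

* **Noise**: additive truncated Gaussian, not Poisson — the simplest model
  under which standard-error arguments set test tolerances analytically.
* **Geometry**: circles and annuli, so the directional-profiling oracle is
  tractable; irregular shapes are exercised only through mask perturbations.
* **Correlated markers**: channels listed in `shared_population_channels`
  share one latent population label per cell, which is how joint quadrant
  designs (e.g. 70% double-positive / 10/10/10) are expressed.
* **Serialization**: images are written as multipage 16-bit TIFF at one grey
  level per intensity unit (integer-valued images round-trip exactly);
  probability maps as 32-bit float TIFF. HDF5 probability maps are not
  supported; export such maps as TIFF.
* **Live amplitudes**: in live mode the trajectory value at $t$ is applied to
  all cells — live quantification is per image, so per-cell amplitude
  variation would only blur the designed truth.
* **Placement density** (`min_spacing`): by default only nuclear overlap is
  forbidden, emulating confluent cultures. Benchmarks that compare against
  the generator's per-cell truth use isolated-cell geometry instead —
  `min_spacing` of at least `ray_length` + ring outer radius for fixed
  recovery, and at least twice the ring outer radius for live ratios — and
  the recovery benchmark uses a ring width of 5 px so the membrane spans the
  $k = 5$ radial samples the top-20%-of-25 statistic averages. Without
  these, the designed per-cell amplitude is not the true value of what the
  operator measures (neighbouring membranes enter the window; neighbouring
  cytoplasm overlaps annuli), so the benchmark would test the geometry, not
  the operator.

What the generator does **not** emulate: point-spread blur, Poisson shot
noise, uneven illumination, irregular nuclear shapes, cell crowding effects
beyond simple overlap, z-structure beyond duplicated slices, or motion
between live frames. Passing benchmarks therefore demonstrate correctness of
the *operators* under their stated assumptions, not segmentation or staining
robustness on real microscopy.

# Problem sizes and determinism

The shipped test suite and `scripts/acceptance.R` run at sizes chosen to make
sampling arguments sharp while staying quick on one CPU: profiling-oracle
equivalence on 20 fields × 50 cells (agreement to 1e-9 against an explicit
loop/sort oracle); amplitude recovery on 50-cell isolated fields at noise =
10% of the mean amplitude (Spearman ρ > 0.95 per field; observed ≈ 0.99);
all 441 integer shifts up to ±10 px recovered exactly; a 22-timepoint
trajectory with its designed peak at index 15 recovered within 5% per
timepoint (observed < 1%); pooled quadrant recovery over 20 seeds × 1000
cells inside exact 99% binomial regions; Welch size in [0.04, 0.06] over
10,000 null replicates. Generation is fully deterministic given a
`field_spec` (the seed is part of the spec, and the generator restores the
caller's RNG state), and `run_pipeline()` reruns reproduce byte-identical
CSVs.

# Known limitations

* No masking of neighbouring cells during profiling (see above); at high
  densities membrane signals are upward-contaminated.
* Integer-pixel registration only; subpixel chromatic offsets remain.
* The fallback segmenter is basic; use a trained pixel classifier for real
  data and feed its probability maps in.
* Bonferroni (not FDR) is the only adjustment offered, matching the intended
  per-panel comparison structure.
* 16-bit serialization quantizes non-integer intensities to grey levels;
  in-memory analysis is unaffected.
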