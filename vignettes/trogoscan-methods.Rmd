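---
title: "Quantifying trogocytosis in fluorescence images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying trogocytosis in fluorescence images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Tumor cells can acquire immune-cell membrane proteins by trogocytosis —
nibbling membrane fragments off a donor cell on contact.  In
formalin-fixed paraffin-embedded (FFPE) tumor tissue stained for a
trogocytic marker (e.g. CD45RA, a naive T-cell isoform of the pan-leukocyte
phosphatase CD45), the evidence is a punctate marker signal scattered over
tumor cells that should not express it at all.  In co-cultures of tumor
cells with T cells, the acquired material concentrates in intracellular
marker-coated spheres ("trogosomes", often hollow, up to several
micrometres across).  `trogoscan` turns both observations into numbers:

* per tumor cell, the fraction of its 2D area covered by binarized marker
  signal, plus a strict-bound *trogocytic* flag and a control-calibrated
  *expressing* flag;
* per co-culture field, the trogosomes it contains, their equivalent-circle
  diameters and hollowness, and the percentage of cells holding a
  trogosome larger than a physical cutoff (default 5 µm).

## Pipeline model

### Nuclei

Nuclei are the only per-cell anchor available (there is no membrane
stain), so cells are counted and localized through nuclear instance
segmentation.  The built-in detector is deliberately classical and
deterministic: Gaussian smoothing (default sigma 2 px), Otsu threshold,
hole filling, Euclidean distance transform, and a peak-seeded watershed to
split touching nuclei.  Ties in watershed flooding and all label numbering
are canonicalized to row-major raster order of each instance's first
pixel, so two runs are comparable bit-for-bit.  Users with a trained
instance segmenter can bypass the detector entirely: any integer label
raster read through `read_label_image()` enters the pipeline at the same
point.  In both paths instances are filtered by physical area (default
8–150 µm²), which rejects bright debris such as paraffin specks and
grossly under- or over-segmented clumps.

The detector's parameters (smoothing scale, seed minimum distance,
watershed tolerance) are free parameters surfaced in
`pipeline_config()$segmentation`; no published values constrain them, and
the defaults were chosen to resolve touching DAPI-like blobs of 2–4 µm
radius at 0.2–0.35 µm/px sampling.

### Tumor tissue and cell territories

Tumor tissue is delineated by thresholding the pan-cytokeratin channel
(Otsu by default, or a fixed value), with interior holes below a
configurable area filled.  A nucleus is accepted as a *tumor* nucleus when
at least half of its pixels lie inside the tumor mask — "encapsulated by
the tumor border" has no single quantitative reading, so majority-inside
is the package's, exposed as `min_overlap_fraction`.

Each tumor nucleus then receives a *territory*: every tissue pixel is
assigned to the nucleus whose instance is nearest in Euclidean distance.
This is the generalized (region-based) Voronoi tessellation — distance to
the nearest *pixel* of each instance, not to its centroid — which reduces
to ordinary point Voronoi for point-like seeds and is robust to nucleus
size and shape.  Distances are computed in the full plane by an exact
integer squared Euclidean distance transform (a two-pass lower-envelope
algorithm run per instance) and then restricted to the tumor mask;
equidistant pixels go to the lower nucleus id.  Because squared distances
are integers, the tie rule is exact, and the whole assignment is verified
against a brute-force per-pixel nearest-instance search in the test suite.
A geodesic (mask-constrained) variant is a recognized alternative and an
explicit non-goal here.

One corner case is worth stating: a nucleus can pass the majority-inside
test while part of it lies outside the tumor mask.  A cell must contain
its own nucleus, so the territory support is defined as the union of the
tumor mask and the retained nuclei; territory areas therefore sum to the
area of that union.

The territory is also the denominator of the coverage fraction — the
"surface area" of a tumor cell is read as its 2D territory area.  This is
the single most consequential modeling choice in the package: with no
membrane stain, any per-cell area is a proxy, and the Voronoi territory is
the proxy that matches the nuclei-plus-tissue information actually present
in these images.  Cells whose territory touches the image border are kept
but flagged (`on_border`), since truncation biases their coverage;
`exclude_border = TRUE` drops them.

### Marker conditioning and binarization

The trogocytic-marker channel is processed in a fixed order: rolling-ball
background subtraction, then contrast-limited adaptive histogram
equalization (CLAHE), then binarization.  Background subtraction is
implemented as grayscale morphological opening with a disk of the
configured physical radius (default 12.5 µm, i.e. the canonical 50 px at
0.25 µm/px); it removes smooth shading and leaves features much smaller
than the disk untouched, and it is idempotent up to one intensity quantum.
CLAHE (default 64 px tiles, clip limit 0.01 of the tile pixel count,
256 bins, bilinear tile interpolation) normalizes local contrast before
thresholding; a tile larger than the image degrades gracefully to global
histogram equalization with a warning.  Binarization is Otsu by default,
or a fixed threshold, or the control gate (below).

Two intensity scales coexist deliberately:

* **Coverage** is measured on the binarized CLAHE output — local contrast
  normalization is what makes a single threshold meaningful across a
  heterogeneous FFPE field.
* **Per-cell mean intensity** for the expression gate is measured on the
  background-subtracted channel *before* CLAHE.  CLAHE rescales
  intensities image-adaptively, so a threshold learned on control images
  would not transfer across images after it; the pre-CLAHE scale is the
  one on which a control distribution is comparable between fields.

### The expression gate

Secondary-antibody-only control fields define the null distribution of
per-cell mean marker intensity (autofluorescence plus camera background,
processed identically).  The gate is a percentile of that distribution
(default the 99th, linear-interpolation definition); a cell *expresses*
the marker when its mean exceeds the gate.  This is the imaging analog of
an isotype/FMO gate in flow cytometry.  By construction the false-positive
rate on pure-control cells is close to `100 - percentile` percent; the
test suite checks it against the exact binomial interval at n = 1000
control cells.  At least 10 control cells are required, and several
hundred are recommended — the gate inherits the sampling noise of an
upper-tail quantile.

### The trogocytic flag

A cell is flagged trogocytic when its coverage fraction lies strictly
between the configured bounds, default 0.55 and 0.90.  Both bounds are
strict, so coverage exactly at a bound is not flagged.  The upper bound
exists to discard cells dominated by autofluorescence or bright anomalies
(paraffin debris) rather than genuine punctate transfer; both bounds are
configurable.  Coverage itself is an exact integer ratio
(marker-positive pixels in the territory divided once by territory
pixels), so the strict comparisons are well defined.

### Trogosome morphometry

Trogosomes are detected on the background-subtracted marker channel by
scale-space Laplacian-of-Gaussian (LoG) blob detection over a geometric
scale grid spanning the configured diameter range (default 1–10 µm,
12 scales), restricted to cell territories; a detection whose centroid
falls inside the owner's nucleus is rejected, reflecting the observation
that trogosomes sit beside and deform the nucleus rather than inside it.
Candidates are local maxima in position and scale above a response
threshold.  Two merge stages follow:

1. the scale-space overlap rule — detections whose centers are closer
   than half the smaller scale diameter collapse to the stronger
   response;
2. an overlap rule on refined geometry — the sharp rim of a marker-coated
   sphere produces spurious small-scale ridge maxima along and just
   outside the shell, so any detection whose refined disk overlaps a
   larger kept detection is treated as the same object.

The reported diameter is the *equivalent-circle diameter* of the locally
segmented blob: a window around the detection is thresholded at 10% of
its local dynamic range above background, holes are filled (so a hollow
ring becomes a disk), and the 4-connected component containing the center
— clipped to the owning territory — gives the area.  The LoG scale
estimate `2 * sigma * sqrt(2)` is the fallback when the local segmentation
is degenerate (a component leaking out of its window, or fewer than 4 px).
The area-based estimate is preferred because the LoG scale maximum is
systematically biased for hollow objects: for a thin ring the maximizing
scale sits near the ring radius rather than `radius / sqrt(2)`, inflating
the scale-derived diameter by tens of percent, while the filled-component
area recovers the geometric diameter regardless of hollowness.

`is_large` is strict (`diameter_um > large_cutoff_um`, default 5 µm), so a
sphere measuring exactly the cutoff does not count.  Hollowness is the
ratio of mean intensity in the central disk (radius 0.4 r) to the ring
annulus (0.7–1.0 r): 1 for a uniform disk, 0 for an empty ring, undefined
below 2 px radius.  Timepoint summaries count a cell once no matter how
many large trogosomes it holds, and report both the per-trogosome diameter
distribution and the mean of per-cell average diameters, since either
convention is found in practice.

## The synthetic generator

Every stage is tested against fields generated by `synthetic_params()` /
`generate_ffpe_field()` / `coculture_params()` with exact ground truth.
Design choices:

* **Layout.** Nucleus centers sit on a jittered hexagonal lattice (jitter
  ±10% of pitch), which guarantees the requested cell count and minimum
  spacing; radii are drawn from a clipped Gaussian and shrunk if needed so
  disks stay disjoint.  Defaults emulate a dense FFPE tumor nest: 100
  cells at 10 µm pitch, 3 µm nucleus radius, 0.25 µm/px, in a central
  tumor disk covering 55% of a 640×640 px field; the co-culture preset
  spreads 100 adherent cells at 22 µm pitch with a 9.5 µm cell-body
  footprint at 0.3 µm/px.
* **Territories.** Ground-truth territories are computed with the
  pipeline's own region-nearest tessellation of the planted nucleus
  raster, so planted per-cell coverage is exactly recoverable in the
  noiseless limit even for unequal nucleus radii (a point-Voronoi ground
  truth would disagree with the region rule near boundaries between
  unequal nuclei).
* **Coverage.** Planted coverage is realized as an exact pixel subset:
  `round(target * area)` territory pixels set to marker intensity, and the
  realized ratio — not the target — recorded as ground truth.
* **Expression.** A configurable fraction of cells draws coverage from the
  "expressing" range; the rest from a low range (zero by default, matching
  cells with no marker).  Control fields have zero planted signal and
  per-cell autofluorescence drawn from a log-normal law
  (`meanlog = log(0.05)`, `sdlog = 0.25`), whose sampler and analytic
  quantile are exported (`rautofluor()`, `qautofluor()`) so gate
  calibration can be checked against a closed form.
* **Trogosomes.** A sphere of nominal diameter *d* is planted as the
  `floor(pi r^2)` pixels nearest its center, i.e. the largest pixel set
  whose equivalent-circle diameter does not exceed *d*; the realized
  diameter is recorded.  This discretization makes the strict 5 µm
  boundary testable: a sphere planted at exactly the cutoff can never
  measure above it.  Interiors inside 0.7 r are rendered at 30% of ring
  intensity by default (hollow).  Placement keeps the whole sphere inside
  its territory, the centroid clear of the nucleus, and spheres disjoint;
  an infeasible large sphere raises an error rather than silently
  shrinking.
* **Noise.** Three independently switchable nuisances: scaled-Poisson shot
  noise (default 800 photons at full scale), additive Gaussian read noise
  (sd 0.005), and a linear shading gradient (off by default).  Channels
  are quantized to the 16-bit grid before writing, so written fixtures
  re-read bit-exactly.
* **Determinism.** One seed fixes the entire sample; generation restores
  the caller's RNG state.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: optics (no point-spread function beyond a
1 px nuclear blur, no chromatic offsets), texture within cells
(autofluorescence is flat per cell), irregular nucleus shapes, tissue
folds, sectioning artifacts, out-of-focus light from adjacent Z planes,
and marker patterns that are spatially correlated rather than random
within a cell.  Results on real FFPE material depend on segmentation and
threshold quality in ways the synthetic fields cannot probe.

## Numerical and degenerate-input conventions

* Rasters are `[row, col]` matrices; `(x, y)` in tables is `(column, row)`
  0-based.  Areas are reported in µm², diameters in µm; pixel-level
  intermediates stay in pixels.
* Flat channels under Otsu yield an empty mask (or zero nuclei) with a
  warning, never an error; empty record sets summarize to flagged `NA`
  percentages rather than `NaN`.
* Voronoi ties go to the lower nucleus id; label numbering is raster-scan
  canonical; watershed ties are fixed by the underlying flooding order,
  making identical inputs produce identical outputs.
* CSV writers serialize doubles with 17 significant digits, so round trips
  agree to better than 1e-12 relative error.
* Test and acceptance runs use deliberately modest problem sizes — fields
  of 9–100 cells, 200–840 px on a side, 200 random tessellation fixtures,
  1000-cell gate calibrations — chosen as the smallest sizes at which each
  property is meaningfully exercised.

## Known limitations

* The 2D territory is a proxy for cell area; columnar or overlapping cells
  (which practitioners address by confocal sectioning) are outside the
  model.
* The classical nucleus detector underperforms learned segmenters on
  crowded or irregular chromatin; the external-label path exists for that
  reason.
* The 55–90% rule can reasonably be applied to a CLAHE-normalized binary
  or to a control-gated binary; both are supported via `binarize_method`,
  and both the control-gated expression call and the coverage flag are
  always reported, so either definition of "positive" can be reproduced.
* Fully hollow rings (interior at 0) fall back to the LoG scale diameter
  when the ring is thinner than the refinement threshold reach; at the
  default 30% interior this path is not exercised.
* Single-plane analysis only: Z-stacks and 3D reconstruction are
  non-goals.
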