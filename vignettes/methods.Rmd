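---
title: "Methods: cohort galleries for multiplexed tissue images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort galleries for multiplexed tissue images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imgtsne)
```

This vignette explains the models, procedures and numerical choices behind
`imgtsne`: what each stage computes, which parameters matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and where the genuinely open design decisions were resolved.

## The problem

A multiplexed-imaging cohort is a set of images, each a stack of 4–64
single-marker channels sharing one pixel grid. The package builds two linked
views of such a cohort: a *static canvas* — one large PNG in which every
image appears as a cleaned, composited thumbnail at a meaningful position —
and a *live canvas* — an interactive scatterplot in which every image is a
dot carrying its full metadata on hover. Positions come from user-supplied
embedding coordinates (t-SNE or UMAP, computed however the user prefers), a
vertical grid, or blue-noise random placement; when the user supplies
neither coordinates nor labels, an inbuilt embedding/clustering fallback
fills the gap.

## Reading the containers

Three TIFF-family dialects are read through one interface
(`read_multiplex()`): plain multi-page TIFF (one page per channel), OME-TIFF
(channel names parsed from the OME-XML `ImageDescription`), and pyramidal
QPTIFF. Pages are grouped into pyramid levels by their pixel dimensions in
encounter order; the default policy loads the highest-resolution level whose
longer edge is at most 4,096 px. That bound keeps a 13-GB whole-slide
pyramid readable on a desk machine while leaving full resolution available
via `pyramid_policy = "full"`; nothing downstream depends on which level was
chosen. Marker names resolve with the precedence *embedded metadata → user
list → autogenerated* (`ch00`…), because embedded OME names are
authoritative when present. Stored intensities are never rescaled at read
time — conversion to unsigned-byte range happens only inside cleaning, so
the reader is lossless for 8- and 16-bit data.

Metadata arrive as one delimited table per annotation category (comma or
tab, sniffed from the header line), mapping `image_id` to a value; a
`colors` table optionally maps values to display colors. Duplicated ids keep
the last row (with a warning); rows referencing unknown images are skipped
(with a warning), never fatal — a partially annotated cohort should still
render.

## Channel cleaning

Each selected channel is denoised independently (`clean_channel()`), in five
steps:

1. **Median filter** (default 3×3) — edge-preserving noise removal. The 3×3
   case runs through a vectorized median-of-9 sorting network with
   replicate border padding; larger windows use `EBImage::medianFilter`.
2. **Otsu threshold** — the split of the 256-level histogram minimizing
   total within-class variance, computed from cumulative histogram moments.
   Pixels strictly above the threshold are foreground. When several integer
   thresholds tie exactly (a plateau, e.g. any two-level image), the
   plateau midpoint is returned: it separates the same two classes and
   avoids an arbitrary end-of-plateau choice. A constant channel is flagged
   degenerate and treated as all background.
3. **Morphological closing** of the binary mask (disc of radius 1 by
   default) — fills small gaps, refining morphological boundaries.
4. **Border clearing** — connected mask components touching any image edge
   are removed; partial cells at the field-of-view boundary otherwise
   dominate thumbnails.
5. **Upweighting** — surviving foreground intensities are multiplied by
   1.5 and clipped to 255.

Two of these steps resolve ambiguities that the pipeline description leaves
open. First, the threshold could either *binarize* the image or *mask* it;
we mask (multiply the median-filtered intensities by the cleaned mask), so
the foreground keeps its morphology — which is the stated purpose of the
upweighting step and would be pointless after binarization. Second, closing
could apply to the grayscale image or the mask; we close the mask, keeping
steps 3–4 purely set-valued. The upweighting rule itself (multiplicative,
factor 1.5, clipped) is our choice; the factor is deliberately modest so
that upweighting brightens without saturating mid-range foreground, and the
monotonicity property (a larger factor never darkens any pixel) is tested.

Channels of wider dtype are min–max scaled per channel into [0, 255] before
cleaning; output is always unsigned-byte. Cleaned channels are additively
blended into RGB using a fixed 10-color categorical palette in selection
order (user-overridable per marker); additive blending with clipping is
commutative, so selection order affects colors only through palette
assignment.

## Thumbnails and borders

Thumbnails preserve aspect ratio; the longer edge is scaled to `max_edge`
(default 222 px) and the shorter edge rounds half-up. Downscaling is area
averaging — every source pixel contributes to exactly one destination pixel
— so constant images stay constant and pixel mass is conserved up to
rounding. The 222-px default produces tiles of a few kB for Vectra-scale
fields of view, comfortably inside typical per-tile size budgets, and reads
clearly on a 4,000 × 3,000 canvas. Borders paste the tile onto a rectangle
`2 × border_px` larger (default 4 px) filled with a metadata color; the
interior is the unbordered tile, exactly — a tested invariant.

## Layouts

*Coordinate mode* maps the embedding box onto the drawable span (canvas
minus margins minus one tile) by an affine map per axis, preserving order;
the embedding y-axis is flipped because canvas y grows downward while
scatterplot y grows upward, so the two canvases agree visually. Overlap is
allowed and expected — embeddings cluster — and the only mitigation is the
render-order shuffle, which lets occluded images surface; no collision
resolution is attempted, by design.

*Grid mode* places tiles row-major with
`per_row = floor((width − gap) / (tile_w + gap))`; rows are added as needed
and the canvas grows vertically. Non-overlap at any cohort size is a tested
invariant.

*Random mode* uses Bridson-style Poisson-disc sampling: a background grid of
cell size $r/\sqrt2$ (at most one point per cell), an active list, and up to
`k = 30` candidates per active point drawn uniformly from the annulus
$[r, 2r]$. The variant here stops after `n_points` accepted points and
tolerates under-filling with a warning instead of failing, because the
caller needs exactly one point per image and a partially filled canvas is
more useful than an error. The minimum-distance guarantee (every pair at
least `r` apart) is verified against a brute-force O(n²) oracle in the
tests. One configuration-level seed drives sampling and shuffling, making
every layout reproducible.

## The inbuilt fallback: features, embedding, clustering

Each image is abstracted to the arithmetic means of its **first six
channels**, in stored plane order, computed on the raw (pre-cleaning)
intensities — cleaning is a display transformation, and features should
describe the data, not the rendering. Images with fewer than six channels
are zero-padded (with a warning) to keep the matrix rectangular. Six is a
deliberate lowest-common-denominator: every supported platform provides at
least six channels, and the ordering convention ("initial" channels) is the
stored plane order even when a user marker list names them differently.

The 6-column matrix is embedded by **exact t-SNE**: per-point Gaussian
bandwidths calibrated to the target perplexity by bisection, symmetrized
similarities, and momentum gradient descent (early exaggeration 12 for 100
iterations, momentum 0.5 then 0.8, 500 iterations). The learning rate
follows the usual $n / (4 \cdot \text{exaggeration})$ rule floored at 50; a
fixed large rate makes small maps oscillate and keeps tight pairs from
converging. Cohorts are tens to a few hundred images, so the O(n²)
algorithm is the right tool, not a concession. Default perplexity is
$\min(30, (n-1)/3)$; a perplexity too large for the cohort is reduced to
$\max(2, (n-1)/3)$ with a warning rather than an error. Identical feature
rows embed essentially coincidently once the perplexity is large enough
that the pair dominates each other's similarity mass; at very small n the
heavy-tailed map genuinely keeps duplicates slightly apart (reference
implementations behave identically), which is why the coincidence property
is tested at n = 60.

Clustering is a **variational Bayesian Gaussian mixture** with a truncated
stick-breaking (Dirichlet-process) weight prior (concentration $1/K$,
truncation `max_components = 10`) and Gauss–Wishart component priors
($\beta_0 = 1$, $m_0$ the data mean, $\nu_0 = d$, covariance prior at the
cohort's empirical per-axis variance). Responsibilities are initialized
from k-means (seeded, 5 restarts) and updated by mean-field coordinate
ascent until they change by less than $10^{-5}$. Superfluous components
receive vanishing weight, so the number of populated components is
inferred. Labels are the most probable component, renumbered 0-based by
first appearance. A singular covariance update (possible only for
pathological inputs) falls back to a single cluster with a warning, as does
a cohort of identical rows. We evaluated ELBO-selected multi-restart
variants and a tighter within-cluster covariance prior; both degraded
recovery on synthetic cohorts (the broad prior biases the bound toward
merged solutions, the tight prior oversplits), so the single-initialization
configuration — which matches the reference implementation's defaults — is
used.

When this fallback runs, its coordinates are written in the same delimited
dialect the reader accepts, and its labels are injected as a `cluster`
metadata category, so any fallback run can be repeated later as a pure
coordinate-mode run.

## Rendering

The static canvas is a theme-colored background (black `#000000`, gray
`#404040`, dark blue `#0B0B45`) onto which thumbnails are pasted in render
order, later over earlier; thumbnail pixels are never altered by the theme.
PNG output is byte-deterministic given inputs and seed — a tested
end-to-end invariant. The stack montage renders every channel of one image
as its own cleaned single-channel tile in that channel's display color,
with the marker name drawn beneath each tile using an embedded 5×7 bitmap
font; drawing text directly into the pixel array keeps montage PNGs
device-independent and deterministic.

The live canvas is a single self-contained HTML file: the per-image records
(image name, thumbnail filename, coordinates, all metadata) are embedded as
JSON, the scatter is drawn as SVG, and plain JavaScript provides hover
tooltips, drag-pan, wheel zoom, shift-drag box zoom, PNG save and reset,
with one selectable view per metadata category and an uncolored view when
no metadata exist. The contract is the document's interactive behavior, not
any serving mechanism, so no web framework or server is involved.

## The synthetic-data generator

`cohort_recipe()`/`generate_image()` emulate what matters to this pipeline:
compact bright cell-like regions (Gaussian-profile blobs, default σ = 6 px)
over a dark background (level 8) with additive Gaussian pixel noise
(SD 4), per-channel group-specific amplitudes, and per-image multiplicative
amplitude jitter (CV 3%) as biological variability. Blob centers are placed
by Poisson-disc sampling at spacing 2.5σ, at least 3σ from the border. The
spacing is what makes effect sizes well-posed: non-overlapping blobs never
clip at the 8-bit ceiling, so a channel's spatial mean is independent of
where the blobs land, within-group variance is governed by the jitter
alone, and two groups whose amplitudes differ by `effect_size × CV` are
separated by `effect_size` pooled standard deviations in feature space — a
relationship we verified empirically (nominal 5 SD realizes ≈ 5 SD).

The generator does *not* emulate staining chemistry, spectral bleed-through,
cell-to-cell morphology variation, tissue architecture, or segmentation
ground truth. Tests passing on these fixtures therefore demonstrate the
pipeline's algorithmic contracts (cleaning operators, layout guarantees,
recovery of group structure present in channel means) — not robustness to
the full messiness of real stains.

The default recipe mirrors a 7-channel Vectra field of view at quarter
linear scale (336 × 252 px) so a full cohort generates in seconds;
recovery-style tests use 92-image cohorts — the scale of a real
92-field-of-view study — with 96 × 128 px images, because group-recovery
behavior depends on cohort size far more than on pixel count. A full-scale
(1,344 × 1,008) image is exercised where the claim genuinely concerns image
size, e.g. the thumbnail on-disk footprint.

## Known limitations

- The OME-XML parser extracts channel names only; physical pixel sizes,
  z-stacks and time series are ignored (single-plane-per-channel cohorts).
- The fallback features use only the first six channel means; images whose
  group structure lives in channels 7+ or in spatial arrangement will not
  be separated by the inbuilt pipeline (supply coordinates instead).
- Static canvases are rendered fully in memory; a 4,000 × 3,000 canvas is
  ~36 MB of doubles per color plane during assembly.
- The live canvas targets modern browsers; no fallback for `file://`
  restrictions on very old engines is attempted.
- Variational mixtures on very small cohorts (n ≲ 20) are under-resolved —
  the prior dominates — and may merge true groups; this mirrors the
  reference implementation's behavior.
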