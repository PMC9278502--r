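# imgtsne

Gallery views for multiplexed tissue-imaging cohorts.

Multiplexed imaging platforms (Vectra, CyCIF, t-CyCIF, CODEX/PhenoCycler)
produce cohorts of images with 4–64 protein-marker channels each. Before any
cell-level analysis it helps to *see the whole cohort at once*: which images
express a phenotype, which fields of view are artefactual, how images group.
`imgtsne` builds that preview as an **image t-SNE** — a 2D scatter of the
cohort in which every point is replaced by that image's thumbnail — plus a
linked interactive scatterplot carrying the per-image metadata.

It is aimed at imaging cores and computational pathology groups who need a
first exploratory look at a cohort of multichannel TIFFs before committing to
single-image viewers or segmentation pipelines.

## What it does

- **Reads** plain multi-page TIFF, OME-TIFF (channel names from the embedded
  OME-XML) and pyramidal QPTIFF, plus delimited metadata and coordinate
  side-files.
- **Cleans** each selected marker channel: median filter → Otsu threshold →
  morphological closing of the foreground mask → clearing of border-touching
  components → intensity upweighting of the surviving foreground, with
  unsigned-byte output. Cleaned channels are additively color-blended into an
  RGB composite.
- **Thumbnails** the composite by area-averaged downscaling (optionally
  channel-weighted), with optional metadata-colored borders.
- **Lays out** the thumbnails on a static PNG canvas three ways: by
  user-supplied t-SNE/UMAP coordinates, as a vertical grid, or at
  blue-noise random positions from Bridson-style Poisson-disc sampling
  (minimum pairwise distance guaranteed). Render order can be shuffled to
  reveal overlapped images.
- **Falls back**, when no coordinates or labels are given, to an inbuilt
  pipeline: each image is abstracted to the 6-vector of its first six
  channel means, the cohort is embedded with exact t-SNE and clustered with
  a variational Bayesian Gaussian mixture (truncated stick-breaking prior;
  the effective number of clusters is inferred).
- **Renders** a stack montage of all channels of a single image, and a
  self-contained interactive HTML scatterplot with hover metadata, pan,
  wheel/box zoom, save and reset.
- **Simulates** whole cohorts (Gaussian-blob immunofluorescence images with
  group-specific channel abundances in pooled-SD units), so everything above
  is testable with no external data.

## The two core algorithms

**Otsu threshold.** For an 8-bit histogram with class probabilities
$\omega_0(t), \omega_1(t)$ and class means $\mu_0(t), \mu_1(t)$ induced by a
threshold $t$, the method picks $t^\* = \arg\max_t\,
\omega_0(t)\,\omega_1(t)\,[\mu_0(t) - \mu_1(t)]^2$, which minimizes the total
within-class variance. Ties (exact plateaus) resolve to the plateau midpoint.

**Variational Gaussian mixture.** The fallback clustering fits
$p(x) = \sum_{k=1}^{K} \pi_k\, \mathcal N(x \mid \mu_k, \Sigma_k)$ with a
truncated stick-breaking prior $\pi_k = v_k \prod_{j<k}(1 - v_j)$,
$v_k \sim \mathrm{Beta}(1, \gamma)$, and Gauss–Wishart priors on
$(\mu_k, \Sigma_k^{-1})$, by mean-field variational inference;
superfluous components receive vanishing weight, so `max_components` is a
truncation level, not a cluster count.

## Worked example

```r
library(imgtsne)

# a synthetic 40-image, 7-channel cohort: two groups whose channel-2 and
# channel-5 abundances differ by 5 pooled SDs
recipe <- cohort_recipe(n_images = 40, n_channels = 7, image_dims = c(96, 128),
                        blob_count = 8, effect_size = 5, seed = 42)
cohort <- generate_cohort(recipe, "demo_cohort", format = "ome-tiff")

images <- read_cohort("demo_cohort/images")
images[[1]]
#> <multiplex_image> img001 [ome-tiff]
#>   7 channel(s), 96 x 128 px
#>   markers: marker01, marker02, marker03, marker04, marker05, marker06, marker07

# inbuilt fallback: channel-mean features -> exact t-SNE -> variational mixture
emb <- embed_and_cluster(images, seed = 42)
glance(emb)
#> # A tibble: 1 × 3
#>   n_images n_components_used  seed
#>      <int>             <int> <int>
#> 1       40                 2    42
head(tidy(emb), 4)
#> # A tibble: 4 × 4
#>   image_id     x     y cluster
#>   <chr>    <dbl> <dbl>   <int>
#> 1 img001    8.27 -5.19       0
#> 2 img002   -7.40  4.89       1
#> 3 img003   11.8  -4.27       0
#> 4 img004   -7.08  4.96       1
```

The mixture infers two populated components (out of ten allowed) and — as
the cross-tabulation against the generator's group labels shows — assigns
all 20 + 20 images to the right group. A full run then produces the canvas,
tiles and live scatterplot:

```r
cfg <- run_config(input_dir = "demo_cohort/images", out_dir = "demo_out",
                  layout = "coords", metadata_dir = "demo_cohort/metadata",
                  border = TRUE, border_category = "group",
                  canvas_dims = c(1600, 1200), max_edge = 64, seed = 42)
res <- run_pipeline(cfg)
#> demo_out/cohort_coords_42.png    (static canvas, one bordered thumbnail per image)
#> demo_out/output_tiles/*.png      (40 tiles)
#> demo_out/live_canvas.html        (interactive scatter with hover metadata)
#> demo_out/generated_coords.csv    (fallback coordinates, reusable as input)
```

The same can be driven from a shell via the thin CLI wrapper:

```sh
Rscript inst/cli/imgtsne.R --input-dir demo_cohort/images --out-dir demo_out \
    --layout coords --metadata-dir demo_cohort/metadata --seed 42
```

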