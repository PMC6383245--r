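---
title: "Range-envelope suitability modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range-envelope suitability modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichebox)
```

## The model and its assumptions

`nichebox` implements a presence-only rectilinear envelope model. The niche
is represented as an axis-aligned box: per environmental dimension, the
closed interval between the minimum and maximum observed at occupied raster
cells. A cell's suitability score is its Euclidean distance to that box —
zero inside (every factor within the observed range), and otherwise the
root-sum-of-squares of the per-dimension distances to the nearer interval
endpoint.

The model's assumptions are strong and worth stating plainly:

* **The realized niche is a box.** Interactions between factors are ignored:
  a cell that pairs the coldest observed temperature with the driest
  observed precipitation is scored suitable even if no occurrence combines
  them. This is the classic rectilinear-envelope simplification.
* **Every record is informative.** The box is the min/max hull, so a single
  mislabelled or georeferencing-error record enlarges the envelope
  permanently. There is no outlier rejection — by design: the guarantee that
  every occurrence site scores maximal similarity is the method's selling
  point for sparse-record species, and its main fragility for noisy
  databases. Records should be cleaned upstream.
* **Presence-only.** Nothing constrains the model away from regions the
  species avoids for non-environmental reasons (dispersal limits,
  competition, land use).

One cluster is fitted — all occurrences form a single envelope. A
multi-envelope (disjunct-niche) extension would need a rule for assigning
points to clusters that the method does not define; it is out of scope.

## Pipeline order and value spaces

The full pipeline is: extract occurrence-cell values → optional PCA →
per-dimension linear standardization to [0, 100] → envelope fit → distance
surface → classification → soil overlay. Two modes are exposed:

* **`mode = "pca"`** reduces collinear climate layers first (components are
  eigenvectors of the sample covariance of the occurrence samples, kept up
  to a cumulative explained-variance target, default 0.95, or a pinned
  count). Standardization is then applied to the component scores, and the
  envelope lives in standardized score space. PCA before standardization
  follows the conventional stage order for this model family; covariance
  (not correlation) PCA is used, so dominant-variance layers dominate the
  rotation — pinning the component count is advisable when mixing units.
* **`mode = "raw"`** skips PCA and standardizes the raw layers directly.
  Envelope bounds then correspond one-to-one to interpretable factor ranges,
  which is why the factor range table is always computed on raw-space
  samples regardless of mode.

Every sample matrix, envelope and stack carries a value-space tag (`raw`,
`pca`, `standardized`); distance evaluation refuses mismatched spaces rather
than silently producing nonsense.

A deliberate interpretation choice: the envelope bounds are the min/max of
the **occurrence samples** after transformation, not the min/max of the
whole layer. Taking layer-wide extremes would make every in-layer cell score
distance zero — a degenerate model in which everything is suitable. Only the
occurrence-range reading produces the intended behaviour (occurrence cells
at 100% similarity, everything else graded by distance).

Distance aggregation uses the square root of the summed squared
per-dimension distances, making the score a true metric (the Euclidean
distance from the point to the box). A `aggregate = "sumsq"` switch exposes
the raw sum of squares for error-bookkeeping (`training_error()` uses it);
the two orderings of cells are identical, so classification is unaffected by
the choice.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `new_min`, `new_max` | 0, 100 | Target bounds of the linear standardization; the conventional percentage-like scale. |
| `variance_target` | 0.95 | Cumulative explained variance retained by PCA when the component count is not pinned. |
| `n_classes` | 5 | Suitability classes: class 0 (distance 0) plus four equal-width bins over `(0, max_d]`. Explicit breaks override. |
| `suitable_classes` | `{0}` | Classes counted as climatically suitable in the overlay. |
| `dedup` | `TRUE` | Collapse occurrence points sharing a raster cell. The model operates on cells; duplicates cannot change a min/max fit and would only distort the range table's mean/SD. |
| `earth_radius_m` | 6,371,000 | Sphere radius for geographic cell areas. |

Standardization **extrapolates** linearly outside the fitted range
(prediction cells routinely exceed occurrence-derived extremes); values may
fall outside [0, 100] and distances remain well defined. Degenerate
(constant) dimensions have no definable scale and are excluded from distance
computation with a warning rather than dividing by zero.

## Numerical and boundary conventions

* **Rasterization**: half-open cells; a point on a cell edge belongs to the
  cell whose fractional index floors to it, row 0 at the raster's top edge.
  Points outside the extent or on nodata cells are dropped with a logged
  count (an error only if nothing remains) — occurrence databases are noisy,
  and a hard failure per stray point would be unusable.
* **Class breaks**: intervals are half-open `(lo, hi]`; a distance exactly
  on a break goes to the lower class; class 0 is reserved for distance
  exactly 0, so the class-0 set is invariant to the class count.
* **Nodata**: propagates through every cell-wise operation. In the soil
  overlay, soil nodata with valid climate yields nodata, not unsuitable —
  unknown is not evidence of absence of suitability.
* **Alignment**: layers must agree exactly in shape, georeference and CRS.
  Misalignment is a hard error naming the first offending layer; silent
  resampling would corrupt a min/max fit invisibly.
* **Geographic areas** use the exact spherical band formula
  `R² Δλ (sin φ_top − sin φ_bottom)` per raster row, which reduces to the
  familiar `cos φ` scaling for identical cells at different latitudes.
* **Reproducibility**: rasters are written with 17 significant digits
  (`%.17g`, lossless for doubles); model sidecars store doubles as C99
  hexadecimal float strings, so a saved and reloaded model reproduces
  predictions bit-for-bit. All randomness in the synthetic module flows
  through one explicit integer seed per call; no global RNG state is left
  behind.

## The synthetic-data generator

`make_landscape()` produces spatially autocorrelated layers by Gaussian
smoothing of white noise (length scale in cells) rescaled to plausible
bioclimatic unit ranges; `make_soil()` produces contiguous categorical
patches as the nearest-seed partition of random points; `make_truth()`
declares a known suitable region (an explicit raw-space box intersected with
a suitable-soil set); `sample_occurrences()` draws occurrence cells
uniformly, and noiselessly, from that region. Defaults emulate a modest
regional study: six factors, 200 × 200 cells at 30 arc-seconds, smoothing
length 5 cells, a true envelope at the 25–75% layer quantiles, and 50–158
occurrence records — the scale of a small GBIF collation for a cultivated
species.

What the generator deliberately does **not** emulate: real covariance
structure between climate factors (layers are independent fields), elevation
gradients, geographic realism of soil units, coordinate error and sampling
bias in occurrence records, and false presences. Passing tests therefore
demonstrate algorithmic correctness — containment guarantees, oracle
agreement, determinism, recovery of a known envelope — not predictive skill
on real species data, which depends on record quality and niche-shape
assumptions no synthetic test can certify. Occurrence sampling is noiseless
because the model guarantees every record shapes the fit; a noise option for
robustness experiments can be layered on by perturbing the sampled
coordinates before extraction.

Test and validation problem sizes (200 × 200 landscapes, 500-sample
recovery experiments with 100 replicates, 1,000 random point–box pairs) were
chosen so the full suite documents the model's properties in seconds on a
single CPU while keeping Monte-Carlo noise far below the asserted margins;
the envelope-recovery experiment's expected per-side gap for uniform samples
is `width/(n+1)`, ≈ 0.2% of the interval width at n = 500, an order of
magnitude inside the 2% bound tested.

## Known limitations

* The box-niche assumption overpredicts at the corners of factor space and
  cannot represent disjunct niches (single cluster).
* Min/max fitting is maximally sensitive to single aberrant records.
* Covariance-based PCA mixes units; standardizing before PCA (a correlation
  PCA) is a defensible alternative the pipeline does not currently expose.
* No reprojection or resampling: co-registration of inputs is the user's
  responsibility, and only ESRI ASCII grids are read natively.
* Areas per administrative region (zonal statistics over polygons) are not
  computed; area summaries are per suitability class over the whole grid.
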