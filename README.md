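# phenocrown

Detection of mass-flowering tree crowns in high-resolution multispectral
satellite imagery, and tracking of those crowns across acquisition dates.

Canopy trees with "big-bang" phenology (e.g. yellow-flowering *Tabebuia*
species) put their entire reproductive population on display for a day or
two after a triggering rain. In a well-timed 2.4 m-resolution 4-band
image each flowering crown is a bright, compact object a few pixels
across. phenocrown maps those objects to crown centroids and, from two
flowering events, partitions the population into crowns common to both
dates, crowns lost (fallen, dead or non-reproducing), and new crowns.
It is written for remote-sensing ecologists who want a reproducible,
fully automatic version of this analysis, with a synthetic scene
generator standing in for proprietary imagery.

## Method

For a scene with pixel spectra `r` and a flower target spectrum `t`:

- **Pure-pixel extraction.** A one-class SVM (RBF kernel,
  `K(x,y) = exp(-γ‖x−y‖²)`) is fit to the top-quantile flower-likeness
  pixels by solving the dual `min ½ αᵀKα` subject to
  `0 ≤ αᵢ ≤ 1/(νl)`, `Σαᵢ = 1`; pixels with
  `f(x) = Σᵢ αᵢ K(xᵢ,x) − b ≥ 0` form the pure-pixel mask, and their
  per-band mean is the endmember `t`. `ν` bounds the training outlier
  fraction; `γ` is scene-dependent (defaults `ν = 0.1`, `γ = 0.1` on
  percent-reflectance features).
- **Joint spectral mapping.** Per pixel, the spectral angle
  `θ = cos⁻¹(t·r / (|t||r|))` and the flower fractional abundance `F`
  from linear unmixing `r_b = Σᵢ Fᵢ R_ib + E_b` under `ΣFᵢ = 1`,
  `Fᵢ ≥ 0`. Pixels with `F > 0.80` are pure flower (region A); pixels
  with `0.25 < F ≤ 0.80` and `θ < 0.05` rad are mixed crown edges
  (region B).
- **Crown isolation.** ISODATA clustering into 25 spectral classes;
  classes whose pixel majority is region A/B form the flower raster;
  8-connected components become centroids; centroids within 5 m merge
  (transitive closure, iterated to a fixed point) into single crowns.
- **Change detection.** Greedy nearest-pair one-to-one matching of two
  dates' centroids within 5 m; `match_rate()` scores detections against
  a reference survey table.

## Worked example

```r
library(phenocrown)

# a 256 x 256 Quickbird-like scene pair: 100 crowns, half flower on both dates
pair <- generate_scene_pair(scene_params(n_crowns = 100, seed = 7),
                            shared_fraction = 0.5)
res  <- run_two_date(pair$image1, pair$image2, run_config(seed = 7))
glance(res$report)
#> # A tibble: 1 × 6
#>   n_date1 n_date2 n_common n_lost n_new tolerance
#>     <int>   <int>    <int>  <int> <int>     <dbl>
#> 1      75      75       50     25    25         5
```

75 crowns are detected on each date (50 shared + 25 date-exclusive per
the planted truth); all 50 shared crowns are re-identified as common,
and the 25 + 25 exclusive crowns appear as lost and new — the planted
fates, recovered end to end from the pixel data.

The packaged aerial-photo comparison table (18 reference sites) gives
the single-date detection confirmation rate:

```r
match_rate(aerial_photo_counts(), "2002")
#> [1] 88
```

i.e. 88% of the crowns detected in the first acquisition (84 of 96) were
confirmed by the reference air photos.

Diagnostics: `autoplot(maps)` draws the abundance-vs-angle plane with
the A/B thresholds, `autoplot(crowns)` the centroid map, and
`plot_change()` the common/lost/new partition. `tidy()`/`glance()`
methods give tabular views of fitted models and change reports.

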