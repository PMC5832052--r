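# pqct — quantitative CT assessment of paraquat-induced lung injury

Paraquat (PQ) poisoning attacks the lung: over the first days after
ingestion, ground-glass opacity and consolidation spread through the
parenchyma, and how *fast* they spread predicts survival better than most
bedside parameters. Plasma PQ assays, the reference prognostic test, are not
available in every hospital — but serial chest CT is. `pqct` implements an
automated image-analysis pipeline that quantifies injury progression from two
routine CT scans (admission and follow-up) and reports a single prognostic
number, the **ratio of injured lung volume fraction**:

```
f(scan)  =  V_injured / V_lung            (injured lung volume fraction)
ratio    =  f(scan 1) / f(scan 2)         (admission over follow-up)
```

A low ratio means the injured volume grew quickly between the scans — rapid
disease evolution and poor prognosis. In the motivating cohort the ratio was
0.73 ± 0.17 in survivors versus 0.40 ± 0.14 in nonsurvivors, with no
survivors below 0.3 and no deaths above 0.8.

The per-scan pipeline is:

1. **Edge-preserving smoothing** — slice-wise Perona–Malik anisotropic
   diffusion (`anisotropic_diffusion()`).
2. **Lung segmentation** — seeded region growing: a 40 × 40 window around a
   seed near the pleura gives local extremes `CTmax`, `CTmin`, and voxels
   join the lung while `|CT(p) − CT(seed)| < 0.3 · (CTmax − CTmin)`;
   enclosed dense tissue is restored by cavity filling
   (`segment_lungs()`).
3. **Texture features** — nine per in-lung pixel over a 7 × 7 window
   (centre HU; window mean, SD, max, min, skewness, kurtosis; the 3-D mean
   CT value correlation `rco = (m_n − m_{n−1})(m_n − m_{n+1})`, which flags
   partial-volume pixels; and the air-density area fraction below −825 HU)
   (`extract_feature_table()`).
4. **Injury classification** — a two-layer feed-forward neural network with
   18 sigmoid hidden units and a sigmoid output, trained with cross-entropy
   and an iteration cap of 5000 on a stratified 70/15/15
   train/validation/test split (`train_injury_ann()`, `classify_volume()`).
5. **Vessel removal** — blood vessels share HU with injured tissue, so a
   Hessian-based multiscale (Frangi) vesselness filter segments them and
   they are subtracted from the candidate mask (`vesselness()`,
   `remove_vessels()`).
6. **Post-processing and volumetrics** — very small regions are removed,
   volumes are computed by voxel counting, and the two scans give the
   prognostic ratio (`remove_small_regions()`, `injured_fraction()`,
   `fraction_ratio()`).

A deterministic **digital chest phantom** (`phantom_spec()`,
`render_phantom()`, `render_scan_pair()`) with exact ground-truth masks makes
every stage testable without clinical data, and `sample_cohort()` +
`compare_groups()`/`cohort_table()` reproduce the cohort-level
survivor-versus-nonsurvivor statistics (Welch t / Mann–Whitney / χ²).

## Worked example

```r
library(pqct)

# a serial scan pair with known ground truth (admission 20%, follow-up 50%)
pair <- render_scan_pair(phantom_spec(seed = 5), target_fractions = c(0.2, 0.5))

# train the 9-18-1 sigmoid network on labelled pixels from the admission scan
sm <- anisotropic_diffusion(pair$scan1$volume)
ds <- build_dataset(sm, pair$scan1$truth$lung, pair$scan1$truth$injured,
                    n_per_class = 1000, seed = 5)
model <- train_injury_ann(ds, seed = 5)
glance(evaluate_classifier(model, split_dataset(ds, seed = 5)$test))
#> # A tibble: 1 × 6
#>       n   auc accuracy sensitivity specificity threshold
#>   <int> <dbl>    <dbl>       <dbl>       <dbl>     <dbl>
#> 1   300     1        1           1           1       0.5

# run the full pipeline on both scans
res <- run_pipeline(list(scans = list(pair$scan1$volume, pair$scan2$volume),
                         model = model))
res$volumetrics
#> # A tibble: 2 × 4
#>   scan_id whole_lung_ml injured_ml injured_fraction
#>   <chr>           <dbl>      <dbl>            <dbl>
#> 1 scan1            11.0       2.21            0.200
#> 2 scan2            11.0       5.75            0.521
res$ratio
#> <pq_ratio> fractions 20.0% (scan 1) / 52.1% (scan 2); ratio 0.38
```

The held-out classifier evaluation is perfect on this phantom (the injured
texture is strongly separable from aerated parenchyma), the estimated
per-scan fractions are 0.200 and 0.521 against ground truth 0.200 and 0.500,
and the estimated prognostic ratio 0.38 sits next to the true 0.40. With the
fractions reported for the clinical example — 35.4% and 78.1% —
`fraction_ratio(0.354, 0.781)` prints a ratio of 0.45.

A thin command-line front end with `phantom`, `train`, `quantify`, `ratio`
and `cohort-stats` subcommands ships in `inst/cli/pqct.R`; a YAML config can
drive the whole pipeline (see `?run_pipeline`).

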