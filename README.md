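# tundramorph

Object-based mapping of polygonal tundra landforms and robust NDVI trend
analysis, with built-in synthetic landscapes for testing.

Arctic coastal-plain tundra is a mosaic of patterned-ground landforms —
ice-wedge polygons (low/flat/high center), drained thaw-lake basins, ponds,
lakes, rivers, riparian corridors, sandy barrens, dunes and drained slopes —
that control hydrology, vegetation and carbon cycling at 10–100 m scales.
`tundramorph` provides the three analysis stages needed to produce and
validate regional maps of this mosaic from 30 m multispectral imagery:

1. **Landform classification** (OBIA): region-merging segmentation of a
   nine-band reflectance scene into image objects, followed by a rule
   hierarchy over spectral indices and object geometry. Objects split into
   wet/dry tundra by NDWI; rules then extract CLC and nDTLB, open water
   (fused into water bodies and sized as CS > 100,000 ha, large > 90 ha,
   medium > 20 ha, small > 1 ha lakes, or ponds ≤ 1 ha, with rivers peeled
   off by roundness 4πA/P²), ice, FC, RC (river-adjacent), sand/gravel
   (SB/SD via BlueMax = ρ_Blue/MaxDiff), DS (high albedo), with LC/HC
   residuals guaranteeing that every pixel gets one of the fifteen legend
   classes. A proximity pass rectifies the known confusions (pond/CLC by a
   lake → nDTLB; by a river → SB).
2. **NDVI trend mapping**: per-pixel Theil-Sen regression over a seasonally
   filtered (Jul 1 – Aug 30), cloud-masked time stack — slope = median of
   all pairwise slopes (y_j − y_i)/(t_j − t_i), intercept = robust level at
   the 2014 reference year, plus rank-based (Sen/Kendall) 95% confidence
   bounds and multi-sensor (TM/ETM+/OLI) bias diagnostics.
3. **Accuracy assessment**: stratified random reference sampling, confusion
   matrices (rows = classification, columns = reference), overall accuracy
   100·trace/N, per-class user/producer accuracies, Cohen's kappa
   κ = (p₀ − p_e)/(1 − p_e), and misclassification composition.

Because the real inputs are tens of thousands of km² of satellite imagery,
the package includes a first-class synthetic module: labeled landform
mosaics with class-specific spectral signatures, and NDVI time stacks with
known trends, sensor offsets and masking — so the full pipeline runs and is
tested at desk scale.

## Worked example

```r
library(tundramorph)

mos   <- generate_landform_mosaic(seed = 42)      # 128 x 128 truth mosaic
scene <- render_scene(mos, noise_sd = 0, seed = 1)
map   <- classify_scene(scene)
print(map)
#> landform_map: 16384 classified pixels
#>         CLC          DS          FC          HC  lake_large lake_medium
#>           9         707        1477        3362        1334         500
#>  lake_small          LC       nDTLB        pond          RC       river
#>          89        1886        4814          14         503         256
#>          SB          SD
#>         588         845

mean(map$labels == mos$labels, na.rm = TRUE)      # truth recovery
#> 0.9997

head(landform_attribute_table(map), 4)            # area budget + SMR rank
#>      landform area_km2 smr_rank
#> 2  lake_large   1.2006        2
#> 3 lake_medium   0.4500        3
#> 4  lake_small   0.0801        4
#> 5       river   0.2304        5
```

The classified map recovers 99.97% of the ground truth on a noise-free
rendering; the attribute table's areas (0.09 ha per pixel) sum exactly to
the scene area, and the soil-moisture-regime rank follows the wet→dry class
ordering.

Trend estimation on the textbook micro-example — points (0,0), (1,1),
(2,10), whose pairwise slopes are {1, 9, 5}:

```r
theil_sen(0:2, c(0, 1, 10), ref_year = 0)
#> $slope      5      (median of pairwise slopes)
#> $intercept  0
#> $ci_low 1  $ci_high 9  $n_pairs 3
```

Accuracy statistics recomputed from the packaged regional confusion matrix
(1000 stratified reference sites, 13 map classes):

```r
cm <- acp_reference_confusion()
overall_accuracy(cm)          #> 75.7
round(cohens_kappa(cm), 3)    #> 0.706
subset(user_producer_accuracies(cm), class == "FC")$producer_pct  #> 40.5
misclassification_composition(cm, "FC")["HC"]                     #> 63.8
```

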