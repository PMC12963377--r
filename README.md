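# laggr

Lymphoid-aggregate detection and immune statistics for cell-resolved
spatial transcriptomics, with companion IHC and clinical-endpoint modules.

## What it does

Lymphoid aggregates (LAs) in tumors — up to mature tertiary lymphoid
structures — are usually found by looking for B-cell-dense neighborhoods.
Aggregates that have matured toward plasma-cell output can hold few B cells
and are missed that way. `laggr` demarcates LAs **independently of B-cell
content**, from the spatial co-occurrence of the two lymphoid-organizing
chemokines:

1. **Seeds** — all CCL19⁺ cells within 50 µm of a CXCL13⁺ cell
   (boundary-inclusive, center-to-center);
2. **DBSCAN** — clusters of ≥ 15 seeds within a 75 µm radius;
3. **Merging** — clusters with centroids within 400 µm merged
   (single-linkage, one pass);
4. **Polygons** — alpha-shape concave hull (α = 150 µm) of each cluster,
   dilated by a 100 µm buffer with round joins;
5. **Assignment** — every cell inside or on a polygon belongs to that LA.

Over the detected aggregates it computes the statistics that characterize
them:

* **PBR**, the plasma-cell-to-B-cell ratio:
  `PBR = log2(n_PC + 1) − log2(n_B + 1)` (high PBR ⇔ PBR > 0 ⇔ more plasma
  cells than B cells);
* compartment cell-type fractions inside vs outside LAs and their
  enrichment `log2(f_in / f_out)`;
* per-LA subset densities (cells/mm²) and the exhaustion log-ratio
  `log2((n_TEX + 1) / (n_PEX + 1))` for terminally (T_TEX) vs progenitor
  (T_PEX) exhausted CD8 T cells;
* associations by Spearman correlation (exact permutation p for n ≤ 9,
  t-approximation above) plus a least-squares trend line.

Companion modules: cell QC / representative-cell selection /
low-confidence-label filtering; IHC LA identification on CD20/CD3/CD23/MUM1
centroid tables with tumor-bed classification and density comparisons;
clinical endpoint summaries (RECIST 1.1 single-lesion best response, CA19-9
response with the bilirubin < 3 mg/dL evaluability rule, pathology
proportions, Kaplan–Meier medians); and synthetic-data generators with full
planted ground truth for all of the above.

## Worked example

```r
library(laggr)

tg  <- generate_tissue(tissue_sim_params(n_las = 5, seed = 2,
                                         width = 6000, height = 5000,
                                         min_la_separation = 1200,
                                         chemokine_noise_rate = 0))
las <- detect_lymphoid_aggregates(tg$cellmap)
las
#> <la_set 'sim_seed2': 5 lymphoid aggregate(s), 200 seed cells, 2153 cells assigned>

prof <- la_profiles(las)
prof[, c("la_id", "area_um2", "n_B", "n_PC", "pbr", "log2_tex_pex", "high_pbr")]
#>   la_id area_um2 n_B n_PC         pbr log2_tex_pex high_pbr
#> 1     1 118683.6  52   97  0.88678939    0.8231222     TRUE
#> 2     2 108139.3 177   34 -2.34645041   -2.3219281    FALSE
#> 3     3 113662.7  88   89  0.01611967   -0.4854268     TRUE
#> 4     4 119343.8  66  138  1.05285188    1.2563398     TRUE
#> 5     5 102470.8  91  111  0.28379297    0.3033921     TRUE

associate_pbr(prof, "log2_tex_pex")
#> Spearman rho = 1.000 (p = 0.01667, exact permutation), LS slope = 1.012, intercept = -0.063, n = 5
```

Each row is one detected aggregate: its boundary-polygon area (µm²), B- and
plasma-cell counts, PBR, and exhaustion log-ratio. Here the generator
planted a unit slope between PBR and the TEX:PEX log-ratio, and the
association analysis recovers it (slope 1.012) with a perfect rank
correlation over the 5 aggregates. The clinical module reproduces a trial
endpoint table from a per-patient cohort:

```r
summarize_cohort(generate_clinical_cohort("trial_2026", seed = 1))
#> Cohort summary
#>   enrolled 28; resected 22 (79%); completed treatment 26
#>   CAP 0/1/2/3: 2/2/16/2 (% of resected: 9/9/73/9)
#>   R0 19 (86%); pN0/1/2: 11/7/4 (pN0 50%)
#>   ORR 7/26 (27%); SD 19 (73%); shrinkage 21 (81%)
#>   CA19-9 decreased 19/26 (73%); normalized 8 (31%)
#>   grade-4 AEs: 4
```

A thin CLI wraps the same functions
(`inst/cli/laggr simulate | detect-la | la-stats | ihc | clinical | report`),
reading/writing CSV cell tables, MatrixMarket expression matrices, and
GeoJSON polygons (coordinates stay in µm).

## Vignette

`vignettes/lymphoid-aggregate-analysis.Rmd` documents the model and its
assumptions, every tunable with units and defaults, what the synthetic
generators do and do not emulate, the numerical choices, and known
limitations.
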