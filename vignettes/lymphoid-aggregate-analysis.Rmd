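---
title: "Demarcating lymphoid aggregates and their immune statistics"
author: "laggr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demarcating lymphoid aggregates and their immune statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laggr)
```

## The problem

Lymphoid aggregates (LAs) — dense intra-tissue clusters of lymphocytes, up to
and including mature tertiary lymphoid structures — shape anti-tumor immunity
in pancreatic ductal adenocarcinoma and other solid tumors. The conventional
way to find them in cell-resolved spatial transcriptomics is to look for
B-cell-dense neighborhoods. That breaks down exactly where it is most
interesting: aggregates that have matured toward plasma-cell output can hold
few B cells. `laggr` therefore demarcates LAs *independently of B-cell
content*, from the spatial co-occurrence of cells expressing the two
chemokines that organize lymphoid neogenesis, CCL19 and CXCL13, and then
computes the immune statistics defined over the detected aggregates.

## The demarcation procedure

Given a cell table (planar coordinates in micrometres, a cell-type label from
a controlled vocabulary, and per-gene transcript counts including CCL19 and
CXCL13), `detect_lymphoid_aggregates()` composes five stages:

1. **Seed selection.** A cell is chemokine-positive when its transcript count
   is at least `marker_positivity_min` (default 1 — the positivity notion is
   stated without a count threshold in common usage, so the floor of one
   detected transcript is the default and is configurable). The seed set is
   every CCL19-positive cell with a CXCL13-positive cell within `pair_radius`
   = 50 um, center-to-center and boundary-inclusive. A CCL19+CXCL13
   double-positive cell pairs with itself by default (`self_pairing`),
   because such a cell already evidences local co-occurrence.
2. **Density clustering.** DBSCAN over the seed cells with `eps =
   dbscan_radius` = 75 um and the core condition "at least
   `min_cluster_cells` = 15 seeds within eps, counting the cell itself".
   Neighbor-count conventions differ between DBSCAN implementations;
   counting self is declared and configurable. Expansion proceeds in
   ascending cell order, so border cells reachable from two clusters join
   the first-discovered one and the stage is deterministic without a seed.
   Noise cells are discarded; every emitted cluster has at least 15 members.
3. **Centroid merging.** Clusters whose centroids lie within
   `merge_distance` = 400 um are merged by single-linkage connected
   components computed once on the original centroids. A single pass is
   used, rather than iterative recomputation, because it is
   order-independent and cannot chain indefinitely.
4. **Boundary polygons.** The concave hull of each merged cluster's seed
   cells is the alpha-shape with disc radius `hull_alpha` = 150 um (twice
   the clustering radius; no published algorithm or parameter is attached to
   "concave hull", so the alpha-shape with this radius is the package's
   choice), dilated by `hull_buffer` = 100 um with round joins approximated
   by 32 segments per quarter turn. Degenerate clusters get closed forms
   (one point gives a disc, collinear points a capsule); a disconnected or
   pinched alpha complex falls back to the convex hull, with a log entry.
   The buffered polygon always contains every member point.
5. **Cell assignment.** Every cell inside or on an LA polygon is assigned to
   it; cells inside several overlapping polygons go to the LA with the
   nearest source-cluster centroid (ties to the lower id). Everything else
   is "outside".

All distance comparisons in the pipeline are boundary-inclusive (`<=`),
matching the plain reading of "within". Coordinates are planar micrometres
with y increasing upward; no axis flip is ever applied implicitly, so
image-convention inputs must be pre-flipped by the caller. The pipeline is
invariant to cell-row order and translation, and rotation changes areas only
within polygonization tolerance (about 1%).

## Statistics over aggregates

* **PBR** — the plasma-cell-to-B-cell ratio, `log2(nPC + 1) - log2(nB + 1)`;
  an aggregate with more plasma cells than B cells ("high PBR") has PBR > 0.
* **Compartment fractions** (`compartment_fractions()`) — relative cell-type
  fractions pooled over all LA member cells versus all outside cells.
  "Mean relative fraction" can also be read as a per-LA average, so both
  modes are provided (`mode = "per_la"`); pooling is the default because it
  weights cells, not aggregates. Cells labelled "unassigned" (see below)
  are excluded from all denominators.
* **Enrichment** (`enrichment_score()`) — log2 ratio of the fractions. With
  both fractions positive no pseudocount is used; when one is zero and
  compartment totals are supplied, half of one cell over the smaller
  compartment total is added (and declared in the result), otherwise the
  score is reported missing.
* **Per-LA profiles** (`la_profiles()`) — densities in cells/mm^2
  (`count / area_um2 * 1e6`) computed from raw counts; pseudocounts appear
  only inside log-ratios. The exhaustion log-ratio
  `log2((nTEX + 1) / (nPEX + 1))` mirrors the PBR's +1 convention, since the
  handling of zero counts is otherwise unspecified.
* **Associations** (`associate_pbr()`) — Spearman correlation with average
  ranks for ties and a two-sided p-value from the t-approximation (exact
  permutation enumeration for n <= 9, where the t-approximation is poor),
  plus a least-squares line for the trend. Per-patient inside-versus-outside
  exhaustion ratios (`inside_outside_patient_ratio()`) pool counts within
  each compartment, where the count ratio equals the density ratio because
  the compartment area cancels.

Upstream of the niche analysis, `qc_filter_cells()` keeps cells with at
least 10 detected genes and 20 total transcripts (inclusive),
`select_representative_cells()` retains up to 500 cells per cluster closest
to the cluster mean — similarity is Euclidean distance on depth-normalized,
log1p-transformed counts, the common convention where only "most similar" is
specified; Pearson distance is available — and `filter_low_confidence()`
sets labels with prediction scores strictly below 0.6 to "unassigned".

## The IHC module

`identify_ihc_las()` operationalizes the histology-side definition —
compact clusters of more than 50 CD20+ cells with a proximal CD3+ cluster —
on marker-centroid tables. The published workflow outlined aggregates by
hand; this module substitutes an explicit, reproducible surrogate: DBSCAN
over CD20+ centroids (eps 40 um, 5 neighbors), the strict `> 50` member
rule, and at least 20 CD3+ cells within 50 um of the cluster hull. "Compact"
and "proximal" have no published quantitative definition, so these defaults
are placeholders and every one is configurable. Intra- versus extra-tumoral
location uses the polygon centroid against the tumor-bed annotation
(inclusive on the boundary); intra-tumoral plasma-cell density is MUM1+
cells inside the bed over the bed area. CD23 positivity of an aggregate
defaults to >= 3 CD23+ cells — a package default, not a published value.
Group comparisons use the two-sided Mann-Whitney test, and plasma-cell
versus LA-burden relations use simple linear regression.

## The clinical module

`summarize_cohort()` computes the endpoint summary of a neoadjuvant trial
cohort: RECIST 1.1 best response of a single target lesion (partial response
at a best change of -30% or better, inclusive; progression requires both
+20% from the nadir and the +5 mm absolute rule, which applies even though
only the -30% line is usually drawn, because the criteria are RECIST v1.1),
CA19-9 response (draws at bilirubin >= 3 mg/dL dropped; decrease = last <
first; normalization = first > 37 U/mL and last <= 37), pathology
proportions, a grade-4 adverse-event instance count, and Kaplan-Meier
medians via the product-limit estimator with log-log intervals, where the
median is the smallest time with survival at or below 0.5 ("not reached"
when the curve never crosses it). Percentages round to the nearest integer,
half away from zero; denominators are enrolled patients for the resection
rate, resected patients for pathology, and patients completing treatment
with at least two measurements for response and CA19-9 rates (the
over-enrolled view is also emitted, since summary tables are published both
ways — one published partial-response cell, 16 of 22 printed as 72%, is
consistent only with truncation and is therefore matched as a count).

## What the synthetic data emulates

`generate_tissue()` plants the structure the analysis assumes, with full
ground truth: background cells uniform over a rectangle with a fixed type
mix; LAs as discs (radius 100 ± 10 um) with Dirichlet-sampled,
lymphocyte-rich compositions; chemokine organizer cells inside each disc;
Poisson stray chemokine-positive singletons; and a planted linear coupling
in which each LA's log2 TEX:PEX count ratio targets
`beta0 + beta1 * PBR + Normal(0, sigma)` (defaults 0, 1, 0.25). The coupling
is implemented on counts — T_PEX is drawn, then T_TEX is set to match the
target with +1 pseudocounts and rounded — precisely so the analysis module's
own estimator can recover the planted slope. Defaults are chosen once as
realistic study conditions: about 10 aggregates per tissue section and a
mean of 400 member cells per aggregate (reported size distributions give
only medians of roughly this order; 400 keeps desk-scale runtimes while
preserving every density relationship), and 60 CCL19 and 60 CXCL13
organizers per aggregate so that the seed density at the center of an
aggregate comfortably exceeds the 15-in-75-um core condition across the
whole radius distribution, as it must in any aggregate the chemokine rule
can see at all. The background carries the same vocabulary at different
proportions so enrichment scores are finite and non-trivial, and
`outside_log2_tex_pex` lets a cohort simulation give each patient a shared
exhaustion tone inside and outside aggregates, without which inside and
outside ratios would be independent by construction. Stray chemokine noise
is a homogeneous Poisson process — the simplest stationary false-positive
model for the pairing stage.

What the generator does *not* emulate: full gene panels, segmentation
errors, transcript bleed-over between adjacent cells, anisotropic or
non-disc aggregate shapes, and within-tissue density gradients. Passing
recovery tests therefore show that the pipeline implements its definition
correctly and recovers planted structure under clean conditions; they do
not certify performance on real sections, where the stated parameters
(pairing radius, core threshold, alpha radius) interact with segmentation
and panel quality.

## Numerical choices and verification scale

Polygon areas use the shoelace formula on rings oriented counter-clockwise;
round joins at 32 segments per quarter turn keep closed-form area checks
within 1%. Point-in-polygon tests are crossing-number with an explicit
boundary tolerance, so "on the boundary" counts as inside everywhere.
Spearman p-values switch from exact enumeration to the t-approximation
above n = 9 (9! permutations enumerate in seconds via a cross-product
identity). The exact-permutation and oracle-equivalence tests run DBSCAN
against an independent core-graph + connected-components reference on
random instances up to n = 300; planted-aggregate recovery uses 20
simulated tissues of 20 aggregates each; coupling recovery uses 200
simulations of 100 aggregates; type-I calibration uses 1000 permuted-null
replicates at n = 67 aggregates. These sizes are the package's validation
conditions and finish in well under a minute each.

Known limitations: coverage of the planted-slope confidence interval runs a
shade below nominal (the count-rounding in the coupling makes residuals
mildly non-normal at small T-cell counts); the alpha-shape fallback to the
convex hull is rare but makes those particular boundaries slightly
generous; and the IHC identification is a surrogate for an operator-driven
process, so its parameters should be tuned against a hand-annotated slide
before use on real data.

## A worked example

```{r example}
tg <- generate_tissue(tissue_sim_params(n_las = 5, seed = 2,
                                        width = 6000, height = 5000,
                                        min_la_separation = 1200,
                                        chemokine_noise_rate = 0))
las <- detect_lymphoid_aggregates(tg$cellmap)
las
summary(las)
prof <- la_profiles(las)
prof[, c("la_id", "area_um2", "n_B", "n_PC", "pbr", "log2_tex_pex", "high_pbr")]
associate_pbr(prof, "log2_tex_pex")
```

```{r clinical}
summarize_cohort(generate_clinical_cohort("trial_2026", seed = 1))
```
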