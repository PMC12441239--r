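---
title: "Stand structural diversity and forest carbon pools: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stand structural diversity and forest carbon pools: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standcarbon)
```

## What the package computes

`standcarbon` links the structure of a mapped forest stand to its carbon
storage. The workflow has five stages, each usable on its own:

1. **Spatial structural diversity** from each tree's k nearest neighbours:
   uniform angle (W), dominance (U), mingling (M) and crowding (C).
2. **Non-spatial (diameter) diversity** from the DBH distribution:
   coefficient of variation (CV), skewness (SK), Gini coefficient of
   basal area (GC), and Shannon diversity of diameter classes (H).
3. **Carbon pools** per plot: tree (allometric), shrub, herb and litter
   (subplot harvests), and soil (layer stock equation), in Mg C ha⁻¹.
4. **Stand typing**: log-transform, redundancy filtering, PCA, Ward
   clustering into structural types, and per-variable ANOVA with
   Tukey–Kramer contrasts.
5. **Association**: permutation Mantel tests between structure and
   carbon-pool distance matrices, plus the Pearson correlation matrix.

A synthetic-stand generator emulates the kind of field campaign this
analysis is designed for — 13 plots of 20 m × 20 m in a subtropical pine
forest, 700–1,650 stems ha⁻¹, DBH 5–62 cm, around 35 woody species — so
the entire pipeline can be exercised and validated without field data.

## The spatial indices

All four indices score a *reference tree* against its `k = 4` nearest
neighbours and average over reference trees, giving per-tree values on
the grid {0, 0.25, 0.5, 0.75, 1}:

* **W (uniform angle)** sorts the neighbour azimuths and, for each pair
  of circularly adjacent rays, takes the smaller angle between them
  (≤ 180°); `W_i` is the fraction of these angles below the standard
  angle `alpha0 = 72°` (= 360°/(k+1)). A perfect lattice gives W = 0,
  complete spatial randomness about 0.5 (we measure ≈ 0.497 by
  simulation), clusters push W towards 1.
* **U (dominance)** is the fraction of neighbours with strictly larger
  DBH; equal diameters count as "not larger", which makes the index
  deterministic. U is a rank statistic — invariant under any strictly
  increasing re-expression of DBH — and its stand mean is ≈ 0.5 whenever
  size and location are unrelated. The opposite orientation (fraction of
  *smaller* neighbours) is available via `dominance(orientation =
  "smaller")`, because the verbal definition in the literature is used in
  both directions.
* **M (mingling)** is the fraction of heterospecific neighbours.
* **C (crowding)** is the fraction of neighbours whose crowns overlap the
  reference crown, with crown radius closed from DBH by the linear model
  `r = c0 + c1·DBH` (defaults 0.5 m + 0.05 m/cm — a 16.6 cm stem carries
  a 1.33 m crown radius, typical of dense subtropical pine). Overlap is
  strict: exact tangency does not count. Note that in stands above about
  1,000 stems ha⁻¹ most nearest neighbours are within crown reach, so C
  saturates near 1 and differentiates sparse stands much better than
  dense ones.

**Edge handling.** The analysis must decide which trees may serve as
reference trees, since boundary trees have truncated neighbourhoods.
`edge_policy("buffer", 5)` (the recommended field default) excludes
references within 5 m of a plot edge while keeping them available as
neighbours; `edge_policy("torus")` wraps the plot and is the right choice
for stationary synthetic patterns; `edge_policy("none")` uses everything.
Distance ties in the neighbour search are broken by the smaller tree id,
so results are fully deterministic.

## The diameter-based indices

CV uses the sample (n−1) standard deviation — plots hold only tens of
trees. Skewness defaults to the population-moment form `g1 = m₃/m₂^{3/2}`
with the `b1` and `G1` small-sample variants selectable, since software
packages differ in their default and a silent mismatch would be worse
than an explicit choice. The Gini coefficient is computed on per-tree
basal areas `π(DBH/200)²` with the sorted-index formula, which equals the
mean-absolute-difference form (tested to 1e−12). Shannon H bins DBH into
5 cm classes anchored at the 5 cm census floor — the forestry convention —
with the width configurable; a species-based Shannon index is provided
separately for users who want composition rather than size diversity.

## Carbon accounting

Tree biomass uses power-law allometries `biomass = a·DBH^b` (kg, cm) per
species, with component-split entries (stem/branch/leaf/root) summed and
a mandatory fallback entry for species without their own model — a stand
with 35 species will never have 35 fitted models. Fallback use warns and
is reported once per pipeline run. The shipped `default_allometry()` and
`default_carbon_fractions()` are *synthetic* defaults of realistic
magnitude for testing and simulation; real analyses should load their own
coefficient tables (`read_allometry()`, `read_carbon_fractions()`).

Pool conversions, all to Mg C ha⁻¹:

* tree: `Σ biomass_i × fraction_i × 10 / plot_area (m²)`;
* shrub/herb/litter: mean subplot dry-mass density (kg m⁻²) × 10 ×
  pool carbon fraction (shrub and herb harvests include above- and
  below-ground parts, so the pool covers both);
* soil: `C_s = Σ_i SOC_i·BD_i·D_i·10` in g m⁻² over layers
  (SOC in g kg⁻¹, bulk density in g cm⁻³, thickness in cm), divided by
  100 for Mg ha⁻¹. The g m⁻² figure is retained because it is the
  equation's native unit.

Totals are exact component sums; a conservation test holds them to 1e−9.

## Stand typing

All indices are log-transformed for normality. Because skewness can be
negative, any column containing non-positive values is shifted by
`1 − min` before the log and the shift is recorded — a documented
convention rather than a silent failure. Index pairs with |Pearson r| ≥
0.9 are then reduced to one member by a greedy pass in decreasing |r|;
the default priority keeps GC over CV when the two collide, the standard
resolution for that frequently collinear pair. PCA is computed by
eigen-decomposition of the correlation matrix with a deterministic sign
convention (each loading's largest element is positive), and plots are
clustered by Ward (`ward.D2`) linkage on the leading principal scores,
cut at `k = 3` types and renumbered by descending mean PC1 so type labels
are stable across runs.

Retained components default to the smallest set explaining ≥ 90% of
variance. With at most eight input indices the spectrum is short, and an
80% cutoff frequently keeps only two components, truncating real
structure that sits in the third; 90% keeps that component while still
discarding trailing noise. The cutoff is exposed (`retain_variance`), as
is the cluster count and the redundancy threshold.

Group contrasts use one-way ANOVA with Tukey–Kramer studentized-range
adjusted pairwise p-values — valid for the unequal type sizes (4/5/4)
this design produces — and a compact letter display computed from maximal
cliques of the "not significantly different" graph. A zero-variance
response is flagged degenerate rather than producing an undefined F.

## Association stage

Distance matrices are Euclidean on z-scored variables (metric
configurable). The Mantel statistic is the Pearson correlation of the
lower-triangle entries; its null distribution comes from simultaneously
permuting rows and columns of the second matrix, with
`p = (1 + #{r_perm ≥ r_obs}) / (1 + n_perm)` one-sided by default and 999
permutations under a caller-supplied seed for bit-reproducibility. For
four to seven plots an exact mode enumerates all n! relabelings. No
multiplicity adjustment is applied across the structure × pool table by
default, matching how such tables are conventionally reported;
Benjamini–Hochberg is available via `adjust = "bh"`. Simulation tests
confirm the 5% level of both the Mantel test and the ANOVA within
[0.03, 0.07] under their nulls.

## The synthetic study generator

`generate_stand()` draws stem positions from one of three point
processes — homogeneous Poisson (randomness), a Thomas cluster process
(Poisson parents, Gaussian offspring, wrapped on the torus; two
parameters that map directly onto W and C), or a jittered square lattice
(regularity) — with an optional hard-core minimum spacing. DBH marks are
i.i.d. from a 5 cm-shifted Weibull truncated at 62 cm; species marks come
from a 35-species pool with geometrically decaying abundances and a
*mingling control*: each stem copies its nearest already-placed
neighbour's species with a set probability, producing conspecific clumps
and tunable segregation.

`generate_study()` draws 13 plots from three latent types (4/5/4):

| | pattern | stems/ha | DBH shape | mingling |
|---|---|---|---|---|
| type 1 (high spatial + non-spatial) | tight Thomas clusters | 1,450–1,650 | heavy right tail | high |
| type 2 (high spatial only) | tight Thomas clusters | 1,000–1,250 | narrow | high |
| type 3 (low both) | jittered lattice | 700–900 | narrow | low |

The two contrast axes are deliberately non-collinear: the spatial family
(W, M, C) separates type 3 from the rest, the diameter family (CV, SK,
GC, H) separates type 1. Per-plot generator parameters (cluster spread,
jitter, species-copy probability) are drawn from narrow ranges so that no
index is a deterministic function of another and the 0.9 redundancy
filter does not collapse an entire family to one column. Densities stay
inside the emulated 700–1,650 ha⁻¹ window with a pooled mean near
1,200 ha⁻¹ and pooled mean DBH near 16 cm.

`generate_ecosystem()` couples the other pools to the overstory:
log understory (shrub, herb) density falls with the stand crowding index
(`beta_under = −1.8` per unit C) and with log canopy leaf biomass
(`beta_shade = −0.8`) — the second term expresses light interception,
which keeps increasing with canopy mass after the crown-overlap indicator
has saturated in dense stands. Litter standing mass is proportional to
canopy leaf biomass (leaf fraction 0.05, litter ratio 0.8). Topsoil SOC
rises with herb biomass (2 g kg⁻¹ per Mg ha⁻¹ over a 35 g kg⁻¹ base,
standing for root and residue inputs) and the 20–40 cm layer carries
0.55× the topsoil concentration in expectation. All noise is log-normal
(subplot sd 0.25, SOC sd 0.15) so every mass and concentration stays
positive, which also makes the pipeline's log transform natural.

**What the generator does and does not emulate.** It reproduces the
study's design envelope (plot size and count, density and DBH ranges,
species richness, type contrasts, the negative overstory–understory
coupling) with known ground truth, so passing tests demonstrate that the
estimators and the inference chain recover planted structure at field
sample sizes. It does not emulate measurement error, spatial
autocorrelation of size (available only through the cluster-inheritance
option), topography, or soil chemistry beyond SOC — so agreement here
cannot certify behaviour on real data with those features. One known
divergence from field experience is deliberate: because synthetic litter
tracks canopy leaf biomass, the densest type carries the *most* litter,
whereas shaded field understories often shed less; qualitative checks on
the planted pattern therefore use shrub + herb as the understory
quantity.

## Numerical choices and degenerate inputs

* Neighbour ties → smaller tree id (radix/C-locale order); coincident
  coordinates are an error naming the pair.
* Crown tangency (`d = r_i + r_j`) counts as non-overlap (strict
  inequality); equal DBH counts as non-dominant.
* Gini needs a non-zero total; skewness needs non-zero variance; CV needs
  n ≥ 2; Mantel needs ≥ 4 plots; every violation is a named error, not a
  silent NA.
* Buffer widths must stay below half the smallest plot dimension.
* Permutation p-values can never be 0 (the +1 convention), and exact
  enumeration is capped at 7 plots (5,040 relabelings).
* All generators restore the caller's RNG state and are bit-identical
  under a fixed seed; the pipeline manifest stores relative paths and md5
  digests with no timestamps, so a rerun with the same config and seed
  reproduces every output byte.

## Problem sizes used in the shipped checks

The package's own validation runs at deliberately compact sizes chosen to
exercise every code path at field-realistic scale: neighbour-search
equality on 100 random maps of up to 200 stems; spatial-randomness
calibration on 200 Poisson stands of 500 stems; 1,000 random vectors for
the Gini identity; 1,000 replicates for each 5%-level check; and 50
independent 13-plot studies for cluster recovery (median adjusted Rand
index) and the qualitative carbon pattern. At these sizes the whole suite
completes in a few minutes on one core.

## Known limitations

* Crowding saturates in dense stands; if fine discrimination among dense
  stands matters, lower the crown coefficients or use a larger k.
* With 13 plots the Mantel and ANOVA tests have limited power; the
  package reports effect sizes (r, F) alongside p-values for that reason.
* The letter display enumerates group subsets and is intended for the
  handful of types this design produces, not for dozens of groups.
* PCA sign and label conventions make runs comparable with each other,
  not with other software's arbitrary sign choices.
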