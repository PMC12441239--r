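# standcarbon

Quantifies forest stand structure from mapped stem data and relates it to
ecosystem carbon storage. The package is aimed at forest ecologists
working with small mapped plots (the motivating design is 13 plots of
20 m × 20 m in secondary subtropical pine forest) who want a reproducible
chain from a stem map to the statement *"stands of this structural type
store this much carbon, and these indices are the ones that matter"*.

## What it computes

**Spatial structural diversity** — per tree, from its `k = 4` nearest
neighbours, each index on {0, 0.25, 0.5, 0.75, 1}, averaged over
reference trees chosen by an edge policy (5 m buffer, torus, or none):

- *Uniform angle* W: fraction of circularly adjacent neighbour-ray angles
  below α₀ = 72°; lattice → 0, random ≈ 0.5, clusters → 1.
- *Dominance* U: fraction of neighbours with strictly larger DBH.
- *Mingling* M: fraction of heterospecific neighbours.
- *Crowding* C: fraction of neighbours with overlapping crowns, crown
  radius r = 0.5 + 0.05·DBH (m, configurable).

**Non-spatial (diameter) diversity** — CV of DBH, skewness
(g1 = m₃/m₂^{3/2}; b1/G1 variants available), Gini coefficient of basal
area π(DBH/200)², and Shannon diversity of 5 cm diameter classes.

**Carbon pools** (Mg C ha⁻¹) — tree biomass by power-law allometry
a·DBH^b times species carbon fractions; shrub, herb and litter pools from
subplot harvest densities (×10 kg m⁻² → Mg ha⁻¹, × pool fraction); soil
from the layer stock equation C_s = Σ SOC_i·BD_i·D_i·10 (g m⁻²).

**Stand typing** — log-transform, drop index pairs with |r| ≥ 0.9
(keeping GC over CV), correlation-matrix PCA, Ward clustering of leading
scores into three types, one-way ANOVA + Tukey–Kramer letters per index.

**Association** — one-sided permutation Mantel tests (999 permutations,
seeded; exact enumeration for ≤ 7 plots) between structure and carbon
distance matrices, plus the Pearson correlation matrix with t-based
p-values.

**Synthetic studies** — Poisson / Thomas-cluster / jittered-lattice stem
maps with Weibull DBH and species-copy mingling control, three planted
structural types, and understory/litter/soil measurements coupled to
overstory crowding and canopy leaf biomass, all bit-reproducible per
seed.

## Worked example

```r
library(standcarbon)

# one synthetic stand: clustered, 1,500 stems/ha
sm <- generate_stand(stand_config(pattern = "thomas", n_trees = 60,
                                  seed = 42), plot_id = "demo")
structural_profile(sm, edge = edge_policy("torus"))
#>       W     U     M     C    CV   SK    GC     H n_trees density_ha
#> 1 0.542 0.533 0.708 0.883 0.545 1.48 0.524 1.791      60       1500

eco <- generate_ecosystem(sm, seed = 42)
carbon_pools(sm, default_allometry(), default_carbon_fractions(),
             eco$harvest, eco$soil)
#>    tree shrub herb litter  soil  total
#> 1 77.51  0.88 0.28   3.54 146.9 229.11
```

The W of 0.54 (above the ≈ 0.50 random benchmark) reflects the clustered
pattern, C = 0.88 the dense canopy, SK = 1.48 a stand dominated by a few
large stems. The plot stores 229 Mg C ha⁻¹, two thirds of it in the soil
and a third in the tree layer, with under 5 Mg in understory and litter.

The full pipeline — simulate 13 plots in three latent types, compute
indices and pools, classify, associate — is one call:

```r
m <- run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
m$results$types$type
#>  [1] 1 1 1 1 2 2 2 2 2 3 3 3 3      # recovers the planted 4/5/4 types

subset(m$results$mantel, pool %in% c("shrub", "herb", "total"))
#>           set  pool      r     p
#> 2     spatial shrub  0.839 0.003
#> 3     spatial  herb  0.843 0.003
#> 6     spatial total -0.172 0.912
#> 8  nonspatial shrub  0.056 0.221
#> 9  nonspatial  herb  0.057 0.198
#> 12 nonspatial total  0.486 0.008

m$results$anova[c("variable", "F", "p", "letters")]
#>   variable        F        p     letters
#> 1        W 139.4454 4.97e-08 1:a 2:a 3:b
#> 2        U   0.0379 9.63e-01 1:a 2:a 3:a
#> 3       SK  10.1382 3.93e-03 1:a 2:b 3:b
#> 4       GC 199.9877 8.63e-09 1:a 2:b 3:b
```

Spatial structure is tied to the understory pools (Mantel r ≈ 0.84:
denser, more clustered canopies shade out shrubs and herbs), while
diameter inequality tracks total storage (r ≈ 0.49). The uniform angle
separates the regular type 3 from the clustered types (letters a/a/b);
skewness and the Gini coefficient separate the high-diversity type 1.
Every output table is also written as CSV under `out_dir` together with
`manifest.json` (relative paths + md5 digests); a rerun with the same
config and seed reproduces every byte.

All defaults — neighbour count, standard angle, crown model, edge
policy, bin width, redundancy threshold, retained variance, permutation
count — are arguments of the corresponding functions; the methods
vignette (`vignettes/stand-structure-carbon.Rmd`) explains each choice.

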