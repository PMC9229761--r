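# mcnet — morphometric correlation networks of cortical thickness

`mcnet` is an R package for building and analysing **morphometric
correlation networks (MCNs)**: graphs whose nodes are the 66 bilateral
Desikan–Killiany cortical regions and whose edges are cross-subject Pearson
correlations of mean regional cortical thickness. It is aimed at
neuroimaging researchers studying large-scale structural covariance — e.g.
comparing cognitively impaired and non-impaired brain-tumor survivors —
from FreeSurfer `aparcstats2table`-style thickness tables.

## What it computes

Given per-subject regional thickness T (subjects × 66, mm) and ages:

1. **Age residualization** — per region, OLS residuals of `T_j ~ 1 + age`.
2. **MCN** — interregional Pearson matrix `r` with two-sided p-values from
   `t = r√((n−2)/(1−r²))` on n−2 df, masked at p < 0.05 (uncorrected).
3. **Binary graphs** — at density d, the `⌊d·2145⌋` significant pairs of
   largest |r| become edges (sign retained as an attribute).
4. **Graph metrics** — degree centrality k_i, betweenness centrality
   b_i ∈ [0,1], clustering coefficient Cp, characteristic path length Lp,
   and the small-world index **σ = (Cp/Cp_rand)/(Lp/Lp_rand)** against
   degree-preserving (Maslov–Sneppen) null graphs; *predominant nodes* are
   regions with both k and b above mean + 1 SD across the density grid.
5. **Robustness** — targeted attack: remove nodes in decreasing betweenness
   order and track the relative size of the largest remaining connected
   component (÷ 66); group differences are tested per removal fraction with
   a group-label permutation test (two-tailed 2.5/97.5 percentile bands).
6. **Associations** — age-covaried partial correlations (p on n−3 df,
   R² = partial r²) between each region's thickness and FACT-Cog PCI, WPAI
   ability (percent), and times since surgery / last treatment; unpaired
   t-tests on thickness between impairment groups.

A seeded synthetic-cohort generator (`sim_config()` / `simulate_cohort()`)
with linear age effects, group-dependent modular block covariance and
planted thickness→outcome links makes every stage testable without real
data. The packaged fixtures are the 66-region atlas registry and the
clinical table of the 24-survivor study cohort.

## Worked example

```r
library(mcnet)

cohort <- simulate_cohort(sim_config(n_per_group = 12, seed = 42))
config <- pipeline_config(n_perm = 1000, seeds = list(null = 11, permutation = 42))
report <- run_full_pipeline(cohort, config)
print(report)
#> Morphometric correlation network report
#>   subjects: 24 (impaired=12, nonimpaired=12)
#>   MCN impaired     n=12, 465 significant edges (0 negative)
#>   MCN nonimpaired  n=12, 336 significant edges (3 negative)
#>   MCN pooled       n=24, 640 significant edges (1 negative)
#>   robustness: permutation-significant at no fractions
#>   predominant nodes (pooled): lh_cuneus_thickness, ...

subset(report$small_world_pooled, density == 0.20)
#>   density      cp       lp    gamma   lambda    sigma
#> 4     0.2 0.69442 2.335664 3.306369 1.258102 2.628061

head(report$associations$pci[, c("region", "partial_r", "r_squared", "p_value")], 3)
#>                              region partial_r r_squared     p_value
#> 1     lh_superiortemporal_thickness 0.5421968 0.2939774 0.007524174
#> 2 lh_rostralmiddlefrontal_thickness 0.4556295 0.2075982 0.028896877
#> 3          lh_frontalpole_thickness 0.4490147 0.2016142 0.031613616
```

Reading the output: both group MCNs are dense in significant edges because
the generator plants strong modular covariance; σ = 2.63 at density 0.20
(σ > 1 ⇒ small-world organization: clustered like a lattice, integrated
like a random graph). The default generator links the left superior
temporal gyrus to the PCI score, and the association scan duly ranks that
region first (R² = 0.29, p = 0.008). With both groups drawn from the same
covariance structure, the robustness permutation test flags no removal
fraction — as it should.

Real data enter through `read_thickness_table()` (wide TSV, FreeSurfer
dialect) and `read_clinical_table()` (CSV), assembled with `as_cohort()`.
A thin command-line wrapper lives at `inst/scripts/mcn.R`
(`simulate` / `run` subcommands).

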