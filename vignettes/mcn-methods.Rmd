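---
title: "Morphometric correlation networks: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric correlation networks: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcnet)
```

## The scientific problem

Cortical thickness — the distance between the white-matter and pial surfaces,
averaged within an atlas region — covaries between brain regions across
subjects. A *morphometric correlation network* (MCN) treats the 66 bilateral
Desikan–Killiany cortical regions as nodes and the cross-subject Pearson
correlations of their mean thickness as edges. Group differences in that
network's topology (hubs, small-world organization, tolerance to targeted
node removal) are used to study large-scale structural reorganization, for
example in brain-tumor survivors grouped by cognitive impairment status.

`mcnet` implements that full analysis as a tested pipeline:

1. per-region **age residualization** (OLS of thickness on age, pooled);
2. **MCN construction**: the 66×66 interregional Pearson matrix with
   two-sided p-values (t transform, n−2 df) and a significance mask at
   p < 0.05, uncorrected;
3. **binarization** at a target connection density: the `floor(d · 2145)`
   significant pairs of largest |r| become edges;
4. **graph metrics**: degree and betweenness centrality, clustering
   coefficient (Cp), characteristic path length (Lp), and the small-world
   index σ against degree-preserving null graphs, swept over a density grid;
5. **targeted-attack robustness**: nodes removed in decreasing betweenness
   order while tracking the relative size of the largest remaining connected
   component, compared between groups with a group-label permutation test;
6. **ROI associations**: age-covaried partial correlations between regional
   thickness and cognitive/functional outcomes, plus unpaired t-tests on
   thickness between groups.

Since no per-subject thickness data are published for the motivating cohort,
every stage is validated on synthetic cohorts whose generating structure is
known (see below); the packaged clinical table of the 24-survivor cohort is
the one real fixture.

## The atlas

The bilateral 66-region registry (33 per hemisphere) is the standard
gyral-based Desikan–Killiany parcellation. The standard FreeSurfer `aparc`
emits 34 cortical labels per hemisphere; the 33-region bilateral variant used
here excludes `bankssts` (banks of the superior temporal sulcus), the only
exclusion consistent with every region this analysis reports on (insula and
both poles included). Each region carries a figure-style abbreviation
(`"l STG"`) and a default-mode / salience / language / other annotation used
purely for report grouping — it never enters any computation.

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` emulate the statistical structure the
analysis assumes, not the imaging process. Per group, thickness for subject
*i* in region *j* is

> baseline_j + age_slope · (age_i − mean age) + ε_i

with ε drawn from a 66-dimensional Gaussian whose correlation matrix is
block compound-symmetric: `rho_within` inside each of `n_modules` contiguous
modules (11 regions each by default), `rho_between` across modules, scaled by
`noise_sd`. This is the simplest structure that makes within/between
contrasts, σ > 1, and hub emergence testable; positive semi-definiteness is
verified at configuration time (`rho_within ≥ rho_between ≥ 0` suffices).

Default parameter choices and why:

* `n_per_group = 12` — the motivating cohort's group size (24 subjects).
* `age_range = c(22, 70)` years — the span of the packaged clinical table
  (its narrative summary says 26–69; the table itself contains 22 and 70;
  the fixture transcribes the table verbatim and the generator follows it).
* `baseline_thickness = 2.5` mm, `noise_sd = 0.1` mm — typical adult mean
  regional thickness and between-subject spread.
* `age_slope = −0.005` mm/year — a realistic magnitude of adult cortical
  thinning.
* `rho_within = 0.6`, `rho_between = 0.1` — strong modular covariance that
  yields MCNs of realistic edge density at n = 24.
* outcome links — each link adds `slope · (thickness_region − mean)` plus
  Gaussian noise to one outcome. The defaults link the left superior
  temporal gyrus to the FACT-Cog PCI score (slope 100 PCI-units/mm, noise
  SD 16) and the left precuneus negatively to the raw WPAI ability score,
  giving partial correlations near 0.5 — the magnitude the motivating
  analyses report. PCI is clamped to its 0–72 scale (higher = better); WPAI
  to 0–10 (higher = worse; `wpai_to_percent()` maps it to the percent
  scale as raw × 10, the interpretation consistent with a reported 0–80%
  range). Note the raw WPAI instrument nominally starts at 1; the package
  accepts 0 permissively.
* clinical covariates (sex ratio 2:1 M:F, tumor-location and grade
  frequencies, log-normal years-since-surgery) follow the packaged cohort's
  marginals; they are realism dressing except for `age`, which drives the
  residualization, and the outcome columns.

Group labels are assigned by construction (`impairment_mode = "group"`), or
derived by simulating a 10-test Z-score battery and applying the impairment
rule (`"zscores"`), which exercises the classification path end-to-end. The
rule itself: impaired ⇔ at least two test scores ≤ −2 Z, the boundary
counting toward impairment.

What the generator does **not** emulate: resection cavities and lesion
geometry, spatially smooth measurement error, non-linear age effects,
hemispheric asymmetries, and site/scanner effects. Passing recovery tests
therefore demonstrates correctness of the estimators under the assumed
model, not robustness to those real-data complications.

## Numerical and design choices

* **Age residualization is unconditional.** A conditional variant
  (residualize only when the age fit is significant) would make the pipeline
  discontinuous in the data; since age is treated as a covariate throughout,
  the fit is always removed and its p-value stored. Residualization is
  idempotent and leaves residuals orthogonal to age to ~1e−10.
* **Uncorrected p < 0.05 edge mask.** The edge mask deliberately applies no
  multiple-testing correction across the 2,145 pairs, matching the
  motivating analysis; at n = 24 the mask is equivalent to |r| > 0.404.
  An FDR option exists for the association scan but is off by default.
* **Negative correlations are edges.** Binarization ranks significant pairs
  by |r| — anticorrelations carry topological information — and keeps the
  sign as an edge attribute for reporting. Ties in |r| break toward the
  smaller region-index pair, making edge sets deterministic and nested
  across densities.
* **Density grid** 0.05–0.50 in steps of 0.05 for sweeps; robustness and the
  headline small-world evaluation use the mid-grid density 0.20.
* **Lp on fragmented graphs** averages over mutually reachable pairs only
  and reports the reachable fraction, since density thresholds routinely
  fragment graphs; mapping unreachable pairs to an arbitrary large distance
  would make Lp threshold-dependent in an uninterpretable way.
* **Betweenness** is normalized by (N−1)(N−2)/2 so values are fractions in
  [0, 1]; for N < 3 it is identically zero.
* **σ = (Cp/Cp_rand)/(Lp/Lp_rand)** with Maslov–Sneppen degree-preserving
  rewired nulls (10·|E| swap attempts, 100 nulls by default, seeded). When a
  degree sequence admits no rewiring (complete graphs, stars), the null
  falls back to density-matched G(n, m) graphs with a warning; on a complete
  graph this leaves σ = 1 exactly.
* **Attack order is static**: betweenness is ranked once on the intact
  graph (ties: larger degree, then lower index), matching the definition of
  the targeted attack as removal "in decreasing order of betweenness";
  `recompute = TRUE` provides the adaptive re-ranking variant for
  sensitivity analysis. The largest-component curve is computed by an
  incremental union-find over the reversed removal order, which makes the
  permutation test tractable (one curve costs O(E α(N)) rather than N
  component searches).
* **Permutation test**: group labels are reshuffled preserving group sizes
  (draws with replacement from the shuffle space, standard when the number
  of permutations is far below C(24,12)); both group MCNs and attack curves
  are rebuilt per shuffle; pointwise 2.5/97.5 percentile bands give the
  two-tailed p < 0.05 criterion per removal fraction. No family-wise
  correction is applied across the 67 grid points — a deliberate mirror of
  the per-fraction significance convention, and a known limitation.
  Permutations that land a zero-variance region in one group are redrawn
  and counted. The reference analysis uses 1000 repetitions; the test suite
  uses 200 for its calibration study.
* **Associations**: "age as a covariate" is implemented as a partial
  correlation by double OLS residualization, with p from the t transform on
  n − 3 df; the reported R² is exactly the squared partial correlation. The
  two-predictor-regression variant would give the same R² for these models;
  partial correlation was chosen because each reported R² pairs with a
  correlation-style p-value. The group t-test is the classical
  pooled-variance test, with Welch available by flag.
* **Determinism**: every random draw (simulation, null ensembles,
  permutations) traces to a named seed; `run_full_pipeline()` is
  byte-reproducible for a fixed cohort and configuration.

## Validation strategy and problem sizes

The test suite checks the graph machinery for *exact* agreement with
brute-force enumeration oracles (Floyd–Warshall distances, explicit
shortest-path enumeration, reachability-closure components) on every labeled
graph with up to 5 nodes and 500 random graphs on 6–8 nodes, and the attack
curve against an exhaustive-reachability oracle on 200 random graphs of up
to 10 nodes. Closed forms anchor the extremes (complete graphs, stars,
rings). The permutation test's pointwise type-I error is measured over 200
null cohorts at 200 permutations each and must fall inside the 99% binomial
confidence band around 0.05; generator recovery (block correlations at
n = 500, planted outcome links at n = 100, group correlation differences at
n = 50/group) rounds out the evidence. These sizes were chosen so the full
suite completes in a few minutes on one CPU while keeping every Monte-Carlo
bound comfortably powered.

## Worked example

```{r example, eval = FALSE}
library(mcnet)

cohort <- simulate_cohort(sim_config(n_per_group = 12, seed = 42))
config <- pipeline_config(n_perm = 1000,
                          seeds = list(null = 11, permutation = 42))
report <- run_full_pipeline(cohort, config)
print(report)

# headline small-world index at density 0.20
subset(report$small_world_pooled, density == 0.20)
```

## Known limitations

* The 24-subject scale of the motivating design gives noisy correlation
  estimates (SE ≈ 0.2 per edge); density-thresholded topology at such n
  should be interpreted over the full density sweep, never at one density.
* Pointwise permutation bands are not corrected across removal fractions.
* The generator's block-constant covariance cannot produce realistic hub
  geometry beyond what modular structure induces; predominant-node calls on
  synthetic data validate the mechanics, not anatomical claims.
* Thickness input is taken as given; surface reconstruction, parcellation
  quality and resection-cavity editing are upstream of this package.
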