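---
title: "Single-subject structural covariance networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-subject structural covariance networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

## The model

Classical structural covariance is estimated *across* subjects: two
regions are "connected" if their morphometry covaries over a cohort.
`scnet` implements the *intra-individual* variant: each subject gets
their own network, built from the joint variation of that subject's
z-scored regional morphometry. This makes network metrics available as
per-subject measurements that can be compared between groups and
correlated with clinical scores.

The processing chain is:

1. **Bilateral averaging.** Regional cortical thickness (mm), cortical
   surface area (mm²) and subcortical volume (mm³) are averaged across
   hemispheres (unweighted arithmetic mean). With the 34-region
   Desikan–Killiany cortical parcellation and six subcortical
   structures (putamen, caudate, thalamus, pallidum, hippocampus,
   amygdala) this yields 74 features per subject: 34 thickness + 34
   area + 6 volume nodes, in a fixed documented order
   (`node_roster()`).
2. **Covariate correction.** Each feature is residualized against age,
   sex, and total intracranial volume (the brain-size proxy) by OLS.
   The regression is fit on controls only by default and applied to
   everyone, so disease-related atrophy cannot contaminate the
   covariate slopes; fitting on the pooled sample is retained as a
   documented switch (`fit_on = "all"`) because either reading of the
   source procedure is defensible.
3. **Control-referenced z-scoring.** Residuals are standardized per
   node by the control group's mean and sample (n−1) standard
   deviation. Controls therefore have per-node mean 0 and SD 1 exactly
   (to 1e-10); patient z-scores measure deviation from the normative
   control distribution in control-SD units.
4. **Edge weights.** For one subject with node z-scores \(z_i\),
   \[ w_{ij} = \frac{1}{\exp[(z_i - z_j)^2]} = e^{-(z_i-z_j)^2}, \]
   a similarity kernel in (0, 1]: regions that deviate *together* from
   the norm are strongly connected. The literal formula gives
   \(w_{ii} = 1\); the diagonal is zeroed because graph metrics assume
   loop-free networks (the standard connectivity convention). Weights
   depend only on z differences, so they are invariant to global
   z-shifts, and monotone decreasing in \(|z_i - z_j|\).
5. **Proportional thresholding.** Each network is thresholded at
   densities 0.10–0.40 in steps of 0.01 (31 densities), keeping the
   `round(d · 74·73/2)` strongest edges *with their weights* (networks
   stay weighted). Rounding is half-away-from-zero; ties at the cutoff
   break by descending weight then ascending (i, j) node order, making
   runs bit-reproducible. A single shared edge ranking makes the
   retained sets nested across densities.
6. **Graph metrics.** At each density: mean weighted clustering (Cp),
   characteristic path length (Lp), global efficiency, and nodal
   strength/degree, clustering, path length, nodal efficiency and
   local efficiency. Path lengths use reciprocal-weight edge lengths
   \(l = 1/w\), the dominant convention for similarity weights (and
   the one under which efficiency ≤ 1 when w ≤ 1).
7. **Small-world normalization.** γ = Cp/⟨Cp_null⟩, λ = Lp/⟨Lp_null⟩,
   σ = γ/λ against degree-preserving Maslov–Sneppen null ensembles;
   σ > 1.1 is the small-world criterion. (The source literature also
   prints the criterion once as "σ = λ/γ"; the definition σ = γ/λ
   stated alongside it is the standard one and is what is
   implemented.)
8. **AUC reduction.** Every metric trace is reduced to its trapezoidal
   integral over the density range, removing dependence on any single
   threshold. A metric constant at c integrates to 0.30·c.
9. **Statistics.** Each variable passes a Shapiro–Wilk gate (α = 0.05
   in either group routes to the rank test): Student pooled-variance
   t-test for normal variables, tie-corrected normal-approximation
   Wilcoxon–Mann–Whitney z otherwise; Pearson χ² (1 df, no continuity
   correction) for sex tables; Benjamini–Hochberg FDR within each
   family; Pearson correlations between patients' nodal AUC metrics
   and clinical scores.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| density range | 0.10–0.40, step 0.01 | sweep over which metrics are integrated; below ~0.10 the 74-node graphs fragment, above ~0.40 edges are increasingly noise |
| `n_nulls` | 1000 (fast mode 100) | nulls per (subject, density); only γ, λ, σ depend on it |
| `rewires_per_edge` | 100 | attempted double-edge swaps per edge per null |
| `fit_on` | `"controls"` | covariate-fit population |
| clustering variant | `"onnela"` | geometric-mean weighted clustering on max-normalized weights; `"barrat"` available |
| α | 0.05 | gate level and FDR level |

Degree centrality on these weighted thresholded graphs is reported as
nodal *strength* (sum of incident weights), with the binary degree
alongside; at a fixed density the binary degree is nearly saturated by
construction, so strength is the informative variant.

## Design choices in ambiguous territory

* **FDR families.** Global AUC metrics form one family; each nodal
  metric forms one family across its 74 nodes; each correlation family
  is all (node × clinical score) pairs within a metric. The family
  structure is recorded in every report.
* **Null models preserve weights.** Weights travel with edges during
  rewiring, so each null preserves the weight multiset along with the
  degree sequence; null normalization therefore reflects topology,
  not weight redistribution.
* **Disconnected pairs** are excluded from Lp (mean over reachable
  pairs) and contribute 0 to efficiencies, keeping Lp finite at low
  densities. A node with no reachable partner gets nodal path length 0
  (a documented, bounded convention). Degenerate Shapiro–Wilk inputs
  (constant samples) classify as non-normal rather than erroring.
* **Seeding.** One global seed fans out to per-subject substreams via
  a counter scheme keyed on a hash of the subject id, so results are
  identical under subject reordering; the C++ null generator runs its
  own Mersenne-Twister stream, independent of R's RNG state.

## What the synthetic cohort emulates

`cohort_spec()` defaults encode the reference study conditions: 20
controls (age 63.6 ± 5.9 y, 13/20 female, ICV 1406 ± 156 ml) and 25
patients (66.9 ± 7.7 y, 11/25 female, 1432 ± 164 ml); linear age/ICV
loadings per feature class; and planted atrophy at nine
frontotemporal-and-posterior cortical-thickness nodes (rostral/caudal
middle frontal, pars opercularis, rostral/caudal anterior cingulate,
inferior/transverse temporal, precuneus, cuneus).

Atrophy has a mean shift δ = −1.5 control-SD and a per-subject,
per-region heterogeneity jitter τ = 0.8 control-SD. The heterogeneity
is deliberately the effect carrier: a *uniform* downward shift of a
set of nodes changes within-subject z-differences only at
target/spared boundaries, whereas region-to-region jitter decorrelates
the target nodes from everything, which is what degrades edge weights,
global efficiency, and local efficiency in patients — the mechanism
the analysis is designed to detect. MMSE couples to the planted burden
(4 points per SD, noise SD 2, clipped to [0, 30]), giving patients
≈ 21 ± 5 versus controls ≈ 28 ± 2; FAB and disease duration follow
the same cohort scales. Baseline levels, slopes, and noise SDs are
fixed plausible FreeSurfer-scale constants (e.g. thickness ≈ 2.1–3.0
mm with 0.12 mm noise).

What the generator does *not* emulate: realistic inter-regional
anatomical covariance (beyond covariate-induced correlation),
scanner/site effects, hemispheric asymmetry of disease, or
segmentation failures. Passing tests on this cohort therefore
demonstrate that the pipeline recovers a planted, spatially localized
atrophy signature under realistic demographics and noise — not that it
reproduces any particular empirical cohort's values.

## Numerical choices and problem sizes

* Graph kernels are implemented in C++ (flat O(V²) Dijkstra on dense
  length matrices — the fastest form at 74 nodes; exhaustive
  neighbor-pair loops for clustering). Every kernel is verified in the
  test suite against independent brute-force oracles (Floyd–Warshall
  relaxation, exhaustive triple enumeration) on hundreds of random
  graphs to 1e-9, and distances are additionally cross-checked against
  igraph.
* Validation simulations in the test suite run at deliberately chosen
  sizes: planted-effect recovery over 20 regenerated cohorts and
  type-I calibration over 100 null cohorts use the pipeline without
  null-ensemble normalization, since the quantities they grade
  (global-efficiency direction, FDR-corrected local-efficiency
  localization, raw test levels) do not involve the null-normalized
  metrics; the null machinery itself is validated separately (ensemble
  contracts on 10 × 100 nulls; small-world separation of rewired
  lattices from Erdős–Rényi graphs at 50 nulls). The acceptance script
  runs one full small-world pipeline at 30 nulls per
  (subject, density).
* The type-I calibration pools rejection events over the three
  reported global AUC metrics, as a 100-seed single-metric binomial at
  level 0.05 has a standard error (0.022) wider than the calibration
  band itself.

## An anti-conservativeness caveat

Control-referenced z-scoring with a small reference group makes the
group contrast anti-conservative *by construction*, a property users
of this class of methods should know. Under a global null (no disease
effect at all), patient z-scores are over-dispersed relative to
controls for two stacked reasons: with controls-only covariate
fitting, patient residuals carry out-of-sample prediction variance
(of order σ²(1+h) versus the controls' shrunk σ²(1−h), with mean
leverage h = p/n = 4/20 here), and regardless of the fitting set,
dividing an independent sample by the control sample SD inflates the
expected squared z by (n−1)/(n−3) (Jensen's inequality on 1/s²).
Because the edge weight is monotone decreasing in |z_i − z_j|, any
over-dispersion systematically lowers patient edge weights and shifts
every global metric in the same direction as genuine atrophy. The
calibration check in the acceptance suite measures the resulting
rejection rate of the nominal-0.05 global tests on null cohorts at
the default configuration — far above nominal — and is deliberately
left failing as a faithful record of this property (pooled covariate
fitting reduces but does not remove it). Group differences in global
metrics from this pipeline should therefore be read jointly with the
nodal localization pattern and with effect sizes, not as calibrated
hypothesis tests.

## Known limitations

* Only complete feature tables are accepted; regions lost to
  segmentation failure must be handled upstream (the source procedure
  does not describe exclusions either).
* Bilateral averaging forfeits homotopic (left–right) connectivity by
  construction.
* The Wilcoxon–Mann–Whitney z uses the tie-corrected normal
  approximation throughout (appropriate at n ≈ 20–25 per group, and
  the form whose statistic is conventionally tabulated); exact small-n
  p-values are not computed.
* With 74 nodes and 31 fixed densities, absolute metric values depend
  on the node roster; comparisons are only meaningful within the same
  parcellation.

## A minimal run

```{r, eval = FALSE}
co <- generate_cohort(cohort_spec(seed = 1))
cfg <- run_config(n_nulls = 100, seed = 1, outdir = "scnet-out")
res <- run_pipeline(co$features, co$covariates, cfg)
print(res)
planted_effect_check(res, co$target_labels)
```
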