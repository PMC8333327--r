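# zoopcurves

Macroecology of zooplankton communities from quantitative plankton-imaging
data: from per-individual scanner records to community metrics,
environmental response curves, and clusters of groups that respond alike.

## What it does, and for whom

Net samples digitized by a plankton scanner yield one record per imaged
organism: a taxonomic label and the major/minor axes of its best-fitting
ellipse. Ecologists working with such exports (e.g. Ecotaxa-style tables
from WP2 / Bongo / Régent net surveys) typically want to know how community
**abundance** and **size structure** vary along environmental gradients,
and which taxa share a common response. `zoopcurves` implements that whole
chain as tested, reusable R functions:

1. **Metrics** — individual size as the area-equivalent spherical diameter,
   ESD = √(major × minor); abundance as count / filtered volume
   (ind m⁻³); median ESD per station × group × net, computed over a nested
   taxonomic registry (each organism counts in its group and every ancestor
   up to total zooplankton). Size metrics require ≥ 20 individuals per
   station and ≥ 30 qualifying stations per series.
2. **Screening** — response transforms chosen among {√, ln, log₁₀, ∛} by
   Shapiro–Wilk normality; Spearman correlation screens with significance
   labels; a collinearity filter that resolves every covariate pair with
   |ρ| ≥ 0.7 toward the more normal member and emits two parallel
   ten-covariate sets, one containing temperature and one oxygen
   (the pair is too collinear, ρ ≈ −0.95, to coexist in one model).
3. **Response models** — penalized-spline additive models
   y = α + Σⱼ fⱼ(xⱼ) + ε, with a second-difference penalty plus null-space
   shrinkage (so smoothness selection can remove a term entirely), REML
   smoothing-parameter selection, per-term basis dimension
   k = max(3, ⌊n/p⌋), Wald-type F ranking of terms, and backward removal of
   insignificant terms (α = 0.05). The engine's inner loops are compiled
   (RcppArmadillo); a ten-smooth REML fit takes milliseconds.
4. **Shape clustering** — each model's covariate-specific smooth curves on
   a common 1–100 index form a multivariate series; dynamic time warping
   (DTW) distances between series feed partitioning-around-medoids (PAM)
   over k = 2–10; the number of clusters is chosen by a plurality vote of
   five validity indices (Calinski–Harabasz, Dunn, silhouette, classic and
   modified Davies–Bouldin); classical MDS gives 2-D coordinates.
5. **Comparison & reporting** — Kruskal–Wallis with Dunn/Bonferroni post
   hocs on explained deviance across nets and covariate sets, cross-net
   rank correlations, and a publication-style model summary table.

A first-class **virtual-transect simulator** generates stations with a
planted collinearity structure (temperature–oxygen ρ = −0.95, nutrient
inter-correlations 0.95/0.87, compositional phytoplankton fractions),
nested communities with planted response-shape families, a
temperature-size rule on individual sizes, and logistic mesh retention per
net — with full ground-truth bookkeeping, so the pipeline's recovery of
known structure is measurable.

## Worked example

Simulate the recovery design — 24 groups planted in four response-shape
families, 120 stations, WP2 net — and run the full pipeline on it:

```r
library(zoopcurves)

cfg <- recovery_config()   # 4 planted families, 6 groups each
pl <- run_pipeline(cfg, seed = 1, metrics = "abundance",
                   variants = "temperature",
                   groups = registry_leaves(cfg$registry))

pl$clustering$abundance$k      # 4
pl$recovery$abundance$ari      # 1
head(pl$summary[, c("group", "first_term", "pct_dev",
                    "significant_terms", "cluster")], 5)
```

which prints

```
k: 4
ARI: 1
  group      first_term  pct_dev significant_terms                  cluster
1 SimGroup01 temperature   0.877 temperature, no2no3, chl_a         1
2 SimGroup02 temperature   0.877 temperature, no2no3, chl_a         1
3 SimGroup03 temperature   0.778 temperature, no2no3, chl_a         1
4 SimGroup04 temperature   0.878 temperature, no2no3, chl_a         1
5 SimGroup05 temperature   0.928 temperature, no2no3, bbp470, chl_a 1
```

Reading this: the five groups shown belong to the planted "polar" family
(log-abundance decreasing linearly with temperature, increasing with
nitrate and chlorophyll). The fitted additive models explain 78–93% of the
deviance, rank temperature as the top term by its F statistic, retain
essentially the planted covariates after backward removal, and the
DTW + PAM step puts all of them in one cluster. The chosen number of
clusters equals the number of planted families (4), and the adjusted Rand
index between recovered clusters and planted labels is 1 — a perfect
recovery on this seed.

The same `run_pipeline()` call accepts the full 36-group registry
(`transect_config()`), both community metrics
(`metrics = c("abundance", "median_esd")`) and both covariate variants
(`variants = c("temperature", "oxygen")`), and writes every stage's tables
with `out_dir = ...`.

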