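---
title: "Statistical methods behind factoseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind factoseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(factoseq)
```

factoseq analyses multifactorial bulk RNA-seq count experiments: up to two
crossed biological factors plus an optional replicate factor, with a
*complete* design (every combination of biological-factor modalities
observed in at least one sample; unbalanced replicate numbers are fine,
an empty condition is fatal). This vignette explains the models, the
tunable parameters and the numerical choices, and what the synthetic-data
tests do and do not demonstrate.

## Input model and quality control

A project is a pair of CSV files: a genes × samples count table and a
target table describing each sample by its factor modalities. Counts are
reordered to the target's sample order; modality order is the order of
first appearance in the target file, and the first modality of each factor
is the reference level of the GLM coding. This convention is what makes
the automatically generated contrast names reproducible: pairs are always
oriented "first-appearing minus later-appearing" modality.

Low-count filtering uses counts per million computed on **raw** library
sizes, because filtering precedes normalization in the workflow. Two
strategies are offered and, since their names alone do not pin down a
rule, we define them exactly:

* `NbConditions` (default): keep gene *g* iff its mean CPM within at
  least one biological condition reaches `cpm_cutoff` (default 1).
* `NbReplicates`: keep *g* iff its CPM reaches the cutoff in at least
  *r* samples, where *r* is the minimum replicate count over conditions.

An alternative reading (count samples above the cutoff per condition) is
possible; the chosen semantics are deliberately the laxer of the two for
conditions with many replicates, and raising the cutoff is always
monotone (never re-admits a gene).

Normalization factors come from TMM (default; weighted trimmed mean of
M-values, 30% trim on log-ratios, 5% on abundance, inverse binomial
variance weights, reference sample = upper-quartile ratio closest to the
mean; delegated to edgeR, whose implementation follows exactly this
recipe) or RLE (median across all-positive genes of the count over the
gene's geometric mean; the median is taken in raw space). Both are
rescaled to geometric mean 1, and effective library sizes are
`N_j * f_j`. QC summaries use `log2(normalized count + 1)`: per-sample
quartiles, a Ward (`ward.D2`) dendrogram on Euclidean distances between
samples, and centered, unscaled PCA. Ties in the dendrogram are resolved
by `hclust`'s deterministic lowest-index merging.

## The GLM basis and automatic contrasts

For factors A (modalities $a_1..a_I$), B ($b_1..b_J$) and replicate R,
the per-gene model for the log mean is treatment-coded:

$$\log \mu_{g,\,rij} = o_j + m + \rho_r + \alpha_i + \beta_j' + \gamma_{ij}$$

with offsets $o$ the log effective library sizes and
$\rho_1 = \alpha_1 = \beta_1 = \gamma_{1j} = \gamma_{i1} = 0$. With the
interaction, the basis has $1 + (R-1) + (I-1) + (J-1) + (I-1)(J-1)$
coefficients, full rank for any complete design.

Contrasts are zero-sum weightings of *condition means at the reference
replicate*. For every unordered pair of A modalities the package writes
an averaged contrast (unweighted mean over B modalities — the
interpretable quantity under unbalance, rather than a sample-size
weighted mean), one per-modality contrast for each B modality, the
symmetric set for B, and a difference-of-differences interaction contrast
for every pair of pairs, giving
$\binom{I}{2}(J+1) + \binom{J}{2}(I+1) + \binom{I}{2}\binom{J}{2}$
contrasts. For the canonical 2 × 2 × 3 design this is seven. Replicate
coefficients always receive weight zero (weights sum to zero within each
condition-mean expansion), and every generated vector is estimable by
construction since it is a combination of rows of the design space. Under
an additive (no-interaction) model the interaction contrasts are
identically zero; they are flagged degenerate and dropped unless
explicitly requested.

## Negative-binomial inference

Counts are modelled as NB with variance $\mu + \phi\mu^2$. Per-gene fits
use iteratively reweighted least squares with Fisher weights
$\mu/(1+\phi\mu)$, a $10^{-10}$ ridge on the normal equations,
step-halving on any deviance increase, coefficients clipped to
$|\beta| \le 50$ (which also gives all-zero genes a well-defined floored
fit), and convergence at a relative deviance change below $10^{-8}$
(at most 100 iterations).

The common dispersion maximizes the summed Cox–Reid adjusted profile
log-likelihood (the NB log-likelihood at the IRLS fit minus
$\tfrac12 \log\det X^\top W X$) over a 19-point log grid on
$[10^{-4}, 10]$ refined by golden-section search; this is deterministic.
Per-gene dispersions are shrunk empirically toward the common value by
maximizing `APL_g + (prior_df / df_residual) × mean APL` with
`prior_df = 10` by default: zero prior gives the raw per-gene maximizer,
an infinite prior collapses to the common value.

Each contrast is tested by a 1-df likelihood-ratio test: the coefficient
basis is completed orthonormally around the contrast vector, the
constrained null model is refitted with dispersions held fixed, and
$2\Delta\ell$ is referred to $\chi^2_1$. `log2FC` is the contrast value
divided by $\ln 2$. BH adjustment is applied across genes within each
contrast (each contrast is reported independently), and DEGs are called
at adjusted $p \le \alpha$ (default 0.05). Raw p-value histograms
(20 right-closed bins) carry a `uniform_tail` flag — true iff each of the
last four bins is within $3\sqrt{m/20}$ of $m/20$ — and a false flag
logs the advice to refilter with a more stringent CPM cutoff before
trusting the fit.

**Calibration and a known limitation.** On null NB simulations
(12-sample 2 × 2 × 3 design, $\phi = 0.1$, 5000 genes) the rejection
rate at raw $p \le 0.05$ is 0.049–0.056 when the test uses the true or
the pooled common dispersion. With tagwise shrinkage at `prior_df = 10`
the per-gene estimation noise at six residual degrees of freedom adds
roughly half a point (0.057–0.062): the LRT with estimated per-gene
dispersions is mildly liberal at small sample sizes, a known property of
this class of tests. The calibration test in the suite therefore
measures the rate at the common estimate, which isolates the chi-square
approximation; analyses that need strict small-sample type-I control
should prefer `dispersion = "common"` or larger `prior_df`.

## Co-expression

Genes from a chosen DEG combination (union by default) are scaled by the
effective-size factors, genes with mean normalized count below 50
(configurable) go to **Cluster 0**, and the rest are row-normalized to
profiles summing to 1 and transformed by $v = \arcsin\sqrt{p}$ (the
variance-stabilizing transform for proportions; the square-root form is
our reading of "arcsine transformation", made explicit here).

Profiles are clustered with full-covariance, unequal-proportion Gaussian
mixtures fitted by EM. Because EM is initialization-sensitive, each K
uses a small-EM strategy: several k-means++-seeded starts, 10 short EM
iterations each, and the best short run continues to convergence
(relative log-likelihood change below $10^{-8}$, at most 1000
iterations). Covariances whose Cholesky factorization fails get
$10^{-6}\,\mathrm{tr}(\Sigma)/d$ added to the diagonal (escalating
tenfold as needed). Model choice minimizes the integrated completed
likelihood in its soft-entropy form,
$\mathrm{ICL} = -2\log L + \nu_K\log n + 2\,\mathrm{Ent}(\tau)$,
which equals BIC exactly when posteriors are hard (in particular K = 1).

Selection runs in two loops: K ∈ {5, 10, 15, 20, 25, 30} with 5
initializations each to locate the grid minimizer $K^\*$, then every K in
$[K^\*-4, K^\*+4]$ (clipped to $[2, 30]$ — ±4 spans halfway to the
neighbouring grid points) with 40 initializations. The selected model is
the global ICL minimizer; clusters are relabeled by decreasing size with
ties broken by original index, and a convexity flag records whether the
loop-2 ICL curve has a single local minimum (a wiggly curve is the
standard symptom of flat profiles or insufficient initializations).
Sub-seeds for every (loop, K, initialization) derive deterministically
from the run seed, so runs reproduce bit-identically and per-K fits can
be checkpointed to disk and resumed.

## Enrichment

Term enrichment of any gene list (DEG lists, clusters) is a two-tailed
hypergeometric test against a universe that defaults to the filtered
(expressed) gene set; genes outside the universe are dropped with a
warning, and annotation pairs for unknown genes are kept until this
restriction so a single annotation file serves every project.
`p_over = P(X \ge k)` and `p_under = P(X \le k)` both include the
observed count, so they sum to at least 1. BH adjustment is applied
separately to the over and under families since they answer different
questions; both the correction and the universe are configurable.

## The synthetic-data generator

`simulate_counts()` emulates the targeted experiment class: a complete
factorial layout written in the same target-table format the readers
accept, NB counts with variance $\mu + \phi\mu^2$ ($\phi = 0.1$ by
default, the magnitude typical of biological replicates), baseline log2
means uniform on [3, 12] (spanning weakly to strongly expressed genes),
log-normal library multipliers with sdlog 0.1 (the heterogeneity seen in
routine QC), and planted 4-fold main and interaction effects with
randomized signs in configurable fractions of genes. Ground truth per
contrast is derived from the planted condition means, so recovery tests
measure sensitivity and observed FDR without circularity in the test
statistics. `simulate_coexpression()` plants cluster-specific profiles
(spiky Dirichlet draws, concentration 0.7, per-gene totals 500–5000,
$\phi = 0.02$) — deliberately well-separated structure for recovery
tests; `simulate_annotation()` plants enriched terms over a background
pair rate.

What the simulations do **not** emulate: mean–dispersion trends,
correlated genes outside planted clusters, outlier samples, batch
effects, or zero inflation. Passing recovery tests therefore shows the
estimators work under their own model assumptions, not that real data
meet those assumptions — the p-value histogram diagnostic exists
precisely because real data often do not.

## Problem sizes used by the test suite

The suite and the acceptance script run at sizes chosen to make the
statistical assertions stable while staying desk-scale: 5000 genes for
null calibration, 2000 for planted-DE recovery, 903 genes × 12 samples ×
7 planted clusters for the two-loop selection, and toys of a few genes
for every closed-form oracle. Full-scale datasets (tens of thousands of
genes) run through the identical code paths, only longer.

## Known limitations

* At most two biological factors; the replicate factor is crossed, not
  nested.
* LRT with estimated tagwise dispersions is mildly liberal at few
  residual degrees of freedom (see above); quasi-likelihood F-tests are
  not implemented.
* No dispersion–abundance trend is modelled.
* Full-covariance mixtures in high dimension with few genes can chase
  likelihood spikes; the ICL convexity flag and Cluster-0 filtering are
  the guard rails, and profile dimensions beyond the gene count trigger
  a warning.
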