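---
title: "Dissecting latitudinal diversity gradients with mossgrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting latitudinal diversity gradients with mossgrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whether species richness rises toward the equator in every major clade is
an open question: groups such as bryophytes, with strong inherent cold
tolerance and poikilohydric water relations, may show the *inverse*
latitudinal gradient, growing richer toward the pole. Deciding the
question from atlas data raises three methodological obstacles that this
package addresses as one tested chain:

1. **Sampling bias.** Atlas records concentrate where collectors worked.
   Per-species ensemble distribution models, stacked into a potential
   richness surface (S-SDM), estimate what the gradient would look like if
   every pixel had been surveyed.
2. **Mechanism.** A richness gradient alone does not say whether species
   are *lost* in an ordered sequence toward the harsh end (nestedness) or
   *replaced* by others (turnover). The multiple-site Sørensen
   dissimilarity, partitioned into its Simpson-based turnover component
   and the nestedness-resultant remainder, separates the two.
3. **Spatial dependence.** Comparing two richness surfaces pixel by pixel
   with an ordinary correlation ignores spatial structure; Lee's L blends
   the Pearson correlation with spatial smoothing through a weights
   matrix and admits a per-pixel (local) decomposition with Monte Carlo
   significance.

Because the package is developed and validated on synthetic communities,
every stage can be checked against a known ground truth.

## Spatial data model

All stages share one frame: an equal-area lattice of square pixels
(nominally 100 km), stored row-major from the north-west corner, with a
land mask and a centroid latitude per pixel. Ocean pixels are excluded
from every statistic rather than zero-filled — zero-filling would
fabricate absences. Occurrence records are binned with half-open pixel
intervals `[x0, x0 + s) × [y0, y0 + s)`, so boundary points belong
deterministically to the pixel on their lower-left and rasterization is
record-order invariant. Records falling off-grid or on ocean are counted
and reported, never silently dropped.

Regions are split at a configurable parallel (default 46°N, the
Pyrenees–Alps axis) by pixel centroid latitude, strictly-above meaning
north.

## The beta-diversity partition

For `n` sites with per-site richness $S_i$, pooled richness $S_T$, and
$b_{ij}$ the number of species of site $i$ absent from site $j$:

$$\beta_{SIM} = \frac{\sum_{i<j}\min(b_{ij},b_{ji})}
  {\left(\sum_i S_i - S_T\right) + \sum_{i<j}\min(b_{ij},b_{ji})},\qquad
\beta_{SOR} = \frac{\sum_{i<j}\min + \sum_{i<j}\max}
  {2\left(\sum_i S_i - S_T\right) + \sum_{i<j}\min + \sum_{i<j}\max},$$

with $\beta_{SNE} = \beta_{SOR} - \beta_{SIM}$. The additivity is exact
(the test suite asserts it to 1e-12 on 1000 random matrices), perfectly
nested site sets give $\beta_{SIM} = 0$, pairwise-disjoint sites give
$\beta_{SNE} = 0$, and for two sites the measures collapse to the
pairwise Sørensen and Simpson dissimilarities. Species absent from every
site in a subset are dropped before computing $S_T$: dissimilarity is
defined on the realized pool.

Regional distributions are built by resampling: 1000 independent
without-replacement draws of 50 pixels per region (both configurable),
each partitioned as above. Two distributions are compared pairing samples
by index, with the two-sided Monte Carlo p-value
$p = 2\min(m/R,\, 1 - m/R)$ from the exceedance count
$m = \#\{r: a_r > b_r\}$, ties counted half, floored at $1/R$. The
tie-half rule is deliberate: it makes identical distributions yield
$p = 1$ rather than the floor, while complete separation still attains
$1/R$. Whether sample sets should be paired or pooled is not determined
by the resampling design itself; pairing by index is this package's
documented choice and is stated in every comparison result
(`n_resamples`).

## The SDM ensemble

Per species, presences are contrasted against a seeded uniform background
drawn from land pixels without a presence (size
`min(max(n_presences, 1000), available)`). Predictors are screened for
collinearity first: while any retained pair has $|r| > 0.8$, the member
of the worst pair with the larger mean absolute correlation to the other
candidates is dropped (greedy, fully logged; constant layers are excluded
up front). Species with fewer than 15 presence pixels are removed before
modelling — too little signal for split-sample evaluation.

Three member families are available: a logistic regression with linear
and quadratic terms, a random forest, and a presence/background weighted
logistic model (a maximum-entropy-style member in which the background is
re-weighted to carry the same total weight as the presences). The
quadratic terms of the logistic members are pruned by a single AIC pass
(`drop1` over the quadratic scope): under complete separation an
unpenalized quadratic diverges with arbitrary curvature that can invert
the predicted ranking at the range extremes, whereas curvature that
genuinely captures a unimodal niche survives the AIC comparison.

Each technique is evaluated by 70/30 split-sampling, replicated 10 times
by default (the split is shared across techniques so members differ only
by algorithm). Held-out scores are the rank-sum AUC and the true skill
statistic $TSS = \text{sensitivity} + \text{specificity} - 1$ maximized
by an exhaustive scan over observed prediction values (ties break to the
smallest threshold); the sensitivity = specificity threshold is the
second binarization rule. Every technique × replicate × threshold-rule
member contributes one binary map; the consensus marks a pixel present
iff the TSS-weighted vote fraction exceeds 0.5, with exact ties resolved
to absence (the conservative choice for stacked richness; unweighted
voting is a configuration switch). Stacking sums the per-species
consensus maps, so potential richness is bounded by the species count and
monotone in the species set.

## Lee's L

$$L = \frac{n}{\sum_i \left(\sum_j w_{ij}\right)^2}\;
  \frac{\sum_i \left(\sum_j w_{ij}(x_j-\bar x)\right)
               \left(\sum_j w_{ij}(y_j-\bar y)\right)}
       {\sqrt{\sum_i (x_i-\bar x)^2}\,\sqrt{\sum_i (y_i-\bar y)^2}}$$

with the local decomposition $L_i$ scaled so that
$\sum_i L_i / \sum_i(\sum_j w_{ij})^2 = L$. With identity weights $L$ is
exactly the Pearson correlation — a reduction the tests hold to 1e-12.
Three choices the statistic itself does not fix are made explicit and
configurable:

* **Weights.** Queen contiguity, row-standardized, zero diagonal by
  default; rook and identity schemes are provided. Neighbour links to
  ocean are removed and isolated land pixels flagged.
* **Rescaling.** Local values are reported raw and divided by the
  maximum absolute local value. Classification is rank-based, so any
  monotone rescaling leaves the significance map unchanged.
* **The null.** Permutations jointly shuffle the paired $(x_i, y_i)$
  observations across pixels, preserving the aspatial correlation while
  destroying spatial arrangement; the tested null is "no spatial
  structure in the bivariate field". The observed value is included in
  its own null ranking (rank among `n_permutations + 1`, default 999), and
  a pixel is classified Positive (Negative) when its local value ranks
  above the 97.5th (below the 2.5th) percentile — a two-tailed test at
  the 95% level. Under iid inputs the flagged fraction calibrates to
  ≈ 5% (the suite checks the median over 20 seeds against [3%, 7%]).

## Latitudinal bands

Richness maps are aggregated in equal strips of projected northing
(default 100 km), reporting per band the land-pixel count, the richness
sum and the per-pixel mean. Because bands differ in land area, the
Arrhenius species–area relationship $S = cA^z$ scales each band's summed
richness to the largest band's area, $S_{norm} = S\,(A_{ref}/A)^z$, with
$z = 0.25$ by default (configurable); with equal-area bands the
normalization is the identity for any $z$. Per-band means and standard
deviations of every environmental layer accompany the profiles.

## The synthetic generator

The generator emulates the features of a continental atlas analysis that
the pipeline's claims depend on, and nothing more:

* a latitudinal climate gradient (temperature falling ~0.9 °C per degree
  latitude) plus heterogeneity layers and a potential-evapotranspiration
  layer deliberately collinear with temperature, so the predictor screen
  has real work;
* species with unimodal (Gaussian, truncated at 3 breadths) responses
  multiplied across drivers;
* two contrasting community architectures along the thermal gradient,
  mixed by a parameter θ: *ordered loss* (θ = 1), one-sided cold-edge
  tolerance limits evenly spaced along the gradient so ranges are
  strictly nested by cold rank and multisite turnover is zero by
  construction; and *replacement* (θ = 0), evenly spaced narrow optima.
  Turnover breadth defaults to twice the optimum spacing, giving species
  realistic range sizes (tens of pixels at the default scale) while
  preserving genuine replacement;
* class noise: presence is Bernoulli in suitability with maximum
  occupancy probability $1 -$ `noise` (default 0.95), so the modelling
  stage faces genuine label noise, and a zero-noise pool is exactly
  deterministic;
* spatially biased recording: records are drawn from true
  (pixel, species) pairs with probability proportional to a supplied
  effort surface; no false presence is ever emitted, and record
  coordinates are pixel centroids so exhaustive uniform sampling
  reproduces the truth exactly.

The default study scenario is a 20 × 20 lattice spanning 38–54° (placing
the regional midline at the 46th parallel), 60 species split evenly
between a northern pool with θ = 1 and a southern pool with θ = 0 — the
configuration whose regional contrast (nestedness-resultant dissimilarity
higher in the north, turnover higher in the south) the pipeline is
designed to recover, and which reverses when θ is reversed.

What the generator does *not* emulate: dispersal limitation, speciation,
abundance structure, observation-level false presences, or irregular
coastlines. Passing tests therefore demonstrate that the chain recovers
known incidence architecture under realistic class noise and sampling
bias — not that any particular real flora follows that architecture.

## The bias-mitigation experiment

The claim that stacking distribution models mitigates sampling bias is
kept as a testable property: with effort biased 5:1 toward the
species-poor (southern) region and 40% of true presence pairs sampled,
the Spearman correlation of stacked potential richness with true richness
exceeds that of raw record counts (median over 10 seeds). The direction
of the bias matters and is chosen deliberately: over-recording the *rich*
region merely amplifies a gradient that is already there, and rank
correlations of raw counts survive such thinning; over-recording the poor
region flattens and locally reverses the apparent gradient, which is the
failure mode distribution models are meant to repair.

## Numerical choices and degenerate inputs

* All stochastic stages draw sub-seeds from one master seed through a
  documented key scheme (`derive_seed(seed, "sdm/<species>/<tech>/rep<r>")`),
  so the full pipeline is byte-identical across reruns and any stage is
  reproducible in isolation. RNG state of the caller is always restored.
* Replicates whose training split holds fewer than 2 presences, or whose
  test split has one class, are skipped and logged; an ensemble with no
  usable member is an error, not a silent absence map.
* Zero-variance maps make correlation and Lee's L undefined and raise
  typed errors; one-sided region splits warn that comparisons downstream
  are impossible; resampling a region smaller than the subset size is an
  error suggesting a smaller subset.
* Fully identical sites give $\beta_{SOR} = 0$ (the 0/0 denominators are
  resolved to zero dissimilarity); an all-empty incidence matrix is an
  error.
* Problem sizes used by the test and acceptance workloads — 20 × 20
  grids, 60 species, 1000 × 50 resamples, 999 permutations, 10–20 seeds
  for medians — are the package's desk-scale defaults, chosen so the full
  chain with known ground truth runs in minutes while every contrast it
  must detect is decisive at those sizes.

## Known limitations

* The latitude of a pixel is a linear function of northing; genuinely
  curved graticules on an equal-area projection are approximated, which
  is adequate for banding but not for reprojection (out of scope).
* The maximum-entropy-style member is a weighted logistic model, not the
  full feature-class machinery of the original Maxent.
* Between-distribution p-values are Monte Carlo summaries of resampled
  (hence autocorrelated) subsets, not frequentist tests on independent
  units; they are comparable between regions and groups but should not be
  read as population-level error rates.
* Band normalization assumes one global species–area exponent; floras
  whose $z$ varies with latitude will be under- or over-corrected.
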