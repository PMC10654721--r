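---
title: "Methods: quantifying temporal crop diversification and its effect on pesticide use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying temporal crop diversification and its effect on pesticide use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotapest)
```

## The scientific problem

Crop rotations that cycle through more species, more botanical families
and more sowing periods are expected to disrupt the life cycles of pests,
weeds and diseases, and therefore to reduce the reliance on synthetic
pesticides. `rotapest` implements the quantitative chain needed to test
this on farm-network data: (i) diversity indicators of a cropping
system's crop composition, (ii) a pesticide-reliance score per crop and
system, (iii) a multivariate check that a single time point's spatial
crop composition is a usable proxy for the rotation (space-for-time
substitution), and (iv) regression models separating two mechanisms —
*dilution* (diversified rotations contain crops that intrinsically need
fewer pesticides) and *regulation* (a given crop needs fewer pesticides
when grown in a more diversified rotation).

The unit of observation is a *cropping system*: a set of fields within a
farm following the same rotation and decision rules, described at one or
more *time points* (an entry description averaging 2–3 years, then
annual descriptions). A crop of a cropping system at one time point is
one observation for the pesticide-use models.

## Diversity indicators

All indicators derive from Hill numbers of order 1, the exponential of
Shannon entropy:

$$ {}^1D = \exp\Big(-\sum_i p_i \ln p_i\Big), $$

the "effective number" of equally abundant categories. Order 1 was kept
because it weighs rare and abundant crops similarly. `hill_shannon()`
treats zero proportions as contributing nothing ($0\ln 0 := 0$) and
rejects compositions that do not sum to 1 within `1e-9`.

Crop proportions are **field counts**, not areas: the composition of a
system at a time point is the frequency of each crop over its fields
(`composition_from_fields()`). Field areas matter only inside the TFI
surface ratio. Indicators are deliberately not rarefied by field count.

The effective number of crops decomposes into:

* **functional diversity** (FD): ${}^1D$ over botanical-family
  proportions $p_k$ (families from a closed 14-label vocabulary;
  the shipped 16-crop catalog occupies 7 of them);
* **taxonomic diversity** (TD): the average effective number of crops
  per family. Two weightings are computed. The arithmetic form
  ${}^1D_{TD} = \sum_k p_k\, {}^1D_k$ is the reported indicator and the
  default in the models. The geometric form
  $\prod_k ({}^1D_k)^{p_k}$ is also emitted because only this weighting
  satisfies $FD \times TD = {}^1D$ exactly (additivity of Shannon
  entropy); with arithmetic weighting $FD \times TD \ge {}^1D$ with
  equality iff all family-specific Hill numbers coincide (weighted
  AM–GM). Both identities are enforced as property tests on 1000 random
  compositions.

Two more indicators complete the profile: the effective number of
sowing periods (five categories: fall, winter, spring, summer,
perennial) and the cover-crop frequency. The latter is defined here as
the proportion of *fields* preceded by a cover crop; an alternative
reading (proportion of crops) exists, and the field-count definition was
adopted because cover crops are managed per field. The effective number
of cereal species (`cereal_effective_number()`) supports correlation
checks against TD; a composition without cereals returns 1 by
convention, with a message.

```{r indicators}
comp <- c(winter_wheat = 0.5, winter_barley = 0.25, spring_pea = 0.25)
hill_shannon(comp)
decompose_diversity(comp)[c("fd", "td_arith", "td_geom")]
```

## Treatment Frequency Index

Pesticide reliance is scored with the Treatment Frequency Index: the
number of applications at the full recommended dose,

$$ \mathrm{TFI} = \sum_i \frac{D_i\, S_i}{Dh_i\, S_t}, $$

with applied dose $D_i$, reference dose $Dh_i$ (the lowest registered
dose of the product on that crop), treated surface $S_i$ and field
surface $S_t$. Rules implemented on top of the ratio:

* seed coating with chemical pesticides adds **1.0 TFI point** per
  coated crop; the point is carried in the total and in a separate
  `coating` component, not in the herbicide/fungicide/insecticide
  columns, since no class attribution is defined for it;
* biocontrol products are excluded (contribution 0);
* products outside the three main classes ("other", e.g. growth
  regulators) count in the total but in none of the three class columns;
* reference-dose lookup is exact on (product, crop), and a missing pair
  is an error rather than a fallback;
* when a crop spans several fields of a system at a time point, field
  values are averaged with equal weights (area-unweighted).

TFI is additive over sprays, invariant to splitting an operation while
preserving dose and total treated surface, and scales linearly in the
applied doses; all three properties are unit-tested.

## Space-for-time substitution: composition stability

If a system's spatial composition at one time point proxies its
rotation, the composition should be stable across time points.
`permanova()` partitions the squared Bray–Curtis dissimilarities among
cropping-system identifiers and reports $R^2$, a pseudo-F and a
permutation p-value with permutations restricted to climatic regions
(labels are shuffled only within a stratum; the observed configuration
is counted in the reference set, the "+1" convention). On a Euclidean
distance matrix of univariate data the pseudo-F reproduces the one-way
ANOVA F exactly, which the tests exploit as a closed-form oracle, along
with exhaustive within-strata enumeration at small n and a 500-replicate
type-I-error simulation.

Because PERMANOVA confounds location and dispersion effects in
unbalanced designs, `dispersion_test()` embeds the dissimilarity matrix
by principal coordinates — negative eigenvalues are kept as an imaginary
block rather than corrected — computes each group's spatial median by
iterative reweighting (tolerance `1e-8`, at most 500 iterations, with
the standard perturbation when the iterate lands on a data point), forms
$d^2 = d^2_{\mathrm{real}} - d^2_{\mathrm{imag}}$ clamped at zero, and
compares group dispersions by one-way ANOVA. Groups of size 1 get
distance 0 and are excluded from the ANOVA with a warning (their
treatment is not standardized; exclusion keeps the F well defined).
`balanced_subset_analysis()` then re-runs the PERMANOVA separately
within each observation-count class (systems with 2, 3, … time points),
which removes the imbalance entirely.

## Tweedie regression models

Crop-level TFI is nonnegative, continuous, and has genuine zeros, which
the Tweedie (compound Poisson–Gamma) family handles natively for index
power $1 < p < 2$: a Poisson number of gamma jumps, zero mass
$e^{-\lambda}$ with $\lambda = \mu^{2-p}/(\phi(2-p))$, variance
$\phi\mu^p$. `dtweedie_cp()` evaluates the series density around its
dominant index to relative tolerance `1e-12`; `rtweedie_cp()` samples by
construction. Both are validated against closed forms, quadrature
normalization, moment identities and an independent implementation.

`fit_tweedie_glm()` fits the fixed-effect log-link GLM by IRLS
(coefficient tolerance `1e-10`, 200-iteration cap, rank-deficient
designs rejected with the aliased columns named). The dispersion $\phi$
is estimated by maximum likelihood by default (Pearson estimator
available for speed in simulations), and $p$ can be fixed or profiled
over 1.05–1.95 in steps of 0.05 with golden-section refinement.
AIC counts $k = \#\beta + 2$ parameters ($\phi$ and $p$). Factors use
sum-to-zero contrasts throughout so that `type3_wald()` gives type III
tests. Continuous predictors are centered and scaled
(`scale_predictors()`), and the constants are stored so raw-scale
effects stay recoverable.

The paper-scale analysis fits mixed models with a priori random
intercepts; exact replication of Laplace-approximation mixed-model
numerics is out of scope here. The pipeline's core is the fixed-effects
fit; `fit_random_intercepts()` offers a documented approximation
(penalized IRLS with Schall-type variance updates) flagged
`approximate`, which collapses to the fixed fit when the variance
component is zero.

**Model selection.** The regulation analysis compares five candidate
fixed-effect structures respecting marginality — a baseline
(region + crop + FD·TD + cover) and four elaborations adding
crop-by-indicator interactions (`regulation_candidates()`); the
sowing-period alternative for herbicides has four candidates because
the TD-by-sowing interaction is not considered meaningful. "Most
parsimonious" is read as lowest AIC, ties broken toward fewer
parameters. Within the pipeline the index power is profiled once on the
baseline model of each response and then fixed across that response's
candidates: the profile is the expensive step, and a common $p$ keeps
the AIC comparison on identical footing.

**Effects.** `marginal_means()` averages the linear predictor with
equal weights over climatic regions (and any other non-focal factor) and
back-transforms; intervals are Wald on the link scale, exponentiated
(delta method for a monotone transform), Bonferroni-adjusted when
simultaneous. Pairwise contrasts use two-tailed Wald z tests with
Benjamini–Hochberg adjustment and an insert-and-absorb compact letter
display. `slope_tests()` evaluates per-crop indicator slopes (at the
mean of the partner indicator when an indicator interaction is present)
and `percent_change_effect()` converts a scaled slope into the percent
change over a raw-scale move, e.g. functional diversity 1 → 4:
$\Delta\eta = \hat\beta\,(4-1)/\mathrm{sd}$, $\%\Delta =
100(e^{\Delta\eta}-1)$. The percent change is invariant to the scaling
constants, and reversing the endpoints satisfies
$(1+x/100)(1+y/100)=1$; both are tested.

## The synthetic network generator

`generate_network()` draws a full input dataset from a generative model
whose defaults emulate the structure of the French DEPHY-like farm
network: 6 climatic regions, 16 soil types, systems of 10 fields
(minimum 8 enforced), 1–11 time points with half the systems described
once, region-specific pools of 10 of the 16 main crops, Dirichlet
(concentration 0.5) base compositions, and a drift mixture over time
points (with probability $\varepsilon$, default 0.3, a time point's
composition is redrawn; $\varepsilon = 0$ freezes it). Fields are
assigned to crops by largest-remainder apportionment of the composition,
so the realized field-count composition is deterministic given the drawn
proportions — which is what makes $\varepsilon = 0$ produce exactly
$R^2 = 1$ in the stability stage.

Crop-level TFI is drawn from the Tweedie model
$\log\mu = a_c + b_r + \beta_{FD} z_{FD} + \beta_{TD} z_{TD} +
\beta_{cover} z_{cover} (+\, u_{system})$, with indicators scaled by the
generated dataset's own means and SDs (mirroring the analysis), default
slopes $\beta_{FD} = \beta_{TD} = -0.05$, $\beta_{cover} = 0.04$,
$\phi = 0.8$, $p = 1.6$, system-intercept SD 0.3, and per-crop
intercepts spanning feed crops near 0.1–0.2 up to potato near 9 —
chosen once to reproduce the qualitative ordering of pesticide reliance
across crops (so that the 0.7/0.1/0.2 inclusion filters bite
realistically; four feed crops fall below the 0.7 total threshold).
Optional named vectors `beta_fd_crop` / `beta_td_crop` add crop-specific
slope deviations for selection-consistency studies.

The drawn crop-level total is then decomposed *exactly* into spray
operations — $\lfloor t\rfloor$ full-dose applications plus one partial
application of the remainder, with classes drawn from crop-specific
mixes and reference doses drawn per (product, crop) — so that re-scoring
the generated sprays through `compute_tfi()` reproduces the drawn
values to machine precision (an airtight round trip, tested at `1e-9`).
When a seed-coating flag is drawn (probability 0.15, only for totals
$\ge 1$), the coating point replaces one TFI point, keeping the total
exactly Tweedie-distributed. Occasional biocontrol sprays (probability
0.05) exercise the exclusion rule without affecting totals.

What the generator does **not** emulate: agronomic feasibility of crop
sequences and return delays, weather, spatially structured soil
assignment, dose heterogeneity within products, or the paper-scale
random-effect structure beyond a single system intercept. Passing tests
therefore demonstrate correctness of the computational chain under a
faithful stochastic model of the data's shape, not agronomic realism.

## Validation design and problem sizes

The test suite validates each stage against independent oracles
(closed forms, enumeration, quadrature, hand-derived values,
`vegan::adonis2`/`betadisper`, `mgcv::ldTweedie`, `glmmTMB`) and runs
four simulation studies chosen to be informative at desk scale:

* PERMANOVA size: 500 null replicates (n = 24, 4 groups, 2 strata,
  199 permutations), rejection within the binomial 3σ band of 0.05;
* coefficient recovery: 200 replicates of a 300-system network with
  `sigma_system = 0` (so the fitted fixed-effects model is the
  generating model, which is the property under test) and
  `beta_cover = 0`; 95% Wald coverage of the three indicator slopes must
  fall in [0.90, 0.99], and the type III test of the null cover effect
  must reject at a near-nominal rate;
* AIC selection: 30 replicates of a 250-system network with a fixed
  spread of crop-specific FD slopes (−0.2 to 0.2); a model containing
  the crop-by-FD interaction must win in at least 90%;
* an end-to-end null pipeline run (80 systems, $\varepsilon = 0$, all
  diversity effects 0): stability $R^2 = 1$ exactly and slope tests
  rejecting at roughly the nominal rate.

## Known limitations

* Mixed-model estimates are approximate only; inferences in the default
  pipeline ignore within-system correlation beyond what the Tweedie
  dispersion absorbs.
* The compact letter display depends on the set of adjusted p-values,
  which under FDR adjustment is not guaranteed transitive; letters are a
  display, not a partition proof.
* The dispersion ANOVA excludes singleton groups, which slightly favors
  homogeneity in very unbalanced data.
* Percent-change effects assume the log-linear model holds over the full
  raw-scale move (e.g. FD from 1 to 4), a substantial extrapolation for
  systems observed mostly at low diversity.
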