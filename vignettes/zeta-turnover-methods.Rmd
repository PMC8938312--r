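---
title: "Methods: diversity and multi-site turnover of community components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity and multi-site turnover of community components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`zetaturn` compares diversity and compositional turnover between components
of a plant community surveyed on a plot network — typically the alien
versus native species of an invaded understory, and the rare versus common
species within each component. This vignette explains the statistical
machinery, the choices made where several defensible options existed, and
what the synthetic validation data can and cannot establish.

## The data model

The unit of analysis is a **survey dataset**: `P` plots, each divided into
`n_subplots` (default 25) contiguous subplots, with every species recorded
as the integer number of subplots it occupies (frequency 0–25). Plots
carry planar coordinates in kilometres and a park label; species carry an
origin label (`alien` / `native`); and each plot has four environmental
descriptors: soil organic matter (%), live basal area (m²/ha), effective
cation exchange capacity (ECEC, cmol/kg) and soil pH. Frequencies divided
by `n_subplots` give a within-plot relative frequency in [0, 1];
thresholding at zero gives the presence–absence (incidence) matrix on
which all turnover quantities are computed. Longitude/latitude input can
be projected to planar kilometres with `project_coordinates()`, a local
equirectangular approximation that is accurate to well under a percent at
survey extents of tens of kilometres.

## Incidence descriptors

*Occupancy* is the number (or proportion) of plots occupied, the
operational definition of rare versus common. *Extent of occurrence* is
the area of the convex hull of a species' occupied plots; species in fewer
than three plots, or whose plots are collinear, are excluded with area 0 —
we read "minimum bounding polygon" literally, so a degenerate hull has
zero area rather than a buffered line. Whether an alpha shape would be a
better minimum polygon is moot for scattered forest plots; the convex hull
is the standard choice and is what we implement.

*Chao2* extrapolates total richness from the counts of species seen in
exactly one (`Q1`) and exactly two (`Q2`) plots. The default is the
bias-corrected form `S_obs + ((m-1)/m) Q1(Q1-1) / (2(Q2+1))`, which
remains defined when `Q2 = 0`; the classical `Q1²/(2 Q2)` form is a flag
away. The ratio `S_obs / estimate` is reported as sampling completeness.

*Rarefaction* accumulates richness over plots, either in fully random
order or spatially constrained: a random starting plot, then the
remaining plots in order of increasing distance from that start. The
spatial ordering is anchored to the start rather than chained
nearest-neighbour accretion — both are defensible readings of "in order
of proximity"; the anchored form is simpler to reason about and is the
default. Bands are 2.5/97.5 percentiles of the permutation distribution
(1000 permutations by default); the gap between the random and spatial
curves measures spatial aggregation of composition.

## Zeta diversity and its decline

Zeta diversity of order `i`, ζ_i, is the expected number of species
shared by `i` plots; ζ_1 is mean plot richness and ζ_2 relates to
pairwise similarity. As the order grows only widespread species keep
contributing, so the sequence ζ_2, ζ_3, … (the *zeta decline*) summarises
turnover across the rarity spectrum in one curve.

Combinations of plots are either enumerated exhaustively — whenever
`choose(P, i)` does not exceed the replicate budget — or sampled
uniformly (the `ALL` scheme, 10,000 Monte-Carlo replicates by default).
The `NN` scheme instead draws a random focal plot and combines it with
its `i − 1` nearest neighbours; comparing `NN` with `ALL` curves reveals
how much of the species-sharing structure is spatial. Distance ties are
resolved uniformly at random (after rounding distances to 10⁻¹² km to
absorb floating-point noise), which makes the scheme well behaved in the
degenerate all-equidistant case, where it reproduces `ALL`.

The *Simpson-equivalent* normalization divides each shared-species count
by the minimum richness among the plots combined, yielding a turnover
measure in [0, 1] that is insensitive to richness differences.
Combinations containing an empty plot are skipped and counted.
Uncertainty bands default to mean ± 1.96 sd of the per-combination
values, with percentile bands available; exhaustive orders have the
honest zero-width band when all combinations agree.

The decline form is compared between a power law (`ln ζ ~ ln i`) and an
exponential (`ln ζ ~ i`), both fitted by ordinary least squares on the
same log response so that their Gaussian AICs (three parameters each) are
commensurable. A power-law decline is the signature of niche-structured
turnover, an exponential one of stochastic turnover. Orders with ζ = 0
cannot enter a log fit and are truncated with a warning; exact synthetic
series recover their generating exponents to 10⁻⁶.

## Multi-site generalized dissimilarity models

For a chosen order, each sampled combination of plots contributes one row
of a regression design: the response is the raw shared-species count and
each predictor is the mean pairwise absolute difference of one
environmental variable — or the mean pairwise spatial distance — over the
combined plots, rescaled to [0, 1] by its observed maximum. The raw count
(identity link, Gaussian error) is used as the response rather than a
Sørensen-type ratio because the per-combination counts are what the
sampling scheme produces directly; a rescaled option can be layered on
without changing the machinery. Orders are restricted to 2–10 by default
because the predictive power of these models fades at higher orders.

Predictor effects are forced monotone: a larger environmental difference
or distance cannot increase the number of shared species. Each predictor
is expanded in an **I-spline** (integrated M-spline) basis — every basis
function is non-decreasing, 0 at 0 and 1 at 1 — and the response is
regressed on the negated basis under non-negativity-constrained least
squares with a free intercept (the constrained problem is solved after
profiling out the intercept by centring). The default basis is degree 2
with one interior knot, i.e. three basis functions per predictor, with the
interior knot at the median of the predictor's sampled values (quantile
placement adapts resolution to where the data actually lie; evenly spaced
knots are the fallback when quantiles degenerate). The sum of a
predictor's coefficients is the total height of its I-spline — its
*amplitude* — and is the model's measure of that predictor's explanatory
power.

Explained variation is `1 − SSE/SST`. Fitting the full model, a
distance-only model and an environment-only model partitions it into
pure-distance, pure-environment and shared fractions (plus unexplained).
With correlated predictors a pure fraction can come out slightly
negative; the raw values are always reported, and the headline fractions
clip negatives to zero and renormalise so the four fractions sum to one,
with a flag recording that clipping occurred.

## Component regression models

*Richness models.* Per-plot species richness of a component is modelled
with a negative-binomial GLM (log link) on the four environmental
predictors, standardized to z-scores — the full linear model, no
interactions, with Wald z tests. The negative binomial absorbs the
overdispersion typical of richness counts; on equidispersed data the
dispersion estimate grows large and the fit collapses to Poisson. Fit
quality is the deviance pseudo-R², `1 − residual/null deviance`
(McFadden's likelihood-ratio variant by flag). Coefficients are reported
on the standardized-predictor scale. Residual spatial structure is
checked with a Mantel test between the residual-difference and spatial
distance matrices, with a permutation p-value.

*Multivariate frequency models.* Subplot frequencies (counts out of 25)
are modelled per species with the same NB structure; species in fewer
than three plots are excluded. For each predictor, the likelihood-ratio
statistics from dropping it are summed over species into a community-level
statistic, and significance comes from resampling: the rows of the
response matrix are permuted jointly — preserving the cross-species
correlation structure — and the sums recomputed, with
`p = (1 + #{resampled ≥ observed}) / (n_resamples + 1)`. Two
approximations keep this tractable and are worth stating plainly: the
permutation targets the global null (no predictor effects) rather than a
per-predictor conditional null, and each species' dispersion is estimated
once from the observed data and held fixed across resamples, so each
statistic is a genuine likelihood ratio at that dispersion. Under null
simulations the test holds its nominal 5% size (checked over 100 datasets
in the test suite), and strong single-predictor effects are detected with
p at the resolution floor of the resample count.

*Auxiliary contrasts.* Paired t comparison of native versus alien per-plot
richness (df = P − 1) and an OLS regression of alien on native richness; a
two-sample Kolmogorov–Smirnov test on the per-species occupancy
distributions of the two components; and pH-threshold contrasts that split
plots at pH 5.5 and compare, with a Kruskal–Wallis rank test, the per-plot
richness or mean relative frequency of *rare native* species (occupancy
below 20% of plots) or of *acid-tolerant alien* species. "Tolerant" is
operationalized as alien species present in at least one below-threshold
plot — an interpretation, flagged as such; their per-plot relative
frequency is averaged over the plots where they actually occur.

## The synthetic metacommunity generator

Because validation needs data with known structure, the package generates
communities from an explicit niche-plus-dispersal model. The subplot
occupancy probability of species *s* in plot *p* is

> p_sp = q_s · [ w · Π_v exp(−(z_pv − μ_sv)² / 2σ_s²) + (1 − w) · exp(−d_sp / λ_s) ]

where `z` are standardized environmental fields, μ and σ the species'
niche optimum and breadth, `d_sp` the distance to the nearest of the
species' seed foci, λ its dispersal scale, `q_s` a per-species prevalence
ceiling, and `w` the mixing weight between environmental sorting (`w = 1`)
and dispersal limitation (`w = 0`). Frequencies are binomial draws over
the subplots. Gaussian niches multiplied across axes and an exponential
kernel are the simplest forms that realise the sorting-versus-dispersal
dichotomy the analyses are meant to separate. Environmental fields are a
linear spatial gradient plus kernel-smoothed white noise, min–max rescaled
to field-realistic ranges (pH 4.5–6.9, organic matter 2–14%, live basal
area 8–40 m²/ha, ECEC 2–10 cmol/kg); smoothed noise gives spatial
autocorrelation without full Gaussian-process machinery.

The `paper_like` preset emulates the structure of a four-park dry-forest
survey: 50 plots in four parks over a ~1030 km² extent, 25 subplots, 178
native and 73 alien species. Natives draw narrower niches (σ 0.18–1.5 sd)
and shorter dispersal (λ 0.5–6 km); aliens broader (0.45–2.2 sd) and
longer (4–25 km), with more seed foci; prevalence ceilings are
right-skewed Beta draws so most species are locally sparse. These defaults
were fixed by matching structural descriptors of such surveys — a strongly
right-skewed occupancy distribution, incidence-based sampling completeness
near 0.85–0.9, a native component richer per plot by roughly 15–20 species
but with a small tail of near-ubiquitous aliens — and are not tuned per
analysis. A species generated but never observed is given a single
occurrence at its most suitable plot, so realized dimensions always match
the scenario. One master seed drives deterministic child seeds for layout,
fields, species parameters and sampling, so realizations are reproducible
byte for byte.

What the generator deliberately omits: temporal and demographic dynamics,
disturbance (e.g. fire), explicit interspecific competition, and
observation error in species identification. Passing recovery tests on
these data therefore shows the estimators can separate sorting from
dispersal signals *when the generating model is of this form* — not that
field data meet the model's assumptions.

## Numerical choices and degenerate inputs

* Combination sampling is uniform, without repetition inside a
  combination; repeats across replicates are allowed, and enumeration
  replaces sampling whenever it is cheaper than the replicate budget.
* Constant predictors yield all-zero design columns (flagged through a
  rank-deficiency note rather than an error); constant responses yield
  all-zero coefficients and zero explained variation.
* The non-negative least-squares fit is exact (active-set), not
  penalized; amplitudes are sums of exactly-zero or positive
  coefficients, so a predictor with no support drops out cleanly.
* Pseudo-R² and explained variation are clamped at 0; the NB dispersion
  is capped at 10⁴ in the resampling engine, where larger values are
  numerically Poisson.
* Decline fits require at least three positive orders; richness models at
  least ten plots; dissimilarity designs at least ten rows per basis
  column.

## Default problem sizes

Defaults follow survey-scale practice (10,000 zeta replicates and design
rows, 999–1000 permutations). The pipeline wrapper `run_full()` and the
bundled analysis scripts use reduced sizes chosen so that a complete run
stays interactive on a single core — 1000 zeta replicates, 2000 design
rows, 199 resamples — which widens Monte-Carlo bands slightly but changes
no point estimate systematically; every such size is recorded in the run
manifest and can be raised to survey scale with one argument.

## Known limitations

* The NN scheme's focal-plus-neighbours construction is one reading of
  nearest-neighbour subsampling; chained accretion (growing the set by
  its nearest unvisited plot) is a planned alternative mode.
* The manyGLM-style resampling tests the global null for every predictor
  simultaneously rather than each predictor's conditional null.
* Variation partitioning inherits the usual caveats of R²-difference
  partitions with correlated predictor groups: the shared fraction is not
  a causal quantity.
* Extent of occurrence ignores coastline or habitat masks — it is a
  convex hull in the projected plane.
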