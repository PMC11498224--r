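---
title: "Methods: three-dimensional multifunctionality for multipurpose forest management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-dimensional multifunctionality for multipurpose forest management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestmf)
library(dplyr)
```

# The problem

Multipurpose forest management asks whether a stand can serve several
objectives at once: harbouring diverse communities (**multidiversity**),
sustaining ecosystem processes (**ecosystem multifunctionality**), and
meeting the production-, income- and risk-related goals of a private owner
(**economic multifunctionality**). `forestmf` implements this
three-dimensional analysis for blocked comparative designs in which pure
European beech stands are compared with pure conifer stands (Norway
spruce, Douglas-fir) and beech–conifer enrichment mixtures, laid out as
*quintets*: five co-located plots, one per forest type, replicated across
locations in two regions.

Because field campaigns of this kind are expensive and the underlying
plot data are rarely deposited, the package ships a first-class synthetic
generator that emulates the statistical structure such a study produces.
Every downstream stage — preprocessing, index computation, economic
valuation, effect inference — is exercised and tested on generated data.

# Effective numbers of taxa and functions

## Normalization

Each dimension is measured by a block of indicators (seven richness
indicators for multidiversity, eight ecosystem functions, six economic
indicators in the default preset). Within each block, `minmax_normalize()`
rescales every indicator to $[0, 1]$ over the included plots,

$$x' = \frac{x - \min(x)}{\max(x) - \min(x)},$$

so the best-performing plot scores 1 and the worst 0. All preset
indicators are oriented "more is better"; a `direction = "less"` flag
reflects the scale for indicators where smaller raw values are
preferable (e.g. reading litter decomposition as carbon loss rather than
nutrient turnover), so alternative orientations are expressible even
though the default uses none.

Imputation precedes normalization, so group medians are computed on the
raw measurement scale. Whether to impute before or after rescaling is
genuinely open; imputing first keeps the imputed values interpretable in
the indicator's units and makes the scaling constants describe the
completed data. The default preset imputes the six missing
litter-decomposition cells with the median of their forest type
(`impute_median_by_group()`); indicators measured only on a location
subset (birds, canopy arthropods, fine-root biomass) are excluded from
the integrative indices rather than imputed, because extrapolating
whole-plot values from a regional subset would manufacture signal.

## Correlation-corrected aggregation

A plain sum of normalized indicators overcounts bundles of correlated,
redundant functions. The package therefore computes an *effective
number* of taxa/functions. Pairwise indicator distances are derived from
the Pearson correlation across plots,

$$d_{kj} = \frac{1 - r_{kj}}{2} \in [0, 1],$$

so perfectly correlated indicators are redundant ($d = 0$) and perfectly
anti-correlated ones maximally distinct ($d = 1$). Treating negative
correlation as distinctness is a design choice; a $1 - |r|$ variant
(negative correlation as redundancy) is available via
`function_distance(metric = "abs")`.

At a distinctiveness threshold $\tau$, distances are truncated,
$d_{kj}(\tau) = \min(d_{kj}, \tau)$, and each indicator's level is
inflated by the levels of its near-redundant neighbours,

$$a_k(\tau) = \sum_j \left(1 - \frac{d_{kj}(\tau)}{\tau}\right) f_j,
\qquad
{}^{0}\mathrm{MF}(\tau) = \sum_k \frac{f_k^2}{a_k(\tau)},$$

with $0/0$ terms defined as 0 so an all-zero plot scores 0. This order-0
form has the limits that make it interpretable:

* if all pairwise distances are $\ge \tau$, nothing is redundant and
  ${}^{0}\mathrm{MF} = \sum_k f_k$, the weighted sum of performance
  levels;
* $K$ identical, perfectly correlated functions at level $f$ count once:
  ${}^{0}\mathrm{MF} = f$;
* for all $\tau$,
  $\left(\sum f^2\right)/\left(\sum f\right) \le {}^{0}\mathrm{MF}(\tau)
  \le \sum f \le K$, and the profile is non-increasing in $\tau$.

Rather than fixing one arbitrary $\tau$, `mf_effective_number()`
evaluates the profile on a uniform grid of 100 points between the
smallest positive and the largest pairwise distance and reports the
range-normalized area under the $\tau$-curve (trapezoidal rule). The
grid size is a numerical choice: the profile is piecewise smooth with
kinks only at observed distances, and 100 points reproduce the AUC of a
1000-point grid to well below the bootstrap noise of any downstream
statistic. Degenerate geometries are handled explicitly: a single
distinct positive distance yields a flat profile (the AUC is that single
value), and an all-zero distance matrix (full redundancy) returns the
common-level value with a warning. Only $q = 0$ — richness weighting, in
which any nonzero performance counts — is implemented; the $q$ argument
exists so that other orders can be added without changing call sites,
but no other order is part of the tested surface.

`compute_dimension_indices()` applies this machinery per dimension block
and returns per-plot `multidiversity`, `ecosystem_mf` and `economic_mf`
— bounded by 7, 8 and 6 (the member counts) in the default preset.

As a robustness companion, `threshold_mf()` implements the classical
threshold approach: for $t = 1, \dots, 99$, count the indicators
reaching at least $t\%$ of their observed maximum. Ties at the boundary
count as meeting the threshold ($\ge$), which keeps the $t = 100$ edge
case meaningful (the plot holding every maximum scores $K$).

## Rarefaction

OTU-based richness indicators (soil and root fungi) are sampling-depth
sensitive, so they are rarefied before use: `rarefy_richness()` returns
the hypergeometric expectation
$E[S_n] = \sum_i \left(1 - \binom{N - N_i}{n}\big/\binom{N}{n}\right)$,
delegated to `vegan::rarefy()` for numerically stable evaluation. The
default depth, when rarefying a whole matrix, is the minimum per-plot
total — the common convention when no depth is prescribed.

# The synthetic study generator

`generate_design()` lays out quintets with the establishment rules of
the emulated design: in mixtures each focal species holds $\ge 20\%$ of
basal area ($\ge 80\%$ in pure stands), with an "other species" share
drawn uniformly on $[0, 0.1]$ — other species occur, but with small
shares. Plot exclusions (e.g. bark-beetle losses) are flagged, not
dropped, so sensitivity analyses can toggle them; the preset excludes
the spruce plots of two quintets, giving the canonical 38 of 40 plots.

`generate_indicators()` draws every indicator from a one-factor model:

$$y_{pk} = \mu_k + \beta_{k,\mathrm{type}(p)} + u_{k,\mathrm{quintet}(p)}
 + \lambda_k \, z_p + \varepsilon_{pk},$$

with a shared standard-normal latent factor $z_p$ per plot whose
loadings $\lambda_k$ induce the inter-indicator correlation that the
Hill-style correction acts on. A one-factor structure is the simplest
mechanism that produces a realistic, dense correlation matrix; richer
structures (taxon-specific factors, spatial gradients) are deliberately
out of scope. Count indicators (richness) use the same linear predictor
on the log scale with a Poisson or negative-binomial family
(`dispersion` = NB size, `Inf` = Poisson).

`paper_like_preset()` freezes the study conditions: 8 quintets × 5
forest types, 9/9/6 indicators with 7/8/6 index members, the documented
missingness patterns, and forest-type effects that embody the qualitative
result pattern the analysis should detect — beech–Douglas-fir enrichment
positive on all three dimensions, beech–spruce positive on
multidiversity but negative on economic multifunctionality. Two
honesty notes:

* The emulated study reports no within-plot sampling variances, so all
  preset SDs and loadings are placeholders chosen once for plausible
  signal-to-noise, not calibrated to data.
* The preset's six economic indicator columns are generated
  statistically like every other indicator, because the integrative
  analysis needs a plots × indicators table with controlled effects.
  The econ module (below) computes the same six indicators
  mechanistically from stand trajectories and is exercised as its own
  pipeline stage; wiring its outputs into the indicator table is a
  one-line substitution for users who want a fully mechanistic economic
  block.

What the generator does **not** emulate: real soil chemistry, species
pools, spatial autocorrelation, climate gradients, or observation error
models of individual field protocols. Passing tests therefore
demonstrate that the statistical machinery behaves as specified under
the design's structure — not that any ecological conclusion transfers
to field data.

```{r design}
design <- generate_design(n_quintets = 8, seed = 1,
  exclusions = c("q07_spruce", "q08_spruce"))
nrow(included_plots(design))
```

# Economic indicators from stand trajectories

The six economic functions are computed from a 30-year projection of the
2021 stand state in 5-year steps. The package replaces an external
single-tree growth simulator with a deterministic fixture
(`simulate_trajectory()`): cohorts grow along species-specific increment
curves, cohorts at their target diameter are harvested (conifer targets
are below beech's, so conifers in mixtures are harvested first, shifting
mixtures toward beech dominance), and an optional thinning fraction is
removed each interval. The default Douglas-fir target (55 cm) is set so
that typical ~80-year-old cohorts reach it within the projection window,
reproducing the intense-harvest dynamic that drives Douglas-fir's
immediate-profit and income indicators.

Monetary valuation is pluggable: `build_valuation()` takes price,
harvest-cost and sawn-assortment curves by species and quadratic mean
diameter (QMD). The shipped coefficients are synthetic placeholders with
conventional shapes (saturating price, decreasing cost, logistic sawn
share) — `validate_config()` reminds you of this. Net revenue
`price - cost` may legitimately be negative for small-diameter timber.

The financial indicators follow standard forest-economics identities at
interest rate $i = 0.015$:

$$\mathrm{npv} = \sum_{t=0}^{t_{\max}} V_{h,t}\,(1+i)^{-t}
 + \left[V_{s,t_{\max}}(1+i)^{-t_{\max}} - V_{s,0}\right],
\qquad
a = \mathrm{npv}\,\frac{i\,(1+i)^{t_{\max}}}{(1+i)^{t_{\max}} - 1},$$

with $V_{h,t}$ the stumpage-valued harvest booked at the end of its
5-year interval (within-interval timing is not specified by the
indicator definitions; end-of-interval discounting is the conservative
choice) and $V_{s,t}$ the stumpage value of the standing stock. The
annuity/npv pair is an exact duality — discounting the annuity stream
recovers the npv to machine precision — and this identity is asserted
over random rates and horizons in the test suite. The annuity is
undefined at $i = 0$; `annuity()` refuses that input and points to the
$\mathrm{npv}/t_{\max}$ limit rather than silently taking it.
Immediate profit is the time-0 stumpage value; the investment-corrected
variant subtracts planting costs compounded over the stand age,
$c\,(1+i)^{\mathrm{age}}$.

Resistance against disturbances is a conditional Weibull
survival probability in the accelerated-failure-time style:
$S(t) = \exp(-(t/\lambda)^k)$ and the 30-year window probability
$S(\mathrm{age}+30)/S(\mathrm{age})$. The scale is
$\lambda = \lambda_0 \exp(\gamma\,(1 - \mathrm{share}) + \beta^\top z)$:
a positive stabilization coefficient $\gamma$ (spruce, Douglas-fir)
makes admixture raise survival, and $z$ is an opaque covariate hook for
climate effects. Stand-level survival is the share-weighted mean of the
species' conditional probabilities — crown-cover maintenance is a graded
outcome, so averaging is more faithful than demanding joint survival of
all components; a product-style aggregation is available behind the
`aggregation` argument.

# Effect inference

Two complementary contrasts are implemented. `net_diversity_effect()`
quantifies non-additivity of a mixture against its monoculture-weighted
expectation,

$$D_t = \frac{O_t\,p_{ij} - E_{t,ij}}{E_{t,ij}}, \qquad
E_{t,ij} = E_{t,i}\,p_i + E_{t,j}\,p_j .$$

The printed form of this estimator is ambiguous about one parenthesis;
the implementation multiplies the observed level by the joint focal
share $p_{ij} = p_i + p_j$, which reduces to the classical
proportional-deviation form when the mixture holds only the two focal
species and keeps $D_t$ exactly 0 under additivity and invariant to
common rescaling — both properties are tested. Pure-stand expectations
use global means over all quintets by default (a within-quintet variant
is a flag), since blocking buys precision but costs degrees of freedom
at $n = 8$.

`proportional_deviation()` and `transformation_analysis()` compare each
forest type against the mean of the pure beech stands:
$(\bar{x}_{\mathrm{type}} - \bar{x}_{\mathrm{beech}})/\bar{x}_{\mathrm{beech}}$,
so $\pm 1$ is a $\pm 100\%$ change. Inference is by ordinary
nonparametric bootstrap — default $B = 10{,}000$ replicates, 95% level —
with BCa ("adjusted percentile") intervals implemented in
`bootstrap_ci()`: bias correction $z_0$ from the bootstrap distribution,
acceleration from jackknife influence values, grouped resampling with
the plot as the resampling unit. Whether the published analyses
resampled the baseline jointly with the transformed group is not
documented; both behaviours exist here (`fixed_baseline`), with joint
group-wise resampling as the default because it propagates baseline
uncertainty. Cells are labelled `win`/`lose`/`neutral` by the CI sign
convention (a CI excluding zero is a significant change).

Numerical edge cases are handled explicitly rather than silently: a
degenerate bootstrap distribution returns the point value as both
bounds with a warning; an extreme bias correction (statistic outside the
bootstrap support) falls back to the percentile interval with a warning;
BCa and percentile intervals coincide on symmetric cases with zero
acceleration, which is asserted in the tests.

```{r pipeline, eval = FALSE}
res <- run_pipeline(paper_like_preset(), seed = 1)
res$transformation
autoplot(res$transformation)
```

# Problem sizes and validation strategy

The test suite validates each operation against an independent oracle at
sizes chosen for tight brute-force checks: rarefaction against exact
subset enumeration at tiny counts and against $10^4$-draw Monte-Carlo
subsampling (with a rule-of-three floor on the tolerance where the MC
distribution degenerates); threshold counts against per-cell scans of
random tables; the BCa implementation against `boot::boot.ci` on the
same data and against nominal 95% coverage for the Gaussian mean
($n = 30$, $B = 2000$, 1000 simulations); financial identities over
1000 random (npv, $i$, $t_{\max}$) triples; and the preset's win/lose
pattern across 20 generator seeds at $B = 2000$. Full-scale analyses use
$B = 10{,}000$ as the preset default; the reduced $B$ in the multi-seed
robustness checks trades replicates for seeds, which is the binding
dimension for checking pattern stability.

# Known limitations

* All valuation, survival and planting coefficients, and all generator
  variance components, are synthetic placeholders; absolute index and
  indicator values are not comparable to any published per-plot values.
* Only $q = 0$ effective numbers are implemented; the correlation
  correction's exact published functional form is not reproduced from
  its primary source, but the implementation satisfies every stated
  limit (weighted sum, full-redundancy collapse, $\tau$-AUC bounds).
* The trajectory fixture has no mortality, competition or climate
  response; it exists to exercise the valuation formulas, not to
  forecast stands.
* The analysis is stand-scale (alpha) only; no landscape (gamma)
  aggregation or alpha/beta decomposition is provided.
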