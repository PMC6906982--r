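---
title: "Phylogenetic correlates of hybridization: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic correlates of hybridization: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybcorr)
```

hybcorr asks a comparative question: do plant groups that hybridize more share
particular traits — longer lifespans, woody growth, particular pollination or
breeding systems, larger or less variable genomes — once the phylogenetic
non-independence of those groups is taken into account? This vignette is the
package's own account of the models it fits, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the design choices
made where the design was genuinely open.

## Hybridization metrics

The unit of observation is a genus in a regional flora: the number of
nonhybrid species recorded, the number of distinct intrageneric hybrid
combinations (a hybrid is one unique pair of parental species, counted once
per flora however many times the pair crossed), and half-assignments from
intergeneric hybrids, each of which contributes 0.5 to both parental genera.
Records flagged as "multiple hybrids, unspecified" are resolved to
$\max(2,\ 0.2\,n)$ hybrids before any aggregation.

Counts are summed across floras per genus — deliberately without
de-duplicating the same parental pair observed in two regions, so the metrics
mix *how many* pairs hybridize with *how often across regions* — and turned
into two metrics for a group of $n$ nonhybrid species with $H$ hybrids:

$$\mathrm{HP} = 100\,\frac{H}{n(n-1)/2}, \qquad \mathrm{HR} = \frac{H}{n}.$$

Hybridization propensity (HP) is the realized percentage of possible pairwise
combinations; because $H$ accumulates across floras while the pair count does
not, genus-level HP can exceed 100. Hybrid ratio (HR) divides by opportunity
only. The two are algebraically linked, $\mathrm{HR} = \mathrm{HP}(n-1)/200$,
which the test suite asserts to 1e-12. Genera seen with a single species in a
single flora and no hybrids are excluded (no chance to hybridize); family
metrics are means of genus metrics weighted by genus species counts, with
family $n$ and $H$ as sums. Both metrics include exact zeros, so
`log_transform_metrics()` uses $\ln(x + \text{offset})$ with a default offset
of 1 on both scales: it preserves zero-to-zero mapping and ordering. The
offset is configurable; results for small metrics are sensitive to it, which
is inherent to any log-plus-offset choice.

Two conventions were genuinely open and are exposed as switches with these
defaults: `distinct_n = FALSE` in `aggregate_genus()` (the denominator $n$ is
the literal across-flora sum, matching the summation convention that produces
propensities up to 300%), and half-integer $H$ carried exactly, never rounded.

## Trait scoring

Species-level states are scored on 0 / 0.5 / 1 scales per trait (e.g.
herbaceous = 0, either = 0.5, woody = 1; abiotic pollination = 0, biotic = 1),
Red List categories on a 0–5 threat scale, and group values are unweighted
means over scored species. Family-level pooling averages across *species*
(equivalently genus means weighted by species count) rather than averaging
genus means — the choice matters when genus sizes vary and was not fixed by
convention, so it is a documented default. Slash-joined life-history states
split unit mass equally across categories; the perenniality *score* uses the
intermediate coding (any mixture containing perennial and non-perennial
categories scores 0.5). Genome sizes are averaged in this order: ploidy-level
variants within species, then species within the group, log-transformed
*last*; the coefficient of variation is computed across the per-ploidy-level
means pooled in the group, with a sample (n−1) standard deviation by default
(`cv_sd = "population"` switches). Missing traits are never imputed — each
analysis prunes the tree to taxa with data, and a trait with no scored species
is `NA`, never 0.

## Phylogenetic covariance models

All comparative machinery is built on the among-taxon covariance implied by a
rooted, branch-length tree. Under Brownian motion (BM),
$C_{ij}$ is the shared root-to-tip path length, computed by
`ape::vcv.phylo()`. Three transforms are provided:

* **Pagel's λ** multiplies off-diagonal entries by $\lambda \in [0,1]$:
  $\lambda = 0$ is a star phylogeny (independence), $\lambda = 1$ pure BM.
  λ is restricted to $[0,1]$; the extension of the upper bound to the maximum
  keeping $C$ positive semidefinite is deliberately not implemented, so
  estimates are directly comparable to the usual reporting convention.
* **Ornstein–Uhlenbeck (OU)**, stationary form on an ultrametric tree of
  depth $T$:
  $C_{ij} = \tfrac{1}{2\alpha} e^{-2\alpha(T - t_{ij})}(1 - e^{-2\alpha t_{ij}})$
  with $t_{ij}$ the BM shared path. Below $\alpha = 10^{-9}$ the BM limit is
  returned analytically. Ultrametricity is required to a relative tip-depth
  spread of 1e-6.
* **Early burst (EB)**: $C_{ij} = (e^{r t_{ij}} - 1)/r$ for $r \le 0$, the
  exponentially decelerating-rate model; $r = 0$ returns BM.

Polytomies are retained, not randomly resolved — the covariance handles them
natively and random resolution would add undocumented stochasticity.
Zero-length terminal branches would make $C$ singular; they trigger a warning
and a diagonal jitter of $10^{-8}$ times tree depth. Every construction is
symmetric and Cholesky-factorable after at most a $10^{-10}\,\mathrm{tr}(C)$
jitter, which `gls_fit()` applies once if a factorization fails.

## GLS, phylogenetic signal and PGLS

`gls_fit()` solves $y = X\beta + \varepsilon$, $\varepsilon \sim
N(0, \sigma^2 C)$ by Cholesky whitening:
$\hat\beta = (X^\top C^{-1}X)^{-1}X^\top C^{-1}y$. Maximum likelihood is used
throughout (σ² with the 1/n denominator inside the likelihood) because
likelihood-ratio tests and AIC comparisons mix fixed-effect structures, where
REML likelihoods are not comparable; standard errors use the small-sample
$1/(n-p)$ variance. The whitened-OLS equivalence (to 1e-10) and the identity
of PGLS-BM slopes with OLS-through-origin on Felsenstein's independent
contrasts (to 1e-8) are the module's two correctness anchors, and the fit is
additionally cross-checked against `nlme::gls` with a Brownian correlation
structure.

`fit_lambda_ml()` profiles λ on $[0,1]$ for one trait (intercept-only design;
mean and rate concentrated out analytically) with a bounded scalar optimizer
at tolerance 1e-8, explicitly comparing the interior optimum against both
endpoints. The likelihood-ratio test against the star phylogeny uses
$\chi^2_1$, as is conventional, despite λ = 0 sitting on the boundary (the
test is therefore mildly conservative); the LRT statistic is clamped at 0,
since boundary optimization can produce tiny negative values. A constant
trait makes λ unidentifiable: the fit is flagged degenerate with LRT 0 and
p = 1 rather than erroring.

`fit_pgls_model()` regresses a hybridization metric on one trait under BM, OU
or EB. The OU and EB nuisance parameters are profiled by bounded ML with
bounds tied to tree depth — $\alpha \in [10^{-8}, 50/T]$,
$r \in [-10/T, 0]$ — because unbounded α overflows the exponentials. The
slope p-value is two-sided t with $n-2$ df. $R^2$ is deviance-based: one
minus the ratio of whitened residual sums of squares of the fitted and
intercept-only GLS models under the *same* covariance, with
$R^2_{adj} = 1-(1-R^2)(n-1)/(n-p-1)$, which can be negative for weak fits.
AIC counts the intercept, slope, σ² and any profiled covariance parameter
(k = 3 for BM, 4 for OU/EB). `compare_models()` reports ΔAIC/ΔBIC and selects
a representative fit: BM whenever all models are within 2 AIC of the best
(indistinguishable, so the simplest baseline is reported), otherwise the
AIC-best model. Benjamini–Hochberg flags are applied within each metric ×
taxonomic level family of tests at q = 0.05 via `stats::p.adjust`, with the
brute-force step-up definition as the test oracle. Raw Pearson correlations
(p from t with $n-2$ df) are provided for frame of reference only — they do
not correct for shared ancestry.

## Phylogenetic path analysis

Candidate causal structures over woodiness (W), perenniality (P) and
hybridization (H) are compared by directional separation. For each DAG the
basis set contains one claim per non-adjacent pair — with x before y in
topological order (lexicographic tie-breaks, so ordering is deterministic),
x ⟂ y given the union of the parents of both. Each claim is tested by
BM-PGLS of y on the conditioning set plus x, taking x's two-sided p-value
(t, $n-p$ df). Claims combine into Fisher's statistic
$C = -2\sum \ln p_i$, $\chi^2$ with $2k$ df under the model; p-values are
floored at 1e-300 before the log. Models are ranked by
$\mathrm{CICc} = C + 2qn/(n-1-q)$ with $q$ = edges + nodes (the convention of
the phylopath-style implementations; configurable to edges-only), all fitted
on the common complete-case taxon set so CICc values are comparable, with
ties broken by fewer edges and then by name. Path coefficients of the
selected model are standardized slopes: every variable is z-scored on the
analysis set and each node with parents is regressed on all its parents under
BM-PGLS.

The default candidate set holds five DAGs: the two mediation chains
(W→P→H and P→W→H), each chain plus a direct edge from the distal trait, and
the two-direct-paths model W→H, P→H with W→P. Three of the five are
saturated on three nodes, a structural fact with a statistical consequence
discussed under limitations.

## The synthetic-data generator

No machine-readable flora or megatree data ship with the package, so a seeded
generator stands in for them; its defaults are the package's reference
conditions and are not adjusted per analysis.

* **Trees**: pure-birth (Yule) via `ape::rphylo`, ultrametric, unit
  speciation rate.
* **Traits**: latent multivariate normal whose per-trait covariance is the
  λ-scaled BM matrix (scaled to unit depth, so σ² is tip variance) and whose
  cross-trait correlation is a specified matrix — for equal λ this is exactly
  the Kronecker structure. Bounded traits pass through a logistic map (0–5
  scale for the threat score, exponential for the strictly positive
  coefficient of variation). Default λ values follow the genus-level signal
  structure typical of these traits (strong for woodiness, pollination
  syndrome and genome size; weak for breeding system; none for genome-size
  variability); perenniality and woodiness get a latent rate of σ² = 4
  because their group-mean distributions in floras are broad and strongly
  bimodal (many fully annual/herbaceous and fully perennial/woody genera),
  and a latent correlation of 0.6, since the two traits are strongly
  associated in plants.
* **Counts**: genus species totals are $2 + \mathrm{NB}(\text{size}=0.8,
  \mu=8)$ — a heavy right tail mimicking the skewed genus-size distributions
  of regional floras; hybrid totals are Poisson with
  $\ln \mathbb{E}[H_i] = \beta_0 + \textstyle\sum_t \beta_t x_{ti} +
  \ln\{n_i(n_i-1)/2\} + b_i$, where $b_i$ is Brownian noise (sd 0.5 at unit
  depth). The pairwise-combination offset makes planted effects act on
  propensity rather than on raw counts. $\beta_0 = -3.5$ puts baseline
  propensity near 3% and the zero-hybrid genus fraction near two thirds, the
  order observed in flora compilations. Counts and species are scattered
  multinomially across eight floras. Everything derives deterministically
  from one seed through fixed child seeds; stochastic stages refuse to run
  unseeded.

Benchmark scenarios: `null` (no effects), `perenniality-driven`
(β = 0.8 on perenniality), `chain-causal` (analysis-level variables with
standardized path coefficients 0.5 and 0.3, plus counts driven by
perenniality), and `family-structured` (strong signal, for family-level
aggregation). The chain-causal scenario plants its coefficients at the
analysis-variable level deliberately: path analysis consumes standardized
variables, and routing the coefficients through the count channel would
attenuate them by an amount that depends on every other generator setting.

What the generator does **not** emulate: flora recording biases (the real
floras were chosen because their authors noticed hybrids), taxonomic
misassignment, hybrid speciation feeding back into species counts,
correlation between genus size and traits, and non-Yule tree shape. Passing
tests therefore demonstrate correctness of the machinery under known
conditions, not robustness to these real-data features.

## Known limitations

**Count-derived metrics violate the BM error model.** Poisson sampling of
hybrid counts adds noise that is independent across taxa and heteroscedastic
in genus size, so the log-metrics have weak phylogenetic signal even when the
underlying rates evolve by BM — fitted λ for the metrics is far below 1, as
is typical for such data. BM-PGLS applied to them is then misspecified: its
reported standard errors understate the heavy-tailed sampling variability of
the slope (a handful of sister-pair contrasts dominate), and its type-I rate
under the count-channel null is inflated at any realistic genus size. The
package's calibration tests therefore check the PGLS machinery on
Gaussian-BM responses, where it is exact (type-I within the nominal band,
agreement with `nlme::gls` to 1e-6), and check planted count-channel effects
through the raw-correlation stage, where they are reliably detectable. Users
analyzing real flora counts should read genus-level PGLS slopes with the same
caution and lean on the λ estimates of the metrics themselves as a
diagnostic.

**CICc separates nested structures by only one penalty unit.** Three of the
five default candidate DAGs are saturated, differing from the generating
chain by one edge; the CICc penalty difference is ≈ 2 regardless of the q
convention, so the probability of selecting the true chain when its single
d-separation claim holds is $P(\chi^2_2 < 2) \approx 0.64$ — at any sample
size and effect strength. The acceptance report's chain-selection rate
(~0.7) reflects this ceiling, not an implementation defect; the modal winner
is the true chain, and the qualitative structure (a direct
perenniality→hybridization path, no direct woodiness→hybridization path) is
what replicates.

**Boundary and degenerate cases.** The λ LRT is conservative at the
boundary; constant traits and zero-variance responses are flagged, not
silently fit; propensity is undefined for $n < 2$ and such groups must be
excluded upstream (the exclusion rule does this for the only case the
counting conventions can produce).

## Problem sizes

The test suite and acceptance script use sizes chosen to make
sampling-variability bands tight while keeping a full run inside a few
minutes on one core: identity and oracle checks at 10–50 taxa (100 and 50
random instances), λ recovery at 500 tips × 20 replicates per true λ,
PGLS null calibration at 200 tips × 500 replicates, Fisher's C calibration at
300 tips × 1000 replicates, path-model selection at 500 tips × 100
replicates, and the end-to-end pipeline at 400 genera.
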