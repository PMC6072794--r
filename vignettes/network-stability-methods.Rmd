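---
title: "Co-occurrence network stability analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence network stability analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conetstab)
library(dplyr)
```

## The scientific problem

Soil bacterial and fungal communities respond very differently to disturbances
such as drought, and ecological theory predicts that the *structure of the
interaction network* — how strongly taxa are coupled, how many couplings are
antagonistic, how compartmentalised the network is — governs how a community
withstands and recovers from perturbation. Communities dominated by many
strong, positive couplings are expected to co-oscillate and destabilise;
weakly coupled, modular communities with some negative links are expected to
be buffered.

`conetstab` implements the complete analysis chain used to test these ideas on
amplicon OTU tables: quality filtering and rarefaction, diversity metrics,
Bray–Curtis resistance/resilience statistics, ordination and PERMANOVA,
indicator-taxon (IndVal) analysis with a permutation null, all-pairs Spearman
correlation sets, thresholded positive co-occurrence networks with node and
network statistics against random-graph nulls, and the group comparisons that
connect all of this back to treatments. A latent-factor synthetic community
generator with planted ground truth makes the whole chain testable end to end.

## The analysis chain and its assumptions

### Filtering and diversity

Analysis starts from a taxa × samples integer count matrix. The standard
filter chain is:

1. **Rarefaction** to a common depth (default 4000 reads) by subsampling
   without replacement; samples below the target depth are dropped. Each
   sample's subsample uses an RNG stream derived from the global seed and a
   hash of the sample id, so results do not depend on column order.
2. **Shannon outlier removal**: samples with implausibly high Shannon
   diversity (H in nats, on relative abundances) usually reflect
   contamination. Typical ceilings are around 6 for 16S libraries and 3.2 for
   ITS libraries; because the appropriate ceiling is data-dependent QC, the
   pipeline applies the filter only when a ceiling is supplied.
3. **Low-count taxon removal**: taxa with fewer than 10 reads total.
4. **Prevalence filter** per network cell: only taxa present in at least 8 of
   the cell's 36 communities enter correlation analysis, so edges cannot be
   driven by shared absences.

Diversity is reported as richness, Shannon H (natural log — consistent with
the ceilings above at observed richness scales), and Pielou evenness
J = H / ln(richness), with J defined as 0 for single-taxon samples. The
evenness formula and log base are documented choices: the field's "evenness"
is almost always Pielou's J, and both are configurable in principle by
computing from the returned tibble.

### Resistance and resilience

Community-level response is measured as Bray–Curtis similarity
(1 − dissimilarity) between control and drought communities at each sampling.
Low similarity during the disturbance indicates low resistance; the recovery
of similarity afterwards measures resilience. Two pairing schemes are
implemented because the choice is genuinely open: `matched` (default) joins
control and drought mesocosms sharing block and plant-community treatment,
mirroring a split-block design; `all_pairs` crosses every control with every
drought community. Neither is asserted to be the only valid scheme. A one-way
fixed-effects ANOVA across samplings accompanies the similarities; the full
split-plot error-strata model used for field data is deliberately out of
scope and the fixed-effects approximation is documented, not presented as
equivalent.

### Ordination and PERMANOVA

PCoA is classical scaling: double-centre −D²/2, eigendecompose, scale
eigenvectors by the square root of their eigenvalues. Bray–Curtis is not
Euclidean, so negative eigenvalues can occur; they are reported and their
axes omitted, and requesting more axes than there are positive eigenvalues
truncates with a warning.

The treatment test is the one-factor PERMANOVA pseudo-F
(SS_between/(a−1)) / (SS_within/(N−a)) computed from squared distances, with
significance from label permutation. Two numerical conventions matter:

* the Monte-Carlo p always uses the +1 correction,
  p = (1 + #{F_perm ≥ F_obs}) / (1 + n_perm), so p is never 0;
* with `permutations = "exhaustive"` every distinct label arrangement is
  enumerated and the exact p (#{F ≥ F_obs} / #arrangements, observed
  arrangement included) is returned — used for validation on small designs.

Permutation-F comparisons use a relative tolerance of 1e−12 so that
relabellings reproducing the observed partition count as ties regardless of
floating-point summation order.

### Indicator taxa

The IndVal score of taxon i in group g is A · B, where A is the taxon's mean
relative abundance in g divided by the sum of its group means and B is its
occurrence fraction in g. Scores are computed on relative abundances, which
on rarefied tables is equivalent to counts and makes the score invariant to
per-sample depth rescaling (a property test asserts this). Significance uses
the taxon's maximum score across groups against a null built by permuting
sample labels — one permutation shared by all taxa per iteration, preserving
taxon–taxon dependence — with the same +1 correction. Indicators are
classified `tolerant` (best group = drought) or `sensitive` (best group =
control) when p < 0.05 and the mean relative abundance in the best group
exceeds 1%. Whether the 1% gate uses the best-group mean or the overall mean
is not fixed by convention; the best-group mean is the default and the
overall mean is available via `abundance = "overall"`. Raw p-values are
reported (no correction across taxa) to match standard practice for this
analysis; a BH adjustment can be applied downstream with `p.adjust`.

### Correlation sets and networks

All-pairs Spearman correlations are computed as Pearson correlations of
mid-ranks; zeros enter the ranking as ties at the bottom, with no
pseudocounts. p-values use the t approximation
t = ρ√((n−2)/(1−ρ²)) with n−2 df (n = 36 in the reference design, where the
approximation is accurate); |ρ| = 1 is assigned the smallest representable
double. Taxa that are constant across samples have no defined rank
correlation; they are excluded and reported.

Co-occurrence edges are pairs with ρ > 0.6 **and** p < 0.01, positive
correlations only; a parallel signed set (|ρ| > 0.6, p < 0.01) is retained so
the proportion of negative correlations can be compared between communities.
The ρ > 0.6 cutoff spans a range of interaction strengths rather than only
the strongest; the p threshold is 0.01 by default and configurable (stricter
conventions such as 0.001 exist for the same analysis). No multiple-testing
correction is applied to edge p-values, again mirroring standard practice;
this inflates the absolute number of edges but affects both communities
equally in comparisons.

Node and network statistics: degree; normalised degree (default
degree/(n−1), which bounds the metric in [0, 1] — an alternative
normalisation by total connection ends, degree/2m, is available because the
verbal definition "standardised by the total number of connections" is
ambiguous); unweighted, unnormalised shortest-path betweenness; global
transitivity 3·triangles/triples (defined as 0 when no connected triple
exists); Girvan–Newman modules via iterative removal of the
highest-edge-betweenness edge, returning the nested partition maximising
Newman–Girvan Q (igraph's tie-breaking applies); and the inclusion
proportion, nodes / taxa passing the prevalence filter.

The random-graph null draws G(n, m) graphs with exactly the observed node and
edge counts and compares observed transitivity to the ensemble with the +1
empirical p. A network "more clustered than random" at p ≤ 0.01 is the basic
sanity property of factor-structured communities.

### Group statistics

Proportions are compared by Pearson χ² on the 2×2 table without continuity
correction (the correction is immaterial at the scales involved and a flag
restores it); one-way and two-factor crossed ANOVA use ordinary
fixed-effects least squares (Type I sums of squares on balanced designs, with
a warning when unbalanced); regressions are OLS with the two-sided t test on
the slope. The degenerate all-values-identical ANOVA returns F = 0, p = 1
rather than NaN. Covariate–node analysis computes each node's Spearman
correlation with a per-sample covariate (e.g. biomass of a dominant plant),
then regresses |ρ| on centrality within groups and contrasts slopes via the
interaction term of a pooled model — a documented stand-in for a full ANCOVA
whose exact specification (covariate coding, error strata) is not fixed by
the analysis tradition.

## The synthetic community generator

The generator produces the statistical structure the analysis assumes, plus
ground truth for validation:

log a_is = μ_i + δ_i·decay(s)·1[drought] + Σ_k λ_ik f_ks + ε_is,
counts ~ Multinomial(depth, a_.s / Σa_.s)

with factors f ~ N(0,1) per sample, noise ε ~ N(0, σ²), and baselines
μ ~ N(0, mu_sd²). Key parameters (all in log-abundance units unless noted):

| parameter | meaning | default |
|---|---|---|
| `loading_mean`, `loading_sd` | primary factor-loading magnitude | 1.0 ± 0.1 |
| `neg_fraction` | probability a loading is negative (antagonism) | 0 |
| `sigma` | residual noise SD | 0.3 |
| `depth` | reads per sample | 4000 |
| `n_per_cell` | mesocosms per treatment arm | 36 |
| `effect_size` | responder drought shift | log 4 (a 4-fold change) |
| `effect_decay` | shift multiplier per sampling | 0, 1, 0.5, 0.25 |
| `global_fraction`, `global_loading`, `global_mu_boost` | shared co-oscillation factor | 0 (off) |

Two taxa sharing one factor with loadings λ₁, λ₂ have population log-scale
correlation λ₁λ₂ / √((λ₁²+σ²)(λ₂²+σ²)) — the closed form behind
`expected_edges()`. Multinomial sampling adds compositional closure exactly
as in rarefied real tables, which is deliberate: correlations estimated from
counts are attenuated and slightly distorted, and the validation thresholds
account for that.

### Presets and why they look the way they do

* **`bacteria_like`** (2000 taxa, 40 factors, dense strong ± loadings, 15%
  negative): most of its coupling runs through a *graded shared factor*
  (loading 2.0 ± 50%) carried by the most abundant 30% of loaded taxa, whose
  baselines are boosted (+2.6). This structure is what real 16S tables imply
  at depth 4000: with 2000 taxa only a few hundred are abundant enough for a
  rank correlation of 0.6 to be detectable at n = 36, so a large, dense,
  weakly transitive network can only arise among a dominant co-oscillating
  guild with a graded core–periphery. Equal-loading alternatives produce
  either small cliques (high transitivity — the fungal pattern) or no edges.
* **`fungi_like`** (400 taxa, 15 factors, sparse weaker loadings, 5%
  negative): couplings confined to small factor blocks, which surface as
  small near-cliques — fewer nodes, lower connectivity, high transitivity,
  high modularity.
* **`strong_coupling`**: 25 planted pairs at loading 1.2, σ = 0.3
  (population correlation 0.94) among 150 background taxa. The planted taxa
  are down-weighted (μ shift −1.2) because otherwise their joint share of
  reads is large enough that compositional closure induces spurious
  correlations among background taxa.
* **`strong_responder`**: 30% responders at 1.5 log-fold units — the regime
  where ordination separation and resilience trajectories are unambiguous.
* **`planted_modules`**: five clean 12-taxon blocks for module-recovery
  validation.

Preset numbers were chosen once, from the closed-form correlation model and
small design-time simulations, and then frozen before the validation battery
was written.

### What the generator does *not* emulate

Real amplicon data have heavier-tailed abundance distributions, overdispersion
beyond multinomial, phylogenetic structure, and mechanistic (e.g.
Lotka–Volterra) dynamics; the generator has none of these. Passing the
validation battery therefore demonstrates that the *analysis chain* is
correct and that the qualitative community contrasts follow from the planted
structure — it does not certify performance on real data with different noise
anatomy.

## Numerical choices

* Permutation p-values always use the +1 correction; exhaustive enumeration
  is available for small designs.
* Permutation-statistic ties are detected at relative tolerance 1e−12.
* Transitivity of a graph with no connected triple is defined as 0.
* Pielou J is defined as 0 at richness ≤ 1; Shannon terms with p = 0 are
  dropped.
* Rarefaction seeds derive from (global seed, id hash) modulo 2³¹−1.
* Edge thresholds are strict inequalities (ρ > 0.6, p < 0.01), and the
  prevalence boundary is inclusive (≥ 8 samples), matching "at least".
* Degenerate inputs: empty networks are legal results (warned, not fatal);
  zero-total samples are fatal with the sample named; a constant covariate is
  fatal.

## The pipeline

`run_pipeline(pipeline_config(...))` orchestrates the chain per community:
simulate (or read TSVs), filter, diversity, resilience, per-sampling
PERMANOVA and indicators, then one network per treatment × sampling cell
(8 per community in the full design) with metrics, modules and nulls, and
cross-community comparisons — writing TSV/GraphML outputs and a JSON report.
The run is a pure function of (config, seed): re-running an identical config
reproduces byte-identical tables. Configuration is an R list rather than an
external config file, which keeps the full default set visible in one
documented constructor and serialises into the report.

Problem sizes in the shipped validation battery are chosen to exercise the
full design where it matters (36 samples per cell, depth 4000, 2000-taxon
bacteria-like tables) while keeping replicate counts modest (10 replicate
contrast runs, 50 edge-recovery tables, 1000-graph null ensembles,
1000-replicate calibrations), which a single CPU completes in a few minutes.

## Known limitations

* Spearman-threshold networks inherit all caveats of correlation networks on
  compositional data; no SparCC/SPIEC-EASI-style compositionality correction
  is attempted (out of scope by design).
* The split-plot repeated-measures error structure of mesocosm experiments is
  approximated by fixed-effects ANOVA throughout.
* IndVal here is the two-group (control/drought) form; multi-level or
  combined-group extensions are not implemented.
* The t approximation for Spearman p is inaccurate below ~10 samples; an
  exact permutation p would be preferable there (the package's permutation
  machinery can be used manually for such designs).
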