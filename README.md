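# conetstab

Stability analysis of microbial co-occurrence networks under disturbance.

Soil bacteria and fungi respond very differently to climate extremes such as
drought, and network theory suggests why: communities whose members are
coupled by many strong, positive correlations co-oscillate and destabilise,
while weakly coupled, modular communities with some antagonistic links are
buffered. Testing these ideas from amplicon data requires a long chain of
standard steps — rarefaction, diversity, Bray–Curtis resistance/resilience,
PERMANOVA, indicator-species analysis, all-pairs Spearman correlations,
thresholded co-occurrence networks, graph statistics against random-graph
nulls — each with conventions that are easy to get subtly wrong.
`conetstab` packages that chain as tested, composable R functions for
ecologists working with OTU tables from disturbance experiments.

## The statistics at the core

* **Resistance / resilience**: Bray–Curtis similarity `1 − Σ|x−y|/Σ(x+y)`
  between matched control and drought communities per sampling time.
* **PERMANOVA**: pseudo-F = (SS_between/(a−1)) / (SS_within/(N−a)) on squared
  distances, permutation p with the +1 correction; exact enumeration for
  small designs.
* **IndVal** (Dufrêne–Legendre): IndVal_ig = A_ig·B_ig with A the relative
  mean-abundance concentration and B the occurrence fraction of taxon i in
  group g; permutation null over sample labels; indicators classified
  drought-*tolerant* / *sensitive* at p < 0.05 and > 1% abundance.
* **Co-occurrence networks**: edges are positive Spearman rank correlations
  with ρ > 0.6 and p < 0.01 among taxa present in ≥ 8 of 36 communities;
  node normalised degree (degree/(n−1)) and betweenness, global transitivity,
  Girvan–Newman modularity Q, and an Erdős–Rényi G(n, m) null for the
  clustering coefficient.
* **Synthetic truth**: a latent-factor generator
  (log-abundance = baseline + treatment shift + Λf + noise, multinomial
  reads) with planted modules, antagonistic loadings and drought responders,
  so every stage can be validated against known ground truth.

## Worked example

Simulate a fungi-like community at the end of a drought, build the control
network, and test the treatment effect:

```r
library(conetstab)

gen  <- generate_community(synth_preset("fungi_like", samplings = "end_drought"),
                           seed = 7)
tbl  <- prevalence_filter(filter_low_count_taxa(gen$table, 10), 8)
meta <- align_metadata(tbl, gen$metadata)

ctrl <- otu_table(unclass(tbl)[, meta$treatment == "control"], "fungi_like")
cs   <- spearman_matrix(ctrl, label = "fungi control end_drought")
glance(cs)
#>   label        n_taxa n_pairs n_samples mean_abs_rho prop_negative n_significant
#> 1 fungi contr…    400   79800        36        0.139         0.481           249

net <- detect_modules(threshold_network(cs, rho_min = 0.6, p_max = 0.01,
                                        table = ctrl))
glance(net)
#>   label          nodes edges density inclusion_proportion clustering_coefficient
#> 1 fungi control…   123   235  0.0313                0.308                  0.774

random_network_null(net, ensemble = 1000, seed = 1)
#> G(n,m) null: observed clustering 0.7743 vs null 0.0317 +/- 0.0099 (p = 0.000999, 1000 graphs)

permanova(bray_curtis(tbl), meta$treatment, n_perm = 999, seed = 1)
#> PERMANOVA: pseudo-F(1, 70) = 19.87, R2 = 0.221, p = 0.001 (random, 999 perms)
```

Reading: of 400 taxa passing the prevalence filter, 123 (31%) enter the
co-occurrence network; its clustering coefficient (0.77) is far above the
random-graph expectation at the same size (0.03), i.e. the network is
strongly compartmentalised; and drought restructured the community
(PERMANOVA p = 0.001, R² = 0.22). A bacteria-like preset run the same way
yields a larger, denser, less clustered network with more negative
correlations — the contrast between destabilising and stabilising network
architectures.

`run_pipeline(pipeline_config(out_dir = "run1"))` executes the whole chain —
filters, diversity, resilience, PERMANOVA, indicators, and one network per
treatment × sampling cell — writing TSV/GraphML outputs plus a JSON report,
reproducibly from a single seed.

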