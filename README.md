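# pknfilter

Expression-filtered prior-knowledge network analysis.

Curated interaction databases describe a theoretical "whole-genome cell":
they connect molecules that may never be expressed in the same tissue.
Expression profiling, conversely, says which genes are present but predicts
no interactions. `pknfilter` combines the two for tissue/disease studies: it
takes a directed reference network (signaling reactions, or an
enzyme-centered metabolic graph built from a reaction table), restricts it
to the genes detected in tag-count expression data, and then validates and
mines the filtered networks. It is aimed at systems-biology analysts who
have a reference edge list, a pathway collection (GMT) and per-condition
tag counts, and want enrichment and key-node results with defensible null
models.

## Methods in brief

* **Filtering.** The *strict* network is the induced subgraph of the
  reference G on the detected vertex set D; the *k-extended* network adds
  all in- and out-neighbors k times before inducing edges
  (`strict_filter()`, `extended_filter()`, `extend()`). Conditions are
  combined by set algebra (union by default).
* **Enrichment.** For a pathway P, the overlap k of the filtered set
  (size n) with P (size K) inside the mappable universe (size N) is tested
  one-sided against the noncentral (Fisher) hypergeometric null
  f(x) ∝ C(K,x)·C(N−K,n−x)·ω^x, where the odds ω is the ratio of mean
  tissue-panel expression inside P to outside — genes broadly expressed
  across tissues are more likely to be drawn under the null
  (`noncentral_fisher_test()`, `compute_weights()`, `group_odds()`). ω = 1
  recovers the classical Fisher test. For 1-extended networks, where vertex
  inclusion is dependent through the extension, empirical p-values are
  obtained by Monte-Carlo: strict-sized sets are drawn from the
  expression-weighted urn, extended, and their overlaps tabulated
  (`monte_carlo_extended_test()`). FDR is controlled with Storey q-values
  (`storey_qvalues()`).
* **Key nodes.** The pairwise disconnectivity index Dis(v) is the fraction
  of connected ordered vertex pairs destroyed by removing v; ΔDis compares
  max-normalised Dis between filtered and reference networks
  (`dis_index()`, `dis_increase()`). Bow-tie decomposition (LSCC/IN/OUT)
  and a mean-centered Levene test relate topology to the variance of
  per-vertex log fold-changes (`bowtie_decompose()`, `levene_test()`,
  `compartment_variance_report()`).
* **Synthetic data.** `sim_config()` + `simulate_*()` generate all inputs
  (reference SIF, GMT pathways, tag counts, identifier map, tissue matrix,
  reaction table) with planted structure — a strongly connected core, a
  detection-enriched pathway, currency metabolites, compartment-dependent
  expression variance — so the whole pipeline is testable offline.

## Worked example

```r
library(pknfilter)

cfg <- sim_config(seed = 7, detection_base_rate = 0.3,
                  enrichment_factor = 3)     # plant pathway PW001
ref <- simulate_reference(cfg)
pws <- simulate_pathways(ref, cfg)
ex  <- simulate_expression(ref, pws, cfg)

u <- combine_conditions(map_detection(ex$normal,  ex$idmap, ref),
                        map_detection(ex$disease, ex$idmap, ref))$union
strict <- strict_filter(ref, u)
strict
#> <pkn_network 'synthetic reference [strict]'> 573 vertices, 534 edges (534 distinct pairs)

w <- compute_weights(ex$tissue, ex$idmap, ref$vertices)
res <- enrich_all(ref, u, pws, w, mode = "strict_exact")
head(res[, c("pathway", "K", "k", "omega", "p", "q")], 3)
#>   pathway  K  k    omega            p            q
#> 1   PW001 45 43 1.009470 8.933555e-20 9.648240e-18
#> 2   PW054 47 25 1.024047 2.183503e-03 1.165531e-01
#> 3   PW005 52 26 1.001376 4.373255e-03 1.165531e-01
```

The planted pathway PW001 overlaps the strict network in 43 of its 45
members where ~15 would be expected under the expression-weighted null, and
is the only pathway significant after FDR control (q ≪ 0.05); its odds
ω ≈ 1.01 shows the signal is not an expression-bias artefact. Key nodes:

```r
dis <- dis_index(remove_orphans(strict))
head(dis[order(-dis$dis), c("vertex", "dis", "dis_norm")], 3)
#>     vertex        dis  dis_norm
#> 186  V0895 0.32115039 1.0000000
#> 233  V1133 0.14051522 0.4375371
#> 58   V0242 0.09461426 0.2946105
```

Removing V0895 disconnects ~32% of the connected ordered vertex pairs of
the strict network — a non-local bottleneck that plain degree would miss.

The same analysis runs end-to-end from the shell:

```sh
Rscript inst/scripts/pknfilter.R all --out run1 --seed 7
```

writing per-stage TSVs and manifests under `run1/`.

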