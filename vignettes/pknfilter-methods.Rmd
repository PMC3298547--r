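---
title: "Expression-filtered network analysis: models, null distributions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-filtered network analysis: models, null distributions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pknfilter)
```

This vignette explains the statistical models behind `pknfilter`, the
parameters that matter, and the design decisions taken where the problem
admits more than one reasonable answer. The companion README shows a worked
example; here we focus on *why* the pieces look the way they do.

## The filtering model

The input is a directed reference network $G = (V, E)$ extracted from a
curated knowledge base (signaling reactions, or an enzyme graph built from
a reaction table), and a set $D \subseteq V$ of vertices mapped to genes
detected in tag-count expression data. Detection is presence-based: a gene
counts as present with at least one tag (`threshold = 1`, configurable),
because a single observed tag already certifies transcription, and
tag-count magnitudes are better used downstream as fold-changes. The
*strict* network is the induced subgraph $G[D]$; the *1-extended* network
is $G[D \cup N(D)]$ with $N(D)$ the in- and out-neighbors of $D$, and the
2-neighborhood is literally the extension applied twice. Two conditions
(normal/disease) are combined as the union by default — this minimises
fragmentation, keeps both silenced and induced genes, and the
condition-specific difference sets remain available for contrast runs.

Orphan (edgeless) vertices follow a split rule: enrichment analyses keep
them (presence of a gene is evidence regardless of connectivity), while
topological analyses drop them first (`remove_orphans()`), since removing
an edgeless vertex cannot change connectivity.

Edge labels (activation/inhibition) are carried through file I/O as
metadata but never influence any computation; parallel edges that differ
only in label count once topologically. Self-loops are rejected at
ingestion: every pair statistic used here ranges over ordered pairs of
*distinct* vertices, for which a self-loop is inert.

## The enrichment null

The naive null model for pathway over-representation — every gene equally
likely to be detected — is biologically implausible: a ubiquitously
expressed gene (beta-actin) is far more likely to show up in any library
than a specialised one. We therefore weight the null by expression breadth.
From a tissue intensity panel $A_{ij}$ (spot $i$, tissue $j$; the generator
emulates an 84-tissue GCRMA-normalised panel) each reference vertex gets an
overall expression $E_i = \sum_j A_{ij}$ summed over its mapped spots, and
a drawing probability $p_i = E_i / \sum_n E_n$ over the mappable universe.

For a pathway of size $K$ in a universe of size $N$, with filtered-set size
$n$ and observed overlap $k$, the null overlap distribution is the
univariate noncentral (Fisher) hypergeometric distribution

$$ f(x) \propto \binom{K}{x}\binom{N-K}{n-x}\,\omega^x, $$

and the one-tailed p-value is $\sum_{x \ge k} f(x)$, i.e. the total
probability of margin-preserving tables at least as extreme as observed.
The univariate distribution takes a single odds parameter, so the per-gene
weights are collapsed per pathway into the two-group mean ratio
$\omega = \overline{E}_{\text{pathway}} / \overline{E}_{\text{background}}$
(`group_odds()`); only a scalar odds defines this distribution, and the
two groups are exactly the test's margins. Setting $\omega = 1$ recovers
the classical one-sided Fisher exact test, which the package exposes as the
comparison baseline. The probability mass function is evaluated in log
space and normalised over the support, so tables as large as the full
reference ($N \approx 2000$) are handled without under/overflow.

Vertices present in the universe but absent from the intensity panel are
excluded from the universe (and reported); vertices whose panel rows are
all zero receive the smallest positive $E_i$ — a member of the universe
cannot have drawing probability zero, or the null would forbid an event
that evidently occurred.

### The extended network needs Monte Carlo

In the 1-extended network vertex inclusion is not independent: one
detected hub drags in all its neighbors. The exact test is therefore only
used for strict networks. For extended networks the null is simulated:
draw a strict-sized vertex set from the weighted urn (sequentially, without
replacement, probability proportional to $E_i$ among the remaining — the
implementation uses the exponential-key equivalent
$\mathrm{argsort}(\mathrm{Exp}(1)/E_i)$, which has identically the same
distribution and vectorises), apply the strict-to-extended mapping, record
the pathway overlap; after $T$ draws the empirical p-value is
$(1 + \#\{o_t \ge o_{\text{obs}}\})/(1 + T)$. The add-one form keeps
$p > 0$, which downstream FDR estimation requires; the plain $r/T$ form is
available behind a flag. One shared set of $T$ samples serves all pathways
of a collection, which is both faster and exactly valid (the null draw does
not depend on the pathway). $T = 10^4$ is the analysis default; empirical
p-values then carry a resolution of $10^{-4}$ and a binomial standard
error of at most $0.005$.

### Multiple testing

Only pathways overlapping the filtered set in at least `min_overlap = 2`
vertices enter the tested family — a single shared vertex is not
interpretable overlap — and q-values are computed over that family only.
The q-value estimator uses a single fixed $\lambda$ (default 0.5):
$\hat\pi_0 = \#\{p > \lambda\} / (m(1-\lambda))$ clamped to $[1/m, 1]$,
then $q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)} / j$. The spline
smoother over a $\lambda$ grid used elsewhere needs many p-values to be
stable; with $m \approx 50\text{–}140$ pathways a fixed $\lambda$ is the
robust choice, and $\lambda = 0$ reproduces Benjamini–Hochberg exactly.
Overlap counts are discrete, so the p-values are stochastically larger than
uniform and the whole procedure errs conservative.

## Key-node scores

The pairwise disconnectivity index of a vertex $v$ is

$$ \mathrm{Dis}(v) = \frac{N_0(v) - N_{-v}}{N_0(v)}, $$

where $N_0(v)$ counts the ordered connected vertex pairs not involving $v$
and $N_{-v}$ the ordered connected pairs after deleting $v$. Excluding
pairs that involve $v$ itself (the *mediator* convention) isolates the
vertex' role as an intermediary; the all-pairs variant, in which pairs
through $v$ count as destroyed, is available via `pairs = "all"` since the
verbal definition ("fraction of pairs that become disconnected") admits
both readings. Reachability is recomputed per removal by BFS from every
vertex — $O(|V|(|V|+|E|))$ per removal — which is exact and practical to a
few thousand vertices (the 1800-vertex default reference takes on the
order of a minute); vertices with no incoming or no outgoing connected
pair are short-circuited to zero.

Filtering-induced changes are measured on the max-normalised scale,
$\Delta\mathrm{Dis}(v) = \mathrm{Dis}_f(v)/\max_w \mathrm{Dis}_f(w) -
\mathrm{Dis}_r(v)/\max_w \mathrm{Dis}_r(w)$, bounded in $[-1, 1]$;
normalisation is undefined (an error) when a network has no positive
score.

The bow-tie decomposition labels the largest strongly connected component
(ties broken toward the component containing the lexicographically
smallest vertex, for determinism), IN (reaches the LSCC), OUT (reachable
from it) and OTHER. A graph whose strong components are all singletons is
flagged degenerate rather than silently labelled. Tube-like vertices both
reaching and reached by the LSCC cannot exist outside it, so no separate
compartment is needed.

## Differential expression and compartment variance

Per-vertex log fold-changes aggregate tag counts over the vertex' tags,
normalise to counts per million (so library depth cancels), and compare
conditions as $\log_2((\text{cpm}_d + c)/(\text{cpm}_n + c))$ with
pseudocount $c = 0.5$. The compartment variance analysis asks whether
topological position predicts expression stability, comparing the lfc
variance across bow-tie compartments with the classical mean-centered
Levene test (log fold-changes are symmetric and moderate-tailed, the
regime where the mean-centered form is preferable to the median-centered
one). This analysis is restricted to vertices observed in *both*
conditions: a gene switched fully on or off is a categorical event whose
pseudocount ratio (≈ ±11 at typical library depth) would otherwise
dominate every compartment's variance and mask genuine differences in
fold-change variability.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults describe the study conditions: a 1800-vertex,
3900-edge reference with a planted 300-vertex strongly connected core, 137
pathways of mean size 48, an 84-tissue log-normal intensity panel, and
presence-based detection at base rate 0.33, giving strict networks of
roughly 600 vertices. Specific choices worth knowing:

* **Correlated conditions.** Both conditions observe one latent detectable
  gene set, each with an independent 5% dropout. Paired libraries from the
  same tissue overlap almost completely; modelling detection independently
  per condition would make the symmetric difference almost half the union,
  which real paired data contradicts.
* **Core-confined cycles.** Edges with a non-core endpoint are oriented
  along a fixed random vertex order, so every directed cycle passes
  through the planted core and the LSCC remains a moderate fraction
  (~1/6) of the network, as in curated signaling networks; purely random
  orientation at this density would produce a giant LSCC of half the
  network.
* **Mild pathway locality.** Half of each pathway is grown as a connected
  neighborhood ball, half drawn network-wide (`pathway_locality = 0.5`).
  Curated pathways combine a tightly interacting cascade core with
  scattered regulators and targets. Fully ball-grown pathways would be
  almost surely covered by any 1-extension, erasing the contrast the
  extended Monte-Carlo test measures.
* **Detection-planted enrichment.** The planted pathway's members get
  their detection rate multiplied by `enrichment_factor` (capped at 1).
  Enrichment lives in presence probability, not fold-change, because
  presence is what the filtering pipeline consumes.
* **Near-Poisson counts.** Tag counts are negative binomial with
  dispersion 0.1: sampling tags within a single library is close to
  Poisson; larger dispersions describe variation across biological
  replicates, which this single-library design does not model.
* **Compartment-dependent variance.** True log2 fold-changes are
  $N(0, \sigma^2)$ with $\sigma = 0.5$, and the variance is multiplied by
  4 for IN-compartment vertices, tying topology to expression variability
  for the Levene analysis.

The generator reproduces statistical structure, not biology: pathway
identities, the actual curated topology, tissue covariance structure and
batch effects are all absent. Tests passing on synthetic data therefore
certify the *algorithms* (exactness of the tests, calibration, power
against planted signal, agreement with brute-force topology oracles), not
the biological conclusions one would draw from any particular curated
database.

## Numerical and procedural choices

* All serialization orders vertices and edges lexicographically; reruns
  with one seed are byte-identical, and each pipeline stage records its
  effective configuration in a JSON manifest.
* Randomness derives from a single seed; the per-generator streams are
  separated (`seed*10 + offset`) so that, e.g., regenerating expression
  data does not perturb the network draw.
* Replicate studies in the test suite run the Monte-Carlo test at
  $T = 2000$: rank recovery needs resolution of order $10^{-3}$, not
  precise tail estimates, and fifty replicates at $10^4$ samples would
  spend minutes measuring noise. Single-analysis runs keep $T = 10^4$.
* Degenerate inputs are surfaced, not patched: an all-zero weight matrix,
  a network without positive Dis, or fewer than two eligible compartments
  raise errors (or explicit degeneracy flags) rather than returning
  silently meaningless numbers.

## Limitations

* The noncentral test's scalar $\omega$ summarises per-gene weights by a
  group mean ratio; strongly skewed within-pathway weight distributions
  are only partially captured. The Monte-Carlo machinery could in
  principle replace the exact test entirely where this matters.
* The sequential weighted urn is one of two classical noncentral urn
  models; the alternative (conditional independent-Bernoulli) sampling
  scheme would match the Fisher noncentral form exactly. With odds near 1
  the difference is far below the test's discreteness granularity.
* `dis_index()` is exact, not approximate, and its cost grows as
  $O(|V|^2(|V|+|E|))$; beyond ~5000 vertices a sampling approximation
  would be needed.
* SIF/edge-list/GMT/TSV are the only formats read or written; GraphML,
  XGMML and database-specific dumps are out of scope.
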