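---
title: "Switch-gene discovery in signed co-expression networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switch-gene discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimnet)
```

## The problem

When a cell population moves between two states — for instance glioblastoma
stem-like cells differentiating into their adherent, serum-grown
counterparts — a subset of genes appears to *flip allegiance*: they are
differentially expressed between the states, they connect widely across the
co-expression structure rather than sitting inside one module, and they are
predominantly **anti-correlated** with their own network partners. These
"switch genes" are candidate drivers of the state transition. This package
implements the full discovery pipeline on any two-condition expression
matrix, together with a planted-structure simulator that makes every stage
testable without external data.

## Pipeline model

### 1. Differential expression

Per gene, a two-sided Welch *t*-test on the log2 values between the two
conditions, Benjamini–Hochberg adjustment across all tested genes, and a
call rule of adjusted *p* < 0.05 **and** linear fold change ≥ 3.3
(`|log2FC| ≥ log2 3.3 ≈ 1.72`). The underlying DE test is not dictated by
the network method; Welch's test is a defensible default that is valid for
both log-transformed RNA-seq and microarray intensities, and the thresholds
are plain arguments of `compute_deg()`. Genes with zero variance in both
groups are retained with *p* = 1 (equal means) so the BH universe matches
the tested universe.

### 2. Signed Pearson network

All-pairs Pearson correlation between DEG expression profiles over **all
samples pooled across both conditions**; an edge is kept when
|r| ≥ 0.8, carrying the signed r. Pooling is essential: a switch gene is
anti-correlated with a module *because* the two move in opposite directions
across the condition boundary, a signal invisible within either condition
alone. "Exceeds the threshold" is implemented as ≥ (ties kept). Zero-variance
genes have no defined correlation and are excluded with a warning; isolated
DEGs stay in the node table with degree 0 so downstream tables cover the
whole call set.

Each node's **APCC** (Average Pearson Correlation Coefficient) is the mean
signed r over its neighbours. Hubs (degree ≥ 5) are classified as

* **fight-club** — APCC < 0 (mainly anti-correlated with partners),
* **party** — APCC ≥ 0.8 (tight positive co-expression),
* **date** — the remaining hubs (moderate positive APCC).

The party/date boundary is a convention, exposed as `party_cut`; the
fight-club boundary at APCC < 0 is structural.

### 3. Heat cartography

Communities are found by k-means on the node expression profiles (genes as
points, samples as dimensions) — not on the graph — with `k = 3` by default
and an SSE-elbow rule (`k = "auto"`: maximise the second difference of the
SSE curve over k) when the cluster count should be data-driven. Restarts
(`nstart`) guard against bad initialisations and a fixed seed makes labels
reproducible.

Two topological coordinates are computed on the thresholded network:

* the **clusterphobic coefficient** `K_pi(i) = 1 − (k_in / k_i)²`, where
  `k_i` is the degree and `k_in` the links staying inside node *i*'s own
  cluster. `K_pi = 0` iff every link is internal; values near 1 mean almost
  all links leave the cluster. Note this is *not* the participation
  coefficient `1 − Σ_s (k_is/k_i)²`: that statistic measures spread across
  many modules and is bounded by `1 − 1/k` (≈ 0.67 at k = 3), which would
  make the high-K_pi region unreachable at the default cluster count; the
  clusterphobic form measures exactly what the method needs — the fraction
  of links that escape the node's own cluster.
* the **within-module degree** `Z_g(i)`: the z-score of the
  within-own-cluster degree relative to the node's cluster, with the
  *population* standard deviation (so cluster means of Z_g are exactly 0)
  and the conventions Z_g = 0 for sd = 0 and K_pi = 0 for degree 0, keeping
  every node plottable.

The (K_pi, Z_g) plane is cut into seven regions with half-open,
lower-inclusive intervals: non-hubs (Z_g < 2.5) into R1 [0, 0.05),
R2 [0.05, 0.62), R3 [0.62, 0.80), R4 [0.80, 1]; local hubs (Z_g ≥ 2.5) into
R5 [0, 0.30), R6 [0.30, 0.75), R7 [0.75, 1]. These bounds follow the
standard seven-region cartography convention and are arguments of
`assign_regions()`, echoed into the run log.

**Switch genes** are the fight-club hubs that land in R4: anti-correlated
with their partners, almost all links outside their own cluster, not local
hubs. `extract_switch_genes()` also reports each switch gene's counts of
negatively and positively correlated partners.

### 4. Degree-preserving null

`rewire_network()` runs a double-edge-swap chain — pick edges (a,b), (c,d),
rewire to (a,d), (c,b) when no self-loop or multi-edge arises — until 10
accepted swaps per edge (attempt- and accept-counts are reported; graphs
with no legal swap, e.g. a triangle, come back unchanged with a warning).
Degrees are preserved exactly, per node.

`null_switch_count()` then rebuilds the cartography per replicate on the
shuffled topology: APCC, K_pi and Z_g are recomputed over the new neighbour
sets, while the k-means clusters are kept — rewiring does not touch the
expression matrix, so re-clustering would recompute the identical labels.

Two policies exist for the rewired edge weights. `"permute"` (the default
for the null summary) redistributes the observed signed weights uniformly
over the rewired edges: the weight distribution is preserved and only the
weight–topology coupling is broken, which is precisely the feature the
switch-gene definition depends on; under it the planted structure vanishes
from the null maps. `"recompute"` derives each rewired edge's r from its
endpoints' actual profiles; it is the right tool for questions about the
correlation structure itself, but in strongly mean-shifted two-condition
data every up-block/down-block gene pair carries a pooled correlation of
substantial magnitude (the shift dominates the pooled covariance), so
random partners hand every minority-direction node a negative APCC and the
"null" reproduces block anti-correlation rather than removing switch
structure. Both policies are available on both functions.

### 5. miRNA-target enrichment

For a gene list (the switch genes) and a miRNA→target map with universe
size M: for each miRNA with K targets, N list genes inside the universe and
X of them targeted, the p-value is the upper-tail hypergeometric
probability

p = 1 − Σ_{i=0}^{X−1} C(K,i) · C(M−K, N−i) / C(M,N),

evaluated term-by-term in log space (`lchoose`) so genome-scale M does not
overflow; exactness is verified in the tests against full enumeration of
all instances with M ≤ 12 and against `phyper`. List genes outside the
universe are dropped from N, matching the definition of N as the list size
*within* the database. Significance uses the raw p < 0.05 rule; a
BH-adjusted column is reported for completeness.

### 6. Kaplan–Meier screening

Patients are split at the 50th percentile of each gene's expression — ties
go to the low group, keeping "greater than the median" literal for the high
group — and the two groups are compared with the standard 1-df log-rank
test (`survival::survdiff`; the tests check it against a textbook O−E/V
computation to 1e-10). Genes are ranked by increasing p; the reported
direction (`high_expr_worse` / `low_expr_worse`) compares the groups'
restricted mean survival up to the longest follow-up, so "unfavourable
marker" claims are checkable. No multiple-testing gate is applied to the
ranking itself (the screen ranks raw p); the BH column is informational.

## The synthetic-data generator

`synthetic_design()` fixes the study conditions used throughout the tests
and the acceptance script: 300 genes × (20 + 20) samples, three modules of
60 genes (directions alternating up/down in condition A), 15 planted switch
genes, fold-change signal 8 (log2 shift 3), within-module correlation 0.9,
switch anti-correlation −0.9, noise sd 0.5 (log2 units), base mean 6.
Sizes mirror a desk-scale version of a two-condition differentiation
experiment with a planted effect strong enough that failures indicate
implementation defects rather than sampling noise; the fold-change signal
sits comfortably above the 3.3 call threshold for the same reason.

Mechanism: one latent factor per module; a module member is
`loading · factor + noise + condition shift`, with the loading solved from
the target correlation (ρ = a²/(a² + σ²) ⟹ a = σ·sqrt(ρ/(1−ρ))). Planted
switch genes load *negatively* on module 1's factor, with the loading
solved so their correlation with module-1 members hits the target
(requiring |ρ_switch| ≤ sqrt(ρ_module)), and shift in the opposite
direction between conditions. Differential expression is an additive
log2-scale mean shift of ± log2(fold change)/2; remaining genes are pure
noise. One global seed drives fixed-offset substreams per generator, so
adding a generator call never perturbs earlier outputs.

Two numerical details make the planted structure *exact* rather than
merely expected. First, the factors are drawn standard normal and then
centered within each condition, decorrelated across modules (QR) and
standardized: a raw factor draw can carry a spurious condition-mean
difference that — being shared by all module members — would shift an
entire block's observed fold change coherently, and two raw factors can
carry a sampling correlation that pushes a whole cross-module block of
gene pairs over the edge threshold at once. Conditioning the factors
removes both block-coherent fluctuation modes at every seed. Second, the
noise scale is set so that the *mean-shift-induced* pooled correlation
between co-directional DE genes of different modules — (d/2)²/((d/2)² + v)
with d the log2 shift and v the within-condition variance, ≈ 0.47 at the
defaults — stays well below the 0.8 edge threshold; with a smaller noise
sd this unavoidable baseline approaches the threshold and the network
stops being a clean module structure.

The survival generator draws exponential event times with hazard
`baseline · HR^I(expression > median)`; censoring is independent of group —
each subject is censored with probability `censor_rate`, at a time uniform
on (0, event time), so `censor_rate = 1` censors everyone. The target-map
generator samples each miRNA's targets without replacement from the full
gene universe, with the designated miRNA's sampling weights multiplied by
`enrich_factor` on the planted genes (factor 1 recovers the exchangeable
hypergeometric null).

What the generator does **not** emulate: count-model (negative binomial)
noise, library-size and normalisation artefacts, batch effects, correlated
censoring, or the long-tailed degree distributions of genome-scale
networks. Passing tests therefore demonstrate that the pipeline's logic is
correct under its stated model, not that the thresholds (3.3, 0.8, k = 3)
are optimal for any particular real dataset.

## Worked example

```{r example, eval = FALSE}
design <- synthetic_design(seed = 1)
expr <- generate_expression(design)
res <- run_pipeline(expr)
#> stage deg: 195 DEGs of 300 genes (38% down, 62% up)
#> stage network: 195 nodes, 6315 edges; 195 hubs (120 party, 60 date, 15 fight-club)
#> stage cartography: k = 3 clusters; identified 15 switch genes out of 15 fight-club hubs

mean(design$planted_switch_ids %in% res$switch_genes)   # sensitivity: 1
```

The repository's `analysis/` directory runs the same computation as a
five-stage narrative workflow (simulate → discover → null control →
enrichment → survival screen) writing its tables under `results/`, and
`scripts/acceptance.R` recomputes the headline quantities from scratch.

## Numerical choices and degenerate inputs

* Fold-change thresholds are linear-scale; log2 fold changes are mean
  differences of log2 values (the matrix is assumed normalised and
  log-transformed upstream — no preprocessing is imposed, the declared
  scale is only recorded).
* k-means: restarts with best-SSE selection, `iter.max = 100`, seeded; the
  elbow needs SSE at k−1, k, k+1, so `k = "auto"` scans 1..k_max and picks
  from 2..k_max−1.
* Half-open, lower-inclusive region bounds put exact boundary values
  (K_pi = 0.80, Z_g = 2.5) into the higher region.
* Ties at the survival median go low; constant-expression genes and
  all-censored cohorts are skipped with a warning rather than producing
  NaN statistics.
* The rewiring chain caps attempts at 200× the accepted-swap target; dense
  or rigid graphs return partially mixed with an explicit warning.
* Degenerate DE genes (zero variance both groups): p = 1 when means are
  equal, p = 0 otherwise.

## Problem sizes

The default validation surface — 300 genes, 40 samples, ~6300 edges, 20
rewired replicates, 100 survival screens of 51 genes over 200 patients —
was chosen so the full suite re-runs in a couple of minutes on a single
core while leaving each statistical check enough replication to be
diagnostic (e.g. binomial noise on a 100-screen success fraction is ~3%).

## Known limitations

* The DE test, the party/date APCC boundary and the exact K_pi region
  bounds are field conventions rather than identities; all are exposed as
  arguments and logged per run.
* Correlations are Pearson on pooled samples; rank-based or
  condition-stratified variants are out of scope.
* The hypergeometric enrichment treats target sets as fixed and genes as
  exchangeable; no background correction for 3'UTR length or expression
  level is attempted.
* The survival screen is a marginal median-split log-rank ranking, not a
  multivariate prognostic model.
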