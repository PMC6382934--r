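---
title: "Network enrichment scores as pathway-level biomarkers: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network enrichment scores as pathway-level biomarkers: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neamarker)
```

## The problem

Molecular alterations in cancer samples are disparate: two tumors driven by
the same perturbed pathway rarely alter the same individual genes. Per-gene
biomarkers therefore replicate poorly between drug screens and between
screens and clinical cohorts. This package scores each sample's **altered
gene set** (AGS — its most deviating, mutated or copy-number-altered genes)
against **functional gene sets** (FGS — pathways, or single network genes)
through a dense global gene interaction network: what matters is not which
genes overlap, but how many network edges connect the altered genes to the
pathway. The resulting per-sample z-score matrix is a low-dimensional,
cross-platform feature space that can be correlated with drug response or
survival like any other covariate.

## The enrichment statistic

Let $n$ be the number of network edges with one endpoint in the AGS and the
other in the FGS (each edge counted once; edges internal to only one of the
two sets do not count, while an edge between two genes shared by both sets
counts once). Let $N_{AGS}$ and $N_{FGS}$ be the cumulative connectivities
(sums of member node degrees) and $N_{total}$ the total number of network
edges. Under the null in which only node degrees matter, the expected number
of connecting edges is

$$\hat n = \frac{N_{AGS}\, N_{FGS}}{2\, N_{total}}.$$

The observed count is compared with this expectation by a two-cell
goodness-of-fit statistic on connecting versus non-connecting edges,

$$\chi^2 = \frac{(n-\hat n)^2}{\hat n} + \frac{(!n - !\hat n)^2}{!\hat n},
\qquad !x = N_{total} - x,$$

with one degree of freedom (a two-cell table has one free cell; the source
method description does not state the df and we document this choice here).
The upper-tail probability $p$ of $\chi^2$ is mapped to a normal score and
the sign is coerced negative when the pair is *depleted* ($n < \hat n$):

$$Z = \operatorname{sign}(n - \hat n)\; \Phi^{-1}(1 - p/2).$$

Halving $p$ makes the mapping exactly $\operatorname{sign}(n-\hat n)
\sqrt{\chi^2}$, sends $\chi^2 = 0$ to $Z = 0$ rather than $-\infty$, and
preserves the sign semantics. The literal one-tailed reading
$\Phi^{-1}(1-p)$ is available via `mapping = "onetailed"` (its magnitude is
clamped at zero where the tail probability exceeds one half). $|Z|$ is
capped at 40 (configurable), computed through log-space tail probabilities
so extreme enrichments stay finite, ordered and accurate.

When an AGS has no edge at all to a single-gene FGS — the common case in
gene-node-level scoring (GNEA) — the deviation reduces to $-\hat n$, so the
score is more negative for better-connected nodes: a hub you fail to touch
is stronger evidence of depletion than an untouched leaf.

Two points are deliberate and documented rather than resolved:
the formula double-uses shared connectivity when AGS and FGS overlap
heavily (we implement it as printed), and no multiple-testing adjustment
happens inside scoring — adjustment (always Benjamini–Hochberg unless
stated) belongs to the downstream consumers.

## AGS construction

From a genes × samples matrix, per-gene cohort standardization uses the
one-sample z-score with the sample standard deviation ($n-1$ denominator;
the choice of denominator is ours). Alterations in either direction count,
so selection is on $|z|$ and p-values are two-sided normal. Classes:

* `top.200` / `top.400` — fixed-size sets of the most deviating genes;
  ties at the cutoff break lexicographically so output is byte-stable.
* `significant` — genes with BH-adjusted two-sided p below 0.05 within the
  sample; variable size.
* `significant.filtered.mini` / `.maxi` — members of `significant`
  additionally required to be network-enriched (single-gene NEA, FDR 0.05)
  toward a cancer pathway set (mini) or any of a signaling collection
  (maxi), or toward the same sample's mutation set. The BH family is all
  member × filter tests within the sample (configurable in principle to
  per-family; within-sample pooling is the default because the stated
  threshold is a single per-sample FDR).
* `mutations.mgs` — mutated genes enriched toward the cancer set or toward
  the sample's other mutated genes; the gene under test is excluded from
  its own companion set so its own edges cannot inflate the score.
* `combined` — per-sample union across platform-specific collections,
  restricted to shared samples.

Genes absent from the network cannot pass a network filter and are dropped
from filtered classes; in plain connectivity sums they contribute zero and
are reported through the warning channel.

## Baselines

ORA uses Fisher's exact test on the 2×2 membership table over a caller-set
universe (the network node set when comparing against network scores), with
the conditional-MLE odds ratio and the reported score
$\ln(\text{OR} + 0.1)$, so zero overlap maps to $\ln(0.1)\approx-2.30$.

Single-sample GSEA computes only the core enrichment score — the extremum
of the weighted Kolmogorov–Smirnov running sum — under two ranking
conventions: `ssGSEA` (by $|$expression$|$; constitutively high genes rank
top everywhere) and `ZGSEA` (by $|$one-sample z$|$, which restores sample
specificity). The hit increment is $w^{\alpha}/\sum_{hits} w^{\alpha}$ with
$\alpha = 1$ by default ($\alpha = 0$ gives the unweighted statistic). The
miss decrement is $1/N$ by default (`missWeight = "uniform"`); the variant
$1/(N - N_{hits})$, under which the running sum ends at zero, is exposed as
`missWeight = "complement"`. With the uniform step a set containing only
the bottom gene of a 4-gene list scores $-(N-1)/N = -0.75$; a set holding
the top gene scores $+1$. A set covering the whole list scores 1 by
convention (there are no misses).

## Drug-sensitivity association

Continuous features use Spearman rank correlation (t-approximation for
$n > 10$, exact enumeration below), pairwise-complete over missing values,
BH-adjusted per feature family; binary mutation features use a two-level
one-way ANOVA. Every screen carries an explicit orientation flag (whether
larger response values mean more sensitivity — screens genuinely disagree
on this), and cross-screen comparisons harmonize orientation before
correlating the two screens' per-feature association vectors. Summaries:
the fraction of adjusted p-values below a cutoff, fractions of
cross-screen correlations above thresholds (defaults 0.15/0.30/0.45/0.60/
0.75; only the two highest are prescribed by the source analysis, the rest
are configurable defaults), counts of "practically usable" correlates
(both sides $p < 0.001$, $|\rho| > 0.2$, concordant sign — the concordance
requirement is our operationalization and can be disabled; percentages are
half-up rounded to one decimal), and a permutation true discovery rate:
with $C$ matched pairs significant on both sides and $C^*_k$ the counts
after shuffling the feature pairing,
$\mathrm{TDR} = \max(0, (C - \overline{C^*})/C)$. The exact permutation
scheme behind the original summary is under-specified; we permute the
feature pairing and expose a value-shuffling variant, which is equivalent
when only p-values are available.

## The synthetic-data module

Everything above is testable offline because the generators define the
study conditions with known ground truth:

* **Networks**: Erdős–Rényi or preferential-attachment, connected and
  simple, at the desk-scale default of 500 nodes and mean degree 20
  (about 5,000 edges). The calibration and recovery fixtures use the
  Erdős–Rényi model: the planting weight below is proportional to raw
  edge counts toward the FGS, which under heavy-tailed degrees is
  dominated by hubs — precisely the signal the connectivity-normalized
  null is designed to discount — so preferential-attachment fixtures
  attenuate planted contrasts by construction rather than by any defect
  of the statistic. The preferential model remains available for
  degree-distribution realism.
* **Planted enrichment**: an AGS drawn with weight
  $1 + \text{bias} \times \text{edges-to-FGS}$; bias 0 is the
  exchangeable null, bias 5 with AGS size 30 / FGS size 40 is the
  standard planted contrast.
* **Omics**: i.i.d. standard normal background, planted genes shifted by
  `effectSize` sd in a random direction (default 4–6 in the recovery
  fixtures); mutations are Bernoulli background plus planted drivers.
* **Drug response**: $S = \beta F + \varepsilon$ with
  $\varepsilon \sim N(0, \sigma)$; the defaults $\beta = 2$, $\sigma = 1$
  on a Uniform(0,1) activity give a population Spearman correlation near
  0.5, a realistic effect size for a true pharmacogenomic correlate.
* **Two-screen studies** (`simDrugStudy`): a shared cell-line panel with
  a latent per-sample pathway activity; each active sample alters
  *different* FGS-proximal genes (weight $1 + 8\,a \times$ edges-to-FGS),
  while each screen re-measures expression and response with independent
  noise. This reproduces the disparate-genes / confluent-pathway
  structure that makes per-gene correlates fragile and pathway scores
  stable.
* **Rewiring oracle** (`rewiringNullZ`): degree-preserving double-edge
  swaps (at least 5 swap attempts per edge per replicate, at least 50
  replicates) give an empirical null for the connecting-edge count. The
  degree-preserving swap was chosen as the oracle because the analytic
  expectation conditions on node connectivities; a label-permutation
  null would test a different hypothesis.

Every generator takes an explicit integer seed and restores the caller's
RNG state, so all draws are pure functions of (arguments, seed); composite
generators derive per-step sub-seeds by fixed offsets, so adding a step
never perturbs unrelated draws.

What the generators do **not** emulate: correlated co-expression
structure, copy-number segment geometry, mutation signatures, batch
effects, or realistic pathway overlap. Passing the recovery and
robustness suites therefore demonstrates correctness of the statistics
and the claimed orderings *under the stated generative model*, not
performance on any real cohort.

## Numerical choices and degenerate inputs

* Tail probabilities in log-space; $|Z|$ capped at 40; the mapping
  identity $Z^2 = \chi^2$ holds to $10^{-12}$ over $\chi^2 \in [0, 1600]$.
* $\hat n = 0$ (a set with zero connectivity after intersection with the
  network) yields a flagged $Z = 0$ cell, never an error, so matrix jobs
  complete; both sets entirely absent from the network is an error.
* Ties everywhere break lexicographically on the gene symbol; reruns are
  byte-identical.
* Self-loops are dropped at network load (the degree accounting assumes
  simple edges) and counted in the log; duplicate edges collapse; extra
  edge-list columns are ignored (the statistic uses only counts). Whether
  the curated source networks contained self-interactions is unknowable
  from their descriptions; dropping-and-logging is the conservative
  reading.
* Constant cohort rows get undefined z and leave rankings; constant
  features are flagged `NA` and excluded from BH families.

## Problem sizes used by the test and verification suites

The suites run on one CPU in a few minutes: the 500-node / mean-degree-20
fixture for scoring and recovery; 100 (AGS, FGS) pairs × 100 rewired
replicates for the null-model agreement check; $10^5$ simulated tests for
p-value calibration; and a 10-batch × 3-drug × 100-sample two-screen
benchmark (300-node networks, 15 FGS) for the robustness ordering. These
sizes were chosen as the smallest at which the checked quantities are
statistically stable across seeds.

## Worked example

```{r example}
net <- simNetwork(500, meanDegree = 20, model = "erdos", seed = 1)
fgs <- plantFgs(net, 40, seed = 2)
ags <- simEnrichedAgs(net, fgs, 30, bias = 5, seed = 3)
neaScore(net, ags, fgs)
```

```{r benchmark, eval = FALSE}
# the cross-screen robustness benchmark (about 20 s)
bench <- crossScreenBenchmark(nBatches = 10, seed = 31000)
colMeans(bench[, -1])
```

## Known limitations

* The scoring loop is plain R over pre-indexed logical vectors; it is
  comfortable at $10^3$–$10^4$ nodes and $10^2$–$10^3$ sets but was not
  engineered for the $10^6$-edge scale of full curated networks.
* The analytic null conditions only on degrees; clustering and community
  structure in real networks make it anti-conservative for sets
  concentrated in one module (the rewiring oracle quantifies this on any
  given network).
* Survival modeling, elastic-net multivariate models and third-party
  enrichment engines are out of scope; the enrichment matrices this
  package emits are their intended input.
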