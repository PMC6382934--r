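# neamarker

Pathway-level biomarkers from network enrichment analysis.

Individual tumors and cell lines driven by the same perturbed pathway
rarely alter the same genes, so per-gene molecular correlates of drug
sensitivity replicate poorly between screens and almost never transfer to
clinical cohorts. `neamarker` summarizes each sample's **altered gene set**
(AGS) at the pathway level by counting the edges of a global gene
interaction network that connect the AGS to each **functional gene set**
(FGS), and comparing that count with the number expected from the member
genes' connectivities alone:

```
n̂ = N_AGS · N_FGS / (2 · N_total)

χ² = (n − n̂)²/n̂ + (!n − !n̂)²/!n̂ ,   !x = N_total − x

Z  = sign(n − n̂) · Φ⁻¹(1 − p/2) ,   p = P(χ²₁ > χ²)    ( = sign·√χ² )
```

where `N_AGS`, `N_FGS` are sums of member node degrees and `N_total` the
network's edge count. Depleted pairs get negative Z. Scoring against a
pathway collection gives **PWNEA**; scoring against every single network
gene gives **GNEA** (where a zero-edge pair scores `−n̂`, penalizing
untouched hubs more than untouched leaves). The per-sample Z matrices are
low-dimensional, cross-platform features for downstream association with
drug response.

The package also provides: construction of all standard AGS classes from
omics matrices (`top.N`, `significant`, network-filtered `mini`/`maxi`,
`mutations.mgs`, multi-platform `combined`); ORA and single-sample GSEA
baselines (`ssGSEA`/`ZGSEA` rankings, core enrichment score);
drug-sensitivity association statistics with screen-orientation handling,
cross-screen consistency, usable-correlate counting and a permutation true
discovery rate; and a synthetic-data module (networks, planted gene sets,
omics and mutation matrices, linear drug response `S = βF + ε`, and a
degree-preserving rewiring null oracle) so the whole pipeline runs and is
tested without any download.

## Worked example

```r
library(neamarker)

net <- simNetwork(500, meanDegree = 20, model = "erdos", seed = 1)
net
#> GeneNetwork with 500 nodes and 5000 edges
#>   degree: min 6 | median 20 | max 35

fgs <- plantFgs(net, 40, seed = 2)                       # a 40-gene pathway
ags <- simEnrichedAgs(net, fgs, 30, bias = 5, seed = 3)  # planted enrichment
neaScore(net, ags, fgs)
#> NEAResult AGS vs FGS: n_obs = 71, n_exp = 44.101, z = 4.068
```

71 edges connect the planted AGS to the pathway where 44.1 were expected
from the degrees alone — a signed z of +4.07, far outside the null: across
100 unbiased AGS draws of the same size the z-scores center on zero
(median −0.01, range −2.8…+2.6). The analytic score agrees with the
empirical degree-preserving rewiring null:

```r
rewiringNullZ(net, ags, fgs, nReps = 100, seed = 5)$z
#> [1] 5.38
```

From omics data, the full path to features is
`buildTopN()`/`buildSignificant()` → `pwnea()`/`gnea()` →
`associateContinuous()` → `crossScreenConsistency()`/`permutationTdr()`;
`crossScreenBenchmark()` runs that pipeline end-to-end on simulated
two-screen studies. A command-line front end for the common steps is
installed as `exec/neamarker` (subcommands `network-stats`, `nea`, `ags`,
`ora`, `gsea`, `associate`, `simulate`).

See the methods vignette (`vignettes/neamarker-methods.Rmd`) for the
model, its assumptions, parameter defaults and design decisions.

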