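# netcurv

Geometric network analysis of tumour copy-number profiles. netcurv places
gene-level copy-number alterations (CNAs) as node weights on a fixed
protein–protein interaction topology, computes Ollivier–Ricci curvature on
every interaction, contracts it to per-gene and per-sample summaries, and
uses those summaries to stratify patient survival and to rank genes by
between-group curvature change.

The package is aimed at analysts working with copy-number-driven cancers —
where single-gene markers are weak and the signal lives in how amplified and
deleted genes sit *together* on the interaction network — and at
methodologists who want an exactly solved, fully testable reference
implementation of network curvature on weighted graphs.

## The method in brief

For a sample with integer copy numbers $x_j$, each gene gets weight
$w_j = x_j + 1$ on the shared topology $G = (V, E)$ (the largest connected
component of the interaction network restricted to genes with data). The
mass-action Markov chain

$$p_{jk} = \frac{w_k}{\sum_{l\sim j} w_l} \;(j \sim k), \qquad
\pi_j \propto w_j \sum_{j\sim k} w_k$$

defines one-step neighbourhood measures $\mu_j$ and a weighted hop metric
with edge lengths $1/w_{uv}$, $w_{uv} = (p_{uv}+p_{vu})/2$. Edge curvature
compares exact optimal transport between neighbourhood measures to the
ground distance,

$$\kappa_{OR}(j,k) = 1 - \frac{W_1(\mu_j, \mu_k)}{d_{jk}},$$

and is contracted to genes and to the network:
$\kappa_j = \pi_j \sum_{j \sim k}\kappa_{OR}(j,k)$,
$\kappa_G = \sum_j \kappa_j$. Low total curvature — depleted feedback
redundancy — is the risk signal. $W_1$ is solved exactly (successive
shortest augmenting paths with node potentials, no entropic approximation)
and is verified in the test suite against an independent dense-LP oracle.

Downstream: quantile stratification of $\kappa_G$ (default 25th
percentile), Kaplan–Meier / log-rank comparison, maximally selected
cutpoints (naive p, labelled exploratory), comparator genomic features
(TMB, FGA, LST), and ranked gene lists by $\Delta\kappa$ between sample
groups or against the unweighted reference topology.

## Worked example

Everything runs on simulated cohorts, so the example is fully
reproducible. `simulate_cohort()` draws a connected interaction topology,
clustered integer copy numbers, computes curvature, and couples exponential
survival to total curvature (low curvature → higher hazard):

```r
library(netcurv)
library(dplyr)

cfg <- sim_config(n_genes = 60, n_samples = 45, seed = 11)
cohort <- simulate_cohort(cfg)

cohort$topology
#> <cn_topology> 60 genes, 166 interactions, mean degree 5.53

cohort$profiles[["S001"]]
#> <curvature_profile> sample S001: 60 genes, 166 edges, total curvature -1.37911

sp <- percentile_split(rename(cohort$totals, value = total_kappa))
#> percentile split at q = 0.25 (cutoff -1.81287): 12 low, 33 high

joined <- left_join(as_tibble(sp), cohort$clinical, by = "sample")
logrank_test(joined)
#> Log-rank test: chisq = 19.84 on 1 df, p = 8.4206e-06 (n = 12 vs 33)

delta <- delta_scalar_curvature(cohort$profiles,
                                sp$sample[sp$group == "low"],
                                sp$sample[sp$group == "high"])
top_k_ranking(delta, k = 3)
#> # A tibble: 6 × 4
#>    rank gene    delta direction
#>   <int> <chr>   <dbl> <chr>
#> 1     1 G0003  0.142  positive
#> 2     2 G0006  0.0640 positive
#> 3     3 G0002  0.0374 positive
#> 4     1 G0004 -0.708  negative
#> 5     2 G0034 -0.0202 negative
#> 6     3 G0014 -0.0108 negative
```

The split separates the cohort into 12 low- and 33 high-curvature samples;
the log-rank p-value says the low-curvature arm dies faster (that is the
coupling the generator injects, and the pipeline recovers it). The ranked
genes are those whose local feedback connectivity differs most between the
arms — on real data this list is the candidate-biomarker output.

The same analysis runs from files (PPI edge list, CN matrix or SEG +
gene-model BED, clinical TSV) via `run_pipeline()`, which writes
fixed-layout TSV outputs plus a provenance manifest, or from a shell via
`exec/netcurv` (subcommands `build-network`, `curvature`, `features`,
`survival`, `rank-genes`, `simulate`, `run`).

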