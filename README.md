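# chemotaxdist

Do taxonomically closer species make chemically closer natural products?
`chemotaxdist` is an R package for chemotaxonomic analysis of natural-product
(NP) occurrence data: it embeds molecules in a Euclidean "chemical space",
computes an asymmetric percentile-based chemical distance between species,
stratifies species pairs by taxonomic distance, and tests — with one-tailed
Welch tests at pooled and per-reference-species levels — whether chemical
distance increases with evolutionary remove. It is aimed at researchers in
cheminformatics, chemical ecology and NP-guided drug discovery who work with
occurrence databases (molecule, producing species, lineage) such as Lotus.

## The statistic

Taxonomic distance is the integer rank-step distance on the six-rank ladder
species < genus < family < class < phylum < kingdom: 0 for a species against
itself, 1 for congeners, 2 for confamilial genera, 3 for families sharing a
class, and so on (6 when no rank is shared).

Chemical distance from a *current* species *I* to a *reference* species *J*
is built in three steps from molecular embeddings:

1. *d<sub>nm</sub>* — Euclidean distance between the embeddings of molecules
   *n* and *m*;
2. *d<sub>nJ</sub>* = min<sub>m ∈ J</sub> *d<sub>nm</sub>* — each molecule
   of *I* is matched to its nearest molecule in the reference set, the side
   assumed to be the more completely characterized;
3. *d<sub>IJ</sub>* = *P<sub>k</sub>*{*d<sub>nJ</sub>* : *n* ∈ *I*} — the
   *k*-th percentile (median by default) of those nearest-neighbour
   distances.

The percentile discounts both tails: zeros from metabolites shared by both
species and inflated values from gaps in the reference list. The definition
is deliberately asymmetric in *I* and *J*. Species with fewer than
`min_current` (default 15) distinct molecules are excluded as current
species, and fewer than `min_reference` (default 150) as references.

Distances are pooled by taxonomic-distance stratum and compared with Welch's
two-sample *t*-test (unpooled variances, Welch–Satterthwaite effective
degrees of freedom), one-tailed in the direction *near < far*. The same test
runs per reference species, and the fraction of references with raw
*p* < 0.01 summarizes how widely the signal holds; that fraction can be
swept over the inclusion threshold and the percentile level to check
robustness.

Any encoder can supply the chemical space: precomputed embedding matrices
from deep molecular encoders load with `load_embeddings()`, and a
deterministic hashed n-gram featurizer (`encode_hashed_ngrams()`) is built
in so the pipeline runs with no pretrained weights. A synthetic generator
(`simulate_dataset()`) produces occurrence tables whose embeddings diverge
by rank-level Brownian drift on a balanced taxonomy, plus optional
confounders (ubiquitous metabolites, horizontal-transfer-like copying,
missingness), so every stage is testable offline.

## Worked example

A clean synthetic tree (72 species: 2 classes × 3 families × 3 genera × 4
species, 20–40 molecules each in a 16-dimensional space), analysed with the
default percentile and a reference threshold suited to simulated cloud
sizes:

```r
library(chemotaxdist)
sim <- simulate_dataset(synthetic_config(seed = 1))
pd  <- pair_distances(sim$dataset, sim$table, min_reference = 20)

round(tapply(pd$distance, pd$tax_distance, median), 2)
#>     1     2     3
#>  2.66  5.38 11.28

compare_strata(pd, 1, 3)
#> [All] taxonomic distances 1 vs 3: Welch one-tailed test:
#>   t = -134, e.d.o.f. = 1690, p = 0 (n = 216 vs 1728)

pr <- per_reference_pvalues(sim$dataset, sim$table, strata_pair = c(1, 3),
                            min_reference = 20, distances = pd)
pvalue_distribution(pr$results)$fraction_significant
#> [1] 1
```

Median chemical distance rises monotonically across strata 1 → 2 → 3
(2.66 → 5.38 → 11.28), the pooled one-tailed Welch test is overwhelming
(the *p*-value underflows double precision and prints as 0), and every one
of the 72 reference species individually supports *near < far* at
*p* < 0.01 — the pattern the method is designed to detect, recovered from
data simulated under tree-structured divergence.

`run_pipeline(run_config(...))` wraps these stages and writes TSV result
tables plus a JSON manifest; `inst/cli/chemotax.R` exposes `run`,
`simulate`, `sweep` and `selfcheck` subcommands for shell use.

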