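---
title: "Chemical distance across taxonomic distance: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical distance across taxonomic distance: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemotaxdist)
```

## The question and the model

Natural-product (NP) biosynthesis is heritable: related species share
biosynthetic gene clusters and therefore tend to share, or nearly share,
metabolites. `chemotaxdist` quantifies that expectation. Species are
represented as clouds of points in a Euclidean chemical space — one point
per molecule, placed by an embedding of its structure — and the package asks
whether clouds of taxonomically closer species are chemically closer.

Taxonomic distance is the proxy for evolutionary distance: the 0-based index
of the lowest rank at which two six-rank lineages (species, genus, family,
class, phylum, kingdom) agree, requiring every higher rank to agree as well.
The higher-rank requirement matters in practice: taxonomic homonyms (the
genus *Morus* is both mulberries and gannets) would otherwise collapse
distant kingdoms to distance 1. Two lineages sharing no rank are at distance
6. The shipped analyses compare strata 1, 2 and 3 — congeners, confamilial
genera, families within a class — where occurrence data are densest;
distances above 3 are computed but not tested by default.

## The interspecies chemical distance

For a *current* species $I$ and a *reference* species $J$:

$$d_{nJ} = \min_{m \in J} \lVert x_n - x_m \rVert, \qquad
  d_{IJ} = P_k\{\, d_{nJ} : n \in I \,\}$$

The minimum is taken over the reference side only, on the assumption that
the reference species — selected for having a large recorded NP set — is
the more completely characterized, so nearest-neighbour matching against it
is the more robust aggregate. The definition is therefore asymmetric, and no
symmetrization is applied: $d(I,J)$ answers "how far is $I$'s chemistry from
what we know of $J$", which is the quantity stratified and tested.

The percentile $P_k$ (default $k = 50$, the median) is the guard against
both database artifacts the minimum is exposed to: metabolites shared by
both species contribute $d_{nJ} = 0$ and would drag a low aggregate down,
while molecules whose true analogue is missing from the reference list
contribute inflated $d_{nJ}$ and would drag a high aggregate up. Molecules
of $I$ that also occur in $J$ are kept — they are genuine shared chemistry,
they contribute exact zeros, and the percentile bounds their influence.

### The percentile dialect

Percentile conventions differ across software, and $d_{IJ}$ values are only
comparable under one convention, so it is fixed package-wide: linear
interpolation between order statistics at index $h = 1 + (n-1)k/100$
(R's `quantile()` type 7). At $k = 50$ an even-sized sample yields the mean
of the two central values, so $P_{50}\{1,2,3,4\} = 2.5$. `selfcheck()`
re-derives this dialect with independent code at every installation.

## Statistical layer

The hypothesis is directional — chemical distance increases with taxonomic
distance — so all tests are one-tailed Welch two-sample tests with unpooled
variances. The statistic, its Welch–Satterthwaite effective degrees of
freedom, and the lower-tail $p$-value are computed from the formulas
directly (see `welch_one_tailed()`); the test suite cross-checks them
against `stats::t.test()` to $10^{-10}$ and verifies the nominal type-I
rate under a simulated null. The e.d.o.f. is reported alongside every test
because with unequal group sizes and variances it, not $n_a + n_b - 2$,
calibrates the reference distribution.

Two levels of testing are provided. `compare_strata()` pools every computed
$d_{IJ}$ across reference species within a stratum, each distance weighted
equally; the resulting samples are large but not independent (distances
sharing a reference are correlated), a caveat recorded in every run
manifest. `per_reference_pvalues()` tests each reference species on its own
distances, and the fraction of references with raw $p < 0.01$ summarizes
how widely the signal holds. No multiple-testing correction is applied
anywhere: raw $p$-values are the reported quantity, and the 0.01 fraction
is a descriptive summary, not a family-wise claim.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `percentile` ($k$) | 50 | percentile level | aggregation of $\{d_{nJ}\}$ into $d_{IJ}$; 50 = median |
| `min_current` | 15 | distinct molecules | inclusion threshold for current species |
| `min_reference` | 150 | distinct molecules | inclusion threshold for reference species |
| `alpha` | 0.01 | probability | significance threshold for the per-reference fraction |
| `dim`, `max_n` | 256, 3 | — | built-in featurizer: buckets and longest n-gram |

The thresholds exist because occurrence databases are extremely uneven —
most species have only a handful of recorded NPs, and percentiles over tiny
sets are noise. `min_reference = 150` is sized for database-scale inputs;
synthetic analyses in this package use `min_reference = 20` so that every
simulated species (20–40 molecules) can serve as a reference, exercising
the full per-reference machinery. `param_sweep()` re-runs the analysis over
grids of `min_current` or `percentile` to show how sensitive the
significance fraction is to either choice.

## The chemical space

The package is encoder-agnostic: any mapping from structures to fixed-length
real vectors defines a chemical space, and externally computed embedding
matrices (from deep molecular encoders) are loaded as delimited text with
`load_embeddings()`. External embeddings are used exactly as supplied — no
normalization is applied, since the right scaling is the encoder's business.

The built-in `encode_hashed_ngrams()` is a deterministic structural
fingerprint: character n-grams (n = 1..3) of the SMILES string hashed with
32-bit FNV-1a (offset basis 2166136261, prime 16777619, bucket = hash mod
dim) into a 256-bucket count vector, scaled to unit norm. The 32-bit FNV-1a
variant was chosen because its arithmetic stays exactly representable in
doubles, giving bit-identical embeddings on every platform. It is a
featurizer for exercising the pipeline and a neutral baseline — not a model
of chemistry, and nothing downstream depends on its quality.

## The synthetic generator

`simulate_dataset()` produces data with precisely the structure the analysis
assumes, so recovery is a meaningful end-to-end check. On a balanced
taxonomy (defaults: one kingdom and phylum, 2 classes × 3 families × 3
genera × 4 species = 72 species), each taxon's center is its parent's center
plus an isotropic Gaussian step — per-coordinate standard deviations 4.0
(class), 2.0 (family), 1.0 (genus), 0.5 (species) — and each molecule is its
species center plus within-species dispersion 0.25, in 16 dimensions with
20–40 molecules per species. Divergence is per rank step, not per unit
branch length, matching the rank-step taxonomic distance used throughout.
The sizes were chosen so strata are separated but overlapping and a full
simulate-and-test cycle runs in about a second, which is what lets the test
suite average over ten seeds routinely.

Three confounders can be layered on, each a stylized stress test rather
than a biological model:

- **Ubiquitous metabolites** (`inject_ubiquitous()`): molecules placed near
  the global centroid and shared by every species, the zero-inflation case
  the percentile is designed to discount.
- **Horizontal-transfer-like copying** (`inject_hgt()`): with some
  probability each species receives copies of `block` molecules from a donor
  at taxonomic distance ≥ 3, decoupling chemistry from taxonomy; a
  provenance log records every (recipient, donor) event.
- **Missingness** (`subsample_records()`): records dropped independently,
  emulating database incompleteness.

All randomness flows from one master seed; confounder stages draw from
seed + 1 (HGT), seed + 2 (ubiquitous) and seed + 3 (missingness), so each
stage is independently reproducible.

What the generator does **not** emulate: real embedding geometry (learned
spaces are anisotropic and clustered by chemotype, not isotropic Gaussian),
heavy-tailed species sampling (a few species with hundreds of NPs, most
with almost none), correlated missingness (whole clades under-studied), or
convergent evolution as attraction in chemical space. Passing tests on
synthetic data therefore show that the machinery detects tree-structured
divergence when present and degrades sensibly under the modeled
confounders — they do not certify effect sizes or significance levels on
any real database.

Two findings from the stress tests are worth stating because they sharpen
what the percentile does and does not guard:

- *Zero-inflation vs distance-capping.* Adding $m$ shared zeros to
  $\{d_{nJ}\}$ shifts the value at quantile $q$ by about $m(1-q)$
  order-statistic positions — so a **low** percentile is the one sensitive
  to ubiquitous metabolites (the suite verifies $k=10$ moves more than
  $k=50$), and the median's shift is bounded by a single order-statistic
  gap. But a shared metabolite also joins every *reference* cloud, where it
  caps every $d_{nJ}$ at the distance to the centroid. Under the default
  geometry some stratum-3 clean distances (~20) exceed species–centroid
  distances (~13), so those $d_{IJ}$ drop by up to ~34% — a channel no
  percentile choice mitigates, and the reason stratum-3 medians are the
  quantity to watch when a database is rich in primary metabolites.
- *Median robustness under HGT.* Copying up to half a species' own molecule
  count from a distant donor contaminates less than half of its cloud, so
  the median-based $d_{IJ}$ moves by well under one stratum gap and — at
  the generator's default separation — no reference species loses
  significance: the per-reference fraction stays at 1.0 with and without
  HGT at rate 0.5. The statistic's designed robustness means detecting HGT
  through this pipeline requires either contamination beyond the median's
  breakdown point or weaker baseline divergence.

## Numerical and degenerate-input choices

- Nearest-neighbour distances are computed via the quadratic form
  $\lVert x\rVert^2 + \lVert y\rVert^2 - 2x^\top y$ for speed; a molecule
  present in both clouds is assigned distance exactly 0 by ID, since the
  quadratic form leaves a rounding residue (~$10^{-7}$) exactly where the
  semantics require a hard zero ($d_{II} = 0$ at every $k$ is an invariant).
- Welch tests refuse, with explicit errors, samples smaller than 2 and
  degenerate data where both groups have zero variance; no $p$ of 0 or 1 is
  ever fabricated from degenerate input. (Pooled tests on strongly separated
  strata can still underflow double precision and print $p = 0$.)
- `typical_pairs()` — the molecule pairs whose $d_{nJ}$ is closest to the
  stratum mean, used to illustrate "typical" chemistry at a given
  evolutionary remove — averages over the whole stratum (all eligible
  current species pooled), and breaks ties by molecule ID for
  reproducibility. Averaging per species would be the main alternative; the
  stratum-wide mean was chosen because the stratum is the unit the
  statistics compare.
- References below `min_reference`, references with fewer than two eligible
  current species in a stratum, and species emptied by subsampling are
  reported and skipped, never silently dropped and never fatal.
- Occurrence rows with any empty mapped field are dropped and counted in
  the load report; duplicate (molecule, species) records collapse
  first-wins. When no explicit molecule-ID column exists, molecules are
  keyed on their SMILES string (canonicalized via ChemmineOB when that
  toolkit is installed, verbatim otherwise — the policy actually applied is
  recorded in the load report), so structurally identical entries merge
  across species, which is what shared-metabolite semantics require.

## Limitations

Occurrence data record presence, not abundance; absence of a molecule from
a species may mean either "not produced" or "not yet measured", and the
method inherits that censoring. Pooled tests treat correlated distances as
exchangeable. Taxonomic distance is a coarse, rank-quantized proxy — no
branch lengths, no phylogenetic uncertainty. And conclusions are only as
good as the embedding: a space in which biosynthetically related molecules
are not near neighbours will dilute any taxonomic signal regardless of the
statistics downstream.
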