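---
title: "Methods: semantic similarity, transitive prioritization, and their synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic similarity, transitive prioritization, and their synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodiff)
```

## Overview

`phenodiff` ranks candidate disease diagnoses, genes and variants for a
patient described by a set of phenotype ontology terms. The pipeline has
three stages: (1) semantic similarity between the query term set and every
disease in an ontology-annotated catalog; (2) filtering of the resulting
ranked *differential* by gene links, inheritance models, mandatory
phenotypes and manual curation; (3) transitive aggregation of the surviving
disease scores onto the genes cataloged to cause them, with variants
inheriting their gene's score. This vignette documents the model choices,
the tunable parameters, the numerical conventions, and what the synthetic
validation does and does not establish.

## The ontology and its closures

The ontology is a rooted DAG of terms joined by `is_a` edges; only `is_a`
is interpreted. Two closures drive everything: `A{t}`, the term plus all
its ancestors, and `C{t}`, the term plus all its descendants. `C{t}` is
deliberately the *full* reflexive–transitive descendant closure rather
than direct children only: the annotation count "at or below `t`" that
defines information content must include diseases annotated anywhere in
the subtree, which is the standard IC convention. Both closures are
precomputed in topological order at load time, so later scoring is pure
lookup.

Obsolete terms are kept out of the graph; using one in a query is an error
with an explicit message, while alternate ids are remapped silently with a
log line — a clinician pasting an outdated id should not get a silently
wrong answer in the first case, and should not be bothered in the second.
Files with several parentless terms are refused by default because a
forgotten root usually indicates a truncated download; an explicit flag
inserts a synthetic super-root for legitimately multi-rooted toy inputs.

## Information content, and the sign of the log

Catalog IC is `ic(t) = -log(freq(t))` with
`freq(t) = ||d{C{t}}|| / N` (natural log throughout; the base only rescales
scores and never changes a rank, but is fixed for reproducibility). We
*maximize* IC over common ancestors when matching two terms, i.e. we pick
the most informative (rarest) common ancestor. A literal reading of the
best-match expression as maximizing `log(freq)` would instead select the
most *common* ancestor — the root, almost always — and contradicts the
accompanying definition of information content as a transform of rareness;
we treat the missing minus sign as typographical.

Terms with no annotated disease at or below them have no defined IC and
are excluded from the catalog-weighted metrics (`resnik`, `ato_ic`); query
terms falling in that set are dropped with a message, and a query losing
all its terms is an error that suggests the topology-only metrics. `N`
counts only diseases that carry at least one resolvable annotation.

The topology-only weights use a reachability recursion:
`tpc(root) = 1` and, for a non-root term,
`tpc(t) = prod over parents p of [ tpc(p) / |children(p)| ]`,
evaluated in topological order; `tic = -log(tpc)`. The recursion is kept in
one small function so an alternative formulation can be swapped in. Deep
or widely branched ontologies can underflow `tpc` to numeric zero, which
would make `tic` infinite; such terms are clamped to
`2.225074e-308` (the double-precision minimum), which keeps them
essentially weightless without poisoning sums with infinities.

## Similarity metrics

* `resnik`: symmetrized best-match average. For each term on one side, the
  best match on the other side is the maximal IC over the pair's common
  ancestors; the per-side averages are themselves averaged. We read the
  printed "avg[Σ ...]" construction as the arithmetic mean over the outer
  term set: an average of a single sum would be a no-op and would make
  scores grow with annotation density.
* `ato`: the size of the intersection of ancestral closures. Every shared
  ontology node counts exactly once no matter how many term pairs recruit
  it, which is the metric's point: it cannot double-count shared ancestry.
* `ato_ic` / `ato_tic`: the same intersection with nodes contributing
  their catalog IC or topological IC instead of 1.

Scores are in metric-specific units (nats, counts, weight sums) and are
never compared across metrics. Ranking uses competition ("min") ranks for
ties with disease id as a deterministic secondary key.

## The differential and its filters

`qualify_diseases()` applies, in order: the gene-link restriction, the
exome-link restriction (disease genes intersect the variant genes), the
inheritance model, the required-phenotype filter, and curation exclusions.
Each step is a pure subset operation — relative score order is provably
unchanged — and ranks are recomputed afterwards.

The recessive model requires a homozygous variant or at least two distinct
variants in a linked gene. Phase is unknown without parental data, so two
variants establish the *possibility* of a compound heterozygote, which is
the intended semantics. Diseases whose cataloged inheritance modes are
known and exclude the requested model are removed; diseases with unknown
or "other" modes are retained (a missing annotation is not evidence of
incompatibility). Plain gene lists carry no zygosity, so inheritance
constraints other than `none` are refused for them outright rather than
silently treated as dominant.

Required phenotypes use ancestral (approximate) matching — a disease
presenting a *descendant* of the required term qualifies — mirroring how
shared phenotypes are displayed; exact-only matching is available via the
session's `viz_settings$exact_required` flag. Likewise
`shared_phenotypes()` counts a disease term as shared only when its
ancestry meets the query's closure *above* the root: every pair of terms
shares the root, so root-only overlap is noise, not signal.

## Transitive scores

`S_T(G,Q) = F(scores of qualified diseases linked to G)` with
`F ∈ {max, mean, sum}` and max as the default: one well-matched disease
should be enough to nominate its gene, and the synthetic rank-recovery
experiment below confirms max dominates mean on exactly the cases where a
gene is additionally linked to irrelevant diseases. Per gene,
`max ≥ mean` and `sum ≥ max` always hold for nonnegative scores; both are
asserted in tests. Genes with no qualified linked disease are reported in
a separate unscored section rather than given a pseudo-score, keeping the
ranked list's ranks meaningful. Within a gene, variants are ordered by
pathogenicity descending, then MAF ascending, then position — a display
convention, since the transitive model itself assigns all variants in a
gene the same score.

Two comparator scoring modes are provided: the direct term-to-gene mode
(gene scored against its own term annotations from a separate table) and
the phenotype-collapse mode (gene scored against the union of its linked
diseases' term sets as one pseudo-disease). Collapsing merges distinct
diseases' phenotypes into a chimera; keeping the diseases separate is what
enables per-disease curation.

## Map layouts

The global map converts similarities to dissimilarities by subtracting
from the maximum observed score, then embeds with classical (Torgerson)
MDS. The diagonal is forced to zero even when a metric's self-score is not
the global maximum (Resnik cross-scores can exceed some self-scores).
Coordinate columns whose eigenvalues are negative, or negligible relative
to the leading one (below `1e-9` of it), are zeroed with a warning rather
than filled with numerical noise; each column's sign is canonicalized
(first nonzero entry positive) so repeated runs are byte-identical. A
query is projected as the similarity-weighted convex combination of its
`m` nearest semantic neighbors (`m` defaults to 5), so it always lies in
their convex hull.

The radar layout encodes exact dissimilarity to the query as radius,
`r = (S(Q,Q) - S(Q,D)) / S(Q,Q)`, and approximate inter-disease structure
as angle via a 1-D MDS. Scaling the 1-D range across a full 360° would
place the two extreme diseases at the same angle; the range is compressed
to `360·(n-1)/n` degrees instead. Point size encodes rarity,
`-log10(max(maf, 1e-6))`: the floor keeps zero-frequency variants finite,
and a missing MAF renders at maximum size — absence from a population
database is best interpreted as extreme rarity. Color encodes the
pathogenicity of the most pathogenic variant in any linked gene; variants
lacking a pathogenicity score but annotated as exonic frameshifts are
assigned 1.0 at load time. Diseases without linked variants get `NA`
sentinels so a renderer can distinguish "no data" from "benign".

## Discovery

Training genes are the union of gene links over the `top_m` highest
scoring *linked* diseases; unlinked diseases do not consume slots, since
they contribute nothing to the training set. Candidates are patient
variant genes outside the training set, scored by their count of direct
PPI neighbors that are training genes and by the fraction of their total
degree those represent; the fraction is the default ordering (count as
tiebreak, then symbol). Training genes are never candidates — a known
disease gene is a prioritization hit, not a discovery. The validation
statistic compares shortest-path distances between each disease's genes
and its nearest semantic neighbor's genes against randomly paired
diseases, with unreachable pairs set to diameter + 1 (a finite "farther
than anything observed" value), summarized by a two-sample KS statistic.

## Sessions

A session is the complete analysis state — query, variants, method,
aggregation, model, required terms, exclusions, `m`, `top_n`, free-text
narrative, and opaque settings maps — serialized as JSON with a schema
tag. Unknown top-level keys survive a round-trip untouched for forward
compatibility; a schema mismatch is an error naming both versions.

## Synthetic study conditions

All validation runs on seeded synthetic data; the generator's defaults are
the study conditions and were fixed once:

* Ontology: 120 terms, depth 4, three top-level branches that are
  ancestrally disjoint (random top-down attachment below branch heads,
  with a 10 % chance of a second same-branch parent, so the graph is a
  genuine DAG). Disjoint branches give the planted-recovery experiments a
  well-defined notion of "unrelated decoy".
* Catalog: 40 diseases (50 for the class analyses), 3–6 terms each, one
  primary gene per disease with a 30 % chance of a second disease link —
  enough multi-disease genes that max and mean aggregation genuinely
  differ.
* Planted-causal cases: the query is the planted disease's term set plus
  2 noise terms from disjoint branches; 20 decoy genes carry het variants;
  the causal gene carries a hom variant (or two het variants in the
  compound-het variant of the construction). MAFs are log-uniform on
  [1e-6, 1e-2], i.e. all pre-filtered rare.
* Class analyses: 5 classes of 10 diseases; classmates share
  `class_coherence` branch-local terms. Coherence 0 is the null condition
  (signal-to-noise ≈ 1); coherence ≥ 2 is the coherent condition.
* Discovery: per-class gene cliques joined through two intermediate hub
  nodes, so same-class genes are adjacent while cross-class genes are
  several hops apart; the planted candidate is wired to 3 training genes
  and to nothing else, decoy novel genes to at most one training gene plus
  background nodes. Multi-disease gene links are disabled under this
  construction because its validation logic needs per-class gene
  adjacency.

These sizes keep the full test suite and the acceptance script in the
tens of seconds while leaving each experiment's signal far from its
threshold (rank-1 recovery is 100/100 at the 99/100 requirement; coherent
SNRs exceed 1.9 against a >1 requirement).

What the synthetic data does *not* emulate: real HPO term-frequency
distributions and annotation depth heterogeneity, noisy or partial
clinical phenotyping, genes with many diseases of similar relevance,
population structure in allele frequencies, and the literature biases of
real PPI networks. Passing these tests therefore demonstrates the
*algorithmic* correctness and the qualitative behavior of the pipeline —
not clinical-grade accuracy on real exomes, which depends on the catalog
and annotation releases used.

## Numerical conventions and degenerate inputs

* Natural logarithms everywhere; ranks are invariant to the base.
* Ties: competition ranking, disease/gene id ascending as secondary key.
* An all-zero neighbor set in query projection, a non-positive
  self-similarity in the radar, an empty catalog, or a query with no
  annotated terms under a catalog-weighted metric are errors with
  actionable messages, never silent zeros.
* `query_term_weights()` degenerates to uniform weight 1 when every query
  term has IC 0 (a query consisting solely of the root).
* Generated fixtures and all TSV/JSON writers are deterministic under a
  fixed seed, to the byte.

## Known limitations

Only `is_a` edges are used; `part_of` and cross-ontology links are out of
scope. There is no significance calibration of similarity scores (ranks,
not p-values, are the interface). The global MDS map is a lossy projection
and is provided for orientation, not diagnosis — inter-point distances at
the scale of individual differentials are not trustworthy, which is
precisely why the radar layout encodes exact dissimilarities radially.
Free-text phenotype extraction and trio/de novo analysis are outside the
package's scope.
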