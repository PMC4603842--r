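---
title: "Exposing gene-disease and genomic-overlap results as nanopublications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exposing gene-disease and genomic-overlap results as nanopublications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanopubr)
```

## The problem and the model

A differential-expression study produces tables: genes deregulated in
Huntington's disease (HD) caudate, and genes whose promoters overlap
epigenetically meaningful regions — CpG islands, or regions in an active,
weak or poised promoter chromatin state, or heterochromatin. In a journal
article those tables are prose-adjacent artifacts; as nanopublications they
become the smallest publishable units of linked data: each row is packaged
as four RDF named graphs — head, assertion, provenance, publication info —
under one stable IRI.

The two assertion templates are deliberately minimal. The
differential-expression template is an association hub: a minted node typed
as a gene–disease association (linked with altered expression) that
`refers_to` the bio2rdf gene and `refers_to` the HD disease class — three
triples, nothing else. The overlap template is a chain: gene
`associated_with` promoter, promoter typed, promoter `overlaps_with` region,
region typed as a CpG island or as a `chromatin_region` carrying `has_state`
to one of the four state classes — four or five triples. Minimality is a
design commitment, not an accident: everything contextual (coordinates,
scores, run details) belongs in provenance, so that the assertion graph
states exactly the claim a scientist would want cited.

Provenance is PROV-O restricted to a fixed allow-list (`Activity`, `Entity`,
`Agent`, `used`, `wasGeneratedBy`, `wasDerivedFrom`, `wasAssociatedWith`,
`endedAtTime`): the assertion graph `wasGeneratedBy` the workflow activity,
the activity `used` the inputs, outputs `wasGeneratedBy` it, and the
assertion `wasDerivedFrom` the outputs. Each local entity and the activity
cross-link to their counterparts in a Research Object — the aggregation
bundling workflow, data and annotations — so corpus-level queries can
traverse experimental context without fetching the pack. The RO model
itself never prints the predicates for these cross-links, so the link
predicate is configurable; the shipped default (`rdfs:seeAlso`) is an
artifact convention of this package, not an external standard. How much
provenance to include is the author's decision: everything beyond the
activity–assertion linkage is an optional field of `provenance_context()`.

Publication info carries creation time, ORCID-style author and contributor
identifiers (researcher IRIs rather than names, to sidestep author
ambiguity), version and license, with the nanopublication IRI as the
subject of every triple.

## Vocabulary choices and the ontology extension

Chromatin states had no ontology home, so the package emits a small
Sequence Ontology extension: `chromatin_region` under SO:0001411
(biological_region), `chromatin_state` under SO:0000733
(feature_attribute), the four state classes under `chromatin_state`, and
an object property `has_state` with domain `chromatin_region` and range
`chromatin_state`. Each class carries its textual definition as a
`dcterms:description` annotation so definitions stay queryable. Two small
normalizations were needed: the state-class source material spells the
parent URI of one row inconsistently (`chromantin_state`), which this
package normalizes to `chromatin_state` everywhere; and `has_state` is
documented with domain "chromatin" although no such class exists, so the
domain here is `chromatin_region`, the only chromatin-typed class defined.
States are modelled as classes (not individuals): regions are typed
`chromatin_region` and point at a state class, which keeps the value set
open for future state vocabularies.

External identifiers that the templates need but that no authoritative
source pins down — the NIFSTD Huntington's disease, promoter and CpG-island
classes, and the exact SIO identifier for "gene–disease association linked
with altered gene expression" — live in `vocabulary_config()` as
best-effort defaults, every one overridable. The `biosemantics` namespace
IRI is likewise a configuration value with a placeholder default.

## Determinism and serialization

Blank nodes are banned. Every locally defined node is minted by
`mint_iri()` from a `(kind, key)` pair under one base namespace — promoters
per (gene, promoter), regions per (gene, promoter, region kind),
association nodes and graph names per record — so the same record always
produces the same IRIs and graphs compare by plain set equality. N-Quads
output is line-sorted and duplicate-free, making it the canonical test
serialization: two corpora are equal exactly when their N-Quads bytes are.
TriG is the human-facing format; a Turtle subset is accepted on read for
fixture ontologies. The grammar is intentionally restricted (no blank
nodes, no collections, no bare numeric literals); syntax errors report line
numbers. A `content-hash` minting strategy (SHA-1) is available for opaque
identifiers but off by default, since readable slugs make corpus diffs
reviewable.

Graph names follow `nanopub_iri` + `#head/#assertion/#provenance/#pubinfo`.
No external convention fixes this scheme; fragment suffixes are the
least-surprise choice and keep all four graphs dereferenceable from the
nanopublication IRI.

## The store and the integration query

`quad_store()` is a local, in-memory named-graph store; loading is
idempotent per (source, quad). The canned queries and the five-source
drug–target integration are executed natively over the quad table;
equivalent SPARQL texts ship in `inst/queries/` for endpoint users. The
integration runs in a fixed stage order: differentially expressed genes
from the corpus; region filter over the overlap nanopubs (default: CpG
island, `any` mode; the empty kind set is rejected rather than treated as a
vacuous conjunction); GO-annotation join; human-taxon symbol join (an
explicit taxon triple, not a symbol heuristic); targets; drugs. Targets
without drugs keep a target-level row with `NA` drug columns — the faithful
reading of result tables that print targets with blank drug cells.

The GO subclass closure of the four seed processes is materialized into its
own named graph before the join, with term IRIs rewritten from the
ontology-side scheme (`.../obo/GO_0006914`) into the annotation-side scheme
(`.../go:0006914`), because the two sources use different URIs for the same
accession. Materializing first (rather than expanding the hierarchy inline)
keeps the traversal out of the join and leaves a testable intermediate.
Traversal treats subclass edges as a DAG and fails loudly on cycles; a seed
missing from the ontology fragment is kept with no descendants, with a
warning. The PSA prioritization filter is strictly `< 60` Å² (the printed
inequality), threshold configurable; rows without a PSA value are dropped
with a counted warning by default, or kept under the `keep` policy.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` emulates the *shape* of the study's result tables and
queried sources, not the biology: a gene universe in a reserved high id
range (never colliding with real NCBI ids), a differentially expressed
fraction of 0.3 (expression changes in the most affected brain region are
massive), promoter overlaps weighted 0.40/0.20/0.15/0.15/0.10 across CpG
island, active, weak, poised and heterochromatic kinds, a GO fragment of
depth 3 and branching 2 under each seed plus a decoy subtree, 35% of genes
annotated inside seed subtrees, half the genes with targets, 0–3 drugs per
target, and PSA drawn uniformly on 20–120 Å². These values were fixed once
as plausible desk-scale magnitudes; none of them is tuned. The generator
records ground truth for every downstream query as it draws, so the
headline property is end-to-end: pipeline output must equal the generator's
bookkeeping exactly, at every seed and scale.

What passing these tests shows is that the templates, assembly, store and
joins are lossless and deterministic. What they cannot show is robustness
to real-world messiness — retired gene ids, many-to-many annotation
mappings, inconsistent source vocabularies, genuine GO scale (tens of
thousands of terms) — and no statistical claim is made anywhere: the
differential-expression analysis itself is upstream of this package's
scope.

The packaged worked example (`table2_fixture()`) is the exception: it
encodes a fixed reference result set — eight genes, six targets, twelve
drugs across the four seed processes — with ABL1 annotated via the
macroautophagy child term so the closure machinery is genuinely exercised,
the three PPI genes as target-only rows, HTT as a no-annotation control,
and synthetic PSA values (the reference table prints none, so PSA behavior
is checked only as a property).

## Problem sizes and numerical choices

The shipped tests validate a 1,000-nanopublication corpus, check the
closure against an independent depth-first oracle on 100 random DAGs of up
to 200 nodes, and recover generator truth at 50, 200 and 1,000 genes —
sizes chosen to exercise every code path at interactive speed. Timestamps
are serialized as `xsd:dateTime` literals and compared lexically (one
consequence: an external parser may value-normalize `Z` to `+00:00`;
equality checks against external tools normalize this). PSA comparison is
strict inequality; region-kind and seed validation are closed-world
(unknown values are errors, not warnings). Ties never arise in ordering
because all sort keys are full IRIs or (symbol, target, drug) triples.

## Known limitations

No SPARQL engine is embedded: the shipped query texts are for external
endpoints, and the native store answers only the package's canned question
shapes. RDF conformance is deliberately partial (no blank nodes, lists, or
numeric literal shorthand). Nanopublication IRIs are not content-addressed
by default — trusty-style hashing postdates this model; the `content-hash`
policy is an approximation, not an implementation of it. The provenance
model covers one activity per corpus; multi-step workflow decomposition
(wfdesc/wfprov) and Research Object evolution are out of scope.
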