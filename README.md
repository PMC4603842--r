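# nanopubr

Results buried in supplementary tables are effectively invisible to both
search engines and other people's pipelines. `nanopubr` exposes the result
tables of a transcriptomics/epigenomics analysis — differentially expressed
genes in Huntington's disease (HD), and genes whose promoters overlap CpG
islands or chromatin-state regions — as **nanopublications**: RDF
named-graph documents in which a minimal machine-readable assertion travels
together with the workflow provenance that produced it and the citation
metadata needed to credit its authors. Once published this way, the claims
become ordinary linked data, and the package shows what that buys you: a
five-source integration query that walks from the exposed gene lists through
GO annotations and gene info into DrugBank-like drug–target records, ending
in a prioritized candidate list for a disease with no cure.

It is aimed at bioinformaticians who have a differential-expression or
genomic-overlap result table and want to publish it as interoperable RDF, and
at anyone who wants a small, fully testable quad-store pipeline for
linked-data integration experiments.

## The model

A nanopublication is four named graphs under one IRI:

* **head** — `np a Nanopublication; hasAssertion A; hasProvenance P; hasPublicationInfo I`
* **assertion** (`A`) — the claim, kept as small as possible. Two templates:
  1. *differential expression*: a minted association node, typed with the
     SIO gene–disease-association class, `refers_to` the bio2rdf gene IRI
     and `refers_to` the HD disease class — 3 triples;
  2. *genomic overlap*: `gene associated_with promoter`,
     `promoter a Promoter`, `promoter overlaps_with region`, and either
     `region a CpGIsland` (4 triples) or
     `region a chromatin_region; region has_state <state>` (5 triples).
     Over the five region kinds (CpG island; active, weak, poised promoter;
     heterochromatic) this yields five structurally distinct nanopub types.
* **provenance** (`P`) — PROV-O: the assertion graph `wasGeneratedBy` the
  workflow activity, which `used` the input entities; outputs
  `wasGeneratedBy` the activity and the assertion `wasDerivedFrom` them.
  Activity and entities cross-link to their counterparts in a Research
  Object, so the provenance acts as a lightweight proxy for the full
  workflow pack.
* **publication info** (`I`) — creation time, ORCID-style authors and
  contributors, version, license; every subject is the nanopublication IRI.

The chromatin-state vocabulary is a small Sequence Ontology extension
shipped by the package: `chromatin_region ⊑ SO:0001411` (biological_region),
`chromatin_state ⊑ SO:0000733` (feature_attribute), the four state classes
under `chromatin_state`, and the `has_state` object property.

The integration query runs in the order: DE genes → region filter →
GO-annotation join restricted to the materialized subclass closure of four
seed processes (proteasomal protein catabolic process GO:0010498, autophagy
GO:0006914, protein folding GO:0006457, protein unfolding GO:0043335) →
human-taxon symbols → targets → drugs, with a final polar-surface-area
filter (PSA < 60 Å², candidate blood–brain-barrier permeability). Blank
nodes are banned throughout: every local node is a deterministic skolem IRI,
so equal inputs give byte-identical sorted N-Quads.

## Worked example

```r
library(nanopubr)

fx <- table2_fixture()          # the packaged drug-target worked example
st <- fixture_store(fx)         # corpus + GO fragment + annotation/gene/drug slices
rows <- integrate_drug_targets(st)
rows[, c("gene_symbol", "go_label", "drug_name")]
```

```
   gene_symbol                              go_label              drug_name
1         ABL1                             autophagy Adenosine triphosphate
2         ABL1                             autophagy              Dasatinib
3         ABL1                             autophagy               Imatinib
4         ABL1                             autophagy              Nilotinib
5       FKBP1A                       protein folding           Pimecrolimus
6       FKBP1A                       protein folding              Sirolimus
7       FKBP1A                       protein folding             Tacrolimus
8         PPIA                       protein folding                   <NA>
9         PPIB                       protein folding                   <NA>
10        PPIC                       protein folding                   <NA>
11        PPIF                       protein folding              L-Proline
12       PSMD1 proteasomal protein catabolic process             Bortezomib
13      TUBA4A                       protein folding              Podofilox
14      TUBA4A                       protein folding            Vincristine
15      TUBA4A                       protein folding            cabazitaxel
```

Each row is one (gene, seed process, target, drug) join result: ABL1
(geneid 25) reaches four kinase-targeting drugs through its autophagy
annotation, PSMD1 reaches the proteasome inhibitor Bortezomib, and the
three PPI genes appear at target level only (`<NA>` drug) because their
target records carry no drugs. Prioritizing by polar surface area keeps the
one candidate below the permeability bound:

```r
filter_psa(rows)[, c("gene_symbol", "drug_name", "psa")]
#>   gene_symbol drug_name  psa
#> 1        PPIF L-Proline 49.3
```

(The PSA values in the fixture are synthetic stand-ins.) The same pipeline
runs from the shell:

```sh
nanopub fixtures table2 -o fx/
nanopub build --de fx/de.tsv --overlap fx/overlap.tsv \
        --prov run.json --meta fx/meta.yaml -o corpus.trig
nanopub validate corpus.trig         # 20 nanopublication(s), 0 invalid
nanopub integrate --fixtures fx/ --corpus corpus.trig -o rows.tsv
```

The canned queries (DE genes, region filter, closure insert, integration,
PSA filter) also ship as SPARQL text under `inst/queries/` for use against
any external endpoint.

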