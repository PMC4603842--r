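# The composed five-source drug-target integration query. Modular by
# construction — each block joins one source and can be run on its own:
#   (1) DE genes from the nanopub corpus        [local store]
#   (2) region filter over overlap nanopubs     [local store]
#   (3) GO annotations restricted to the materialized seed closure
#   (4) human-taxon gene symbols from gene info
#   (5-6) targets and drugs from the DrugBank-like source
# Equivalent of integrate_drug_targets().
PREFIX sio: <http://semanticscience.org/resource/>
PREFIX so: <http://purl.obolibrary.org/obo/so#>
PREFIX nifstd: <http://uri.neuinfo.org/nif/nifstd/>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
PREFIX vocab: <https://biosemantics.example.org/vocab/>

SELECT DISTINCT ?gene ?symbol ?goLabel ?target ?drug ?drugName WHERE {
  # (1) differentially expressed genes
  GRAPH ?a1 { ?assoc a sio:SIO_000983 ; sio:SIO_000628 ?gene .
              FILTER(STRSTARTS(STR(?gene), "http://bio2rdf.org/geneid:")) }
  # (2) promoter overlaps a CpG island
  GRAPH ?a2 { ?gene so:associated_with ?promoter .
              ?promoter so:overlaps ?region .
              ?region a nifstd:cpg_island . }
  # (3) annotated to a seed process (closure materialized beforehand)
  ?gene vocab:hasGoAnnotation ?goTerm .
  GRAPH <https://biosemantics.example.org/resource/graph/go-closure> {
    ?goTerm vocab:seedAncestor ?seed .
    ?seed rdfs:label ?goLabel .
  }
  # (4) human-taxon gene symbol
  ?gene vocab:geneSymbol ?symbol ;
        vocab:taxon <http://bio2rdf.org/taxonomy:9606> .
  # (5) drug target encoded by the gene
  ?target vocab:gene ?gene .
  # (6) drugs acting on the target (targets without drugs survive)
  OPTIONAL { ?drug vocab:target ?target ; vocab:name ?drugName . }
}
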