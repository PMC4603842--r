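# GO closure materialization — inserts every seed term and its subclass
# descendants into a local closure graph, rewritten into the annotation-side
# (bio2rdf) namespace. Equivalent of materialize_go_closure(); storing the
# mapping first keeps the traversal out of the integration join.
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
PREFIX obo: <http://purl.obolibrary.org/obo/>
PREFIX vocab: <https://biosemantics.example.org/vocab/>

INSERT {
  GRAPH <https://biosemantics.example.org/resource/graph/go-closure> {
    ?term_ann vocab:seedAncestor ?seed_ann .
  }
}
WHERE {
  VALUES ?seed { obo:GO_0010498 obo:GO_0006914 obo:GO_0006457 obo:GO_0043335 }
  ?term rdfs:subClassOf* ?seed .
  BIND(IRI(CONCAT("http://bio2rdf.org/go:",
                  STRAFTER(STR(?term), "GO_"))) AS ?term_ann)
  BIND(IRI(CONCAT("http://bio2rdf.org/go:",
                  STRAFTER(STR(?seed), "GO_"))) AS ?seed_ann)
}
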