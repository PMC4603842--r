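# Stage 1 — all differentially expressed genes exposed by the corpus.
# Endpoint-portable equivalent of query_de_genes(); the package's local
# store executes the same logic natively.
PREFIX sio: <http://semanticscience.org/resource/>

SELECT DISTINCT ?gene WHERE {
  GRAPH ?assertion {
    ?assoc a sio:SIO_000983 ;          # gene-disease association class
           sio:SIO_000628 ?gene .      # refers_to
    FILTER(STRSTARTS(STR(?gene), "http://bio2rdf.org/geneid:"))
  }
}
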