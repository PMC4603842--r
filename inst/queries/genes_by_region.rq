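# Stage 2 — genes whose promoters overlap the requested region kinds.
# Shown for the canned example: promoters associated both with a CpG island
# and a poised chromatin state. Equivalent of
# query_genes_by_region(kinds = c("cpg_island", "poised_promoter"), mode = "all").
PREFIX so: <http://purl.obolibrary.org/obo/so#>
PREFIX nifstd: <http://uri.neuinfo.org/nif/nifstd/>
PREFIX biosemantics: <https://biosemantics.example.org/resource/>

SELECT DISTINCT ?gene WHERE {
  GRAPH ?a1 {
    ?gene so:associated_with ?p1 .
    ?p1 so:overlaps ?r1 .
    ?r1 a nifstd:cpg_island .
  }
  GRAPH ?a2 {
    ?gene so:associated_with ?p2 .
    ?p2 so:overlaps ?r2 .
    ?r2 biosemantics:has_state biosemantics:poised_promoter .
  }
}
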