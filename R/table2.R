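# The packaged worked example: the drug-target integration result set for
# the four impaired processes (proteasomal protein catabolic process,
# autophagy, protein folding, protein unfolding). Eight genes with their
# targets and drugs, plus the DE/overlap nanopub inputs, the GO fragment and
# the annotation/gene-info/drug-target slices needed for every join stage to
# fire. PSA values are synthetic stand-ins (the reference result table
# prints none); HTT is included as a differentially expressed gene with no
# seed-process annotation, so it exercises the join semantics without
# producing a row.

table2_genes <- function() {
  data.frame(
    gene_id = c(25, 2280, 10105, 5478, 5479, 5480, 7277, 5707, 3064),
    symbol = c("ABL1", "FKBP1A", "PPIF", "PPIA", "PPIB", "PPIC", "TUBA4A",
               "PSMD1", "HTT"),
    # ABL1 is annotated to a child term (macroautophagy) so the closure
    # machinery is exercised; the blank-GoTerm genes carry protein-folding
    # annotations but no drugs
    go_id = c("GO:0016236", "GO:0006457", "GO:0006457", "GO:0006457",
              "GO:0006457", "GO:0006457", "GO:0006457", "GO:0010498", NA),
    target = c("http://bio2rdf.org/drugbank_target:17",
               "http://bio2rdf.org/drugbank_target:768",
               "http://bio2rdf.org/drugbank_target:2554",
               "http://bio2rdf.org/drugbank_target:1524",
               "http://bio2rdf.org/drugbank_target:4084",
               "http://bio2rdf.org/drugbank_target:4085",
               "http://bio2rdf.org/drugbank_target:2539",
               "http://bio2rdf.org/drugbank_target:515", NA),
    stringsAsFactors = FALSE)
}

table2_drugs <- function() {
  # synthetic PSA values in squared angstroms (chosen near published
  # topological PSA magnitudes, but not source data)
  data.frame(
    target = c(rep("http://bio2rdf.org/drugbank_target:17", 4),
               rep("http://bio2rdf.org/drugbank_target:768", 3),
               "http://bio2rdf.org/drugbank_target:2554",
               rep("http://bio2rdf.org/drugbank_target:2539", 3),
               "http://bio2rdf.org/drugbank_target:515"),
    drug = paste0("http://bio2rdf.org/drugbank:",
                  c("DB00171", "DB00619", "DB01254", "DB04868",
                    "DB00337", "DB00864", "DB00877",
                    "DB00172",
                    "DB00541", "DB06772", "DB01179",
                    "DB00188")),
    drug_name = c("Adenosine triphosphate", "Imatinib", "Dasatinib", "Nilotinib",
                  "Pimecrolimus", "Tacrolimus", "Sirolimus",
                  "L-Proline",
                  "Vincristine", "cabazitaxel", "Podofilox",
                  "Bortezomib"),
    psa = c(279.0, 86.3, 106.5, 97.6,
            131.5, 178.4, 195.4,
            49.3,
            171.2, 148.8, 92.7,
            124.4),
    description = c("Adenosine triphosphate (ATP)", "Imatinib", "Dasatinib",
                    "Nilotinib", "Pimecrolimus", "Tacrolimus", "Sirolimus",
                    "L-Proline", "Vincristine", "cabazitaxel", "Podofilox",
                    "Bortezomib"),
    stringsAsFactors = FALSE)
}

#' The packaged drug-target worked example
#'
#' A fully wired fixture bundle encoding the reference integration result:
#' the eight genes (plus HTT as a no-annotation control), their GO seed
#' processes (ABL1 via the macroautophagy child term), six drug targets and
#' twelve drugs. All genes are differentially expressed with CpG-island
#' promoter overlaps (ABL1 and FKBP1A additionally poised), human taxon.
#' `truth$integration` holds the expected integration rows and
#' `truth$expected_pairs` the drug-level (symbol, drug) projection.
#'
#' @param vocab A [vocabulary_config()].
#' @param fv A [fixture_vocab()].
#' @return A `"fixture_bundle"`.
#' @export
table2_fixture <- function(vocab = vocabulary_config(), fv = fixture_vocab()) {
  seeds_cfg <- go_seed_config()
  genes <- table2_genes()
  drugs <- table2_drugs()

  de_table <- genes[, c("gene_id", "symbol")]
  ov <- data.frame(gene_id = genes$gene_id, promoter_key = "p1",
                   region_kind = "cpg_island", stringsAsFactors = FALSE)
  ov <- rbind(ov, data.frame(gene_id = c(25, 2280), promoter_key = "p1",
                             region_kind = "poised_promoter",
                             stringsAsFactors = FALSE))

  labels <- c(go_label_table(), "GO:0016236" = "macroautophagy")
  edges <- data.frame(child = "GO:0016236", parent = "GO:0006914",
                      stringsAsFactors = FALSE)
  go_graph <- go_graph_from_edges(edges, labels, seeds_cfg, fv)

  ann_table <- genes[!is.na(genes$go_id), c("gene_id", "go_id")]
  annotation_graph <- annotation_graph_from_table(ann_table, seeds_cfg, vocab, fv)

  info <- data.frame(gene_id = genes$gene_id, symbol = genes$symbol,
                     taxon = "9606", stringsAsFactors = FALSE)
  geneinfo_graph <- geneinfo_graph_from_table(info, vocab, fv)

  targets <- genes[!is.na(genes$target), c("gene_id", "target")]
  drugtarget_graph <- drugtarget_graph_from_tables(targets, drugs, vocab, fv)

  ro_iri <- "https://example.org/ro/hd-epigenetics-run"
  ro_manifest <- list(
    ro_iri = ro_iri,
    aggregates = c(paste0(ro_iri, "/input/expression-matrix"),
                   paste0(ro_iri, "/input/cpg-islands-track"),
                   paste0(ro_iri, "/input/chromatin-states-track"),
                   paste0(ro_iri, "/output/de-gene-table"),
                   paste0(ro_iri, "/output/overlap-table")))
  meta <- publication_meta(
    authors = c("https://orcid.org/0000-0000-0000-0001",
                "https://orcid.org/0000-0000-0000-0002"),
    contributors = "https://orcid.org/0000-0000-0000-0003",
    created = "2014-06-01T12:00:00Z", version = "1.0")

  seed_of_term <- c("GO:0010498" = "GO:0010498", "GO:0006914" = "GO:0006914",
                    "GO:0006457" = "GO:0006457", "GO:0043335" = "GO:0043335",
                    "GO:0016236" = "GO:0006914")
  gtruth <- genes
  gtruth$de <- TRUE
  gtruth$taxon <- "9606"
  gtruth$kinds <- lapply(seq_len(nrow(genes)), function(i) {
    unique(ov$region_kind[ov$gene_id == genes$gene_id[i]])
  })
  integration <- truth_integration(gtruth, ann_table, seed_of_term,
                                   targets, drugs, vocab)
  expected_pairs <- drug_level_pairs(integration)

  structure(list(
    spec = NULL,
    de_table = de_table, overlap_table = ov,
    go_graph = go_graph, annotation_graph = annotation_graph,
    geneinfo_graph = geneinfo_graph, drugtarget_graph = drugtarget_graph,
    ro_manifest = ro_manifest, meta = meta,
    truth = list(
      de_genes = sort(vapply(de_table$gene_id, function(g) gene_iri(vocab, g),
                             character(1)), method = "radix"),
      gene_kinds = stats::setNames(
        gtruth$kinds, vapply(genes$gene_id, function(g) gene_iri(vocab, g),
                             character(1))),
      integration = integration,
      expected_pairs = expected_pairs)),
    class = "fixture_bundle")
}
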