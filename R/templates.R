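# Assertion templates. Two assertion models are exposed:
#   1. differential expression — a gene-disease association node refers_to
#      the bio2rdf gene and the Huntington's disease class (3 triples);
#   2. genomic overlap — gene associated_with a minted promoter, which
#      overlaps_with a minted region; the region is either a CpG island
#      (4 triples) or a chromatin region carrying a has_state link to one of
#      the four chromatin-state classes (5 triples).
# Assertions are kept minimal on purpose: the claim, nothing else.

#' Vocabulary configuration for the assertion templates
#'
#' Collects every external class and predicate IRI the two templates use.
#' The disease, promoter and CpG-island classes come from NIFSTD and the
#' association class / predicates from SIO and the Sequence Ontology; the
#' exact identifiers are best-effort default mappings and should be
#' overridden if your deployment has authoritative ones.
#'
#' @param hd_disease Disease class IRI (NIFSTD Huntington's disease).
#' @param assoc_class Class for a gene-disease association linked with
#'   altered gene expression (SIO).
#' @param refers_to Predicate linking the association to gene and disease
#'   (SIO "refers to").
#' @param associated_with Predicate linking gene to promoter.
#' @param overlaps_with Predicate linking promoter to region.
#' @param promoter_class Promoter class IRI (NIFSTD).
#' @param cpg_island_class CpG island class IRI (NIFSTD).
#' @param gene_pattern `sprintf` pattern with one `%s` slot producing the
#'   bio2rdf gene IRI from an NCBI gene id.
#' @param biosemantics_ns Namespace of the chromatin-state ontology extension.
#' @return An object of class `"vocabulary_config"`.
#' @export
vocabulary_config <- function(
    hd_disease = "http://uri.neuinfo.org/nif/nifstd/birnlex_12503",
    assoc_class = "http://semanticscience.org/resource/SIO_000983",
    refers_to = "http://semanticscience.org/resource/SIO_000628",
    associated_with = "http://purl.obolibrary.org/obo/so#associated_with",
    overlaps_with = "http://purl.obolibrary.org/obo/so#overlaps",
    promoter_class = "http://uri.neuinfo.org/nif/nifstd/promoter",
    cpg_island_class = "http://uri.neuinfo.org/nif/nifstd/cpg_island",
    gene_pattern = "http://bio2rdf.org/geneid:%s",
    biosemantics_ns = "https://biosemantics.example.org/resource/") {
  cfg <- list(
    hd_disease = hd_disease, assoc_class = assoc_class,
    refers_to = refers_to, associated_with = associated_with,
    overlaps_with = overlaps_with, promoter_class = promoter_class,
    cpg_island_class = cpg_island_class, gene_pattern = gene_pattern,
    biosemantics_ns = biosemantics_ns)
  for (f in setdiff(names(cfg), "gene_pattern")) {
    cfg[[f]] <- as.character(iri(cfg[[f]]))
  }
  n_slots <- lengths(regmatches(gene_pattern, gregexpr("%s", gene_pattern, fixed = TRUE)))
  if (n_slots != 1L) {
    np_error("gene_pattern must contain exactly one %s slot", "np_invalid_argument")
  }
  structure(cfg, class = "vocabulary_config")
}

gene_iri <- function(vocab, gene_id) {
  as.character(iri(sprintf(vocab$gene_pattern, format(gene_id, scientific = FALSE))))
}

#' A differentially-expressed gene record
#'
#' One row of the differential-expression result table.
#'
#' @param gene_id Positive NCBI Gene integer id.
#' @param symbol Optional gene symbol (kept for provenance/reporting only;
#'   it never enters the assertion graph).
#' @return An object of class `"de_gene_record"`.
#' @export
de_gene_record <- function(gene_id, symbol = NA_character_) {
  gene_id <- suppressWarnings(as.numeric(gene_id))
  if (length(gene_id) != 1L || is.na(gene_id) || gene_id <= 0 ||
      gene_id != trunc(gene_id)) {
    np_error("gene_id must be a positive integer", "np_validation_error")
  }
  structure(list(gene_id = gene_id, symbol = as.character(symbol)),
            class = "de_gene_record")
}

#' A gene-promoter-region overlap record
#'
#' @param gene_id Positive NCBI Gene integer id.
#' @param region_kind One of [region_kinds()]: `"cpg_island"` or a
#'   chromatin-state kind.
#' @param promoter_key String identifying the promoter within the gene (a
#'   gene can have several promoters).
#' @return An object of class `"overlap_record"`.
#' @export
overlap_record <- function(gene_id, region_kind, promoter_key = "p1") {
  gene_id <- suppressWarnings(as.numeric(gene_id))
  if (length(gene_id) != 1L || is.na(gene_id) || gene_id <= 0 ||
      gene_id != trunc(gene_id)) {
    np_error("gene_id must be a positive integer", "np_validation_error")
  }
  if (length(region_kind) != 1L || !region_kind %in% region_kinds()) {
    np_error(sprintf("unknown region_kind: '%s' (expected one of %s)",
                     region_kind, paste(region_kinds(), collapse = ", ")),
             "np_validation_error")
  }
  if (!is.character(promoter_key) || length(promoter_key) != 1L ||
      !nzchar(promoter_key)) {
    np_error("promoter_key must be a non-empty string", "np_validation_error")
  }
  structure(list(gene_id = gene_id, region_kind = region_kind,
                 promoter_key = promoter_key),
            class = "overlap_record")
}

de_key <- function(rec) sprintf("degene-%s", format(rec$gene_id, scientific = FALSE))

overlap_key <- function(rec) {
  sprintf("overlap-%s-%s-%s", format(rec$gene_id, scientific = FALSE),
          slugify(rec$promoter_key), rec$region_kind)
}

#' Build a differential-expression assertion graph
#'
#' One named graph with exactly three triples: a minted association node is
#' typed with the gene-disease-association class and linked by `refers_to`
#' to the bio2rdf gene IRI and to the Huntington's disease class.
#'
#' @param rec A [de_gene_record()].
#' @param vocab A [vocabulary_config()].
#' @param policy A [uri_policy()].
#' @return A [graph_bundle()] holding one named graph (the provisional
#'   assertion graph; [assemble()] re-homes it under the nanopublication IRI).
#' @export
build_de_assertion <- function(rec, vocab = vocabulary_config(),
                               policy = uri_policy()) {
  stopifnot(inherits(rec, "de_gene_record"), inherits(vocab, "vocabulary_config"))
  key <- de_key(rec)
  g <- as.character(mint_iri(policy, "assertion", key))
  assoc <- as.character(mint_iri(policy, "association", key))
  gene <- gene_iri(vocab, rec$gene_id)
  graph_bundle(rbind_quads(
    quad(assoc, RDF_TYPE, vocab$assoc_class, g),
    quad(assoc, vocab$refers_to, gene, g),
    quad(assoc, vocab$refers_to, vocab$hd_disease, g)
  ))
}

#' Build a genomic-overlap assertion graph
#'
#' One named graph: the gene is `associated_with` a minted promoter (typed
#' with the promoter class); the promoter `overlaps_with` a minted region.
#' For `region_kind = "cpg_island"` the region is typed with the CpG-island
#' class (4 triples); for a chromatin-state kind it is typed
#' `chromatin_region` and linked by `has_state` to the matching state class
#' (5 triples). Feeding all five region kinds yields the five structurally
#' distinct overlap nanopublication types.
#'
#' @param rec An [overlap_record()].
#' @inheritParams build_de_assertion
#' @return A [graph_bundle()] holding one named graph.
#' @export
build_overlap_assertion <- function(rec, vocab = vocabulary_config(),
                                    policy = uri_policy()) {
  stopifnot(inherits(rec, "overlap_record"), inherits(vocab, "vocabulary_config"))
  key <- overlap_key(rec)
  g <- as.character(mint_iri(policy, "assertion", key))
  gene <- gene_iri(vocab, rec$gene_id)
  gid <- format(rec$gene_id, scientific = FALSE)
  promoter <- as.character(mint_iri(policy, "promoter",
                                    sprintf("gene-%s-%s", gid, rec$promoter_key)))
  region <- as.character(mint_iri(
    policy, "region",
    sprintf("gene-%s-%s-%s", gid, rec$promoter_key, rec$region_kind)))
  quads <- rbind_quads(
    quad(gene, vocab$associated_with, promoter, g),
    quad(promoter, RDF_TYPE, vocab$promoter_class, g),
    quad(promoter, vocab$overlaps_with, region, g)
  )
  if (rec$region_kind == "cpg_island") {
    quads <- rbind_quads(quads, quad(region, RDF_TYPE, vocab$cpg_island_class, g))
  } else {
    quads <- rbind_quads(
      quads,
      quad(region, RDF_TYPE, paste0(vocab$biosemantics_ns, "chromatin_region"), g),
      quad(region, paste0(vocab$biosemantics_ns, "has_state"),
           paste0(vocab$biosemantics_ns, rec$region_kind), g)
    )
  }
  graph_bundle(quads)
}

#' Read result-table records from a TSV file
#'
#' @param path Tab-separated UTF-8 file with a header row. The `de` schema
#'   requires columns `gene_id` and `symbol`; the `overlap` schema requires
#'   `gene_id`, `promoter_key` and `region_kind`.
#' @param schema `"de"` or `"overlap"`.
#' @return A list of [de_gene_record()] or [overlap_record()] objects, one
#'   per data row (row order preserved).
#' @export
records_from_tsv <- function(path, schema = c("de", "overlap")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) np_error(sprintf("no such file: %s", path), "np_io_error")
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- if (schema == "de") c("gene_id", "symbol") else
    c("gene_id", "promoter_key", "region_kind")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    np_error(sprintf("%s table is missing column(s): %s", schema,
                     paste(missing, collapse = ", ")), "np_schema_error")
  }
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    out[[i]] <- tryCatch(
      if (schema == "de") {
        de_gene_record(df$gene_id[i], df$symbol[i])
      } else {
        overlap_record(df$gene_id[i], df$region_kind[i], df$promoter_key[i])
      },
      np_validation_error = function(e) {
        np_error(sprintf("row %d of %s: %s", i, path, conditionMessage(e)),
                 "np_validation_error")
      })
  }
  out
}
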