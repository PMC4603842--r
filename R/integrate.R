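# Drug-target integration: the five-source join. Starting from the
# differentially expressed genes in the nanopub corpus, filtered by genomic
# region overlap, the query walks GO annotations (restricted to the
# materialized seed closure), keeps human-taxon genes from the gene-info
# source, and joins targets and drugs from the DrugBank-like source. The
# fixture knowledge-graph vocabulary is artifact-defined (the upstream linked
# data sources use heterogeneous predicate vocabularies); every predicate is
# configurable here.

#' Fixture knowledge-graph vocabulary
#'
#' Predicates and named-graph IRIs of the synthetic GO-annotation, gene-info
#' and drug-target sources.
#'
#' @param ns Namespace the predicates live under.
#' @param graph_ns Namespace the fixture graph names live under.
#' @return An object of class `"fixture_vocab"`.
#' @export
fixture_vocab <- function(ns = "https://biosemantics.example.org/vocab/",
                          graph_ns = "https://biosemantics.example.org/resource/graph/") {
  structure(list(
    has_go_annotation = paste0(ns, "hasGoAnnotation"),
    gene_symbol = paste0(ns, "geneSymbol"),
    taxon = paste0(ns, "taxon"),
    human_taxon = "http://bio2rdf.org/taxonomy:9606",
    target_gene = paste0(ns, "gene"),
    drug_target = paste0(ns, "target"),
    drug_name = paste0(ns, "name"),
    drug_psa = paste0(ns, "psa"),
    drug_description = paste0(ns, "description"),
    annotation_graph = paste0(graph_ns, "go-annotations"),
    geneinfo_graph = paste0(graph_ns, "gene-info"),
    drugtarget_graph = paste0(graph_ns, "drug-targets"),
    ontology_graph = paste0(graph_ns, "go-ontology")),
    class = "fixture_vocab")
}

empty_rows <- function() {
  data.frame(gene = character(0), gene_symbol = character(0),
             go_label = character(0), target = character(0),
             drug = character(0), drug_name = character(0),
             psa = numeric(0), stringsAsFactors = FALSE)
}

require_graph <- function(q, graph_iri, stage) {
  if (!graph_iri %in% q$g) {
    np_error(sprintf("integration stage '%s': required graph not loaded: %s",
                     stage, graph_iri), "np_integration_error")
  }
}

# ---- modular sub-queries (individually invocable) -------------------------

#' Genes annotated to the seed-process closure
#'
#' @param store A [quad_store()] with the GO-annotation fixture and a
#'   materialized closure (see [materialize_go_closure()]).
#' @param fv A [fixture_vocab()].
#' @param prefixes Prefix map (locates the closure graph).
#' @return Data frame `(gene, seed, go_label)`, one row per annotated
#'   (gene, seed-ancestor) pair.
#' @export
genes_annotated_to_seeds <- function(store, fv = fixture_vocab(),
                                     prefixes = default_prefixes()) {
  q <- store_table(store)
  require_graph(q, fv$annotation_graph, "go-annotation")
  cg <- closure_graph_iri(prefixes)
  require_graph(q, cg, "go-closure")
  ann <- q[q$p == fv$has_go_annotation & q$o_type == "iri", c("s", "o")]
  names(ann) <- c("gene", "term")
  clo <- q[q$g == cg & q$p == SEED_ANCESTOR, c("s", "o")]
  names(clo) <- c("term", "seed")
  lab <- q[q$g == cg & q$p == RDFS_LABEL, c("s", "o")]
  names(lab) <- c("seed", "go_label")
  out <- merge(unique(ann), unique(clo), by = "term")
  out <- merge(out, unique(lab), by = "seed", all.x = TRUE)
  unique(out[, c("gene", "seed", "go_label")])
}

#' Human-taxon gene symbols from the gene-info source
#'
#' @inheritParams genes_annotated_to_seeds
#' @return Data frame `(gene, gene_symbol)` restricted to human-taxon genes.
#' @export
human_gene_symbols <- function(store, fv = fixture_vocab()) {
  q <- store_table(store)
  require_graph(q, fv$geneinfo_graph, "gene-info")
  sym <- q[q$p == fv$gene_symbol & q$o_type == "literal", c("s", "o")]
  names(sym) <- c("gene", "gene_symbol")
  human <- q$s[q$p == fv$taxon & q$o_type == "iri" & q$o == fv$human_taxon]
  unique(sym[sym$gene %in% human, , drop = FALSE])
}

#' Drug targets encoded by a set of genes
#'
#' @inheritParams genes_annotated_to_seeds
#' @param genes Character vector of gene IRIs.
#' @return Data frame `(gene, target)`.
#' @export
targets_for_genes <- function(store, genes, fv = fixture_vocab()) {
  q <- store_table(store)
  require_graph(q, fv$drugtarget_graph, "drug-target")
  tg <- q[q$p == fv$target_gene & q$o_type == "iri", c("s", "o")]
  names(tg) <- c("target", "gene")
  unique(tg[tg$gene %in% genes, c("gene", "target")])
}

#' Drugs acting on a set of targets
#'
#' @inheritParams genes_annotated_to_seeds
#' @param targets Character vector of target IRIs.
#' @return Data frame `(target, drug, drug_name, psa)`; `psa` is `NA` when
#'   the source prints none.
#' @export
drugs_for_targets <- function(store, targets, fv = fixture_vocab()) {
  q <- store_table(store)
  require_graph(q, fv$drugtarget_graph, "drug-target")
  dt <- q[q$p == fv$drug_target & q$o_type == "iri", c("s", "o")]
  names(dt) <- c("drug", "target")
  dt <- unique(dt[dt$target %in% targets, , drop = FALSE])
  nm <- q[q$p == fv$drug_name & q$o_type == "literal", c("s", "o")]
  names(nm) <- c("drug", "drug_name")
  psa <- q[q$p == fv$drug_psa & q$o_type == "literal", c("s", "o")]
  names(psa) <- c("drug", "psa")
  psa$psa <- suppressWarnings(as.numeric(psa$psa))
  out <- merge(dt, unique(nm), by = "drug", all.x = TRUE)
  out <- merge(out, unique(psa), by = "drug", all.x = TRUE)
  out[, c("target", "drug", "drug_name", "psa")]
}

sort_rows <- function(rows) {
  o <- order(rows$gene_symbol, rows$target, !is.na(rows$drug), rows$drug_name,
             method = "radix")
  rows <- rows[o, , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' The drug-target integration query
#'
#' Executes the staged join in order: (1) differentially expressed genes
#' from the nanopub corpus; (2) genomic-region filter over the overlap
#' nanopubs; (3) GO-annotation join restricted to the materialized seed
#' closure (materialized on the fly from the loaded ontology fragment if
#' absent); (4) human-taxon gene symbols; (5) targets; (6) drugs. Genes with
#' a target but no drug keep a target-level row with `NA` drug columns.
#'
#' @param store A [quad_store()] loaded with a nanopub corpus, the GO
#'   ontology fragment (or a materialized closure), and the annotation /
#'   gene-info / drug-target fixture graphs.
#' @param seeds A [go_seed_config()].
#' @param kinds Region kinds for the overlap filter (stage 2).
#' @param mode `"any"` or `"all"` for the region filter.
#' @param vocab A [vocabulary_config()].
#' @param fv A [fixture_vocab()].
#' @param prefixes Prefix map.
#' @return Data frame with columns `gene`, `gene_symbol`, `go_label`,
#'   `target`, `drug`, `drug_name`, `psa` — one row per (gene, seed process,
#'   target, drug).
#' @export
integrate_drug_targets <- function(store, seeds = go_seed_config(),
                                   kinds = "cpg_island", mode = "any",
                                   vocab = vocabulary_config(),
                                   fv = fixture_vocab(),
                                   prefixes = default_prefixes()) {
  q <- store_table(store)
  cg <- closure_graph_iri(prefixes)
  if (!cg %in% q$g) {
    if (!fv$ontology_graph %in% q$g) {
      np_error(paste("integration stage 'go-closure': neither a materialized",
                     "closure nor a GO ontology fragment is loaded"),
               "np_integration_error")
    }
    materialize_go_closure(store, fv$ontology_graph, seeds, prefixes)
    q <- store_table(store)
  }
  require_graph(q, fv$annotation_graph, "go-annotation")
  require_graph(q, fv$geneinfo_graph, "gene-info")
  require_graph(q, fv$drugtarget_graph, "drug-target")

  # stage 1+2: DE genes, region-filtered (single chain over the quad table)
  assoc <- q$s[q$p == RDF_TYPE & q$o_type == "iri" & q$o == vocab$assoc_class]
  refs <- q[q$p == vocab$refers_to & q$s %in% assoc & q$o_type == "iri", , drop = FALSE]
  de <- setdiff(unique(refs$o), vocab$hd_disease)
  region <- query_genes_by_region(store, kinds, mode, vocab)
  genes <- intersect(de, region)
  if (length(genes) == 0) return(empty_rows())

  # stage 3: seed-closure annotation join
  ann <- q[q$p == fv$has_go_annotation & q$o_type == "iri" & q$s %in% genes,
           c("s", "o")]
  names(ann) <- c("gene", "term")
  clo <- q[q$g == cg & q$p == SEED_ANCESTOR, c("s", "o")]
  names(clo) <- c("term", "seed")
  lab <- q[q$g == cg & q$p == RDFS_LABEL, c("s", "o")]
  names(lab) <- c("seed", "go_label")
  gs <- merge(unique(ann), unique(clo), by = "term")
  gs <- merge(gs, unique(lab), by = "seed", all.x = TRUE)
  if (nrow(gs) == 0) return(empty_rows())

  # stage 4: human-taxon gene symbols
  sym <- q[q$p == fv$gene_symbol & q$o_type == "literal", c("s", "o")]
  names(sym) <- c("gene", "gene_symbol")
  human <- q$s[q$p == fv$taxon & q$o_type == "iri" & q$o == fv$human_taxon]
  gs <- merge(gs, unique(sym[sym$gene %in% human, , drop = FALSE]), by = "gene")
  if (nrow(gs) == 0) return(empty_rows())

  # stage 5: targets
  tg <- q[q$p == fv$target_gene & q$o_type == "iri", c("s", "o")]
  names(tg) <- c("target", "gene")
  gs <- merge(gs, unique(tg), by = "gene")
  if (nrow(gs) == 0) return(empty_rows())

  # stage 6: drugs (left join: target-level rows survive without drugs)
  dt <- q[q$p == fv$drug_target & q$o_type == "iri", c("s", "o")]
  names(dt) <- c("drug", "target")
  nm <- q[q$p == fv$drug_name & q$o_type == "literal", c("s", "o")]
  names(nm) <- c("drug", "drug_name")
  psa <- q[q$p == fv$drug_psa & q$o_type == "literal", c("s", "o")]
  names(psa) <- c("drug", "psa")
  psa$psa <- suppressWarnings(as.numeric(psa$psa))
  drugs <- merge(unique(dt), unique(nm), by = "drug", all.x = TRUE)
  drugs <- merge(drugs, unique(psa), by = "drug", all.x = TRUE)
  out <- merge(gs, drugs, by = "target", all.x = TRUE)
  if (!"drug" %in% names(out)) out$drug <- NA_character_
  if (!"drug_name" %in% names(out)) out$drug_name <- NA_character_
  if (!"psa" %in% names(out)) out$psa <- NA_real_
  sort_rows(unique(out[, c("gene", "gene_symbol", "go_label", "target",
                           "drug", "drug_name", "psa")]))
}

#' Run the integration as its modular stage chain
#'
#' Same result as [integrate_drug_targets()], but composed from the
#' individually invocable sub-queries — the two routes are implemented
#' separately and tested for stage-wise equivalence.
#'
#' @inheritParams integrate_drug_targets
#' @return Same shape as [integrate_drug_targets()].
#' @export
integrate_drug_targets_staged <- function(store, seeds = go_seed_config(),
                                          kinds = "cpg_island", mode = "any",
                                          vocab = vocabulary_config(),
                                          fv = fixture_vocab(),
                                          prefixes = default_prefixes()) {
  q <- store_table(store)
  if (!closure_graph_iri(prefixes) %in% q$g) {
    if (!fv$ontology_graph %in% q$g) {
      np_error(paste("integration stage 'go-closure': neither a materialized",
                     "closure nor a GO ontology fragment is loaded"),
               "np_integration_error")
    }
    materialize_go_closure(store, fv$ontology_graph, seeds, prefixes)
  }
  de <- query_de_genes(store, vocab)
  region <- query_genes_by_region(store, kinds, mode, vocab)
  genes <- intersect(de, region)
  ann <- genes_annotated_to_seeds(store, fv, prefixes)
  ann <- ann[ann$gene %in% genes, , drop = FALSE]
  sym <- human_gene_symbols(store, fv)
  gs <- merge(ann, sym, by = "gene")
  tg <- targets_for_genes(store, unique(gs$gene), fv)
  gs <- merge(gs, tg, by = "gene")
  if (nrow(gs) == 0) return(empty_rows())
  drugs <- drugs_for_targets(store, unique(gs$target), fv)
  out <- merge(gs, drugs, by = "target", all.x = TRUE)
  sort_rows(unique(out[, c("gene", "gene_symbol", "go_label", "target",
                           "drug", "drug_name", "psa")]))
}

#' Prioritize rows by polar surface area
#'
#' Keeps rows whose drug's polar surface area (PSA, a molecular descriptor
#' in squared angstroms) is *strictly* below the threshold — low PSA
#' suggests blood-brain-barrier permeability, the relevant property for a
#' neurodegenerative-disease target.
#'
#' @param rows Integration rows (see [integrate_drug_targets()]).
#' @param threshold PSA cutoff in squared angstroms; the conventional
#'   permeability bound of 60 by default.
#' @param missing How to treat rows without a PSA value: `"drop"` (default)
#'   removes them with one warning counting the drops, `"keep"` retains them.
#' @return The filtered rows.
#' @export
filter_psa <- function(rows, threshold = 60, missing = c("drop", "keep")) {
  missing <- match.arg(missing)
  if (nrow(rows) == 0) return(rows)
  no_psa <- is.na(rows$psa)
  if (any(no_psa)) {
    np_warning(sprintf("%d row(s) lack a PSA value (%s)", sum(no_psa),
                       if (missing == "drop") "dropped" else "kept"),
               "np_missing_psa")
  }
  keep <- if (missing == "keep") (no_psa | rows$psa < threshold)
  else (!no_psa & rows$psa < threshold)
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drug-level (symbol, drug name) projection of integration rows
#'
#' Drops target-only rows (no drug) and projects to the printed columns of
#' the worked example.
#'
#' @param rows Integration rows.
#' @return Data frame `(gene_symbol, drug_name)`, unique, sorted.
#' @export
drug_level_pairs <- function(rows) {
  out <- unique(rows[!is.na(rows$drug), c("gene_symbol", "drug_name")])
  out <- out[order(out$gene_symbol, out$drug_name, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write integration rows as TSV
#'
#' Column order follows the worked example's table: gene, symbol, GO process,
#' target, drug (then drug name and PSA).
#'
#' @param rows Integration rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_integration_tsv <- function(rows, path) {
  utils::write.table(
    rows[, c("gene", "gene_symbol", "go_label", "target", "drug",
             "drug_name", "psa")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
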