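# Local quad store: named graphs from nanopub corpora and fixture datasets,
# with the canned queries executed natively over the quad table. The
# equivalent SPARQL texts ship under inst/queries/ for users running against
# an external endpoint.

#' Create an empty quad store
#'
#' A mutable store (an environment) holding quads tagged with the source they
#' were loaded from. Loading is idempotent per `(source_id, quad)`.
#'
#' @return An object of class `"quad_store"`.
#' @export
quad_store <- function() {
  e <- new.env(parent = emptyenv())
  e$quads <- cbind(empty_quads(),
                   data.frame(source = character(0), stringsAsFactors = FALSE))
  structure(e, class = "quad_store")
}

#' @export
print.quad_store <- function(x, ...) {
  cat(sprintf("<quad_store: %d quads, %d graphs, %d sources>\n",
              nrow(x$quads), length(unique(x$quads$g)),
              length(unique(x$quads$source))))
  invisible(x)
}

#' Load quads into a store
#'
#' @param store A [quad_store()].
#' @param x A [graph_bundle()], a `"nanopublication"`, or a list of
#'   nanopublications.
#' @param source_id String naming the source; reloading the same quads under
#'   the same source is a no-op.
#' @return The store, invisibly (modified in place).
#' @export
store_load <- function(store, x, source_id) {
  stopifnot(inherits(store, "quad_store"))
  if (!is.character(source_id) || length(source_id) != 1L || !nzchar(source_id)) {
    np_error("source_id must be a non-empty string", "np_invalid_argument")
  }
  bundle <- if (inherits(x, "graph_bundle")) x
  else if (inherits(x, "nanopublication")) nanopub_bundle(x)
  else if (is.list(x) && all(vapply(x, inherits, logical(1), "nanopublication"))) {
    if (length(x) == 0) graph_bundle() else do.call(bundle_union, lapply(x, nanopub_bundle))
  } else {
    np_error(sprintf("cannot load object of class %s (source '%s')",
                     paste(class(x), collapse = "/"), source_id),
             "np_invalid_argument")
  }
  if (bundle_size(bundle) == 0) return(invisible(store))
  incoming <- cbind(bundle$quads,
                    data.frame(source = source_id, stringsAsFactors = FALSE))
  store$quads <- unique(rbind(store$quads, incoming))
  rownames(store$quads) <- NULL
  invisible(store)
}

#' Load an RDF file into a store
#'
#' @param store A [quad_store()].
#' @param path TriG/N-Quads/Turtle file.
#' @param source_id Source tag; defaults to the file name.
#' @return The store, invisibly.
#' @export
store_load_file <- function(store, path, source_id = basename(path)) {
  bundle <- tryCatch(read_rdf_file(path), np_parse_error = function(e) {
    np_error(sprintf("parse error in source '%s': %s", source_id,
                     conditionMessage(e)), "np_parse_error")
  })
  store_load(store, bundle, source_id)
}

#' Number of quads in a store
#' @param store A [quad_store()].
#' @return Integer count (unique quads; a quad loaded from two sources counts
#'   once per source tag but once here).
#' @export
store_size <- function(store) nrow(unique(store$quads[, quad_cols]))

#' Named graphs present in a store
#' @param store A [quad_store()].
#' @return Character vector of graph IRIs.
#' @export
store_graphs <- function(store) sort(unique(store$quads$g), method = "radix")

store_table <- function(store) unique(store$quads[, quad_cols])

# ---- canned queries -------------------------------------------------------

#' All differentially expressed genes in the store
#'
#' Collects, from the loaded differential-expression assertion graphs, the
#' gene IRIs that an association node `refers_to` (the disease class itself
#' is excluded).
#'
#' @param store A [quad_store()].
#' @param vocab A [vocabulary_config()].
#' @return Sorted character vector of gene IRIs (set semantics).
#' @export
query_de_genes <- function(store, vocab = vocabulary_config()) {
  q <- store_table(store)
  assoc <- q$s[q$p == RDF_TYPE & q$o_type == "iri" & q$o == vocab$assoc_class]
  refs <- q[q$p == vocab$refers_to & q$s %in% assoc & q$o_type == "iri", , drop = FALSE]
  genes <- setdiff(unique(refs$o), vocab$hd_disease)
  sort(genes, method = "radix")
}

# per-gene region kinds from the overlap assertion graphs
overlap_gene_kinds <- function(q, vocab) {
  assoc <- q[q$p == vocab$associated_with & q$o_type == "iri", c("s", "o")]
  names(assoc) <- c("gene", "promoter")
  over <- q[q$p == vocab$overlaps_with & q$o_type == "iri", c("s", "o")]
  names(over) <- c("promoter", "region")
  cpg <- q$s[q$p == RDF_TYPE & q$o_type == "iri" & q$o == vocab$cpg_island_class]
  has_state <- paste0(vocab$biosemantics_ns, "has_state")
  st <- q[q$p == has_state & q$o_type == "iri", c("s", "o")]
  names(st) <- c("region", "state_class")
  st$kind <- sub(paste0("^", vocab$biosemantics_ns), "", st$state_class)
  gp <- merge(assoc, over, by = "promoter")
  gp$kind <- ifelse(gp$region %in% cpg, "cpg_island", NA_character_)
  withst <- merge(gp[is.na(gp$kind), c("gene", "region")], st, by = "region")
  rbind(gp[!is.na(gp$kind), c("gene", "kind")],
        withst[, c("gene", "kind")])
}

#' Genes whose promoters overlap given region kinds
#'
#' The canned epigenetics query: e.g. genes whose promoters are associated
#' both with a CpG island and a poised chromatin state
#' (`kinds = c("cpg_island", "poised_promoter"), mode = "all"`).
#'
#' @param store A [quad_store()].
#' @param kinds Non-empty subset of [region_kinds()].
#' @param mode `"any"` (at least one requested kind) or `"all"` (every
#'   requested kind covered).
#' @param vocab A [vocabulary_config()].
#' @return Sorted character vector of gene IRIs.
#' @export
query_genes_by_region <- function(store, kinds, mode = c("any", "all"),
                                  vocab = vocabulary_config()) {
  mode <- match.arg(mode)
  if (length(kinds) == 0) {
    np_error("kinds must be a non-empty set of region kinds", "np_validation_error")
  }
  bad <- setdiff(kinds, region_kinds())
  if (length(bad) > 0) {
    np_error(sprintf("unknown region kind(s): %s", paste(bad, collapse = ", ")),
             "np_validation_error")
  }
  gk <- overlap_gene_kinds(store_table(store), vocab)
  if (nrow(gk) == 0) return(character(0))
  per_gene <- tapply(gk$kind, gk$gene, unique, simplify = FALSE)
  hit <- if (mode == "any") {
    vapply(per_gene, function(k) length(intersect(k, kinds)) > 0, logical(1))
  } else {
    vapply(per_gene, function(k) all(kinds %in% k), logical(1))
  }
  sort(names(per_gene)[hit], method = "radix")
}

# ---- GO closure and URI mapping ------------------------------------------

#' GO seed configuration
#'
#' The four biological processes impaired in Huntington's disease that the
#' drug-target integration query starts from, plus the URI patterns of the
#' ontology side (OBO) and the annotation side (bio2rdf), which use different
#' IRIs for the same accession.
#'
#' @param seeds GO accessions (`"GO:NNNNNNN"`).
#' @param ontology_ns `sprintf` pattern of ontology-side term IRIs.
#' @param annotation_ns `sprintf` pattern of annotation-side term IRIs.
#' @return An object of class `"go_seed_config"`.
#' @export
go_seed_config <- function(
    seeds = c("GO:0010498", "GO:0006914", "GO:0006457", "GO:0043335"),
    ontology_ns = "http://purl.obolibrary.org/obo/GO_%s",
    annotation_ns = "http://bio2rdf.org/go:%s") {
  if (!all(grepl("^GO:[0-9]{7}$", seeds))) {
    np_error("seeds must be GO accessions of the form GO:NNNNNNN",
             "np_invalid_argument")
  }
  structure(list(seeds = seeds, ontology_ns = ontology_ns,
                 annotation_ns = annotation_ns),
            class = "go_seed_config")
}

go_accession <- function(go_id) sub("^GO:", "", go_id)

ns_regex <- function(pattern) {
  escaped <- gsub("([][.\\^$*+?(){}|\\\\])", "\\\\\\1", pattern, perl = TRUE)
  paste0("^", sub("%s", "([A-Za-z0-9]+)", escaped, fixed = TRUE), "$")
}

#' Rewrite a GO term IRI between namespaces
#'
#' Accession-preserving rewrite between the ontology-side and the
#' annotation-side URI schemes (e.g. `...obo/GO_0006914` to
#' `http://bio2rdf.org/go:0006914`).
#'
#' @param term Term IRI (string or [iri()]).
#' @param from_ns,to_ns `sprintf` patterns with one `%s` accession slot.
#' @return The rewritten [iri()].
#' @export
map_go_uri <- function(term, from_ns = "http://purl.obolibrary.org/obo/GO_%s",
                       to_ns = "http://bio2rdf.org/go:%s") {
  term <- as.character(term)
  m <- regmatches(term, regexec(ns_regex(from_ns), term))[[1]]
  if (length(m) < 2) {
    np_error(sprintf("IRI does not match the source namespace pattern: %s", term),
             "np_mapping_error")
  }
  iri(sprintf(to_ns, m[2]))
}

closure_graph_iri <- function(prefixes = default_prefixes()) {
  paste0(prefixes[["biosemantics"]], "graph/go-closure")
}

# artifact vocabulary for the materialized closure graph
SEED_ANCESTOR <- "https://biosemantics.example.org/vocab/seedAncestor"

#' Materialize the GO subclass closure for the seed terms
#'
#' For every seed, walks the `rdfs:subClassOf` hierarchy in the loaded GO
#' ontology fragment and inserts, into a dedicated named graph, one
#' `(term, seedAncestor, seed)` statement per descendant (seeds included,
#' reflexively) — with both term and seed rewritten into the annotation-side
#' namespace so later joins run on annotation IRIs directly. Seed labels are
#' carried over as `rdfs:label`. Storing the closure first (rather than
#' expanding it inline in the integration query) keeps the expensive
#' traversal out of the join and leaves a testable intermediate.
#'
#' @param store A [quad_store()].
#' @param go_graph_iri Named graph holding the ontology fragment; defaults to
#'   every graph in the store (the subclass edges are harvested wherever they
#'   are).
#' @param seeds A [go_seed_config()].
#' @param prefixes Prefix map (locates the closure graph IRI).
#' @return The closure [graph_bundle()] (also loaded into the store under
#'   source `"go-closure"`). A seed absent from the ontology is kept with no
#'   descendants, with a warning. A subclass cycle raises an error.
#' @export
materialize_go_closure <- function(store, go_graph_iri = NULL,
                                   seeds = go_seed_config(),
                                   prefixes = default_prefixes()) {
  q <- store_table(store)
  if (!is.null(go_graph_iri)) q <- q[q$g == go_graph_iri, , drop = FALSE]
  onto <- graph_bundle(q)
  edges <- subclass_edges(onto)
  if (subclass_has_cycle(edges)) {
    np_error("GO ontology fragment contains a subClassOf cycle", "np_cycle_error")
  }
  g <- closure_graph_iri(prefixes)
  quads <- list()
  for (seed in seeds$seeds) {
    acc <- go_accession(seed)
    seed_onto <- sprintf(seeds$ontology_ns, acc)
    seed_ann <- sprintf(seeds$annotation_ns, acc)
    terms <- withCallingHandlers(
      subclass_descendants(onto, seed_onto),
      np_missing_root = function(w) invokeRestart("muffleWarning"))
    if (length(terms) == 0) {
      np_warning(sprintf("seed %s not found in the ontology fragment; kept with no descendants",
                         seed), "np_missing_seed")
      terms <- seed_onto
    }
    for (t in terms) {
      t_ann <- as.character(map_go_uri(t, seeds$ontology_ns, seeds$annotation_ns))
      quads <- c(quads, list(quad(t_ann, SEED_ANCESTOR, seed_ann, g)))
    }
    lab <- q[q$s == seed_onto & q$p == RDFS_LABEL, , drop = FALSE]
    if (nrow(lab) > 0) {
      quads <- c(quads, list(
        quad(seed_ann, RDFS_LABEL,
             rdf_literal(lab$o[[1]],
                         language = if (!is.na(lab$o_lang[[1]])) lab$o_lang[[1]] else "en"),
             g)))
    }
  }
  closure <- graph_bundle(do.call(rbind_quads, quads), prefixes)
  store_load(store, closure, "go-closure")
  closure
}
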