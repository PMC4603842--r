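# Sequence Ontology extension for chromatin states: six classes and one
# object property. chromatin_region sits under SO biological_region
# (SO:0001411) and chromatin_state under SO feature_attribute (SO:0000733);
# the four state classes (active/weak/poised promoter, heterochromatic) are
# subclasses of chromatin_state. has_state links a chromatin region to its
# state class.

RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
RDFS_SUBCLASS <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"
RDFS_LABEL <- "http://www.w3.org/2000/01/rdf-schema#label"
RDFS_DOMAIN <- "http://www.w3.org/2000/01/rdf-schema#domain"
RDFS_RANGE <- "http://www.w3.org/2000/01/rdf-schema#range"
RDFS_SEEALSO <- "http://www.w3.org/2000/01/rdf-schema#seeAlso"
OWL_CLASS <- "http://www.w3.org/2002/07/owl#Class"
OWL_OBJECT_PROPERTY <- "http://www.w3.org/2002/07/owl#ObjectProperty"
DCTERMS_DESCRIPTION <- "http://purl.org/dc/terms/description"
XSD_DATETIME <- "http://www.w3.org/2001/XMLSchema#dateTime"
XSD_DOUBLE <- "http://www.w3.org/2001/XMLSchema#double"
XSD_INTEGER <- "http://www.w3.org/2001/XMLSchema#integer"

#' The four chromatin-state kinds
#'
#' Chromatin states are genome annotations derived from combinations of
#' histone modification marks; the promoters of deregulated genes are
#' classified as being in an active, weak or poised promoter state, or in
#' heterochromatin.
#'
#' @return Character vector of the four state kind names.
#' @export
chromatin_state_kinds <- function() {
  c("active_promoter", "weak_promoter", "poised_promoter", "heterochromatic")
}

#' The five genomic region kinds an overlap record may carry
#'
#' A gene's promoter can overlap a CpG island or a region in one of the four
#' chromatin states.
#'
#' @return Character vector of length 5.
#' @export
region_kinds <- function() c("cpg_island", chromatin_state_kinds())

extension_class_table <- function() {
  data.frame(
    name = c("chromatin_region", "chromatin_state", chromatin_state_kinds()),
    parent = c("so:SO_0001411", "so:SO_0000733",
               rep("biosemantics:chromatin_state", 4)),
    label = c("chromatin_region", "chromatin_state", chromatin_state_kinds()),
    definition = c(
      "A region of chromatin, likely to be involved in a biological process",
      paste("Annotation of chromatin states, defined by combinations of",
            "chromatin modification patterns (described in publication by",
            "Ernst et al. Nature, 2011)"),
      paste("Open chromatin region, associated with promoters,",
            "transcriptionally active, defined by the most highly observed",
            "chromatin marks: H3K4me2, H3K4me3, H3K27ac, H3K9ac"),
      paste("Open chromatin region, associated with promoters, weak",
            "transcription activity, defined by the most highly observed",
            "chromatin marks: H3K4me1, H3K4me2, H3K4me3, H3K9ac"),
      paste("Open chromatin region, associated with promoters, described as",
            "a bivalent domain that has strong signals of both active and",
            "inactive histone marks. Most highly observed histone marks:",
            "H3K27me3, H3K4me2, H3K4me3"),
      paste("Closed chromatin formation, transcriptionally inactive.",
            "It is associated with none histone marks")
    ),
    stringsAsFactors = FALSE
  )
}

ontology_graph_iri <- function(prefixes) {
  paste0(prefixes[["biosemantics"]], "ontology/chromatin-states")
}

#' Build the chromatin-state ontology extension
#'
#' Emits six class declarations (each with a label and a textual definition
#' annotation) with their subclass links into the Sequence Ontology, and the
#' `has_state` object property with domain `chromatin_region` and range
#' `chromatin_state`.
#'
#' @param prefixes Prefix map supplying at least `so`, `biosemantics`, `rdfs`,
#'   `owl` and `dcterms` (see [default_prefixes()]).
#' @return A [graph_bundle()] holding one named graph.
#' @export
build_extension_ontology <- function(prefixes = default_prefixes()) {
  g <- ontology_graph_iri(prefixes)
  bs <- prefixes[["biosemantics"]]
  tab <- extension_class_table()
  quads <- list()
  for (i in seq_len(nrow(tab))) {
    cls <- paste0(bs, tab$name[i])
    parent <- as.character(resolve_curie(tab$parent[i], prefixes))
    quads <- c(quads, list(
      quad(cls, RDF_TYPE, OWL_CLASS, g),
      quad(cls, RDFS_LABEL, rdf_literal(tab$label[i], language = "en"), g),
      quad(cls, DCTERMS_DESCRIPTION, rdf_literal(tab$definition[i], language = "en"), g),
      quad(cls, RDFS_SUBCLASS, parent, g)
    ))
  }
  has_state <- paste0(bs, "has_state")
  quads <- c(quads, list(
    quad(has_state, RDF_TYPE, OWL_OBJECT_PROPERTY, g),
    quad(has_state, RDFS_LABEL, rdf_literal("has_state", language = "en"), g),
    quad(has_state, RDFS_DOMAIN, paste0(bs, "chromatin_region"), g),
    quad(has_state, RDFS_RANGE, paste0(bs, "chromatin_state"), g)
  ))
  graph_bundle(do.call(rbind_quads, quads), prefixes)
}

#' Reflexive-transitive subclass closure beneath a root
#'
#' Follows `rdfs:subClassOf` edges downward (child-to-parent edges reversed)
#' from `root` and returns root plus all descendants.
#'
#' @param bundle A [graph_bundle()] containing subclass edges.
#' @param root Root class IRI (string or [iri()]).
#' @return Character vector of IRIs (root included, sorted). If the root does
#'   not appear in the bundle at all, the empty set with a warning.
#' @export
subclass_descendants <- function(bundle, root) {
  stopifnot(inherits(bundle, "graph_bundle"))
  root <- as.character(iri(as.character(root)))
  edges <- subclass_edges(bundle)
  known <- unique(c(edges$s, edges$o,
                    bundle$quads$s[bundle$quads$p == RDF_TYPE]))
  if (!root %in% known) {
    np_warning(sprintf("root class not present in bundle: %s", root),
               "np_missing_root")
    return(character(0))
  }
  children_of <- split(edges$s, edges$o)
  seen <- character(0)
  frontier <- root
  while (length(frontier) > 0) {
    seen <- union(seen, frontier)
    nxt <- unique(unlist(children_of[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  sort(seen, method = "radix")
}

subclass_edges <- function(bundle) {
  unique(bundle$quads[bundle$quads$p == RDFS_SUBCLASS &
                        bundle$quads$o_type == "iri", c("s", "o")])
}

# TRUE when the child->parent subclass digraph contains a directed cycle
# (Kahn's algorithm: a cycle is whatever survives repeated leaf stripping).
subclass_has_cycle <- function(edges) {
  if (nrow(edges) == 0) return(FALSE)
  repeat {
    sinks <- setdiff(edges$o, edges$s)
    keep <- !(edges$o %in% sinks)
    if (all(keep)) return(nrow(edges) > 0)
    edges <- edges[keep, , drop = FALSE]
    if (nrow(edges) == 0) return(FALSE)
  }
}
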