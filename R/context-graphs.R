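# Context graphs. The provenance graph is a compact PROV-O description of
# the workflow run that produced the assertion, acting as a proxy for a
# Research Object (RO): the activity and each input/output entity carry a
# cross-link to their counterparts inside the RO, so corpus-level queries
# can follow provenance without fetching the RO itself. The publication-info
# graph carries the citation metadata of the nanopublication proper.

PROV <- function(x) paste0("http://www.w3.org/ns/prov#", x)
DCTERMS <- function(x) paste0("http://purl.org/dc/terms/", x)

# Fixed allow-list: the only PROV terms the provenance builder may emit.
prov_allowlist <- function() {
  PROV(c("Activity", "Entity", "Agent", "used", "wasGeneratedBy",
         "wasDerivedFrom", "wasAssociatedWith", "endedAtTime"))
}

prov_entity <- function(entity, ro_entity = NULL, role = NULL, type_iri = NULL) {
  list(entity = as.character(iri(as.character(entity))),
       ro_entity = if (is.null(ro_entity) || is.na(ro_entity)) NULL else
         as.character(iri(as.character(ro_entity))),
       role = role,
       type_iri = if (is.null(type_iri)) NULL else
         as.character(iri(as.character(type_iri))))
}

#' Describe the workflow run behind an assertion
#'
#' @param workflow_activity_iri IRI of the workflow execution (the PROV
#'   activity). Required.
#' @param research_object_iri Optional IRI of the Research Object aggregating
#'   the workflow, its data and annotations.
#' @param inputs,outputs Lists of entities; each element is a list with
#'   `entity` (IRI, required) and optional `ro_entity` (counterpart IRI
#'   inside the RO), `role` (free-text label) and `type_iri` (e.g. a
#'   domain-specific process-ontology class).
#' @param agent_iri Optional IRI of the responsible agent.
#' @param execution_time Optional ISO-8601 timestamp of the run.
#' @return An object of class `"provenance_context"`.
#' @export
provenance_context <- function(workflow_activity_iri,
                               research_object_iri = NULL,
                               inputs = list(), outputs = list(),
                               agent_iri = NULL, execution_time = NULL) {
  if (missing(workflow_activity_iri) || is.null(workflow_activity_iri) ||
      (length(workflow_activity_iri) == 1 && is.na(workflow_activity_iri))) {
    np_error("workflow activity IRI is required", "np_validation_error")
  }
  canon <- function(es) lapply(es, function(e) do.call(prov_entity, e))
  if (!is.null(execution_time)) {
    parsed <- tryCatch(
      as.POSIXct(sub("Z$", "", execution_time), tz = "UTC",
                 tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                "%Y-%m-%d")),
      error = function(e) NA)
    if (is.na(parsed)) {
      np_error(sprintf("unparseable execution_time: '%s'", execution_time),
               "np_validation_error")
    }
  }
  ctx <- list(
    workflow_activity_iri = as.character(iri(as.character(workflow_activity_iri))),
    research_object_iri = if (is.null(research_object_iri)) NULL else
      as.character(iri(as.character(research_object_iri))),
    inputs = canon(inputs), outputs = canon(outputs),
    agent_iri = if (is.null(agent_iri)) NULL else
      as.character(iri(as.character(agent_iri))),
    execution_time = execution_time)
  ro_map <- c(vapply(c(ctx$inputs, ctx$outputs), function(e)
    if (is.null(e$ro_entity)) NA_character_ else e$ro_entity, character(1)))
  names(ro_map) <- vapply(c(ctx$inputs, ctx$outputs), `[[`, character(1), "entity")
  dup <- tapply(ro_map, names(ro_map), function(x) length(unique(stats::na.omit(x))))
  if (any(dup > 1, na.rm = TRUE)) {
    np_error("a local entity maps to more than one Research Object entity",
             "np_validation_error")
  }
  structure(ctx, class = "provenance_context")
}

#' Build the provenance graph for one assertion
#'
#' States, in PROV-O: the assertion graph `wasGeneratedBy` the workflow
#' activity; the activity `used` each input entity; each output entity
#' `wasGeneratedBy` the activity; the assertion `wasDerivedFrom` the outputs;
#' the activity `wasAssociatedWith` the agent and carries the execution
#' timestamp. Every local entity with an RO counterpart gets exactly one
#' cross-link triple (predicate configurable; the default `rdfs:seeAlso` is
#' an artifact convention), and the activity is linked to the Research
#' Object the same way.
#'
#' @param assertion_graph_iri IRI of the assertion graph being described.
#' @param ctx A [provenance_context()].
#' @param policy A [uri_policy()] (used to mint the provisional graph IRI).
#' @param graph_iri Graph IRI to write into; defaults to a minted provisional
#'   IRI derived from the assertion graph (re-homed by [assemble()]).
#' @param ro_link_predicate Predicate for nanopub-to-RO cross-links.
#' @return A [graph_bundle()] holding one named graph.
#' @export
build_provenance_graph <- function(assertion_graph_iri, ctx,
                                   policy = uri_policy(),
                                   graph_iri = NULL,
                                   ro_link_predicate = RDFS_SEEALSO) {
  stopifnot(inherits(ctx, "provenance_context"))
  a_iri <- as.character(iri(as.character(assertion_graph_iri)))
  g <- if (is.null(graph_iri)) {
    as.character(mint_iri(policy, "provenance",
                          paste0(basename(a_iri), "-prov")))
  } else as.character(iri(as.character(graph_iri)))
  act <- ctx$workflow_activity_iri
  quads <- list(
    quad(a_iri, PROV("wasGeneratedBy"), act, g),
    quad(act, RDF_TYPE, PROV("Activity"), g)
  )
  for (e in ctx$inputs) {
    quads <- c(quads, list(
      quad(act, PROV("used"), e$entity, g),
      quad(e$entity, RDF_TYPE, PROV("Entity"), g)))
    if (!is.null(e$type_iri)) {
      quads <- c(quads, list(quad(e$entity, RDF_TYPE, e$type_iri, g)))
    }
    if (!is.null(e$ro_entity)) {
      quads <- c(quads, list(quad(e$entity, ro_link_predicate, e$ro_entity, g)))
    }
  }
  for (e in ctx$outputs) {
    quads <- c(quads, list(
      quad(e$entity, PROV("wasGeneratedBy"), act, g),
      quad(e$entity, RDF_TYPE, PROV("Entity"), g),
      quad(a_iri, PROV("wasDerivedFrom"), e$entity, g)))
    if (!is.null(e$type_iri)) {
      quads <- c(quads, list(quad(e$entity, RDF_TYPE, e$type_iri, g)))
    }
    if (!is.null(e$ro_entity)) {
      quads <- c(quads, list(quad(e$entity, ro_link_predicate, e$ro_entity, g)))
    }
  }
  if (!is.null(ctx$research_object_iri)) {
    quads <- c(quads, list(quad(act, ro_link_predicate, ctx$research_object_iri, g)))
  }
  if (!is.null(ctx$agent_iri)) {
    quads <- c(quads, list(
      quad(act, PROV("wasAssociatedWith"), ctx$agent_iri, g),
      quad(ctx$agent_iri, RDF_TYPE, PROV("Agent"), g)))
  }
  if (!is.null(ctx$execution_time)) {
    quads <- c(quads, list(
      quad(act, PROV("endedAtTime"),
           rdf_literal(ctx$execution_time, datatype = XSD_DATETIME), g)))
  }
  graph_bundle(do.call(rbind_quads, quads))
}

#' Citation metadata for a nanopublication
#'
#' @param authors Character vector of researcher-identifier IRIs (ORCID
#'   style); at least one is required.
#' @param contributors Optional character vector of contributor/curator IRIs.
#' @param created ISO-8601 creation timestamp.
#' @param version Version string.
#' @param license_iri License IRI; required.
#' @return An object of class `"publication_meta"`.
#' @export
publication_meta <- function(authors, contributors = character(0),
                             created = "2014-01-01T00:00:00Z",
                             version = "1.0",
                             license_iri = "http://creativecommons.org/licenses/by/3.0/") {
  if (missing(authors) || length(authors) == 0) {
    np_error("at least one author is required", "np_validation_error")
  }
  if (is.null(license_iri) || length(license_iri) != 1L || is.na(license_iri)) {
    np_error("a license IRI is required", "np_validation_error")
  }
  structure(list(
    authors = vapply(authors, function(x) as.character(iri(x)), character(1),
                     USE.NAMES = FALSE),
    contributors = vapply(contributors, function(x) as.character(iri(x)),
                          character(1), USE.NAMES = FALSE),
    created = created, version = version,
    license_iri = as.character(iri(license_iri))),
    class = "publication_meta")
}

#' Build the publication-info graph
#'
#' Every triple's subject is the nanopublication IRI itself (never the
#' assertion): creation time, authors, contributors, version and license.
#'
#' @param nanopub_iri The nanopublication IRI.
#' @param meta A [publication_meta()].
#' @param graph_iri Graph IRI to write into (defaults to
#'   `nanopub_iri` + `#pubinfo`).
#' @return A [graph_bundle()] holding one named graph.
#' @export
build_pubinfo_graph <- function(nanopub_iri, meta,
                                graph_iri = paste0(nanopub_iri, "#pubinfo")) {
  stopifnot(inherits(meta, "publication_meta"))
  np <- as.character(iri(as.character(nanopub_iri)))
  g <- as.character(iri(as.character(graph_iri)))
  quads <- list(
    quad(np, DCTERMS("created"),
         rdf_literal(meta$created, datatype = XSD_DATETIME), g),
    quad(np, DCTERMS("hasVersion"), rdf_literal(meta$version), g),
    quad(np, DCTERMS("license"), meta$license_iri, g))
  for (a in meta$authors) {
    quads <- c(quads, list(quad(np, DCTERMS("creator"), a, g)))
  }
  for (cb in meta$contributors) {
    quads <- c(quads, list(quad(np, DCTERMS("contributor"), cb, g)))
  }
  graph_bundle(do.call(rbind_quads, quads))
}

#' Read a Research Object manifest
#'
#' Accepts the minimal JSON form `{"ro_iri": ..., "aggregates": [...]}` or an
#' RDF manifest (Turtle/TriG) using `ore:aggregates`.
#'
#' @param path Path to the manifest.
#' @return A list with `research_object_iri` and `entities` (character vector
#'   of aggregated resource IRIs), suitable for filling a
#'   [provenance_context()].
#' @export
read_ro_manifest <- function(path) {
  if (!file.exists(path)) np_error(sprintf("no such file: %s", path), "np_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    doc <- tryCatch(jsonlite::fromJSON(path),
                    error = function(e) np_error(
                      sprintf("malformed RO manifest %s: %s", path,
                              conditionMessage(e)), "np_parse_error"))
    if (is.null(doc$ro_iri)) {
      np_error("RO manifest lacks 'ro_iri'", "np_parse_error")
    }
    aggregates <- as.character(unlist(doc$aggregates))
    return(list(research_object_iri = as.character(iri(doc$ro_iri)),
                entities = vapply(aggregates, function(x) as.character(iri(x)),
                                  character(1), USE.NAMES = FALSE)))
  }
  b <- read_rdf_file(path)
  ore_aggregates <- "http://www.openarchives.org/ore/terms/aggregates"
  agg <- b$quads[b$quads$p == ore_aggregates & b$quads$o_type == "iri", , drop = FALSE]
  if (nrow(agg) == 0) {
    subj <- b$quads$s[b$quads$p == RDF_TYPE &
                        b$quads$o == "http://www.openarchives.org/ore/terms/Aggregation"]
    if (length(subj) == 0) np_error("RDF RO manifest has no aggregation", "np_parse_error")
    return(list(research_object_iri = subj[[1]], entities = character(0)))
  }
  list(research_object_iri = agg$s[[1]], entities = unique(agg$o))
}

#' Fill a provenance context from a Research Object manifest
#'
#' Convenience wrapper: each aggregated resource becomes a workflow input
#' whose RO counterpart is itself.
#'
#' @param manifest Result of [read_ro_manifest()].
#' @param workflow_activity_iri The activity IRI.
#' @param ... Further arguments to [provenance_context()].
#' @return A [provenance_context()].
#' @export
provenance_context_from_manifest <- function(manifest, workflow_activity_iri, ...) {
  inputs <- lapply(manifest$entities, function(e) list(entity = e, ro_entity = e))
  provenance_context(workflow_activity_iri,
                     research_object_iri = manifest$research_object_iri,
                     inputs = inputs, ...)
}
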