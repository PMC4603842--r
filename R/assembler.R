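# Assembly: head + assertion + provenance + publication info under one
# nanopublication IRI. Graph IRIs follow the fragment convention
# nanopub_iri#head / #assertion / #provenance / #pubinfo.

NP <- function(x) paste0("http://www.nanopub.org/nschema#", x)

np_fragments <- c(head = "#head", assertion = "#assertion",
                  provenance = "#provenance", pubinfo = "#pubinfo")

single_graph_iri <- function(bundle, what) {
  gs <- unique(bundle$quads$g)
  if (length(gs) != 1L) {
    np_error(sprintf("%s bundle must hold exactly one named graph (found %d)",
                     what, length(gs)), "np_assembly_error")
  }
  gs
}

rehome_graph <- function(bundle, old_graph, new_graph) {
  q <- bundle$quads
  q$g[q$g == old_graph] <- new_graph
  q$s[q$s == old_graph] <- new_graph
  q$o[q$o == old_graph & q$o_type == "iri"] <- new_graph
  graph_bundle(q, bundle$prefixes)
}

#' Assemble a nanopublication
#'
#' Derives the nanopublication IRI from the assertion graph's minted key,
#' re-homes the three content graphs under `nanopub_iri#assertion`,
#' `#provenance` and `#pubinfo` (rewriting internal references to the
#' provisional assertion-graph IRI), and builds the four-triple head graph.
#'
#' @param assertion,provenance,pubinfo Single-graph [graph_bundle()]s from
#'   [build_de_assertion()]/[build_overlap_assertion()],
#'   [build_provenance_graph()] and [build_pubinfo_graph()].
#' @param policy The [uri_policy()] that minted the assertion graph.
#' @param key Optional explicit nanopublication key; by default the key is
#'   recovered from the provisional assertion-graph IRI.
#' @return An object of class `"nanopublication"` with fields `nanopub_iri`,
#'   `head`, `assertion`, `provenance`, `pubinfo`.
#' @export
assemble <- function(assertion, provenance, pubinfo, policy = uri_policy(),
                     key = NULL) {
  for (b in list(assertion, provenance, pubinfo)) {
    stopifnot(inherits(b, "graph_bundle"))
  }
  if (bundle_size(assertion) == 0) {
    np_error("assertion graph is empty", "np_assembly_error")
  }
  if (bundle_size(provenance) == 0 || bundle_size(pubinfo) == 0) {
    np_error("provenance and publication-info graphs must be non-empty",
             "np_assembly_error")
  }
  a_old <- single_graph_iri(assertion, "assertion")
  p_old <- single_graph_iri(provenance, "provenance")
  i_old <- single_graph_iri(pubinfo, "pubinfo")
  if (is.null(key)) {
    prefix <- paste0(policy$base_namespace, "assertion/")
    if (!startsWith(a_old, prefix)) {
      np_error(paste("cannot derive the nanopublication key: assertion graph",
                     "IRI was not minted under this policy; pass `key`"),
               "np_assembly_error")
    }
    key <- substr(a_old, nchar(prefix) + 1L, nchar(a_old))
  }
  np_iri <- as.character(mint_iri(policy, "nanopub", key))
  g <- function(part) paste0(np_iri, np_fragments[[part]])

  assertion <- rehome_graph(assertion, a_old, g("assertion"))
  provenance <- rehome_graph(provenance, p_old, g("provenance"))
  provenance <- rehome_graph(provenance, a_old, g("assertion"))
  # re-point quads that referenced a provisional nanopub IRI (same key)
  prov_np <- as.character(mint_iri(policy, "nanopub", key))
  pubinfo <- rehome_graph(pubinfo, i_old, g("pubinfo"))
  pubinfo <- rehome_graph(pubinfo, prov_np, np_iri)
  # the assertion graph must keep its own name after re-homing references
  q <- provenance$quads
  q$g <- g("provenance")
  provenance <- graph_bundle(q, provenance$prefixes)

  head_quads <- rbind_quads(
    quad(np_iri, RDF_TYPE, NP("Nanopublication"), g("head")),
    quad(np_iri, NP("hasAssertion"), g("assertion"), g("head")),
    quad(np_iri, NP("hasProvenance"), g("provenance"), g("head")),
    quad(np_iri, NP("hasPublicationInfo"), g("pubinfo"), g("head"))
  )
  structure(list(
    nanopub_iri = np_iri,
    head = graph_bundle(head_quads),
    assertion = assertion, provenance = provenance, pubinfo = pubinfo),
    class = "nanopublication")
}

#' @export
print.nanopublication <- function(x, ...) {
  cat("<nanopublication ", x$nanopub_iri, ">\n",
      "  assertion: ", bundle_size(x$assertion), " triples; provenance: ",
      bundle_size(x$provenance), "; pubinfo: ", bundle_size(x$pubinfo), "\n",
      sep = "")
  invisible(x)
}

#' Merge a nanopublication's four graphs into one bundle
#'
#' @param np A `"nanopublication"`.
#' @param prefixes Prefix map attached to the result.
#' @return A [graph_bundle()] with four named graphs.
#' @export
nanopub_bundle <- function(np, prefixes = default_prefixes()) {
  stopifnot(inherits(np, "nanopublication"))
  b <- bundle_union(np$head, np$assertion, np$provenance, np$pubinfo)
  graph_bundle(b$quads, prefixes)
}

#' Validate a nanopublication's structure
#'
#' Checks, without throwing: four distinct named graphs under the
#' nanopublication IRI's fragments; a head graph of exactly the type triple
#' and the three part links; non-empty content graphs; provenance referring
#' to the assertion graph IRI; publication info speaking about the
#' nanopublication IRI.
#'
#' @param np A `"nanopublication"`.
#' @return A `"validation_report"`: data frame of `(code, message, iri)`
#'   violations; zero rows means the nanopublication is well-formed.
#' @export
validate <- function(np) {
  violations <- list()
  flag <- function(code, message, iri = NA_character_) {
    violations[[length(violations) + 1L]] <<- data.frame(
      code = code, message = message, iri = iri, stringsAsFactors = FALSE)
  }
  if (!inherits(np, "nanopublication")) {
    flag("NOT_A_NANOPUB", "object is not a nanopublication")
    return(structure(do.call(rbind, violations), class = c("validation_report", "data.frame")))
  }
  np_iri <- np$nanopub_iri
  g <- function(part) paste0(np_iri, np_fragments[[part]])
  parts <- c("head", "assertion", "provenance", "pubinfo")
  graph_iris <- vapply(parts, function(p) {
    gs <- unique(np[[p]]$quads$g)
    if (length(gs) == 1) gs else NA_character_
  }, character(1))
  for (p in parts) {
    if (is.na(graph_iris[[p]])) {
      flag("GRAPH_NOT_SINGLE",
           sprintf("%s does not hold exactly one named graph", p))
    } else if (graph_iris[[p]] != g(p)) {
      flag("GRAPH_IRI_MISMATCH",
           sprintf("%s graph IRI is not %s", p, g(p)), graph_iris[[p]])
    }
  }
  if (anyDuplicated(stats::na.omit(graph_iris))) {
    flag("GRAPH_IRI_CLASH", "the four graph IRIs are not distinct")
  }
  for (p in c("assertion", "provenance", "pubinfo")) {
    if (bundle_size(np[[p]]) == 0) {
      flag("EMPTY_GRAPH", sprintf("%s graph is empty", p))
    }
  }
  hq <- np$head$quads
  expected_head <- rbind_quads(
    quad(np_iri, RDF_TYPE, NP("Nanopublication"), g("head")),
    quad(np_iri, NP("hasAssertion"), g("assertion"), g("head")),
    quad(np_iri, NP("hasProvenance"), g("provenance"), g("head")),
    quad(np_iri, NP("hasPublicationInfo"), g("pubinfo"), g("head")))
  if (!bundle_equal(graph_bundle(hq), graph_bundle(expected_head))) {
    flag("HEAD_SHAPE",
         "head graph is not exactly {type, hasAssertion, hasProvenance, hasPublicationInfo}",
         np_iri)
  }
  pq <- np$provenance$quads
  if (nrow(pq) > 0 &&
      !any(pq$s == g("assertion") | (pq$o_type == "iri" & pq$o == g("assertion")))) {
    flag("PROV_NO_ASSERTION_LINK",
         "provenance graph never mentions the assertion graph IRI", g("assertion"))
  }
  iq <- np$pubinfo$quads
  if (nrow(iq) > 0 && !all(iq$s == np_iri)) {
    flag("PUBINFO_OFF_SUBJECT",
         "publication info contains triples whose subject is not the nanopublication IRI",
         np_iri)
  }
  if (nrow(iq) > 0 && !any(iq$s == np_iri)) {
    flag("PUBINFO_NO_NANOPUB_REF",
         "publication info never mentions the nanopublication IRI", np_iri)
  }
  out <- if (length(violations) == 0) {
    data.frame(code = character(0), message = character(0), iri = character(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, violations)
  structure(out, class = c("validation_report", "data.frame"))
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) cat("valid nanopublication (0 violations)\n")
  else {
    cat(nrow(x), "violation(s):\n")
    for (i in seq_len(nrow(x))) cat("  [", x$code[i], "] ", x$message[i], "\n", sep = "")
  }
  invisible(x)
}

#' Is a nanopublication structurally valid?
#' @param np A `"nanopublication"`.
#' @return `TRUE` when [validate()] reports no violations.
#' @export
is_valid_nanopub <- function(np) nrow(validate(np)) == 0

# ---- nanopub and corpus I/O ----------------------------------------------

#' Write one nanopublication to a file
#'
#' @param np A `"nanopublication"`.
#' @param path Output path.
#' @param dialect `"trig"` (default) or `"nquads"`.
#' @param prefixes Prefix map for TriG compaction.
#' @return `path`, invisibly.
#' @export
write_nanopub <- function(np, path, dialect = c("trig", "nquads"),
                          prefixes = default_prefixes()) {
  dialect <- match.arg(dialect)
  writeLines(write_quads(nanopub_bundle(np, prefixes), dialect), path, sep = "")
  invisible(path)
}

#' Write a corpus of nanopublications to one file
#'
#' @param nps List of `"nanopublication"` objects.
#' @inheritParams write_nanopub
#' @return `path`, invisibly.
#' @export
write_corpus <- function(nps, path, dialect = c("trig", "nquads"),
                         prefixes = default_prefixes()) {
  dialect <- match.arg(dialect)
  b <- do.call(bundle_union, lapply(nps, nanopub_bundle))
  writeLines(write_quads(graph_bundle(b$quads, prefixes), dialect), path, sep = "")
  invisible(path)
}

# Regroup a flat bundle into nanopublications via the head graphs.
corpus_from_bundle <- function(bundle) {
  q <- bundle$quads
  heads <- unique(q$g[q$p == NP("hasAssertion")])
  nps <- lapply(sort(heads, method = "radix"), function(hg) {
    hq <- q[q$g == hg, , drop = FALSE]
    np_iri <- unique(hq$s)
    if (length(np_iri) != 1L) {
      np_error(sprintf("head graph %s has %d subjects", hg, length(np_iri)),
               "np_structure_error")
    }
    pick <- function(pred) {
      o <- hq$o[hq$p == pred & hq$o_type == "iri"]
      if (length(o) != 1L) {
        np_error(sprintf("head graph %s lacks a unique %s link", hg, pred),
                 "np_structure_error")
      }
      o
    }
    gs <- c(head = hg, assertion = pick(NP("hasAssertion")),
            provenance = pick(NP("hasProvenance")),
            pubinfo = pick(NP("hasPublicationInfo")))
    part <- function(gi) graph_bundle(q[q$g == gi, , drop = FALSE])
    structure(list(nanopub_iri = np_iri,
                   head = part(gs[["head"]]), assertion = part(gs[["assertion"]]),
                   provenance = part(gs[["provenance"]]),
                   pubinfo = part(gs[["pubinfo"]])),
              class = "nanopublication")
  })
  covered <- unlist(lapply(nps, function(np) unique(nanopub_bundle(np)$quads$g)))
  stray <- setdiff(unique(q$g), covered)
  if (length(stray) > 0) {
    np_error(sprintf("file contains graphs not owned by any nanopublication: %s",
                     paste(stray, collapse = ", ")), "np_structure_error")
  }
  nps
}

#' Read a corpus of nanopublications
#'
#' @param path TriG or N-Quads file written by [write_corpus()] (or any file
#'   following the same head-graph convention).
#' @return List of `"nanopublication"` objects.
#' @export
read_corpus <- function(path) {
  corpus_from_bundle(read_rdf_file(path))
}

#' Read a single nanopublication
#'
#' @param path File holding exactly one nanopublication (four named graphs).
#' @return A `"nanopublication"`.
#' @export
read_nanopub <- function(path) {
  b <- read_rdf_file(path)
  if (length(unique(b$quads$g)) != 4L) {
    np_error(sprintf("expected exactly 4 named graphs, found %d",
                     length(unique(b$quads$g))), "np_structure_error")
  }
  nps <- corpus_from_bundle(b)
  if (length(nps) != 1L) {
    np_error("file does not contain exactly one nanopublication",
             "np_structure_error")
  }
  nps[[1]]
}

#' Build nanopublications from result tables
#'
#' End-to-end convenience: one nanopublication per differential-expression
#' record and per overlap record, all sharing one provenance context and one
#' set of publication metadata.
#'
#' @param de_records List of [de_gene_record()]s.
#' @param overlap_records List of [overlap_record()]s.
#' @param ctx A [provenance_context()].
#' @param meta A [publication_meta()].
#' @param vocab A [vocabulary_config()].
#' @param policy A [uri_policy()].
#' @return List of `"nanopublication"` objects (DE first, then overlaps).
#' @export
build_nanopubs <- function(de_records, overlap_records, ctx, meta,
                           vocab = vocabulary_config(), policy = uri_policy()) {
  one <- function(assertion) {
    a_iri <- single_graph_iri(assertion, "assertion")
    prov <- build_provenance_graph(a_iri, ctx, policy)
    prefix <- paste0(policy$base_namespace, "assertion/")
    key <- substr(a_iri, nchar(prefix) + 1L, nchar(a_iri))
    np_iri <- as.character(mint_iri(policy, "nanopub", key))
    pubinfo <- build_pubinfo_graph(np_iri, meta)
    assemble(assertion, prov, pubinfo, policy, key = key)
  }
  c(
    lapply(de_records, function(r) one(build_de_assertion(r, vocab, policy))),
    lapply(overlap_records, function(r) one(build_overlap_assertion(r, vocab, policy)))
  )
}
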