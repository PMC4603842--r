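# Condition helper: all package errors are classed conditions so callers and
# tests can dispatch on the error kind rather than on message text.
np_error <- function(message, class, ...) {
  stop(structure(
    class = c(class, "nanopubr_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

np_warning <- function(message, class) {
  warning(structure(
    class = c(class, "nanopubr_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Create a validated IRI
#'
#' IRIs are the only node type in this package: blank nodes are banned and
#' every locally-defined resource is minted a stable (skolem) IRI instead,
#' so that graphs compare by plain set equality and serializations diff
#' byte-stably.
#'
#' @param value Absolute IRI string (scheme required, no whitespace or the
#'   characters forbidden inside an `<IRIREF>`).
#' @return A character scalar of class `"np_iri"`.
#' @examples
#' iri("http://bio2rdf.org/geneid:25")
#' @export
iri <- function(value) {
  if (!is.character(value) || length(value) != 1L || is.na(value)) {
    np_error("IRI must be a single character string", "np_invalid_argument")
  }
  if (!is_absolute_iri(value)) {
    np_error(sprintf("not an absolute IRI: '%s'", value), "np_invalid_argument")
  }
  structure(value, class = "np_iri")
}

#' Test whether a string is an acceptable absolute IRI
#'
#' @param x Character vector.
#' @return Logical vector: scheme present and no whitespace / IRIREF-forbidden
#'   characters.
#' @export
is_absolute_iri <- function(x) {
  !is.na(x) &
    grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x) &
    !grepl("[\\x00-\\x20<>\"{}|^`\\\\]", x, perl = TRUE)
}

#' @export
print.np_iri <- function(x, ...) {
  cat("<", unclass(x), ">\n", sep = "")
  invisible(x)
}

#' Create an RDF literal
#'
#' @param lexical Lexical form (character scalar).
#' @param datatype Optional datatype IRI. Mutually exclusive with `language`.
#' @param language Optional BCP-47 language tag. Mutually exclusive with
#'   `datatype`.
#' @return An object of class `"np_literal"`.
#' @examples
#' rdf_literal("autophagy", language = "en")
#' @export
rdf_literal <- function(lexical, datatype = NULL, language = NULL) {
  if (!is.character(lexical) || length(lexical) != 1L || is.na(lexical)) {
    np_error("literal lexical form must be a single string", "np_invalid_argument")
  }
  if (!is.null(datatype) && !is.null(language)) {
    np_error("a literal cannot carry both a datatype and a language tag",
             "np_invalid_argument")
  }
  if (!is.null(language) &&
      !grepl("^[A-Za-z]{1,8}(-[A-Za-z0-9]{1,8})*$", language)) {
    np_error(sprintf("malformed language tag: '%s'", language),
             "np_invalid_argument")
  }
  if (!is.null(datatype)) {
    datatype <- as.character(iri(as.character(datatype)))
  }
  structure(
    list(lexical = lexical, datatype = datatype, language = language),
    class = "np_literal"
  )
}

#' @export
print.np_literal <- function(x, ...) {
  cat(format_object_nq(literal_row(x)), "\n")
  invisible(x)
}

# Internal tabular quad representation: one row per quad, objects split into
# (o, o_type, o_dt, o_lang). This is the package's working currency; the
# np_iri / np_literal classes are the user-facing constructors.
empty_quads <- function() {
  data.frame(
    s = character(0), p = character(0),
    o = character(0), o_type = character(0),
    o_dt = character(0), o_lang = character(0),
    g = character(0),
    stringsAsFactors = FALSE
  )
}

literal_row <- function(lit) {
  data.frame(
    o = lit$lexical, o_type = "literal",
    o_dt = if (is.null(lit$datatype)) NA_character_ else lit$datatype,
    o_lang = if (is.null(lit$language)) NA_character_ else lit$language,
    stringsAsFactors = FALSE
  )
}

#' Construct a single quad
#'
#' @param s,p,g Subject, predicate and graph IRIs (strings or [iri()] values).
#' @param o Object: an IRI (string or [iri()]) or an [rdf_literal()].
#' @return A one-row quad data frame.
#' @export
quad <- function(s, p, o, g) {
  s <- as.character(iri(as.character(s)))
  p <- as.character(iri(as.character(p)))
  g <- as.character(iri(as.character(g)))
  if (inherits(o, "np_literal")) {
    orow <- literal_row(o)
  } else {
    orow <- data.frame(
      o = as.character(iri(as.character(o))), o_type = "iri",
      o_dt = NA_character_, o_lang = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  cbind(
    data.frame(s = s, p = p, stringsAsFactors = FALSE),
    orow,
    data.frame(g = g, stringsAsFactors = FALSE)
  )
}

quad_cols <- c("s", "p", "o", "o_type", "o_dt", "o_lang", "g")

rbind_quads <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(parts) == 0) return(empty_quads())
  out <- do.call(rbind, lapply(parts, function(x) x[, quad_cols]))
  rownames(out) <- NULL
  out
}

#' Create a graph bundle
#'
#' A graph bundle is a *set* of quads (duplicates collapse; equality is set
#' equality) together with a CURIE prefix map used when serializing.
#'
#' @param quads Quad data frame (rows from [quad()], possibly bound together).
#' @param prefixes Named character vector mapping CURIE prefixes to namespace
#'   IRIs.
#' @return An object of class `"graph_bundle"`.
#' @export
graph_bundle <- function(quads = empty_quads(), prefixes = character(0)) {
  if (!is.data.frame(quads) || !all(quad_cols %in% names(quads))) {
    np_error("quads must be a quad data frame", "np_invalid_argument")
  }
  quads <- unique(quads[, quad_cols])
  rownames(quads) <- NULL
  structure(list(quads = quads, prefixes = prefixes), class = "graph_bundle")
}

#' @export
print.graph_bundle <- function(x, ...) {
  cat(sprintf("<graph_bundle: %d quads, %d graphs, %d prefixes>\n",
              nrow(x$quads), length(unique(x$quads$g)), length(x$prefixes)))
  invisible(x)
}

#' Merge graph bundles (set union)
#'
#' @param ... Graph bundles.
#' @return A single [graph_bundle()]; later prefix bindings win on clash.
#' @export
bundle_union <- function(...) {
  bs <- list(...)
  stopifnot(all(vapply(bs, inherits, logical(1), "graph_bundle")))
  quads <- do.call(rbind_quads, lapply(bs, function(b) b$quads))
  prefixes <- character(0)
  for (b in bs) prefixes[names(b$prefixes)] <- b$prefixes
  graph_bundle(quads, prefixes)
}

#' Set equality of two bundles
#'
#' Compares the canonical sorted N-Quads rendering, so graph membership,
#' datatypes and language tags all participate.
#'
#' @param a,b Graph bundles.
#' @return `TRUE` or `FALSE`.
#' @export
bundle_equal <- function(a, b) {
  identical(write_quads(a, "nquads"), write_quads(b, "nquads"))
}

#' Number of quads in a bundle
#' @param b Graph bundle.
#' @return Integer count.
#' @export
bundle_size <- function(b) nrow(b$quads)

#' Default CURIE prefix map
#'
#' Vocabulary namespaces used throughout: the nanopublication schema, PROV-O,
#' ORE aggregation, SIO, the Sequence Ontology OBO namespace, NIFSTD, Dublin
#' Core terms, XSD, and the local `biosemantics` namespace housing the
#' chromatin-state ontology extension. The `biosemantics` and `nifstd` IRIs
#' are configuration values (the canonical ones are not standardized); replace
#' them via [run_config()] if you have institutional namespaces.
#'
#' @return Named character vector prefix -> namespace IRI.
#' @export
default_prefixes <- function() {
  c(
    rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    owl = "http://www.w3.org/2002/07/owl#",
    xsd = "http://www.w3.org/2001/XMLSchema#",
    dcterms = "http://purl.org/dc/terms/",
    np = "http://www.nanopub.org/nschema#",
    prov = "http://www.w3.org/ns/prov#",
    ore = "http://www.openarchives.org/ore/terms/",
    sio = "http://semanticscience.org/resource/",
    so = "http://purl.obolibrary.org/obo/",
    nifstd = "http://uri.neuinfo.org/nif/nifstd/",
    biosemantics = "https://biosemantics.example.org/resource/"
  )
}

#' Resolve a CURIE against a prefix map
#'
#' @param curie String of the form `prefix:local`.
#' @param prefix_map Named character vector (see [default_prefixes()]).
#' @return The expanded [iri()].
#' @examples
#' resolve_curie("so:SO_0001411", default_prefixes())
#' @export
resolve_curie <- function(curie, prefix_map = default_prefixes()) {
  if (!is.character(curie) || length(curie) != 1L || !grepl(":", curie, fixed = TRUE)) {
    np_error(sprintf("not a CURIE: '%s'", curie), "np_resolution_error")
  }
  m <- regexpr(":", curie, fixed = TRUE)
  prefix <- substr(curie, 1L, m - 1L)
  local <- substr(curie, m + 1L, nchar(curie))
  if (!prefix %in% names(prefix_map)) {
    np_error(sprintf("unknown CURIE prefix: '%s'", prefix), "np_resolution_error")
  }
  iri(paste0(prefix_map[[prefix]], local))
}

# ---- IRI minting ----------------------------------------------------------

mint_kinds <- c("nanopub", "assertion", "provenance", "pubinfo",
                "association", "promoter", "region", "entity")

#' Define an IRI-minting policy
#'
#' Every locally-defined node (association hubs, promoters, regions, graph
#' names, the nanopublication itself) is minted deterministically from a
#' `(kind, key)` pair under one base namespace, so identical inputs always
#' produce identical IRIs and repeated runs are byte-stable.
#'
#' @param base_namespace Absolute IRI the minted IRIs live under (keep the
#'   trailing slash or hash).
#' @param strategy `"slug"` (readable keys, the default) or `"content-hash"`
#'   (SHA-1 of the kind+key, for opaque identifiers).
#' @return An object of class `"uri_policy"`.
#' @export
uri_policy <- function(base_namespace = "https://biosemantics.example.org/np/",
                       strategy = c("slug", "content-hash")) {
  strategy <- match.arg(strategy)
  structure(
    list(base_namespace = as.character(iri(base_namespace)), strategy = strategy),
    class = "uri_policy"
  )
}

slugify <- function(key) {
  # keep an IRI-safe alphabet; anything else becomes '-'
  out <- gsub("[^A-Za-z0-9._~-]+", "-", key)
  gsub("^-+|-+$", "", out)
}

#' Mint a deterministic IRI
#'
#' Injective over distinct `(kind, key)` pairs and idempotent: the same call
#' always yields the same IRI. Nanopublication IRIs sit directly under the
#' base namespace; all other kinds are nested under a `kind/` segment.
#'
#' @param policy A [uri_policy()].
#' @param kind One of `"nanopub"`, `"assertion"`, `"provenance"`, `"pubinfo"`,
#'   `"association"`, `"promoter"`, `"region"`, `"entity"`.
#' @param key Non-empty string identifying the resource within its kind.
#' @return An [iri()].
#' @examples
#' mint_iri(uri_policy("https://example.org/np/"), "nanopub", "degene-3064")
#' @export
mint_iri <- function(policy, kind, key) {
  stopifnot(inherits(policy, "uri_policy"))
  kind <- match.arg(kind, mint_kinds)
  if (!is.character(key) || length(key) != 1L || is.na(key) || !nzchar(key)) {
    np_error("mint_iri: key must be a non-empty string", "np_invalid_argument")
  }
  if (policy$strategy == "content-hash") {
    h <- digest::digest(paste(kind, key, sep = "\x1f"),
                        algo = "sha1", serialize = FALSE)
    local <- if (kind == "nanopub") h else paste0(kind, "/", h)
  } else {
    sk <- slugify(key)
    if (!nzchar(sk)) {
      np_error("mint_iri: key has no IRI-safe characters", "np_invalid_argument")
    }
    local <- if (kind == "nanopub") sk else paste0(kind, "/", sk)
  }
  iri(paste0(policy$base_namespace, local))
}
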