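prov_ns <- "http://www.w3.org/ns/prov#"
a_iri <- "https://example.org/np/assertion/degene-25"

test_that("provenance states the workflow run with the contracted counts", {
  b <- build_provenance_graph(a_iri, tiny_ctx(), test_policy())
  q <- b$quads
  expect_identical(sum(q$p == paste0(prov_ns, "used")), 2L)
  expect_true(sum(q$p == paste0(prov_ns, "wasGeneratedBy")) >= 1L)
  expect_true(any(q$s == a_iri & q$p == paste0(prov_ns, "wasGeneratedBy")))
  expect_true(any(q$s == a_iri & q$p == paste0(prov_ns, "wasDerivedFrom")))
  # empty inputs stay valid with no used-statements
  ctx0 <- provenance_context("https://example.org/activity/run-1")
  q0 <- build_provenance_graph(a_iri, ctx0, test_policy())$quads
  expect_identical(sum(q0$p == paste0(prov_ns, "used")), 0L)
})

test_that("every (local, RO) pair yields exactly one cross-link triple", {
  withr::local_seed(5)
  for (rep in 1:5) {
    n_in <- sample(0:4, 1); n_out <- sample(1:3, 1)
    mk <- function(tag, i, linked) {
      e <- list(entity = sprintf("https://example.org/e/%s%d", tag, i))
      if (linked) e$ro_entity <- sprintf("https://example.org/ro/e/%s%d", tag, i)
      e
    }
    in_linked <- if (n_in > 0) stats::runif(n_in) < 0.7 else logical(0)
    out_linked <- stats::runif(n_out) < 0.7
    ctx <- provenance_context(
      "https://example.org/activity/run-1",
      inputs = lapply(seq_len(n_in), function(i) mk("in", i, in_linked[i])),
      outputs = lapply(seq_len(n_out), function(i) mk("out", i, out_linked[i])))
    q <- build_provenance_graph(a_iri, ctx, test_policy())$quads
    links <- q[q$p == "http://www.w3.org/2000/01/rdf-schema#seeAlso", , drop = FALSE]
    # oracle: enumerate the linked pairs directly from the context
    pairs <- c(
      if (n_in > 0) sprintf("https://example.org/e/in%d", which(in_linked)),
      sprintf("https://example.org/e/out%d", which(out_linked)))
    expect_setequal(links$s, pairs)
    expect_identical(nrow(links), length(pairs))
  }
})

test_that("only allow-listed PROV terms ever appear", {
  allowed <- paste0(prov_ns, c("Activity", "Entity", "Agent", "used",
                               "wasGeneratedBy", "wasDerivedFrom",
                               "wasAssociatedWith", "endedAtTime"))
  q <- build_provenance_graph(a_iri, tiny_ctx(), test_policy())$quads
  used <- unique(c(q$p, q$o[q$o_type == "iri"], q$s))
  prov_terms <- used[startsWith(used, prov_ns)]
  expect_true(all(prov_terms %in% allowed))
})

test_that("shared context gives identical RO cross-links across nanopubs", {
  ctx <- tiny_ctx()
  q1 <- build_provenance_graph("https://example.org/np/assertion/a1", ctx,
                               test_policy())$quads
  q2 <- build_provenance_graph("https://example.org/np/assertion/a2", ctx,
                               test_policy())$quads
  link <- function(q) {
    l <- q[q$p == "http://www.w3.org/2000/01/rdf-schema#seeAlso", c("s", "o")]
    l[order(l$s, l$o), ]
  }
  expect_identical(link(q1), link(q2))
})

test_that("publication info speaks only about the nanopublication IRI", {
  np_iri <- "https://example.org/np/degene-25"
  b <- build_pubinfo_graph(np_iri, tiny_meta())
  expect_true(all(b$quads$s == np_iri))
  expect_identical(sum(b$quads$p == "http://purl.org/dc/terms/creator"), 2L)
  expect_identical(write_quads(b, "nquads"),
                   write_quads(build_pubinfo_graph(np_iri, tiny_meta()), "nquads"))
  expect_error(publication_meta(authors = character(0)),
               class = "np_validation_error")
})

test_that("RO manifests round-trip through the fixture writer", {
  d <- withr::local_tempdir()
  fx <- table2_fixture()
  write_fixture(fx, d)
  m <- read_ro_manifest(file.path(d, "ro-manifest.json"))
  expect_identical(m$research_object_iri, fx$ro_manifest$ro_iri)
  expect_setequal(m$entities, fx$ro_manifest$aggregates)
  # degenerate manifest: RO IRI only
  empty <- file.path(d, "empty.json")
  jsonlite::write_json(list(ro_iri = "https://example.org/ro/x",
                            aggregates = list()), empty, auto_unbox = TRUE)
  m0 <- read_ro_manifest(empty)
  expect_length(m0$entities, 0L)
  writeLines("{ not json", empty)
  expect_error(read_ro_manifest(empty), class = "np_parse_error")
})

test_that("context validation rejects ambiguous RO mappings and bad input", {
  expect_error(provenance_context(NULL), class = "np_validation_error")
  expect_error(provenance_context(
    "https://example.org/act/1",
    inputs = list(list(entity = "https://example.org/e/1",
                       ro_entity = "https://example.org/ro/a"),
                  list(entity = "https://example.org/e/1",
                       ro_entity = "https://example.org/ro/b"))),
    class = "np_validation_error")
  expect_error(provenance_context("https://example.org/act/1",
                                  execution_time = "not-a-time"),
               class = "np_validation_error")
})
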