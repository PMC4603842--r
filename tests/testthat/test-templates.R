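rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

test_that("the differential-expression assertion is exactly its three statements", {
  vocab <- vocabulary_config()
  p <- test_policy()
  b <- build_de_assertion(de_gene_record(25, "ABL1"), vocab, p)
  q <- b$quads
  expect_identical(nrow(q), 3L)
  assoc <- unique(q$s)
  expect_length(assoc, 1L)
  # enumerated template statements: one type + two refers_to spokes
  expect_identical(sort(paste(q$p, q$o)), sort(c(
    paste(rdf_type, vocab$assoc_class),
    paste(vocab$refers_to, "http://bio2rdf.org/geneid:25"),
    paste(vocab$refers_to, vocab$hd_disease))))
})

test_that("two genes give graphs differing only in gene IRI and minted keys", {
  p <- test_policy()
  b1 <- write_quads(build_de_assertion(de_gene_record(25), policy = p), "nquads")
  b2 <- write_quads(build_de_assertion(de_gene_record(2280), policy = p), "nquads")
  norm <- function(x) gsub("geneid:[0-9]+", "geneid:N", gsub("degene-[0-9]+", "degene-N", x))
  expect_false(identical(b1, b2))
  expect_identical(norm(b1), norm(b2))
})

test_that("overlap assertions branch on region kind with 4 or 5 triples", {
  vocab <- vocabulary_config()
  p <- test_policy()
  cpg <- build_overlap_assertion(overlap_record(25, "cpg_island"), vocab, p)
  expect_identical(bundle_size(cpg), 4L)
  expect_true(vocab$cpg_island_class %in% cpg$quads$o)
  expect_false(any(grepl("has_state", cpg$quads$p)))
  for (k in chromatin_state_kinds()) {
    b <- build_overlap_assertion(overlap_record(25, k), vocab, p)
    expect_identical(bundle_size(b), 5L)
    q <- b$quads
    expect_true(paste0(vocab$biosemantics_ns, "chromatin_region") %in% q$o)
    hs <- q[q$p == paste0(vocab$biosemantics_ns, "has_state"), , drop = FALSE]
    expect_identical(hs$o, paste0(vocab$biosemantics_ns, k))
  }
  expect_error(overlap_record(25, "enhancer"), class = "np_validation_error")
})

test_that("the five region kinds give five structurally distinct graphs", {
  p <- test_policy()
  shapes <- vapply(region_kinds(), function(k) {
    nq <- write_quads(build_overlap_assertion(overlap_record(25, k), policy = p),
                      "nquads")
    # mask minted IRIs so only the statement structure remains
    gsub("<https://example.org/np/[^>]*>", "<minted>", nq)
  }, character(1))
  expect_length(unique(shapes), 5L)
})

test_that("assertion graphs are closed over minted and configured IRIs", {
  vocab <- vocabulary_config()
  p <- test_policy()
  allowed <- function(x) {
    startsWith(x, p$base_namespace) |
      x %in% unlist(vocab[setdiff(names(vocab), c("gene_pattern", "biosemantics_ns"))]) |
      startsWith(x, vocab$biosemantics_ns) |
      grepl("^http://bio2rdf.org/geneid:", x) |
      x == rdf_type
  }
  for (k in region_kinds()) {
    q <- build_overlap_assertion(overlap_record(77, k), vocab, p)$quads
    nodes <- c(q$s, q$p, q$o[q$o_type == "iri"])
    expect_true(all(allowed(nodes)), info = k)
  }
})

test_that("templates are deterministic down to the serialized bytes", {
  p <- test_policy()
  for (rec in list(de_gene_record(3064), overlap_record(3064, "heterochromatic"))) {
    build <- function() {
      b <- if (inherits(rec, "de_gene_record")) build_de_assertion(rec, policy = p)
      else build_overlap_assertion(rec, policy = p)
      write_quads(b, "nquads")
    }
    expect_identical(build(), build())
  }
})

test_that("TSV readers enforce schema and closed enums with row context", {
  d <- withr::local_tempdir()
  de <- file.path(d, "de.tsv")
  writeLines(c("gene_id\tsymbol", "25\tABL1", "2280\tFKBP1A", "5707\tPSMD1"), de)
  recs <- records_from_tsv(de, "de")
  expect_length(recs, 3L)
  expect_identical(recs[[1]]$gene_id, 25)

  writeLines("gene_id\tsymbol", de)
  expect_length(records_from_tsv(de, "de"), 0L)

  bad <- file.path(d, "bad.tsv")
  writeLines(c("gene_id\tpromoter_key\tregion_kind", "25\tp1\tenhancer"), bad)
  err <- tryCatch(records_from_tsv(bad, "overlap"),
                  np_validation_error = function(e) conditionMessage(e))
  expect_match(err, "row 1")
  writeLines(c("gene_id\tregion_kind", "25\tcpg_island"), bad)
  err2 <- tryCatch(records_from_tsv(bad, "overlap"),
                   np_schema_error = function(e) conditionMessage(e))
  expect_match(err2, "promoter_key")
})
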