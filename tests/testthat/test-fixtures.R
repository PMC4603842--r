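test_that("generation is deterministic per seed and sensitive to it", {
  s1 <- generate_fixture(fixture_spec(n_genes = 60, seed = 1))
  s2 <- generate_fixture(fixture_spec(n_genes = 60, seed = 1))
  s3 <- generate_fixture(fixture_spec(n_genes = 60, seed = 2))
  expect_identical(s1$de_table, s2$de_table)
  expect_identical(s1$overlap_table, s2$overlap_table)
  expect_true(bundle_equal(s1$go_graph, s2$go_graph))
  expect_true(bundle_equal(s1$drugtarget_graph, s2$drugtarget_graph))
  expect_identical(s1$truth$integration, s2$truth$integration)
  expect_false(identical(s1$de_table, s3$de_table))
})

test_that("a zero DE fraction empties the pipeline end to end", {
  fx <- generate_fixture(fixture_spec(n_genes = 40, de_fraction = 0, seed = 4))
  expect_identical(nrow(fx$de_table), 0L)
  expect_identical(nrow(fx$overlap_table), 0L)
  st <- fixture_store(fx)
  expect_identical(nrow(integrate_drug_targets(st)), 0L)
  expect_identical(nrow(fx$truth$integration), 0L)
})

test_that("pipeline output equals the generator's truth bookkeeping", {
  fx <- generate_fixture(fixture_spec(n_genes = 200, seed = 9))
  st <- fixture_store(fx)
  expect_identical(query_de_genes(st), fx$truth$de_genes)
  expect_equal(integrate_drug_targets(st), fx$truth$integration)
  # region truth: per-gene kind sets drive the region query
  for (kinds in list("cpg_island", c("cpg_island", "poised_promoter"))) {
    want <- names(Filter(function(k) all(kinds %in% k), fx$truth$gene_kinds))
    expect_identical(query_genes_by_region(st, kinds, "all"),
                     sort(want, method = "radix"))
  }
})

test_that("invalid specs are rejected up front", {
  expect_error(fixture_spec(n_genes = 0), class = "np_validation_error")
  expect_error(fixture_spec(de_fraction = 1.5), class = "np_validation_error")
  w <- c(cpg_island = 0.9, active_promoter = 0.05, weak_promoter = 0.02,
         poised_promoter = 0.02, heterochromatic = 0.02)
  expect_error(fixture_spec(region_kind_weights = w),
               class = "np_validation_error")
  expect_error(fixture_spec(drugs_per_target = c(3, 1)),
               class = "np_validation_error")
})

test_that("region-kind frequencies track the configured weights", {
  fx <- generate_fixture(fixture_spec(n_genes = 2500, de_fraction = 0.8,
                                      seed = 12))
  obs <- table(factor(fx$overlap_table$region_kind, levels = region_kinds()))
  expect_true(sum(obs) > 2000)
  p <- stats::chisq.test(obs, p = unname(fx$spec$region_kind_weights))$p.value
  expect_gt(p, 1e-4)
})

test_that("fixture bundles round-trip through a directory losslessly", {
  fx <- generate_fixture(fixture_spec(n_genes = 50, seed = 17))
  d <- withr::local_tempdir()
  write_fixture(fx, d)
  back <- read_fixture(d)
  expect_equal(back$de_table, fx$de_table)
  expect_equal(back$overlap_table, fx$overlap_table)
  for (g in c("go_graph", "annotation_graph", "geneinfo_graph", "drugtarget_graph")) {
    expect_true(bundle_equal(graph_bundle(fx[[g]]$quads),
                             graph_bundle(back[[g]]$quads)), info = g)
  }
  expect_identical(back$ro_manifest$ro_iri, fx$ro_manifest$ro_iri)
  expect_equal(back$truth$integration, fx$truth$integration)
  expect_identical(back$truth$de_genes, fx$truth$de_genes)
  # missing pieces are named
  file.remove(file.path(d, "gene-info.ttl"))
  err <- tryCatch(read_fixture(d), np_io_error = function(e) conditionMessage(e))
  expect_match(err, "gene-info.ttl")
  expect_error(read_fixture(file.path(d, "nope")), class = "np_io_error")
})

test_that("the worked-example fixture is self-consistent", {
  fx <- table2_fixture()
  corpus <- fixture_corpus(fx)
  expect_length(corpus, nrow(fx$de_table) + nrow(fx$overlap_table))
  expect_true(all(vapply(corpus, is_valid_nanopub, logical(1))))
  expect_identical(fx$truth$expected_pairs$gene_symbol[1], "ABL1")
  # printed identifiers present in the graphs
  q <- fx$drugtarget_graph$quads
  expect_true(any(q$s == "http://bio2rdf.org/drugbank_target:768" &
                    q$o == "http://bio2rdf.org/geneid:2280"))
  expect_true(any(q$o == "Vincristine"))
})
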