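test_that("loading preserves named graphs and is idempotent per source", {
  st <- quad_store()
  nps <- tiny_corpus(gene_ids = c(25, 2280))
  store_load(st, nps, "corpus")
  expect_identical(length(store_graphs(st)), 4L * length(nps))
  n1 <- store_size(st)
  store_load(st, nps, "corpus")
  expect_identical(store_size(st), n1)
  # empty corpus leaves the store unchanged
  store_load(st, list(), "empty")
  expect_identical(store_size(st), n1)
})

test_that("parse errors propagate with the source id", {
  st <- quad_store()
  f <- withr::local_tempfile(fileext = ".trig")
  writeLines("<http://a> <http://b> { truncated", f)
  err <- tryCatch(store_load_file(st, f, "bad-source"),
                  np_parse_error = function(e) conditionMessage(e))
  expect_match(err, "bad-source")
})

test_that("the DE-gene query returns exactly the asserted genes, deduplicated", {
  st <- quad_store()
  expect_length(query_de_genes(st), 0L)
  ids <- c(25, 2280, 5707, 25, 25)   # duplicated rows in the input table
  nps <- build_nanopubs(lapply(ids, de_gene_record), list(), tiny_ctx(),
                        tiny_meta(), policy = test_policy())
  store_load(st, nps, "corpus")
  expect_identical(query_de_genes(st),
                   sort(sprintf("http://bio2rdf.org/geneid:%d",
                                unique(ids))))
})

test_that("region queries agree with brute force over the overlap table", {
  tab <- data.frame(
    gene_id = c(1111, 1111, 2222, 2222, 3333),
    region_kind = c("cpg_island", "poised_promoter",
                    "cpg_island", "poised_promoter", "cpg_island"),
    stringsAsFactors = FALSE)
  ov <- lapply(seq_len(nrow(tab)), function(i)
    overlap_record(tab$gene_id[i], tab$region_kind[i]))
  st <- quad_store()
  store_load(st, build_nanopubs(list(), ov, tiny_ctx(), tiny_meta(),
                                policy = test_policy()), "corpus")
  brute <- function(kinds, mode) {
    per <- tapply(tab$region_kind, tab$gene_id, unique, simplify = FALSE)
    hit <- vapply(per, function(k)
      if (mode == "any") length(intersect(k, kinds)) > 0 else all(kinds %in% k),
      logical(1))
    sort(sprintf("http://bio2rdf.org/geneid:%s", names(per)[hit]))
  }
  for (kinds in list("cpg_island", c("cpg_island", "poised_promoter"),
                     region_kinds())) {
    for (mode in c("any", "all")) {
      expect_identical(query_genes_by_region(st, kinds, mode),
                       brute(kinds, mode),
                       info = paste(mode, paste(kinds, collapse = "+")))
    }
  }
  expect_error(query_genes_by_region(st, character(0)),
               class = "np_validation_error")
  expect_error(query_genes_by_region(st, "enhancer"),
               class = "np_validation_error")
})

test_that("GO URI mapping preserves the accession and inverts cleanly", {
  mapped <- map_go_uri("http://purl.obolibrary.org/obo/GO_0006914")
  expect_identical(as.character(mapped), "http://bio2rdf.org/go:0006914")
  back <- map_go_uri(mapped, from_ns = "http://bio2rdf.org/go:%s",
                     to_ns = "http://purl.obolibrary.org/obo/GO_%s")
  expect_identical(as.character(back), "http://purl.obolibrary.org/obo/GO_0006914")
  expect_error(map_go_uri("http://example.org/not-go"),
               class = "np_mapping_error")
})

test_that("the closure materializes seed subtrees into the closure graph", {
  fv <- fixture_vocab()
  # toy hierarchy: autophagy with two children, one grandchild
  edges <- data.frame(child = c("GO:9000001", "GO:9000002", "GO:9000003"),
                      parent = c("GO:0006914", "GO:0006914", "GO:9000001"),
                      stringsAsFactors = FALSE)
  labels <- c(nanopubr:::go_label_table(),
              "GO:9000001" = "a", "GO:9000002" = "b", "GO:9000003" = "c")
  st <- quad_store()
  store_load(st, nanopubr:::go_graph_from_edges(edges, labels,
                                                go_seed_config(), fv),
             "go-ontology")
  closure <- suppressWarnings(materialize_go_closure(st, fv$ontology_graph))
  q <- closure$quads[closure$quads$p == nanopubr:::SEED_ANCESTOR, , drop = FALSE]
  under_autophagy <- q$s[q$o == "http://bio2rdf.org/go:0006914"]
  expect_setequal(under_autophagy,
                  sprintf("http://bio2rdf.org/go:%s",
                          c("0006914", "9000001", "9000002", "9000003")))
  # a leaf seed maps only to itself
  leaf <- q$s[q$o == "http://bio2rdf.org/go:0010498"]
  expect_identical(leaf, "http://bio2rdf.org/go:0010498")
})

test_that("a term under two seeds appears once per seed-ancestor pair", {
  fv <- fixture_vocab()
  edges <- data.frame(child = c("GO:9000009", "GO:9000009"),
                      parent = c("GO:0006914", "GO:0006457"),
                      stringsAsFactors = FALSE)
  st <- quad_store()
  store_load(st, nanopubr:::go_graph_from_edges(
    edges, nanopubr:::go_label_table(), go_seed_config(), fv), "go-ontology")
  closure <- suppressWarnings(materialize_go_closure(st, fv$ontology_graph))
  q <- closure$quads[closure$quads$p == nanopubr:::SEED_ANCESTOR, , drop = FALSE]
  seeds_of <- q$o[q$s == "http://bio2rdf.org/go:9000009"]
  expect_setequal(seeds_of, c("http://bio2rdf.org/go:0006914",
                              "http://bio2rdf.org/go:0006457"))
})

test_that("absent seeds warn and subclass cycles fail loudly", {
  fv <- fixture_vocab()
  edges <- data.frame(child = "GO:9000001", parent = "GO:0006914",
                      stringsAsFactors = FALSE)
  st <- quad_store()
  store_load(st, nanopubr:::go_graph_from_edges(
    edges, nanopubr:::go_label_table()["GO:0006914"], go_seed_config(), fv),
    "go-ontology")
  expect_warning(
    materialize_go_closure(st, fv$ontology_graph,
                           go_seed_config(seeds = c("GO:0006914", "GO:0006457"))),
    class = "np_missing_seed")
  cyc <- data.frame(child = c("GO:9000001", "GO:0006914"),
                    parent = c("GO:0006914", "GO:9000001"),
                    stringsAsFactors = FALSE)
  st2 <- quad_store()
  store_load(st2, nanopubr:::go_graph_from_edges(
    cyc, nanopubr:::go_label_table()["GO:0006914"], go_seed_config(), fv),
    "go-ontology")
  expect_error(materialize_go_closure(st2, fv$ontology_graph),
               class = "np_cycle_error")
})

test_that("integration names the missing stage when a fixture graph is absent", {
  fx <- table2_fixture()
  st <- quad_store()
  store_load(st, fixture_corpus(fx, policy = uri_policy()), "corpus")
  store_load(st, fx$go_graph, "go-ontology")
  store_load(st, fx$annotation_graph, "go-annotations")
  # gene-info deliberately not loaded
  store_load(st, fx$drugtarget_graph, "drug-targets")
  err <- tryCatch(integrate_drug_targets(st),
                  np_integration_error = function(e) conditionMessage(e))
  expect_match(err, "gene-info")
  st2 <- quad_store()
  store_load(st2, fx$annotation_graph, "go-annotations")
  err2 <- tryCatch(integrate_drug_targets(st2),
                   np_integration_error = function(e) conditionMessage(e))
  expect_match(err2, "go-closure")
})
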