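# Shared test helpers: random RDF material, a tiny standard corpus, and an
# independent depth-first closure oracle.

test_policy <- function() uri_policy("https://example.org/np/")

random_iri <- function() {
  paste0("https://example.org/r/",
         paste(sample(c(letters, 0:9), 8, replace = TRUE), collapse = ""))
}

random_literal <- function() {
  lex <- paste(sample(c(letters, " ", "\"", "\\", "\n", "\t", "é"),
                      sample(1:12, 1), replace = TRUE), collapse = "")
  r <- stats::runif(1)
  if (r < 1 / 3) rdf_literal(lex)
  else if (r < 2 / 3) rdf_literal(lex, language = sample(c("en", "nl", "en-GB"), 1))
  else rdf_literal(lex, datatype = "http://www.w3.org/2001/XMLSchema#string")
}

random_bundle <- function(n = 20) {
  graphs <- replicate(max(1, n %/% 8), random_iri())
  quads <- do.call(rbind, lapply(seq_len(n), function(i) {
    o <- if (stats::runif(1) < 0.5) random_iri() else random_literal()
    quad(random_iri(), random_iri(), o, sample(graphs, 1))
  }))
  graph_bundle(quads, default_prefixes())
}

tiny_ctx <- function() {
  provenance_context(
    workflow_activity_iri = "https://example.org/activity/run-1",
    research_object_iri = "https://example.org/ro/pack-1",
    inputs = list(
      list(entity = "https://example.org/data/expr",
           ro_entity = "https://example.org/ro/pack-1/expr"),
      list(entity = "https://example.org/data/cpg",
           ro_entity = "https://example.org/ro/pack-1/cpg")),
    outputs = list(
      list(entity = "https://example.org/data/de-table",
           ro_entity = "https://example.org/ro/pack-1/de-table")),
    agent_iri = "https://orcid.org/0000-0000-0000-0001",
    execution_time = "2014-05-30T09:00:00Z")
}

tiny_meta <- function() {
  publication_meta(
    authors = c("https://orcid.org/0000-0000-0000-0001",
                "https://orcid.org/0000-0000-0000-0002"),
    created = "2014-06-01T12:00:00Z")
}

tiny_corpus <- function(gene_ids = c(25, 2280), kinds = "cpg_island",
                        policy = test_policy()) {
  de <- lapply(gene_ids, de_gene_record)
  ov <- unlist(lapply(gene_ids, function(g)
    lapply(kinds, function(k) overlap_record(g, k))), recursive = FALSE)
  build_nanopubs(de, ov, tiny_ctx(), tiny_meta(), policy = policy)
}

# Independent closure oracle: plain recursive depth-first search over an
# explicit child->parent edge table (never touches the package traversal).
dfs_descendants <- function(edges, root) {
  out <- character(0)
  visit <- function(node) {
    if (node %in% out) return(invisible(NULL))
    out <<- c(out, node)
    for (child in edges$child[edges$parent == node]) visit(child)
    invisible(NULL)
  }
  visit(root)
  sort(out, method = "radix")
}

# random DAG of GO-style accessions: edges only from higher to lower index,
# so acyclicity holds by construction
random_go_dag <- function(n_nodes, p_edge = 0.08) {
  accs <- sprintf("GO:%07d", 9000000 + seq_len(n_nodes))
  edges <- data.frame(child = character(0), parent = character(0),
                      stringsAsFactors = FALSE)
  for (i in 2:n_nodes) {
    parents <- which(stats::runif(i - 1) < p_edge)
    if (length(parents) == 0) parents <- sample(i - 1, 1)
    edges <- rbind(edges, data.frame(child = accs[i], parent = accs[parents],
                                     stringsAsFactors = FALSE))
  }
  list(accs = accs, edges = edges)
}

go_dag_bundle <- function(dag, fv = fixture_vocab(),
                          seeds_cfg = go_seed_config()) {
  labels <- stats::setNames(paste("process", seq_along(dag$accs)), dag$accs)
  nanopubr:::go_graph_from_edges(dag$edges, labels, seeds_cfg, fv)
}

python_bin <- function() Sys.which("python")
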