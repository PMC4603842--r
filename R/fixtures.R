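# Seeded synthetic fixtures. The generator emulates the *result tables* of
# the upstream analysis (differentially expressed genes in Huntington's
# disease caudate, and gene-promoter-region overlaps against CpG-island and
# chromatin-state tracks) together with small knowledge-graph slices shaped
# like the queried sources: a GO fragment with subclass structure, GO
# annotations, gene info with taxon, and DrugBank-like targets/drugs. It
# records ground truth for every downstream query so the whole pipeline can
# be checked end to end.

#' Specification for a synthetic fixture bundle
#'
#' Defaults describe a desk-scale study: a few hundred genes with roughly a
#' third differentially expressed (expression changes in the most affected
#' brain region are massive), promoter overlaps dominated by CpG islands and
#' promoter chromatin states, and a GO fragment a few levels deep under the
#' four seed processes.
#'
#' @param n_genes Number of genes in the universe.
#' @param de_fraction Proportion of genes differentially expressed.
#' @param region_kind_weights Named probabilities over [region_kinds()];
#'   must sum to 1.
#' @param go_depth,go_branching Depth and branching factor of the synthetic
#'   subclass tree grown under each seed term.
#' @param fraction_genes_annotated_to_seeds Proportion of genes annotated to
#'   a term inside some seed subtree.
#' @param drugs_per_target Integer range `c(min, max)` of drugs per target.
#' @param psa_range Uniform range (squared angstroms) PSA values are drawn
#'   from.
#' @param seed Integer RNG seed; same seed, same bundle, byte for byte.
#' @return An object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(n_genes = 200,
                         de_fraction = 0.3,
                         region_kind_weights = c(cpg_island = 0.40,
                                                 active_promoter = 0.20,
                                                 weak_promoter = 0.15,
                                                 poised_promoter = 0.15,
                                                 heterochromatic = 0.10),
                         go_depth = 3, go_branching = 2,
                         fraction_genes_annotated_to_seeds = 0.35,
                         drugs_per_target = c(0L, 3L),
                         psa_range = c(20, 120),
                         seed = 0L) {
  if (n_genes < 1) np_error("n_genes must be positive", "np_validation_error")
  if (de_fraction < 0 || de_fraction > 1) {
    np_error("de_fraction must be in [0, 1]", "np_validation_error")
  }
  if (fraction_genes_annotated_to_seeds < 0 || fraction_genes_annotated_to_seeds > 1) {
    np_error("fraction_genes_annotated_to_seeds must be in [0, 1]",
             "np_validation_error")
  }
  if (!setequal(names(region_kind_weights), region_kinds()) ||
      abs(sum(region_kind_weights) - 1) > 1e-9) {
    np_error("region_kind_weights must cover the 5 region kinds and sum to 1",
             "np_validation_error")
  }
  if (length(drugs_per_target) != 2 || drugs_per_target[1] > drugs_per_target[2] ||
      drugs_per_target[1] < 0) {
    np_error("drugs_per_target must be a non-negative c(min, max)",
             "np_validation_error")
  }
  if (psa_range[1] >= psa_range[2]) {
    np_error("psa_range must be an increasing range", "np_validation_error")
  }
  structure(list(
    n_genes = as.integer(n_genes), de_fraction = de_fraction,
    region_kind_weights = region_kind_weights[region_kinds()],
    go_depth = as.integer(go_depth), go_branching = as.integer(go_branching),
    fraction_genes_annotated_to_seeds = fraction_genes_annotated_to_seeds,
    drugs_per_target = as.integer(drugs_per_target), psa_range = psa_range,
    seed = as.integer(seed)),
    class = "fixture_spec")
}

go_label_table <- function() {
  c("GO:0010498" = "proteasomal protein catabolic process",
    "GO:0006914" = "autophagy",
    "GO:0006457" = "protein folding",
    "GO:0043335" = "protein unfolding")
}

# grow a subclass tree under `root_acc`; returns data.frame(child, parent)
# of GO accessions plus the full term list
grow_go_tree <- function(root_acc, depth, branching, counter_env) {
  edges <- data.frame(child = character(0), parent = character(0),
                      stringsAsFactors = FALSE)
  level <- root_acc
  for (d in seq_len(depth)) {
    nxt <- character(0)
    for (p in level) {
      for (b in seq_len(branching)) {
        counter_env$n <- counter_env$n + 1L
        child <- sprintf("GO:%07d", 8000000L + counter_env$n)
        edges <- rbind(edges, data.frame(child = child, parent = p,
                                         stringsAsFactors = FALSE))
        nxt <- c(nxt, child)
      }
    }
    level <- nxt
  }
  edges
}

# vectorized quad-table constructor for the bulk fixture builders
quads_vec <- function(s, p, o, g, o_type = "iri",
                      o_dt = NA_character_, o_lang = NA_character_) {
  if (length(s) == 0) return(empty_quads())
  data.frame(s = s, p = p, o = o, o_type = o_type, o_dt = o_dt,
             o_lang = o_lang, g = g, stringsAsFactors = FALSE)
}

go_graph_from_edges <- function(edges, labels, seeds_cfg, fv) {
  g <- fv$ontology_graph
  terms <- unique(c(edges$child, edges$parent, names(labels)))
  t_iri <- sprintf(seeds_cfg$ontology_ns, vapply(terms, go_accession, character(1)))
  lab <- ifelse(terms %in% names(labels), labels[terms],
                sprintf("synthetic process %s",
                        vapply(terms, go_accession, character(1))))
  quads <- rbind(
    quads_vec(t_iri, RDF_TYPE, OWL_CLASS, g),
    quads_vec(t_iri, RDFS_LABEL, unname(lab), g, o_type = "literal",
              o_lang = "en"),
    quads_vec(sprintf(seeds_cfg$ontology_ns,
                      vapply(edges$child, go_accession, character(1))),
              RDFS_SUBCLASS,
              sprintf(seeds_cfg$ontology_ns,
                      vapply(edges$parent, go_accession, character(1))), g))
  graph_bundle(quads)
}

annotation_graph_from_table <- function(ann_table, seeds_cfg, vocab, fv) {
  g <- fv$annotation_graph
  if (nrow(ann_table) == 0) {
    # keep the (empty-but-present) graph representable: a marker triple
    return(graph_bundle(rbind_quads(quad(
      g, RDF_TYPE, "http://rdfs.org/ns/void#Dataset", g))))
  }
  genes <- vapply(ann_table$gene_id, function(x) gene_iri(vocab, x), character(1))
  terms <- sprintf(seeds_cfg$annotation_ns,
                   vapply(ann_table$go_id, go_accession, character(1)))
  graph_bundle(quads_vec(genes, fv$has_go_annotation, terms, g))
}

geneinfo_graph_from_table <- function(info, vocab, fv) {
  g <- fv$geneinfo_graph
  gi <- vapply(info$gene_id, function(x) gene_iri(vocab, x), character(1))
  graph_bundle(rbind(
    quads_vec(gi, fv$gene_symbol, info$symbol, g, o_type = "literal"),
    quads_vec(gi, fv$taxon,
              sprintf("http://bio2rdf.org/taxonomy:%s", info$taxon), g)))
}

drugtarget_graph_from_tables <- function(targets, drugs, vocab, fv) {
  g <- fv$drugtarget_graph
  tgene <- vapply(targets$gene_id, function(x) gene_iri(vocab, x), character(1))
  with_psa <- drugs[!is.na(drugs$psa), , drop = FALSE]
  with_desc <- drugs[!is.na(drugs$description), , drop = FALSE]
  quads <- rbind(
    quads_vec(targets$target, fv$target_gene, tgene, g),
    quads_vec(drugs$drug, fv$drug_target, drugs$target, g),
    quads_vec(drugs$drug, fv$drug_name, drugs$drug_name, g, o_type = "literal"),
    quads_vec(with_psa$drug, fv$drug_psa,
              vapply(with_psa$psa, format, character(1), scientific = FALSE),
              g, o_type = "literal", o_dt = XSD_DOUBLE),
    quads_vec(with_desc$drug, fv$drug_description, with_desc$description, g,
              o_type = "literal"))
  if (nrow(quads) == 0) {
    quads <- quad(g, RDF_TYPE, "http://rdfs.org/ns/void#Dataset", g)
  }
  graph_bundle(quads)
}

# ground-truth integration rows computed from the generator's bookkeeping
# (never from the store): one row per (gene, seed, target, drug)
truth_integration <- function(genes, ann_table, seed_of_term, targets, drugs,
                              vocab, kinds = "cpg_island", mode = "any") {
  labels <- go_label_table()
  rows <- empty_rows()
  for (i in seq_len(nrow(genes))) {
    gene <- genes[i, ]
    if (!gene$de) next
    gk <- unlist(gene$kinds)
    ok <- if (mode == "any") length(intersect(gk, kinds)) > 0 else all(kinds %in% gk)
    if (!ok) next
    if (gene$taxon != "9606") next
    terms <- ann_table$go_id[ann_table$gene_id == gene$gene_id]
    seeds_hit <- unique(stats::na.omit(unname(seed_of_term[terms])))
    if (length(seeds_hit) == 0) next
    tg <- targets$target[targets$gene_id == gene$gene_id]
    if (length(tg) == 0) next
    for (sd in seeds_hit) for (t in tg) {
      dr <- drugs[drugs$target == t, , drop = FALSE]
      if (nrow(dr) == 0) {
        rows <- rbind(rows, data.frame(
          gene = gene_iri(vocab, gene$gene_id), gene_symbol = gene$symbol,
          go_label = unname(labels[sd]), target = t, drug = NA_character_,
          drug_name = NA_character_, psa = NA_real_, stringsAsFactors = FALSE))
      } else {
        for (j in seq_len(nrow(dr))) {
          rows <- rbind(rows, data.frame(
            gene = gene_iri(vocab, gene$gene_id), gene_symbol = gene$symbol,
            go_label = unname(labels[sd]), target = t, drug = dr$drug[j],
            drug_name = dr$drug_name[j], psa = dr$psa[j],
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  sort_rows(unique(rows))
}

#' Generate a synthetic fixture bundle
#'
#' Deterministic for a given spec: the same seed reproduces the same tables,
#' graphs and truth byte for byte.
#'
#' @param spec A [fixture_spec()].
#' @param vocab A [vocabulary_config()].
#' @param fv A [fixture_vocab()].
#' @return An object of class `"fixture_bundle"` with fields `de_table`,
#'   `overlap_table`, `go_graph`, `annotation_graph`, `geneinfo_graph`,
#'   `drugtarget_graph`, `ro_manifest`, `meta`, and `truth` (the generator's
#'   bookkeeping of which genes satisfy which downstream conditions).
#' @export
generate_fixture <- function(spec = fixture_spec(), vocab = vocabulary_config(),
                             fv = fixture_vocab()) {
  stopifnot(inherits(spec, "fixture_spec"))
  seeds_cfg <- go_seed_config()
  withr::with_seed(spec$seed, {
    n <- spec$n_genes
    # synthetic gene ids live in a reserved high range so they can never
    # collide with real NCBI ids
    gene_id <- sort(sample(900000000:999999999, n))
    genes <- data.frame(gene_id = gene_id,
                        symbol = sprintf("SYN%04d", seq_len(n)),
                        stringsAsFactors = FALSE)
    genes$de <- stats::runif(n) < spec$de_fraction
    genes$taxon <- ifelse(stats::runif(n) < 0.95, "9606", "10090")

    # overlap rows exist for DE genes only (the workflow overlapped the
    # promoters of the deregulated genes with the epigenetic tracks)
    overlap_rows <- list()
    genes$kinds <- vector("list", n)
    for (i in seq_len(n)) {
      if (!genes$de[i]) { genes$kinds[[i]] <- character(0); next }
      k <- sample(0:3, 1, prob = c(0.10, 0.45, 0.30, 0.15))
      kinds <- if (k == 0) character(0) else
        sample(region_kinds(), k, replace = TRUE,
               prob = unname(spec$region_kind_weights))
      genes$kinds[[i]] <- unique(kinds)
      for (j in seq_along(kinds)) {
        overlap_rows[[length(overlap_rows) + 1L]] <- data.frame(
          gene_id = genes$gene_id[i],
          promoter_key = sprintf("p%d", j),
          region_kind = kinds[j], stringsAsFactors = FALSE)
      }
    }
    overlap_table <- if (length(overlap_rows) == 0) {
      data.frame(gene_id = numeric(0), promoter_key = character(0),
                 region_kind = character(0), stringsAsFactors = FALSE)
    } else unique(do.call(rbind, overlap_rows))

    # GO fragment: a subtree under each seed plus a decoy subtree
    counter <- new.env(); counter$n <- 0L
    labels <- c(go_label_table(), "GO:7000001" = "decoy process")
    edge_list <- lapply(c(names(go_label_table()), "GO:7000001"), function(s)
      grow_go_tree(s, spec$go_depth, spec$go_branching, counter))
    edges <- do.call(rbind, edge_list)
    seed_of_term <- character(0)
    for (i in seq_along(edge_list)) {
      root <- c(names(go_label_table()), "GO:7000001")[i]
      if (root == "GO:7000001") next
      members <- unique(c(root, edge_list[[i]]$child))
      seed_of_term[members] <- root
    }
    decoy_terms <- unique(c("GO:7000001", edge_list[[length(edge_list)]]$child))

    # annotations
    n_seed_ann <- round(n * spec$fraction_genes_annotated_to_seeds)
    seed_ann_genes <- sample(genes$gene_id, n_seed_ann)
    remaining <- setdiff(genes$gene_id, seed_ann_genes)
    decoy_ann_genes <- sample(remaining, round(length(remaining) * 0.3))
    ann_rows <- list()
    for (gid in seed_ann_genes) {
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        gene_id = gid, go_id = sample(names(seed_of_term), 1),
        stringsAsFactors = FALSE)
    }
    for (gid in decoy_ann_genes) {
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        gene_id = gid, go_id = sample(decoy_terms, 1), stringsAsFactors = FALSE)
    }
    ann_table <- if (length(ann_rows) == 0) {
      data.frame(gene_id = numeric(0), go_id = character(0),
                 stringsAsFactors = FALSE)
    } else do.call(rbind, ann_rows)

    # targets and drugs
    has_target <- stats::runif(n) < 0.5
    targets <- data.frame(gene_id = genes$gene_id[has_target],
                          stringsAsFactors = FALSE)
    targets$target <- sprintf("http://bio2rdf.org/drugbank_target:9%05d",
                              seq_len(nrow(targets)))
    drug_rows <- list()
    ndrug <- 0L
    for (i in seq_len(nrow(targets))) {
      k <- sample(spec$drugs_per_target[1]:spec$drugs_per_target[2], 1)
      if (k == 0) next
      for (j in seq_len(k)) {
        ndrug <- ndrug + 1L
        drug_rows[[length(drug_rows) + 1L]] <- data.frame(
          target = targets$target[i],
          drug = sprintf("http://bio2rdf.org/drugbank:DBS%05d", ndrug),
          drug_name = sprintf("SYNDRUG%04d", ndrug),
          psa = round(stats::runif(1, spec$psa_range[1], spec$psa_range[2]), 1),
          description = sprintf("synthetic compound %d", ndrug),
          stringsAsFactors = FALSE)
      }
    }
    drugs <- if (length(drug_rows) == 0) {
      data.frame(target = character(0), drug = character(0),
                 drug_name = character(0), psa = numeric(0),
                 description = character(0), stringsAsFactors = FALSE)
    } else do.call(rbind, drug_rows)

    de_table <- genes[genes$de, c("gene_id", "symbol")]
    rownames(de_table) <- NULL

    ro_iri <- "https://example.org/ro/hd-epigenetics-run"
    ro_manifest <- list(
      ro_iri = ro_iri,
      aggregates = c(paste0(ro_iri, "/input/expression-matrix"),
                     paste0(ro_iri, "/input/cpg-islands-track"),
                     paste0(ro_iri, "/input/chromatin-states-track"),
                     paste0(ro_iri, "/output/de-gene-table"),
                     paste0(ro_iri, "/output/overlap-table")))
    meta <- publication_meta(
      authors = c("https://orcid.org/0000-0000-0000-0001",
                  "https://orcid.org/0000-0000-0000-0002"),
      contributors = "https://orcid.org/0000-0000-0000-0003",
      created = "2014-06-01T12:00:00Z", version = "1.0")

    truth <- list(
      de_genes = sort(vapply(de_table$gene_id, function(g) gene_iri(vocab, g),
                             character(1)), method = "radix"),
      gene_kinds = stats::setNames(genes$kinds,
                                   vapply(genes$gene_id, function(g)
                                     gene_iri(vocab, g), character(1))),
      integration = truth_integration(genes, ann_table, seed_of_term,
                                      targets, drugs, vocab))

    structure(list(
      spec = spec,
      de_table = de_table,
      overlap_table = overlap_table,
      go_graph = go_graph_from_edges(edges, labels, seeds_cfg, fv),
      annotation_graph = annotation_graph_from_table(ann_table, seeds_cfg, vocab, fv),
      geneinfo_graph = geneinfo_graph_from_table(
        genes[, c("gene_id", "symbol", "taxon")], vocab, fv),
      drugtarget_graph = drugtarget_graph_from_tables(targets, drugs, vocab, fv),
      ro_manifest = ro_manifest,
      meta = meta,
      truth = truth), class = "fixture_bundle")
  })
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle: %d DE genes, %d overlap rows, go: %d quads>\n",
              nrow(x$de_table), nrow(x$overlap_table), bundle_size(x$go_graph)))
  invisible(x)
}

#' Build the nanopublication corpus for a fixture bundle
#'
#' @param bundle A `"fixture_bundle"`.
#' @param vocab,policy Template configuration.
#' @return List of `"nanopublication"` objects (one per DE row plus one per
#'   overlap row).
#' @export
fixture_corpus <- function(bundle, vocab = vocabulary_config(),
                           policy = uri_policy()) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  de_recs <- lapply(seq_len(nrow(bundle$de_table)), function(i)
    de_gene_record(bundle$de_table$gene_id[i], bundle$de_table$symbol[i]))
  ov_recs <- lapply(seq_len(nrow(bundle$overlap_table)), function(i)
    overlap_record(bundle$overlap_table$gene_id[i],
                   bundle$overlap_table$region_kind[i],
                   bundle$overlap_table$promoter_key[i]))
  ctx <- provenance_context_from_manifest(
    bundle$ro_manifest,
    workflow_activity_iri = paste0(bundle$ro_manifest$ro_iri, "/activity/run-1"),
    agent_iri = bundle$meta$authors[[1]],
    execution_time = "2014-05-30T09:00:00Z")
  build_nanopubs(de_recs, ov_recs, ctx, bundle$meta, vocab, policy)
}

#' Load a fixture bundle (and its corpus) into a quad store
#'
#' @param bundle A `"fixture_bundle"`.
#' @param store Target store (a fresh one by default).
#' @param corpus Optional pre-built corpus (built from the bundle if `NULL`).
#' @param vocab,policy Template configuration.
#' @return The loaded [quad_store()].
#' @export
fixture_store <- function(bundle, store = quad_store(), corpus = NULL,
                          vocab = vocabulary_config(), policy = uri_policy()) {
  if (is.null(corpus)) corpus <- fixture_corpus(bundle, vocab, policy)
  store_load(store, corpus, "nanopub-corpus")
  store_load(store, bundle$go_graph, "go-ontology")
  store_load(store, bundle$annotation_graph, "go-annotations")
  store_load(store, bundle$geneinfo_graph, "gene-info")
  store_load(store, bundle$drugtarget_graph, "drug-targets")
  store
}

#' Write a fixture bundle to a directory
#'
#' Plain-text formats throughout: TSV tables, Turtle graphs, JSON manifest
#' and truth, YAML metadata.
#'
#' @param bundle A `"fixture_bundle"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  utils::write.table(bundle$de_table, p("de.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$overlap_table, p("overlap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_rdf_file(bundle$go_graph, p("go-ontology.ttl"))
  write_rdf_file(bundle$annotation_graph, p("go-annotations.ttl"))
  write_rdf_file(bundle$geneinfo_graph, p("gene-info.ttl"))
  write_rdf_file(bundle$drugtarget_graph, p("drug-targets.ttl"))
  jsonlite::write_json(bundle$ro_manifest, p("ro-manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(
    list(de_genes = bundle$truth$de_genes,
         gene_kinds = bundle$truth$gene_kinds,
         integration = bundle$truth$integration),
    p("truth.json"), auto_unbox = FALSE, dataframe = "columns",
    na = "null", digits = NA, pretty = TRUE)
  yaml::write_yaml(list(
    authors = as.list(bundle$meta$authors),
    contributors = as.list(bundle$meta$contributors),
    created = bundle$meta$created, version = bundle$meta$version,
    license = bundle$meta$license_iri), p("meta.yaml"))
  invisible(dir)
}

#' Read a fixture bundle back from a directory
#'
#' @param dir Directory written by [write_fixture()].
#' @param fv A [fixture_vocab()] (supplies the graph IRIs the Turtle files
#'   are re-homed into).
#' @return A `"fixture_bundle"` (without the `spec` field).
#' @export
read_fixture <- function(dir, fv = fixture_vocab()) {
  if (!dir.exists(dir)) np_error(sprintf("no such directory: %s", dir), "np_io_error")
  needed <- c("de.tsv", "overlap.tsv", "go-ontology.ttl", "go-annotations.ttl",
              "gene-info.ttl", "drug-targets.ttl", "ro-manifest.json",
              "truth.json", "meta.yaml")
  missing <- needed[!file.exists(file.path(dir, needed))]
  if (length(missing) > 0) {
    np_error(sprintf("fixture directory %s is missing component(s): %s", dir,
                     paste(missing, collapse = ", ")), "np_io_error")
  }
  p <- function(f) file.path(dir, f)
  read_tt <- function(f, g) read_quads(readLines(p(f), warn = FALSE),
                                       "turtle", default_graph = g)
  truth_raw <- jsonlite::fromJSON(p("truth.json"), simplifyVector = TRUE)
  integration <- as.data.frame(truth_raw$integration, stringsAsFactors = FALSE)
  if (nrow(integration) == 0) integration <- empty_rows()
  integration$psa <- as.numeric(integration$psa)
  gene_kinds <- lapply(truth_raw$gene_kinds, function(x) as.character(unlist(x)))
  m <- yaml::read_yaml(p("meta.yaml"))
  structure(list(
    spec = NULL,
    de_table = utils::read.delim(p("de.tsv"), colClasses = c("numeric", "character")),
    overlap_table = utils::read.delim(p("overlap.tsv"),
                                      colClasses = c("numeric", "character", "character")),
    go_graph = read_tt("go-ontology.ttl", fv$ontology_graph),
    annotation_graph = read_tt("go-annotations.ttl", fv$annotation_graph),
    geneinfo_graph = read_tt("gene-info.ttl", fv$geneinfo_graph),
    drugtarget_graph = read_tt("drug-targets.ttl", fv$drugtarget_graph),
    ro_manifest = jsonlite::fromJSON(p("ro-manifest.json")),
    meta = publication_meta(authors = unlist(m$authors),
                            contributors = as.character(unlist(m$contributors)),
                            created = m$created, version = m$version,
                            license_iri = m$license),
    truth = list(de_genes = as.character(truth_raw$de_genes),
                 gene_kinds = gene_kinds,
                 integration = sort_rows(integration))),
    class = "fixture_bundle")
}
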