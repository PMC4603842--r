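test_that("assembly yields four distinct graphs and a four-triple head", {
  np <- tiny_corpus(gene_ids = 25)[[1]]
  gs <- vapply(c("head", "assertion", "provenance", "pubinfo"),
               function(p) unique(np[[p]]$quads$g), character(1))
  expect_length(unique(gs), 4L)
  expect_true(all(startsWith(gs, np$nanopub_iri)))
  expect_identical(bundle_size(np$head), 4L)
  expect_identical(nrow(validate(np)), 0L)
})

test_that("assembling the same inputs twice is quad-identical", {
  c1 <- tiny_corpus(); c2 <- tiny_corpus()
  b1 <- do.call(bundle_union, lapply(c1, nanopub_bundle))
  b2 <- do.call(bundle_union, lapply(c2, nanopub_bundle))
  expect_identical(write_quads(b1, "nquads"), write_quads(b2, "nquads"))
})

test_that("empty assertion graphs are refused", {
  np <- tiny_corpus(gene_ids = 25)[[1]]
  expect_error(assemble(graph_bundle(), np$provenance, np$pubinfo, test_policy()),
               class = "np_assembly_error")
})

test_that("constructed violations are reported with their codes", {
  np <- tiny_corpus(gene_ids = 25)[[1]]
  # sever the provenance -> assertion link
  broken <- np
  q <- broken$provenance$quads
  a_g <- unique(np$assertion$quads$g)
  q$s[q$s == a_g] <- "https://example.org/elsewhere"
  q$o[q$o == a_g & q$o_type == "iri"] <- "https://example.org/elsewhere"
  broken$provenance <- graph_bundle(q)
  expect_true("PROV_NO_ASSERTION_LINK" %in% validate(broken)$code)
  # off-subject publication info
  broken2 <- np
  q2 <- broken2$pubinfo$quads
  q2$s[1] <- "https://example.org/not-the-nanopub"
  broken2$pubinfo <- graph_bundle(q2)
  expect_true("PUBINFO_OFF_SUBJECT" %in% validate(broken2)$code)
  # mangled head
  broken3 <- np
  broken3$head <- graph_bundle(np$head$quads[-1, ])
  expect_true("HEAD_SHAPE" %in% validate(broken3)$code)
})

test_that("single-quad deletions invalidate exactly the required quads", {
  withr::local_seed(303)
  np <- tiny_corpus(gene_ids = 25)[[2]]
  a_g <- unique(np$assertion$quads$g)
  parts <- c("head", "assertion", "provenance", "pubinfo")
  for (rep in 1:40) {
    part <- sample(parts, 1)
    q <- np[[part]]$quads
    i <- sample(nrow(q), 1)
    mutated <- np
    mutated[[part]] <- graph_bundle(q[-i, ])
    # oracle: a deletion is fatal iff it hits the head, empties a graph, or
    # removes the provenance graph's last mention of the assertion IRI
    qq <- q[-i, ]
    fatal <- part == "head" ||
      nrow(qq) == 0 ||
      (part == "provenance" &&
         !any(qq$s == a_g | (qq$o_type == "iri" & qq$o == a_g)))
    expect_identical(nrow(validate(mutated)) > 0, fatal,
                     info = sprintf("%s row %d", part, i))
  }
})

test_that("nanopublications and corpora survive file round trips", {
  nps <- tiny_corpus(gene_ids = c(25, 2280, 5707),
                     kinds = c("cpg_island", "poised_promoter"))
  d <- withr::local_tempdir()
  one <- file.path(d, "one.trig")
  write_nanopub(nps[[1]], one)
  back <- read_nanopub(one)
  for (p in c("head", "assertion", "provenance", "pubinfo")) {
    expect_true(bundle_equal(graph_bundle(nps[[1]][[p]]$quads),
                             graph_bundle(back[[p]]$quads)))
  }
  # corpus of many in one file, both dialects
  for (dia in c("trig", "nquads")) {
    f <- file.path(d, paste0("corpus.", if (dia == "trig") "trig" else "nq"))
    write_corpus(nps, f, dia)
    got <- read_corpus(f)
    expect_length(got, length(nps))
    expect_true(bundle_equal(
      do.call(bundle_union, lapply(nps, nanopub_bundle)),
      do.call(bundle_union, lapply(got, nanopub_bundle))))
  }
})

test_that("files without the four-graph structure are rejected", {
  np <- tiny_corpus(gene_ids = 25)[[1]]
  d <- withr::local_tempdir()
  f <- file.path(d, "broken.trig")
  b <- nanopub_bundle(np)
  b3 <- graph_bundle(b$quads[b$quads$g != unique(np$pubinfo$quads$g), ],
                     default_prefixes())
  writeLines(write_quads(b3, "trig"), f, sep = "")
  expect_error(read_nanopub(f), class = "np_structure_error")
})

test_that("a DE table of N rows and overlap table of M rows gives N+M valid nanopubs", {
  nps <- tiny_corpus(gene_ids = c(25, 2280, 10105),
                     kinds = c("cpg_island", "weak_promoter"))
  expect_length(nps, 3 + 3 * 2)
  expect_true(all(vapply(nps, is_valid_nanopub, logical(1))))
  # graphs are disjoint: no quad belongs to two nanopublications
  all_graphs <- unlist(lapply(nps, function(np)
    unique(nanopub_bundle(np)$quads$g)))
  expect_identical(anyDuplicated(all_graphs), 0L)
})

test_that("one hundred generated nanopublications batch through one file", {
  nps <- tiny_corpus(gene_ids = 900000001:900000050)
  expect_length(nps, 100L)
  f <- withr::local_tempfile(fileext = ".trig")
  write_corpus(nps, f)
  expect_length(read_corpus(f), 100L)
})
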