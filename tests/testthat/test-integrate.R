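table2_expected_pairs <- function() {
  data.frame(
    gene_symbol = c(rep("ABL1", 4), rep("FKBP1A", 3), "PPIF",
                    "PSMD1", rep("TUBA4A", 3)),
    drug_name = c("Adenosine triphosphate", "Dasatinib", "Imatinib", "Nilotinib",
                  "Pimecrolimus", "Sirolimus", "Tacrolimus",
                  "L-Proline", "Bortezomib",
                  "Podofilox", "Vincristine", "cabazitaxel"),
    stringsAsFactors = FALSE)
}

test_that("the packaged worked example recovers the printed drug pairs exactly", {
  fx <- table2_fixture()
  st <- fixture_store(fx)
  rows <- integrate_drug_targets(st)
  pairs <- drug_level_pairs(rows)
  rownames(pairs) <- NULL
  expect_identical(pairs, table2_expected_pairs())
  # spot checks against printed identifiers
  abl1 <- rows[rows$gene_symbol == "ABL1", ]
  expect_true(all(abl1$gene == "http://bio2rdf.org/geneid:25"))
  expect_true(all(abl1$go_label == "autophagy"))
  expect_true(all(abl1$target == "http://bio2rdf.org/drugbank_target:17"))
  expect_true("http://bio2rdf.org/drugbank:DB00619" %in% abl1$drug)
  psmd1 <- rows[rows$gene_symbol == "PSMD1", ]
  expect_identical(psmd1$go_label, "proteasomal protein catabolic process")
  expect_identical(psmd1$drug_name, "Bortezomib")
  fkbp <- rows[rows$gene_symbol == "FKBP1A", ]
  expect_true(all(fkbp$target == "http://bio2rdf.org/drugbank_target:768"))
  tub <- rows[rows$gene_symbol == "TUBA4A", ]
  expect_true("Vincristine" %in% tub$drug_name)
})

test_that("blank-cell genes appear at target level but never at drug level", {
  rows <- integrate_drug_targets(fixture_store(table2_fixture()))
  ppis <- rows[rows$gene_symbol %in% c("PPIA", "PPIB", "PPIC"), ]
  expect_identical(nrow(ppis), 3L)
  expect_true(all(is.na(ppis$drug)))
  expect_false(any(c("PPIA", "PPIB", "PPIC") %in%
                     drug_level_pairs(rows)$gene_symbol))
})

test_that("a DE gene missing from the GO annotations yields zero rows", {
  rows <- integrate_drug_targets(fixture_store(table2_fixture()))
  expect_false("HTT" %in% rows$gene_symbol)
  expect_false("http://bio2rdf.org/geneid:3064" %in% rows$gene)
})

test_that("staged sub-queries equal the composed integration query", {
  fx <- table2_fixture()
  expect_equal(integrate_drug_targets_staged(fixture_store(fx)),
               integrate_drug_targets(fixture_store(fx)))
  fx2 <- generate_fixture(fixture_spec(n_genes = 80, seed = 21))
  expect_equal(integrate_drug_targets_staged(fixture_store(fx2)),
               integrate_drug_targets(fixture_store(fx2)))
})

test_that("adding drug-target statements never removes result rows", {
  fx <- generate_fixture(fixture_spec(n_genes = 80, seed = 33))
  st <- fixture_store(fx)
  before <- integrate_drug_targets(st)
  fv <- fixture_vocab()
  # a fresh drug on a target that already appears in the result
  tgt <- before$target[1]
  extra <- graph_bundle(nanopubr:::rbind_quads(
    quad("http://bio2rdf.org/drugbank:DBS99999", fv$drug_target, tgt,
         fv$drugtarget_graph),
    quad("http://bio2rdf.org/drugbank:DBS99999", fv$drug_name,
         rdf_literal("SYNDRUG9999"), fv$drugtarget_graph)))
  store_load(st, extra, "drug-targets-extra")
  after <- integrate_drug_targets(st)
  key <- function(r) {
    r <- r[!is.na(r$drug), ]
    paste(r$gene, r$go_label, r$target, r$drug)
  }
  expect_true(all(key(before) %in% key(after)))
  expect_true(all(paste(before$gene, before$target) %in%
                    paste(after$gene, after$target)))
  expect_true(any(after$drug == "http://bio2rdf.org/drugbank:DBS99999",
                  na.rm = TRUE))
})

test_that("PSA filtering is strictly below the threshold", {
  rows <- data.frame(gene = "g", gene_symbol = "S", go_label = "l",
                     target = "t", drug = c("d1", "d2", "d3"),
                     drug_name = c("a", "b", "c"),
                     psa = c(59.9, 60, 60.1), stringsAsFactors = FALSE)
  kept <- filter_psa(rows)
  expect_identical(kept$psa, 59.9)
  expect_identical(nrow(filter_psa(rows[0, ])), 0L)
  # missing PSA: policy-controlled with a warning counting the rows
  rows$psa <- NA_real_
  w <- tryCatch(filter_psa(rows, missing = "keep"),
                np_missing_psa = function(e) conditionMessage(e))
  expect_match(w, "^3 row")
  expect_identical(nrow(suppressWarnings(filter_psa(rows, missing = "keep"))), 3L)
  expect_identical(nrow(suppressWarnings(filter_psa(rows, missing = "drop"))), 0L)
})

test_that("on the worked example only low-PSA drugs survive prioritization", {
  rows <- integrate_drug_targets(fixture_store(table2_fixture()))
  kept <- suppressWarnings(filter_psa(rows))
  expect_true(all(kept$psa < 60))
  expect_true("L-Proline" %in% kept$drug_name)
})

test_that("integration rows write as TSV in the printed column order", {
  rows <- integrate_drug_targets(fixture_store(table2_fixture()))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_integration_tsv(rows, f)
  header <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_identical(header[1:5], c("gene", "gene_symbol", "go_label",
                                  "target", "drug"))
})
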