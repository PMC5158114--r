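test_that("keyword classification covers the quoted examples and the fallback", {
  expect_equal(classify_function("lipase"), "Lipid metabolism and ketogenesis")
  expect_equal(classify_function(""), "Unknown function")
  expect_equal(classify_function(NA_character_), "Unknown function")
  expect_equal(classify_function("ribosomal protein L2"),
               "Replication, transcription, translation, and DNA repair")
  expect_equal(classify_function("ABC transporter permease"),
               "Transport, secretion, and efflux")
})

test_that("planted keyword annotations classify to their groups exactly", {
  vocab <- metasecretome:::synthetic_annotations()
  withr::with_seed(17, {
    planted <- sample(names(vocab), 200, replace = TRUE)
    ann <- vapply(planted, function(g) sample(vocab[[g]], 1), character(1),
                  USE.NAMES = FALSE)
  })
  expect_equal(classify_function(ann), planted)
})

test_that("first-matching-rule order is respected", {
  rules <- tibble::tibble(pattern = c("lip", "lipase"),
                          group = c("G1", "G2"))
  expect_equal(classify_function("lipase", rules), "G1")
  expect_equal(classify_function("other", rules), "Unknown function")
})

test_that("pathway roles map the published enzyme names into the schema", {
  got <- classify_pathway_role(c("acyl-CoA dehydrogenase",
                                 "lipid-binding protein",
                                 "3-hydroxyacyl-CoA dehydrogenase",
                                 "enoyl-CoA hydratase",
                                 "acetyl-CoA acetyltransferase",
                                 "feruloyl esterase",
                                 "ribosomal protein L2"))
  expect_equal(got$process,
               c("beta_oxidation", "suberin_adhesion", "beta_oxidation",
                 "beta_oxidation", "beta_oxidation", "feruloyl_esterase", NA))
  expect_equal(got$step,
               c("acyl_coa_dehydrogenase", NA, "hydroxyacyl_coa_dehydrogenase",
                 "enoyl_coa_hydratase", "acetyl_coa_acetyltransferase", NA, NA))
})

test_that("pathway rollups sum NSpC over the catalog's process members", {
  ev <- rhodanobacter_lipid_table(long = TRUE)
  cat4 <- dplyr::filter(pathway_catalog(),
                        organism == "Rhodanobacter thiooxydans")
  expect_equal(pathway_rollup(ev, cat4, "beta_oxidation", 5), 1.39)
  expect_equal(pathway_rollup(ev, cat4, "regulation", 5), 0.15)
  expect_equal(pathway_rollup(ev[0, ], cat4, "beta_oxidation", 5), 0)
  expect_error(pathway_rollup(ev, cat4, "glycolysis", 5),
               class = "ms_domain_error")
  # a brute-force sum over the same accessions agrees
  acc <- cat4$accession[cat4$process == "beta_oxidation"]
  manual <- sum(ev$nspc[ev$accession %in% acc & ev$day == 5])
  expect_equal(pathway_rollup(ev, cat4, "beta_oxidation", 5), manual)
})

test_that("functional classification partitions total NSpC", {
  withr::with_seed(23, {
    ev <- toy_evidence(50)
    vocab <- unlist(metasecretome:::synthetic_annotations())
    ev$annotation <- sample(vocab, 50, replace = TRUE)
    ev$spc <- sample(1:20, 50, replace = TRUE)
  })
  m <- function_matrix(ev)
  expect_equal(sum(tidy(m)$nspc, na.rm = TRUE), sum(ev$spc / ev$mw_kda))
  # beta-oxidation roll-up never exceeds the lipid-group total on the same set
  roles <- classify_pathway_role(ev$annotation)
  roles$accession <- ev$accession
  lipid_total <- sum_nspc(
    dplyr::mutate(ev, fg = classify_function(annotation)), "fg")
  lip <- lipid_total$nspc[lipid_total$entity == "Lipid metabolism and ketogenesis"]
  expect_lte(pathway_rollup(ev, roles, "beta_oxidation", 5), lip)
})
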