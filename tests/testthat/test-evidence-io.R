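test_that("a well-formed long table round-trips through the reader", {
  df <- toy_evidence(3)
  path <- write_tmp_tsv(df)
  got <- read_evidence_table(path)
  expect_equal(nrow(got), 3)
  expect_equal(got$accession, df$accession)
  expect_equal(got$spc, df$spc)
  expect_type(got$day, "integer")
})

test_that("malformed rows are rejected with row-indexed diagnostics", {
  df <- toy_evidence(3)
  df$spc[2] <- -1L
  expect_error(read_evidence_table(write_tmp_tsv(df)),
               "row 2.*non-negative", class = "ms_validation_error")
  df <- toy_evidence(3)
  df$protein_prob[3] <- 1.7
  expect_error(read_evidence_table(write_tmp_tsv(df)),
               "row 3.*probability", class = "ms_validation_error")
  df <- toy_evidence(2)
  df$genera[1] <- "Pseudomonas;Pseudomonas"
  expect_error(read_evidence_table(write_tmp_tsv(df)),
               "duplicated candidate genus", class = "ms_validation_error")
})

test_that("schema and empty-input errors name the problem", {
  df <- toy_evidence(2)
  df$mw_kda <- NULL
  expect_error(read_evidence_table(write_tmp_tsv(df)), "mw_kda",
               class = "ms_schema_error")
  empty <- toy_evidence(1)[0, ]
  expect_error(read_evidence_table(write_tmp_tsv(empty)),
               class = "ms_empty_input")
})

test_that("wide-form reader normalizes to long form, dropping absent cells", {
  wide <- tibble::tibble(
    accession = c("A1", "A2"),
    mw_kda = c(30, 40),
    protein_prob = c(1, 1),
    n_unique_peptides_95 = c(3L, 3L),
    spc_5 = c(4L, NA),
    spc_10 = c(2L, 6L)
  )
  long <- read_evidence_wide(write_tmp_tsv(wide))
  expect_equal(nrow(long), 3)
  expect_setequal(long$day, c(5L, 10L))
  expect_false(any(long$accession == "A2" & long$day == 5))
})

test_that("per-peptide tables nest into a peptides list-column", {
  df <- toy_evidence(2)
  pep <- tibble::tibble(
    accession = c("P001", "P001", "P002"),
    sequence = c("AAK", "GGR", "MMK"),
    peptide_prob = c(0.99, 0.80, 0.97),
    is_unique = c(TRUE, TRUE, FALSE)
  )
  got <- read_evidence_table(write_tmp_tsv(df), peptide_path = write_tmp_tsv(pep))
  expect_true(is.list(got$peptides))
  expect_equal(nrow(got$peptides[[1]]), 2)
  bad <- pep
  bad$peptide_prob[1] <- 1.2
  expect_error(
    read_evidence_table(write_tmp_tsv(df), peptide_path = write_tmp_tsv(bad)),
    class = "ms_validation_error")
})

test_that("packaged table transcriptions all parse", {
  expect_equal(nrow(community_genus_matrix()), 34)
  t2 <- rhodanobacter_lipid_table()
  expect_equal(nrow(t2), 50)
  expect_equal(sum(t2$localization == "extracellular" & !is.na(t2$nspc_day5)), 12)
  t3 <- myxococcus_lipid_table()
  expect_equal(nrow(t3), 38)
  expect_equal(t3$note[t3$accession == "Q1D009"], "discussed_outside_lipid_group")
  cat4 <- pathway_catalog()
  expect_true(all(cat4$process %in% c(
    "suberin_adhesion", "depolymerization", "feruloyl_esterase",
    "lipid_entry", "long_chain_fatty_acid_transport", "coa_activation",
    "beta_oxidation", "acetyltransfer", "regulation")))
  expect_true(all(!is.na(cat4$step[cat4$process == "beta_oxidation"])))
  expect_true(all(is.na(cat4$step[cat4$process != "beta_oxidation"])))
})

test_that("abundance matrices survive a write/read round trip to 2 decimals", {
  m1 <- as_abundance_matrix(tibble::tibble(entity = "A", day = 5L, nspc = 0.183))
  path <- tempfile(fileext = ".tsv")
  write_abundance_matrix(m1, path)
  line <- readLines(path)[2]
  expect_match(line, "0\\.18$")

  withr::with_seed(42, {
    long <- tidyr::expand_grid(entity = LETTERS[1:5], day = c(2L, 4L, 6L, 8L, 9L)) |>
      dplyr::mutate(nspc = round(stats::runif(25, 0, 10), 4))
    long$nspc[sample.int(25, 6)] <- NA
  })
  m <- as_abundance_matrix(long)
  write_abundance_matrix(m, path)
  back <- read_abundance_matrix(path)
  expect_match(readLines(path)[2], "—")
  expect_equal(as.data.frame(back),
               as.data.frame(dplyr::mutate(m, dplyr::across(-entity, ~ round(.x, 2)))))
})
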