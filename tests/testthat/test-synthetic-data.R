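test_that("a scenario's seed fully determines its output", {
  sc <- two_genus_scenario(seed = 404L)
  g1 <- generate_community_proteome(sc)
  g2 <- generate_community_proteome(sc)
  expect_identical(g1$evidence, g2$evidence)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_community_proteome(two_genus_scenario(seed = 405L))
  expect_false(identical(g1$evidence, g3$evidence))
  expect_equal(attr(g1$evidence, "seed"), 404L)
})

test_that("impossible parameters are rejected", {
  genera <- tibble::tibble(name = "A", kind = "constant_low", level = 1)
  expect_error(synthetic_scenario(genera, timepoints = 1L, depth = -5),
               class = "ms_domain_error")
  bad <- tibble::tibble(name = "A", kind = "no_such_kind", level = 1)
  expect_error(synthetic_scenario(bad, timepoints = 1L),
               class = "ms_domain_error")
})

test_that("a one-genus community has zero taxonomic diversity at every day", {
  genera <- tibble::tibble(name = "Solo", kind = "constant_low", level = 2)
  sc <- synthetic_scenario(genera, timepoints = c(1L, 5L, 9L), seed = 3L,
                           depth = 5e3)
  g <- generate_community_proteome(sc)
  expect_true(all(g$truth$dt$dt == 0))
  pl <- run_pipeline(g$evidence)
  expect_true(all(pl$dt$value == 0))
})

test_that("planted skewed proportions are recovered within sampling error", {
  genera <- tibble::tibble(
    name = c("Dom", "G2", "G3", "G4"),
    kind = "constant_low",
    level = c(0.90, 0.06, 0.03, 0.01)
  )
  # a large per-genus catalog keeps catalog-composition noise (finite
  # proteins, random MW and expression) well below the sampling-error bound
  # being tested
  sc <- synthetic_scenario(genera, timepoints = 5L, depth = 1e5, seed = 29L,
                           proteins_per_genus = 2000L,
                           fraction_multigenus = 0, predictor_flip_prob = 0)
  g <- generate_community_proteome(sc)
  pl <- run_pipeline(g$evidence)
  # the pipeline tracks the expected-NSpC ground truth to sampling error
  expect_lt(abs(pl$dt$value - g$truth$dt$dt), 0.02)
  # ... and the closed-form Simpson of the planted genus proportions,
  # 1 - sum(p^2) = 0.1854
  expect_lt(abs(pl$dt$value - 0.1854), 0.02)
})

test_that("the community-pattern scenario reproduces the planted structure", {
  g <- generate_community_proteome(table1_like_scenario(seed = 7L))
  pl <- run_pipeline(g$evidence)
  shares <- pl$report$genus_shares
  dom <- shares$share[shares$entity == "Pseudomonas"][order(
    shares$day[shares$entity == "Pseudomonas"])]
  expect_length(dom, 5)
  expect_true(all(diff(dom) < 0))
  # at least five genera appear only at the final timepoint
  late <- pl$report$detection
  expect_gte(sum(late$first_day == 60), 5)
  # planted diversity rises from the first to the second sampling day
  expect_gt(g$truth$dt$dt[2], g$truth$dt$dt[1])
})

test_that("recovery error shrinks with sampling depth", {
  err_at <- function(depth) {
    g <- generate_community_proteome(table1_like_scenario(depth = depth,
                                                          seed = 57L))
    pl <- run_pipeline(g$evidence)
    cmp <- dplyr::left_join(pl$dt, g$truth$dt, by = "day")
    max(abs(cmp$value - cmp$dt))
  }
  expect_lt(err_at(1e5), err_at(1e3))
})

test_that("the filter pass-rate matches the planted invalid fraction", {
  sc <- two_genus_scenario(seed = 71L, proteins_per_genus = 500L,
                           fraction_invalid = 0.25)
  g <- generate_community_proteome(sc)
  truth <- g$truth$proteins
  ev <- dplyr::distinct(g$evidence, accession, .keep_all = TRUE)
  out <- filter_valid(ev)
  planted_valid <- truth$valid[match(ev$accession, truth$accession)]
  # the filter recovers the planted labels exactly ...
  expect_setequal(out$retained$accession, ev$accession[planted_valid])
  # ... and the planted rate is within binomial error of the target
  n <- nrow(truth)
  expect_lt(abs(mean(!truth$valid) - 0.25), 4 * sqrt(0.25 * 0.75 / n))
})

test_that("emitted tables embed the seed and re-read through the evidence reader", {
  sc <- two_genus_scenario(seed = 88L, proteins_per_genus = 10L, depth = 500)
  g <- generate_community_proteome(sc)
  dir <- tempfile()
  write_synthetic_tables(g, dir)
  f <- file.path(dir, "evidence_day1.tsv")
  expect_true(file.exists(f))
  expect_match(readLines(f, n = 1), "seed=88")
  back <- read_evidence_table(f)
  expect_equal(nrow(back), sum(g$evidence$day == 1))
})
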