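test_that("Simpson index hits its closed forms and published day-5 value", {
  expect_equal(simpson_index(1), 0)
  for (n in c(2, 5, 17)) {
    expect_equal(simpson_index(rep(1 / n, n)), 1 - 1 / n)
  }
  day5 <- c(2.04, 0.35, 32.90, 1.21)
  expect_equal(round(simpson_index(as_proportions(day5)), 2), 0.18)
  expect_error(simpson_index(c(0.2, 0.2)), class = "ms_domain_error")
  expect_error(simpson_index(numeric()), class = "ms_domain_error")
  expect_error(as_proportions(c(0, 0)), class = "ms_domain_error")
})

test_that("index matches a brute-force accumulation on 1000 random vectors", {
  withr::with_seed(61, {
    ok <- TRUE
    for (i in 1:1000) {
      s <- sample(1:12, 1)
      p <- as_proportions(stats::rexp(s))
      acc <- 0
      for (j in seq_len(s)) acc <- acc + p[j] * p[j]
      ok <- ok && abs(simpson_index(p) - (1 - acc)) < 1e-12
    }
    expect_true(ok)
  })
})

test_that("index range, merge monotonicity and scale invariance hold", {
  withr::with_seed(62, {
    for (i in 1:50) {
      s <- sample(2:10, 1)
      x <- stats::rexp(s)
      p <- as_proportions(x)
      v <- simpson_index(p)
      expect_gte(v, 0)
      expect_lte(v, 1 - 1 / s)
      # merging two entities never increases the index
      merged <- as_proportions(c(x[1] + x[2], x[-(1:2)]))
      expect_lte(simpson_index(merged), v + 1e-12)
      # positive rescaling leaves the index unchanged
      expect_equal(simpson_index(as_proportions(x * stats::runif(1, 0.1, 9))), v)
    }
  })
})

test_that("diversity series handles missing cells and degenerate columns", {
  m <- as_abundance_matrix(tibble::tibble(
    entity = c("A", "B", "A"),
    day = c(1L, 1L, 2L),
    nspc = c(1, 3, 2)
  ))
  ds <- diversity_series(m, "Dt")
  expect_equal(ds$value[ds$day == 1], simpson_index(c(0.25, 0.75)))
  # day 2: single detected entity -> index 0, missing cell creates no entity
  expect_equal(ds$value[ds$day == 2], 0)
  expect_equal(ds$s, c(2L, 1L))
  zero <- as_abundance_matrix(tibble::tibble(entity = "A", day = 3L, nspc = 0))
  expect_true(is.na(diversity_series(zero, "Dt")$value))
})

test_that("the genus fixture yields the published Dt series and totals", {
  ds <- diversity_series(community_genus_matrix(), "Dt")
  expect_equal(round(ds$value, 2), c(0.18, 0.69, 0.83, 0.79, 0.77))
  expect_equal(ds$day, c(5L, 10L, 20L, 30L, 60L))
  expect_equal(round(ds$total_nspc, 1), c(36.5, 20.9, 6.6, 8.9, 13.0))
  expect_equal(ds$total_nspc[1], 36.50)
})

test_that("succession report summarizes shares, detection and diversity", {
  m <- community_genus_matrix()
  rep <- succession_report(m)
  summ <- tidy(rep)
  expect_equal(round(100 * summ$top_share[summ$day == 5]), 90)
  expect_equal(summ$top_genus[summ$day == 5], "Pseudomonas")
  first60 <- rep$detection$genus[rep$detection$first_day == 60]
  expect_setequal(first60, c("Afipia", "Bacteroides", "Flavobacterium",
                             "Hyphomicrobium", "Niastella", "Oscillatoria",
                             "Salinibacter", "Sphingomonas",
                             "Stenotrophomonas", "Unclassified"))
  expect_length(first60, 10)
  g <- glance(rep)
  expect_equal(g$n_genera, 34)
  # day mismatch between matrices is an error
  fm <- as_abundance_matrix(tibble::tibble(entity = "f", day = 5L, nspc = 1))
  expect_error(succession_report(m, fm), class = "ms_validation_error")
  # empty input gives an empty report
  empty <- as_abundance_matrix(tibble::tibble(entity = character(),
                                              day = integer(),
                                              nspc = double()))
  expect_equal(nrow(tidy(succession_report(empty))), 0)
})
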