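# Builders for small in-code fixtures used across test files.

toy_evidence <- function(n = 3, day = 5L, genera = "Pseudomonas") {
  tibble::tibble(
    accession = sprintf("P%03d", seq_len(n)),
    mw_kda = seq(20, 20 + 10 * (n - 1), by = 10),
    spc = seq_len(n) * 2L,
    protein_prob = rep(0.995, n),
    n_unique_peptides_95 = rep(3L, n),
    genera = rep_len(genera, n),
    annotation = rep("lipase", n),
    day = rep(as.integer(day), n)
  )
}

# Random per-peptide evidence table for one protein.
random_peptides <- function(n, seed_prefix = "PEP") {
  tibble::tibble(
    sequence = sprintf("%s%04d", seed_prefix, sample.int(max(n, 1), n, replace = TRUE)),
    peptide_prob = stats::runif(n),
    is_unique = sample(c(TRUE, FALSE), n, replace = TRUE)
  )
}

write_tmp_tsv <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# A minimal two-genus scenario used by several synthetic-data tests.
two_genus_scenario <- function(seed = 11L, depth = 2e4, ...) {
  genera <- tibble::tribble(
    ~name, ~kind,           ~level, ~rate, ~midpoint, ~emerge_day,
    "Alpha", "constant_low", 3,      NA,    NA,        NA,
    "Beta",  "constant_low", 1,      NA,    NA,        NA
  )
  synthetic_scenario(genera, timepoints = c(1L, 2L), depth = depth,
                     seed = seed, ...)
}
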