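#' Identification-validity policy
#'
#' The defaults are the study's validity criteria: a protein identification
#' counts only if its protein probability reaches 0.99 (inclusive) and at
#' least two unique peptides pass the 0.95 peptide-probability cut-off.
#'
#' @param min_protein_probability Minimum protein identification
#'   probability, in `[0, 1]`.
#' @param min_unique_peptides Minimum number of qualifying unique peptides.
#' @param min_peptide_probability Minimum peptide probability for a peptide
#'   to qualify, in `[0, 1]`.
#' @return A list of class `ms_filter_policy`.
#' @export
filter_policy <- function(min_protein_probability = 0.99,
                          min_unique_peptides = 2L,
                          min_peptide_probability = 0.95) {
  stopifnot(min_protein_probability >= 0, min_protein_probability <= 1,
            min_peptide_probability >= 0, min_peptide_probability <= 1,
            min_unique_peptides >= 0)
  structure(list(min_protein_probability = min_protein_probability,
                 min_unique_peptides = as.integer(min_unique_peptides),
                 min_peptide_probability = min_peptide_probability),
            class = "ms_filter_policy")
}

#' Count qualifying unique peptides
#'
#' A peptide qualifies if it is unique to the protein and its probability
#' meets the policy threshold; duplicate sequences among qualifying
#' peptides are counted once.
#'
#' @param peptides A tibble with columns `sequence`, `peptide_prob`,
#'   `is_unique` (possibly zero rows), or a list of such tibbles.
#' @param policy An [filter_policy()].
#' @return Non-negative integer count (vector when `peptides` is a list).
#' @export
count_qualifying_peptides <- function(peptides, policy = filter_policy()) {
  one <- function(p) {
    if (is.null(p) || nrow(p) == 0) return(0L)
    q <- p$is_unique & p$peptide_prob >= policy$min_peptide_probability
    length(unique(p$sequence[q]))
  }
  if (is.data.frame(peptides)) one(peptides)
  else purrr::map_int(peptides, one)
}

#' Partition evidence into valid and rejected identifications
#'
#' A row is retained iff its protein probability meets
#' `min_protein_probability` and its qualifying unique-peptide count meets
#' `min_unique_peptides`. The peptide count comes from the `peptides`
#' list-column when present, and otherwise from a precomputed
#' `n_unique_peptides_95` column, which Scaffold-style exports often supply
#' instead of per-peptide rows.
#'
#' @param evidence An evidence tibble (see [read_evidence_table()]).
#' @param policy An [filter_policy()].
#' @return A list with `retained` (evidence rows) and `rejected` (evidence
#'   rows plus a `reason` column: `"low_probability"`,
#'   `"insufficient_peptides"` or `"both"`).
#' @export
filter_valid <- function(evidence, policy = filter_policy()) {
  if (nrow(evidence) == 0) {
    return(list(retained = evidence,
                rejected = mutate(evidence, reason = character())))
  }
  if ("peptides" %in% names(evidence)) {
    n_pep <- count_qualifying_peptides(evidence$peptides, policy)
  } else if ("n_unique_peptides_95" %in% names(evidence)) {
    n_pep <- as.integer(evidence$n_unique_peptides_95)
  } else {
    abort("evidence has neither a 'peptides' list-column nor 'n_unique_peptides_95'",
          class = "ms_schema_error")
  }
  low_prob <- evidence$protein_prob < policy$min_protein_probability
  few_pep <- n_pep < policy$min_unique_peptides
  keep <- !low_prob & !few_pep
  rejected <- evidence[!keep, , drop = FALSE]
  rejected$reason <- case_when(
    low_prob[!keep] & few_pep[!keep] ~ "both",
    low_prob[!keep] ~ "low_probability",
    TRUE ~ "insufficient_peptides"
  )
  list(retained = evidence[keep, , drop = FALSE], rejected = rejected)
}
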