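#' Resolve candidate genera at one timepoint
#'
#' Peptide-level evidence in a community sample often matches proteins from
#' several genera, so a protein may carry more than one candidate genus.
#' Each such protein is assigned to the candidate with the highest genus
#' NSpC at the same sampling day. Stated that way the rule is circular
#' (genus NSpC depends on assignments), so it is resolved in two passes:
#'
#' 1. provisional per-genus NSpC totals are accumulated from
#'    single-candidate proteins only;
#' 2. each multi-candidate protein goes to its candidate with the highest
#'    provisional total, candidates never seen in pass 1 ranking as zero.
#'    Multi-candidate proteins do not feed back into the totals, which makes
#'    the assignment deterministic and independent of input order.
#'
#' Ties — including the all-zero case — go to the lexicographically first
#' candidate and are flagged in the `basis` column.
#'
#' @param evidence Evidence rows for a single day with a `genera` column
#'   (semicolon-separated candidates) and `nspc` (or `spc` + `mw_kda`).
#' @return A tibble with columns `accession`, `day`, `assigned_genus`,
#'   `basis` (`"unambiguous"`, `"highest_provisional_total"` or
#'   `"lexicographic_tiebreak"`).
#' @export
assign_genera <- function(evidence) {
  day <- unique(evidence$day)
  if (length(day) != 1) {
    abort("assign_genera() expects evidence from a single day",
          class = "ms_validation_error")
  }
  evidence <- add_nspc(evidence)
  cand <- split_genera(evidence$genera)
  if (any(lengths(cand) == 0)) {
    abort(paste0("empty candidate genus list for: ",
                 paste(head(evidence$accession[lengths(cand) == 0], 5),
                       collapse = ", ")),
          class = "ms_validation_error")
  }
  single <- lengths(cand) == 1
  provisional <- tibble(genus = unlist(cand[single]),
                        nspc = evidence$nspc[single]) |>
    group_by(.data$genus) |>
    summarise(total = sum(.data$nspc), .groups = "drop")
  totals <- setNames(provisional$total, provisional$genus)
  pick <- function(candidates) {
    scores <- unname(totals[candidates])
    scores[is.na(scores)] <- 0
    best <- candidates[scores == max(scores)]
    tied <- length(best) > 1
    best <- sort(best)[1]
    c(best, if (tied) "lexicographic_tiebreak" else "highest_provisional_total")
  }
  choice <- purrr::map(cand, function(cc) {
    if (length(cc) == 1) c(cc, "unambiguous") else pick(cc)
  })
  tibble(accession = evidence$accession,
         day = as.integer(day),
         assigned_genus = purrr::map_chr(choice, 1),
         basis = purrr::map_chr(choice, 2))
}

#' Genus-by-day NSpC abundance matrix
#'
#' Applies [assign_genera()] independently at each sampling day (the
#' highest-abundance rule is defined "at the relevant sampling date") and
#' sums NSpC per assigned genus. Every protein lands in exactly one genus
#' row per day, so column sums equal the total NSpC of that day's proteins.
#'
#' @param evidence Evidence rows across days, with `genera` and `nspc` (or
#'   `spc` + `mw_kda`).
#' @return An [as_abundance_matrix()] with genera as entities.
#' @export
genus_matrix <- function(evidence) {
  evidence <- add_nspc(evidence)
  long <- purrr::map(split(evidence, evidence$day), function(ev) {
    asg <- assign_genera(ev)
    ev |>
      left_join(asg, by = c("accession", "day")) |>
      sum_nspc("assigned_genus")
  }) |>
    bind_rows()
  as_abundance_matrix(long)
}
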