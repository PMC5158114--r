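#' Default functional-group keyword rules
#'
#' The classification into functional groups is manual curation in spirit;
#' here it is packaged as data — an ordered table of case-insensitive
#' regular expressions, first match wins — so the mapping is auditable and
#' editable without touching code. The default vocabulary contains the six
#' named groups used by the source study plus two generic metabolic groups;
#' annotations matching nothing fall into `"Unknown function"`. A custom
#' ruleset may define at most ten groups (plus the unknown fallback).
#'
#' @param path Optional path to a custom rules TSV with columns `pattern`
#'   and `group`.
#' @return A tibble with columns `pattern`, `group`, in match order.
#' @export
function_rules <- function(path = NULL) {
  path <- path %||% ms_extdata("function_rules.tsv")
  rules <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
  if (!all(c("pattern", "group") %in% names(rules))) {
    abort("function rules need columns: pattern, group",
          class = "ms_schema_error")
  }
  if (length(unique(rules$group)) > 10) {
    abort("at most ten functional groups are supported",
          class = "ms_validation_error")
  }
  rules
}

#' Classify annotations into functional groups
#'
#' @param annotation Character vector of free-text putative functions.
#' @param rules A rules tibble from [function_rules()].
#' @return Character vector of group names; every input receives exactly
#'   one group (`"Unknown function"` when nothing matches).
#' @export
classify_function <- function(annotation, rules = function_rules()) {
  out <- rep("Unknown function", length(annotation))
  undecided <- rep(TRUE, length(annotation))
  ann <- tidyr::replace_na(annotation, "")
  for (i in seq_len(nrow(rules))) {
    hit <- undecided & stringr::str_detect(
      ann, stringr::regex(rules$pattern[i], ignore_case = TRUE))
    out[hit] <- rules$group[i]
    undecided <- undecided & !hit
  }
  out
}

#' Default pathway-role keyword rules
#'
#' @param path Optional path to a custom rules TSV with columns `pattern`,
#'   `process` and `step` (`"."` for roles without step detail).
#' @return A tibble with columns `pattern`, `process`, `step`.
#' @export
pathway_rules <- function(path = NULL) {
  path <- path %||% ms_extdata("pathway_rules.tsv")
  rules <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
  if (!all(c("pattern", "process", "step") %in% names(rules))) {
    abort("pathway rules need columns: pattern, process, step",
          class = "ms_schema_error")
  }
  rules$step[rules$step == "."] <- NA_character_
  rules
}

# Vocabulary of suberin degradation/utilization processes; only
# beta-oxidation roles carry a step (the four enzymes of the cycle).
PATHWAY_PROCESSES <- c(
  "suberin_adhesion", "depolymerization", "feruloyl_esterase",
  "lipid_entry", "long_chain_fatty_acid_transport", "coa_activation",
  "beta_oxidation", "acetyltransfer", "regulation"
)
BETA_OXIDATION_STEPS <- c(
  "acyl_coa_dehydrogenase", "enoyl_coa_hydratase",
  "hydroxyacyl_coa_dehydrogenase", "acetyl_coa_acetyltransferase"
)

#' Map annotations to suberin-pathway roles
#'
#' Keyword mapping into the suberin degradation/utilization schema:
#' adhesion, depolymerization (lipases, feruloyl esterase), lipid entry and
#' long-chain fatty-acid transport, CoA activation, the four beta-oxidation
#' steps, acetyltransfer and regulation. Annotations outside the schema get
#' no role (`NA` process).
#'
#' @param annotation Character vector of free-text putative functions.
#' @param rules A rules tibble from [pathway_rules()].
#' @return A tibble with one row per input: `annotation`, `process`,
#'   `step` (step is non-`NA` only for beta-oxidation roles).
#' @export
classify_pathway_role <- function(annotation, rules = pathway_rules()) {
  process <- rep(NA_character_, length(annotation))
  step <- rep(NA_character_, length(annotation))
  undecided <- rep(TRUE, length(annotation))
  ann <- tidyr::replace_na(annotation, "")
  for (i in seq_len(nrow(rules))) {
    hit <- undecided & stringr::str_detect(
      ann, stringr::regex(rules$pattern[i], ignore_case = TRUE))
    process[hit] <- rules$process[i]
    step[hit] <- rules$step[i]
    undecided <- undecided & !hit
  }
  tibble(annotation = annotation, process = process, step = step)
}

#' Sum NSpC over one pathway process at one timepoint
#'
#' @param evidence Evidence rows carrying `nspc` (or `spc` + `mw_kda`) and
#'   `day`. Rows whose accession is absent from `roles`, or not-detected
#'   rows (`NA` NSpC), contribute nothing.
#' @param roles A tibble with columns `accession` and `process` (e.g. a
#'   filtered [pathway_catalog()], or roles built with
#'   [classify_pathway_role()]).
#' @param process One process name from the pathway vocabulary.
#' @param day The sampling day to roll up.
#' @return The summed NSpC (0 when no protein matches).
#' @export
pathway_rollup <- function(evidence, roles, process, day) {
  if (!process %in% PATHWAY_PROCESSES) {
    abort(paste0("unknown process: ", process, "; expected one of ",
                 paste(PATHWAY_PROCESSES, collapse = ", ")),
          class = "ms_domain_error")
  }
  evidence <- add_nspc(evidence)
  acc <- unique(roles$accession[roles$process == process])
  rows <- evidence[evidence$day == day & evidence$accession %in% acc, ,
                   drop = FALSE]
  sum(rows$nspc, na.rm = TRUE)
}

#' Functional-group-by-day NSpC abundance matrix
#'
#' Classifies every row's annotation into a functional group and sums NSpC
#' per group and day. Classification is total, so group sums partition the
#' total NSpC of each day.
#'
#' @param evidence Evidence rows across days with an `annotation` column.
#' @param rules A rules tibble from [function_rules()].
#' @return An [as_abundance_matrix()] with functional groups as entities.
#' @export
function_matrix <- function(evidence, rules = function_rules()) {
  evidence <- add_nspc(evidence)
  evidence$functional_group <- classify_function(evidence$annotation, rules)
  long <- purrr::map(split(evidence, evidence$day),
                     sum_nspc, group_col = "functional_group") |>
    bind_rows()
  as_abundance_matrix(long)
}
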