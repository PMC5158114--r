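#' Read a long-form protein evidence table
#'
#' Reads a delimited text export of protein-level evidence (one row per
#' protein per sampling day) into a validated tibble. This is the pipeline's
#' entry point: upstream database search and protein inference (e.g. a
#' Scaffold export) are assumed done, and their per-protein summaries are the
#' columns here.
#'
#' Required columns: `accession`, `mw_kda` (molecular weight in kilodaltons),
#' `spc` (spectral count), `protein_prob` (protein identification
#' probability), `day`. Recognised optional columns: `n_unique_peptides_95`
#' (precomputed count of unique peptides passing the peptide-probability
#' threshold), the five predictor columns `signalp`, `phobius`, `secretomep`,
#' `tatp`, `tatfind` (logical; an absent column means the predictor was not
#' run), `genera` (semicolon-separated candidate genus names), `annotation`
#' (free-text putative function) and `localization` (`"E"`/`"I"` or
#' `"extracellular"`/`"intracellular"`, a reported label that downstream
#' steps may use instead of recomputing the consensus).
#'
#' Per-peptide evidence can be supplied as a second long table
#' (`peptide_path`) with columns `accession`, `sequence`, `peptide_prob`,
#' `is_unique` and optionally `day`; it is nested into a `peptides`
#' list-column joined by accession (and day when present).
#'
#' @param path Path to the delimited evidence table.
#' @param peptide_path Optional path to a long per-peptide table.
#' @param delim Field delimiter; guessed from the file extension
#'   (`.csv` gives `","`, anything else tab) when `NULL`.
#' @param na Strings read as missing, in addition to empty fields.
#' @return A tibble of validated evidence rows, one per protein x day.
#' @export
read_evidence_table <- function(path, peptide_path = NULL, delim = NULL,
                                na = c("", "NA", "—", "-")) {
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, na = na, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) {
    abort(paste0("evidence table is empty: ", path), class = "ms_empty_input")
  }
  df <- validate_evidence(as_tibble(df))
  if (!is.null(peptide_path)) {
    pep <- readr::read_delim(peptide_path, delim = delim, na = na,
                             comment = "#", show_col_types = FALSE,
                             progress = FALSE)
    df <- nest_peptides(df, as_tibble(pep))
  }
  df
}

#' Read a wide-form evidence table and normalize it to long form
#'
#' Convenience reader for exports that put each sampling day in its own
#' spectral-count column named `spc_<day>` (for example `spc_5`, `spc_30`).
#' Missing cells mean "not detected" and produce no long-form row; a literal
#' zero is kept as a measured zero.
#'
#' @inheritParams read_evidence_table
#' @return A long-form evidence tibble as from [read_evidence_table()].
#' @export
read_evidence_wide <- function(path, delim = NULL,
                               na = c("", "NA", "—", "-")) {
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, na = na, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) {
    abort(paste0("evidence table is empty: ", path), class = "ms_empty_input")
  }
  spc_cols <- grep("^spc_\\d+$", names(df), value = TRUE)
  if (length(spc_cols) == 0) {
    abort("wide evidence table has no 'spc_<day>' columns",
          class = "ms_schema_error")
  }
  long <- tidyr::pivot_longer(df, cols = dplyr::all_of(spc_cols),
                              names_to = "day", names_prefix = "spc_",
                              names_transform = as.integer,
                              values_to = "spc", values_drop_na = TRUE)
  validate_evidence(long)
}

required_evidence_columns <- c("accession", "mw_kda", "spc", "protein_prob", "day")

validate_evidence <- function(df) {
  missing_cols <- setdiff(required_evidence_columns, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("evidence table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ms_schema_error")
  }
  problems <- character()
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0) {
      problems <<- c(problems,
                     paste0("row ", paste(head(idx, 5), collapse = ", "),
                            if (length(idx) > 5) ", ..." else "", ": ", what))
    }
    invisible(NULL)
  }
  bad(is.na(df$accession) | !nzchar(df$accession), "missing accession")
  bad(!is.na(df$mw_kda) & df$mw_kda <= 0, "molecular weight must be > 0 kDa")
  bad(!is.na(df$spc) & (df$spc < 0 | df$spc != round(df$spc)),
      "spectral count must be a non-negative integer")
  bad(!is.na(df$protein_prob) & (df$protein_prob < 0 | df$protein_prob > 1),
      "protein probability outside [0, 1]")
  bad(!is.na(df$day) & df$day < 0, "day must be non-negative")
  if ("genera" %in% names(df)) {
    dup <- purrr::map_lgl(split_genera(df$genera), ~ anyDuplicated(.x) > 0)
    bad(dup, "duplicated candidate genus within a row")
  }
  if (length(problems) > 0) {
    abort(paste0("invalid evidence rows:\n  ",
                 paste(problems, collapse = "\n  ")),
          class = "ms_validation_error")
  }
  df$spc <- as.integer(df$spc)
  df$day <- as.integer(df$day)
  for (col in intersect(PREDICTOR_COLUMNS, names(df))) {
    df[[col]] <- as.logical(df[[col]])
  }
  if ("localization" %in% names(df)) {
    df$localization <- normalize_localization(df$localization)
  }
  df
}

normalize_localization <- function(x) {
  out <- dplyr::case_when(
    x %in% c("E", "e", "extracellular") ~ "extracellular",
    x %in% c("I", "i", "intracellular") ~ "intracellular",
    is.na(x) ~ NA_character_,
    TRUE ~ "invalid"
  )
  if (any(out == "invalid", na.rm = TRUE)) {
    abort("localization labels must be E/I or extracellular/intracellular",
          class = "ms_validation_error")
  }
  out
}

#' Split semicolon-separated candidate genus strings
#'
#' @param genera Character vector of `;`-separated genus names.
#' @return A list of character vectors, one per input element.
#' @export
split_genera <- function(genera) {
  purrr::map(genera, function(g) {
    if (is.na(g)) return(character())
    trimws(strsplit(g, ";", fixed = TRUE)[[1]])
  })
}

nest_peptides <- function(df, pep) {
  need <- c("accession", "sequence", "peptide_prob", "is_unique")
  missing_cols <- setdiff(need, names(pep))
  if (length(missing_cols) > 0) {
    abort(paste0("peptide table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ms_schema_error")
  }
  if (any(pep$peptide_prob < 0 | pep$peptide_prob > 1, na.rm = TRUE)) {
    abort("peptide probabilities outside [0, 1]",
          class = "ms_validation_error")
  }
  pep$is_unique <- as.logical(pep$is_unique)
  keys <- intersect(c("accession", "day"), names(pep))
  nested <- pep |>
    tidyr::nest(peptides = -dplyr::all_of(keys))
  out <- left_join(df, nested, by = keys)
  out$peptides <- purrr::map(out$peptides, function(p) {
    if (is.null(p)) tibble(sequence = character(), peptide_prob = double(),
                           is_unique = logical()) else p
  })
  out
}
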