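#' Normalized spectral count (NSpC)
#'
#' The number of spectra matched to a protein grows with protein size, so
#' the spectral count is normalized by dividing it by the protein's
#' molecular weight. The result — spectra per kilodalton — is the
#' abundance unit used throughout the pipeline. It is a plain quotient:
#' there is no further normalization to proportions here (proportions are
#' formed only where a diversity index needs them).
#'
#' @param spc Non-negative integer spectral counts.
#' @param mw_kda Positive molecular weights in kilodaltons.
#' @return Numeric NSpC values (spectra per kDa); zero exactly when the
#'   spectral count is zero.
#' @export
compute_nspc <- function(spc, mw_kda) {
  if (any(is.na(mw_kda)) || any(mw_kda <= 0)) {
    abort("molecular weight must be > 0 kDa for NSpC",
          class = "ms_domain_error")
  }
  if (any(spc < 0, na.rm = TRUE)) {
    abort("spectral counts must be non-negative", class = "ms_domain_error")
  }
  spc / mw_kda
}

#' Add an `nspc` column to an evidence tibble
#'
#' @param evidence Evidence with `spc` and `mw_kda` columns. Rows that
#'   already carry `nspc` (e.g. transcriptions of published tables that
#'   print NSpC directly) are left untouched.
#' @return The evidence tibble with an `nspc` column.
#' @export
add_nspc <- function(evidence) {
  if (!"nspc" %in% names(evidence)) {
    evidence$nspc <- compute_nspc(evidence$spc, evidence$mw_kda)
  }
  evidence
}

#' Average NSpC over replicates
#'
#' Published per-protein abundances in this pipeline's source tables are the
#' mean of two culture replicates. Under the default `absent = "zero"`
#' policy a protein not detected in a replicate (an `NA`) contributes zero
#' to the mean; `absent = "skip"` averages over detected replicates only.
#'
#' @param values Numeric vector of per-replicate NSpC values (`NA` = not
#'   detected in that replicate).
#' @param absent Missing-replicate policy.
#' @return The replicate mean; `NA` if no replicate detected the protein.
#' @export
aggregate_replicates <- function(values, absent = c("zero", "skip")) {
  absent <- match.arg(absent)
  if (length(values) == 0) {
    abort("no replicate values to aggregate", class = "ms_empty_input")
  }
  if (all(is.na(values))) return(NA_real_)
  if (absent == "zero") mean(tidyr::replace_na(values, 0))
  else mean(values, na.rm = TRUE)
}

#' Sum NSpC per group at one timepoint
#'
#' @param evidence Evidence rows for a single day, carrying `nspc` (or
#'   `spc` + `mw_kda`) and the grouping column.
#' @param group_col Name of the column holding the group label (e.g.
#'   `"assigned_genus"` or `"functional_group"`).
#' @param day The day to aggregate; defaults to the single day present.
#' @return A tibble with columns `entity`, `day`, `nspc` — one row per
#'   group that has at least one detected protein (groups with none are
#'   absent, not zero).
#' @export
sum_nspc <- function(evidence, group_col, day = NULL) {
  evidence <- add_nspc(evidence)
  if (!group_col %in% names(evidence)) {
    abort(paste0("grouping column not found: ", group_col),
          class = "ms_schema_error")
  }
  if (is.null(day)) {
    day <- unique(evidence$day)
    if (length(day) != 1) {
      abort("evidence spans several days; pass `day` explicitly",
            class = "ms_validation_error")
    }
  }
  rows <- evidence[evidence$day == day, , drop = FALSE]
  unlabeled <- is.na(rows[[group_col]]) | !nzchar(rows[[group_col]])
  if (any(unlabeled)) {
    abort(paste0("unlabeled protein(s): ",
                 paste(head(rows$accession[unlabeled], 5), collapse = ", ")),
          class = "ms_validation_error")
  }
  rows |>
    group_by(entity = .data[[group_col]]) |>
    summarise(nspc = sum(.data$nspc), .groups = "drop") |>
    mutate(day = as.integer(day)) |>
    select("entity", "day", "nspc")
}
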