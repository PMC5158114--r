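#' Packaged transcription of the community genus-abundance table
#'
#' Genus-by-day NSpC of predicted extracellular proteins identified in
#' suberin medium inoculated with potato field soil, transcribed from the
#' source study's printed table (2-decimal cells; an em-dash — here a
#' missing cell — means not detected or identification not valid).
#'
#' @return An [as_abundance_matrix()] (34 genera x days 5, 10, 20, 30, 60).
#' @export
community_genus_matrix <- function() {
  read_abundance_matrix(ms_extdata("table1_genus_nspc.tsv"))
}

#' Packaged lipid-metabolism protein tables of the two isolates
#'
#' Transcriptions of the printed per-protein tables for *Rhodanobacter
#' thiooxydans* LCS2 (50 proteins, days 5 and 30) and *Myxococcus xanthus*
#' DK 1622 (38 proteins, days 5 and 25) grown on suberin: accession,
#' putative function, NSpC at the two sampling days (mean of two
#' replicates; `NA` = not detected) and the printed E/I localization.
#' The *M. xanthus* table carries a `note` column flagging Q1D009, which
#' the source text discusses outside the lipid-metabolism group.
#'
#' @param long Return one row per protein x day (`nspc`, `day` columns)
#'   instead of the printed wide layout.
#' @return A tibble.
#' @name isolate_tables
NULL

#' @rdname isolate_tables
#' @export
rhodanobacter_lipid_table <- function(long = FALSE) {
  df <- readr::read_tsv(ms_extdata("table2_rhodanobacter_lipid.tsv"),
                        na = c("", "NA", "—"), comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  df$localization <- normalize_localization(df$localization)
  if (long) pivot_isolate_table(df) else df
}

#' @rdname isolate_tables
#' @export
myxococcus_lipid_table <- function(long = FALSE) {
  df <- readr::read_tsv(ms_extdata("table3_myxococcus_lipid.tsv"),
                        na = c("", "NA", "—", "."), comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  df$localization <- normalize_localization(df$localization)
  if (long) pivot_isolate_table(df) else df
}

pivot_isolate_table <- function(df) {
  tidyr::pivot_longer(df, cols = dplyr::starts_with("nspc_day"),
                      names_to = "day", names_prefix = "nspc_day",
                      names_transform = as.integer,
                      values_to = "nspc", values_drop_na = TRUE)
}

#' Packaged suberin degradation/utilization pathway catalog
#'
#' The per-organism mapping of accessions to pathway processes (adhesion,
#' depolymerization, feruloyl esterase, lipid entry, long-chain fatty-acid
#' transport, CoA activation, the four beta-oxidation steps, regulation),
#' transcribed from the source study's pathway table. The `detection`
#' column carries the table's footnotes (detected at both samplings, late
#' sampling only, or day 5 only).
#'
#' @return A tibble with columns `organism`, `process`, `step`,
#'   `accession`, `detection`.
#' @export
pathway_catalog <- function() {
  df <- readr::read_tsv(ms_extdata("table4_pathway_catalog.tsv"),
                        na = c("", "NA", "."), comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  df
}
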