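# Expasy average residue masses (Da); a protein's average molecular mass is
# the sum of its residue masses plus one water (18.01524 Da).
AVERAGE_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

# Ambiguity conventions: B and Z take the mean of their two possible
# residues, X the mean of all twenty standard residues.
ambiguous_residue_mass <- function() {
  c(B = mean(AVERAGE_RESIDUE_MASS[c("N", "D")]),
    Z = mean(AVERAGE_RESIDUE_MASS[c("Q", "E")]),
    X = mean(AVERAGE_RESIDUE_MASS))
}

#' Average molecular weight of protein sequences, in kilodaltons
#'
#' Computes the average (not monoisotopic) molecular mass of each sequence
#' as the sum of standard average amino-acid residue masses plus one water,
#' reported in kilodaltons. Average masses are used because the molecular
#' weights that normalize spectral counts in this pipeline (gel- or
#' database-derived) are average-mass quantities. The ambiguity codes `B`,
#' `Z` and `X` are accepted and assigned their mean residue mass; any other
#' non-standard letter is an error.
#'
#' @param sequences Character vector of amino-acid sequences (names are
#'   preserved).
#' @return Named numeric vector of molecular weights in kDa.
#' @export
protein_mw_kda <- function(sequences) {
  masses <- c(AVERAGE_RESIDUE_MASS, ambiguous_residue_mass())
  out <- purrr::map_dbl(sequences, function(s) {
    if (is.na(s) || !nzchar(s)) {
      abort("cannot compute molecular weight of an empty sequence",
            class = "ms_validation_error")
    }
    aa <- strsplit(toupper(s), "")[[1]]
    unknown <- setdiff(unique(aa), names(masses))
    if (length(unknown) > 0) {
      abort(paste0("non-standard residue code(s): ",
                   paste(unknown, collapse = ", ")),
            class = "ms_validation_error")
    }
    (sum(masses[aa]) + WATER_MASS) / 1000
  })
  setNames(out, names(sequences))
}

#' Read a protein FASTA and compute molecular weights
#'
#' Parses a FASTA file and returns the average molecular mass of each record
#' in kilodaltons, keyed by accession. UniProt-style headers
#' (`>db|ACCESSION|NAME ...`) are reduced to the accession; otherwise the
#' first whitespace-delimited token of the header is used.
#'
#' @param path Path to a protein FASTA file.
#' @return Named numeric vector: accession -> molecular weight (kDa).
#' @export
read_fasta_weights <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) {
    abort(paste0("FASTA file contains no sequences: ", path),
          class = "ms_empty_input")
  }
  ids <- sub("\\s.*$", "", names(seqs))
  uniprot <- grepl("^[a-z]{2}\\|[^|]+\\|", ids)
  ids[uniprot] <- vapply(strsplit(ids[uniprot], "|", fixed = TRUE),
                         `[[`, character(1), 2L)
  protein_mw_kda(setNames(as.character(seqs), ids))
}
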