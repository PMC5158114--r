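#' Consensus policy for secretion-predictor calls
#'
#' Five predictors cover three largely disjoint export routes: classical
#' signal peptides (SignalP, Phobius), non-classical secretion (SecretomeP)
#' and the Tat pathway (TatP, TatFind). The default consensus is therefore
#' the union — any positive call labels the protein extracellular — since a
#' protein secreted by one route is not expected to score on the others.
#' Stricter aggregations (`majority`, `all`, `k_of_n`) are available.
#'
#' @param mode Aggregation rule.
#' @param k Number of positive calls required when `mode = "k_of_n"`.
#' @param treat_absent_as How a predictor that was not run enters the vote:
#'   `"negative"` counts it as a negative call over the full five-predictor
#'   panel; `"excluded"` drops it from the denominator.
#' @return A list of class `ms_consensus_policy`.
#' @export
consensus_policy <- function(mode = c("any", "majority", "all", "k_of_n"),
                             k = NULL,
                             treat_absent_as = c("negative", "excluded")) {
  mode <- match.arg(mode)
  treat_absent_as <- match.arg(treat_absent_as)
  if (mode == "k_of_n") {
    stopifnot(!is.null(k), k >= 1)
    k <- as.integer(k)
  }
  structure(list(mode = mode, k = k, treat_absent_as = treat_absent_as),
            class = "ms_consensus_policy")
}

#' Collapse predictor calls into a localization label
#'
#' @param calls An evidence tibble (or any data frame) with some of the
#'   predictor columns `signalp`, `phobius`, `secretomep`, `tatp`,
#'   `tatfind`; `NA` means the predictor was not run for that protein.
#' @param policy A [consensus_policy()].
#' @return Character vector of `"extracellular"` / `"intracellular"`, one
#'   per row. A row with no predictor call at all is an error.
#' @export
call_localization <- function(calls, policy = consensus_policy()) {
  cols <- intersect(PREDICTOR_COLUMNS, names(calls))
  if (length(cols) == 0) {
    abort("no predictor columns present; cannot call localization",
          class = "ms_no_call_error")
  }
  m <- as.matrix(as.data.frame(calls)[, cols, drop = FALSE])
  mode(m) <- "logical"
  present <- rowSums(!is.na(m))
  if (any(present == 0)) {
    abort(paste0("no predictor call for row(s): ",
                 paste(head(which(present == 0), 5), collapse = ", ")),
          class = "ms_no_call_error")
  }
  pos <- rowSums(m, na.rm = TRUE)
  denom <- if (policy$treat_absent_as == "negative") {
    rep(length(PREDICTOR_COLUMNS), nrow(m))
  } else {
    present
  }
  extr <- switch(policy$mode,
    any = pos >= 1,
    all = pos == denom,
    majority = pos > denom / 2,
    k_of_n = pos >= policy$k
  )
  ifelse(extr, "extracellular", "intracellular")
}

#' Partition validated evidence into the secretome and the rest
#'
#' Adds a `localization` label to every row and splits the input. A
#' `localization` column already present in the input (for example the
#' printed E/I column of a published table) is taken as-is when
#' `use_reported = TRUE`; otherwise the consensus over predictor columns is
#' computed. Only the extracellular subset — the secretome — is normally
#' analyzed further, since intracellular proteins in a culture supernatant
#' may originate from lysed cells.
#'
#' @param evidence An evidence tibble that already passed [filter_valid()].
#' @param policy A [consensus_policy()].
#' @param use_reported Use an existing `localization` column when present.
#' @return A list with `extracellular`, `intracellular` (tibbles, each with
#'   the `localization` column filled) and `fraction_extracellular` (by
#'   protein count; `NA` for empty input).
#' @export
partition_secretome <- function(evidence, policy = consensus_policy(),
                                use_reported = TRUE) {
  if (nrow(evidence) == 0) {
    return(list(extracellular = evidence, intracellular = evidence,
                fraction_extracellular = NA_real_))
  }
  if (use_reported && "localization" %in% names(evidence) &&
      !anyNA(evidence$localization)) {
    lab <- evidence$localization
  } else {
    lab <- call_localization(evidence, policy)
  }
  evidence$localization <- lab
  list(extracellular = evidence[lab == "extracellular", , drop = FALSE],
       intracellular = evidence[lab == "intracellular", , drop = FALSE],
       fraction_extracellular = mean(lab == "extracellular"))
}
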