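#' Community succession report
#'
#' Bundles the per-day summaries that describe a community's succession:
#' the genus matrix, per-day NSpC totals, per-day genus shares, the
#' dominant genus and its share each day, first/last detection day per
#' genus, the taxonomic diversity (Dt) series and — when a
#' functional-group matrix is supplied — per-day functional-group
#' proportions and the functional diversity (Df) series.
#'
#' @param genus_m Genus-by-day [as_abundance_matrix()].
#' @param function_m Optional functional-group-by-day matrix over the same
#'   days (a mismatch is an error).
#' @return A list of class `ms_succession_report` with elements
#'   `genus_matrix`, `totals`, `genus_shares`, `top_genus`, `detection`,
#'   `dt`, and (if `function_m` given) `function_proportions`, `df`.
#' @export
succession_report <- function(genus_m, function_m = NULL) {
  stopifnot(inherits(genus_m, "ms_abundance_matrix"))
  if (!is.null(function_m)) {
    stopifnot(inherits(function_m, "ms_abundance_matrix"))
    if (!identical(matrix_days(genus_m), matrix_days(function_m))) {
      abort("genus and functional-group matrices cover different days",
            class = "ms_validation_error")
    }
  }
  long <- tidy(genus_m) |> filter(.data$detected)
  totals <- long |>
    group_by(.data$day) |>
    summarise(total_nspc = sum(.data$nspc), .groups = "drop")
  shares <- long |>
    group_by(.data$day) |>
    mutate(share = .data$nspc / sum(.data$nspc)) |>
    ungroup() |>
    select("entity", "day", "nspc", "share")
  top <- shares |>
    group_by(.data$day) |>
    arrange(dplyr::desc(.data$share), .data$entity, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("day", genus = "entity", "share")
  detection <- if (nrow(long) == 0) {
    tibble(genus = character(), first_day = integer(),
           last_day = integer(), n_days = integer())
  } else {
    long |>
      group_by(genus = .data$entity) |>
      summarise(first_day = min(.data$day), last_day = max(.data$day),
                n_days = dplyr::n(), .groups = "drop")
  }
  out <- list(genus_matrix = genus_m,
              totals = totals,
              genus_shares = shares,
              top_genus = top,
              detection = detection,
              dt = diversity_series(genus_m, "Dt"))
  if (!is.null(function_m)) {
    flong <- tidy(function_m) |> filter(.data$detected)
    out$function_proportions <- flong |>
      group_by(.data$day) |>
      mutate(share = .data$nspc / sum(.data$nspc)) |>
      ungroup() |>
      select(group = "entity", "day", "nspc", "share")
    out$df <- diversity_series(function_m, "Df")
  }
  structure(out, class = "ms_succession_report")
}

#' @export
print.ms_succession_report <- function(x, ...) {
  cat("# Succession report:", nrow(x$genus_matrix), "genera over days",
      paste(x$totals$day, collapse = ", "), "\n")
  cat("  per-day total NSpC:",
      paste(round(x$totals$total_nspc, 1), collapse = ", "), "\n")
  cat("  Dt:", paste(round(x$dt$value, 2), collapse = ", "), "\n")
  invisible(x)
}

#' Per-day summary of a succession report
#'
#' @param x An `ms_succession_report`.
#' @param ... Unused.
#' @return A tibble with one row per day: total NSpC, number of detected
#'   genera, Dt, the dominant genus and its share.
#' @method tidy ms_succession_report
#' @export
tidy.ms_succession_report <- function(x, ...) {
  x$totals |>
    left_join(select(x$dt, "day", dt = "value", "s"), by = "day") |>
    left_join(rename(x$top_genus, top_genus = "genus",
                     top_share = "share"), by = "day")
}

#' One-row overview of a succession report
#'
#' @param x An `ms_succession_report`.
#' @param ... Unused.
#' @return A one-row tibble: number of genera and days, range of per-day
#'   totals and of Dt.
#' @method glance ms_succession_report
#' @export
glance.ms_succession_report <- function(x, ...) {
  tibble(n_genera = nrow(x$genus_matrix),
         n_days = nrow(x$totals),
         total_nspc_min = min(x$totals$total_nspc),
         total_nspc_max = max(x$totals$total_nspc),
         dt_min = min(x$dt$value, na.rm = TRUE),
         dt_max = max(x$dt$value, na.rm = TRUE))
}

#' Stacked-share plot of genus succession
#'
#' @param object An `ms_succession_report`.
#' @param ... Unused.
#' @return A ggplot object showing each genus's share of total NSpC per day.
#' @method autoplot ms_succession_report
#' @export
autoplot.ms_succession_report <- function(object, ...) {
  ggplot2::ggplot(object$genus_shares,
                  ggplot2::aes(factor(.data$day), .data$share,
                               fill = .data$entity)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Incubation time (d)", y = "Share of total NSpC",
                  fill = "Genus") +
    ggplot2::theme_minimal()
}

#' Write a succession report to a directory
#'
#' Emits the genus matrix (published-table layout), the per-day summary,
#' genus shares and detection spans as TSVs, plus a JSON summary when the
#' jsonlite package is available.
#'
#' @param report An `ms_succession_report`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_succession_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance_matrix(report$genus_matrix,
                         file.path(dir, "genus_matrix.tsv"))
  readr::write_tsv(tidy(report), file.path(dir, "per_day_summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$genus_shares, file.path(dir, "genus_shares.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$detection, file.path(dir, "detection_spans.tsv"),
                   progress = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(per_day = tidy(report), overview = glance(report)),
      file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
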