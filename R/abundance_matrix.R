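#' Entity-by-day NSpC abundance matrices
#'
#' An abundance matrix holds summed NSpC per entity (genus or functional
#' group) and sampling day. It is stored as a wide tibble whose first column
#' is `entity` and whose remaining columns are days in strictly increasing
#' order; `NA` cells mean "not detected or identification not valid", which
#' is distinct from a measured zero. Aggregations treat `NA` as contributing
#' nothing, while reports preserve the distinction.
#'
#' @param x A long tibble with columns `entity`, `day` and `nspc`, or a wide
#'   data frame already shaped `entity` + one column per day.
#' @return A tibble of class `ms_abundance_matrix`.
#' @export
as_abundance_matrix <- function(x) {
  x <- as_tibble(x)
  if (all(c("entity", "day", "nspc") %in% names(x))) {
    wide <- x |>
      mutate(day = as.integer(.data$day)) |>
      arrange(.data$day) |>
      tidyr::pivot_wider(id_cols = "entity", names_from = "day",
                         values_from = "nspc") |>
      arrange(.data$entity)
  } else if (names(x)[1] == "entity") {
    wide <- x
  } else {
    abort("expected columns entity/day/nspc or a wide entity-first table",
          class = "ms_schema_error")
  }
  days <- suppressWarnings(as.integer(names(wide)[-1]))
  if (anyNA(days)) {
    abort("abundance matrix day columns must be integer day labels",
          class = "ms_schema_error")
  }
  wide <- wide[, c(1L, 1L + order(days)), drop = FALSE]
  cells <- as.matrix(wide[, -1, drop = FALSE])
  if (any(cells < 0, na.rm = TRUE)) {
    abort("abundance matrix cells must be non-negative",
          class = "ms_validation_error")
  }
  class(wide) <- c("ms_abundance_matrix", class(tibble()))
  wide
}

#' @export
print.ms_abundance_matrix <- function(x, ...) {
  cat("# NSpC abundance matrix: ", nrow(x), " entities x ",
      ncol(x) - 1L, " days\n", sep = "")
  NextMethod()
}

matrix_days <- function(m) as.integer(names(m)[-1])

#' Tidy an abundance matrix into long form
#'
#' @param x An `ms_abundance_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `entity`, `day`, `nspc` and `detected`
#'   (`FALSE` for not-detected cells, whose `nspc` is `NA`).
#' @method tidy ms_abundance_matrix
#' @export
tidy.ms_abundance_matrix <- function(x, ...) {
  if (ncol(x) == 1) {
    return(tibble(entity = character(), day = integer(),
                  nspc = double(), detected = logical()))
  }
  as_tibble(x) |>
    tidyr::pivot_longer(-"entity", names_to = "day", values_to = "nspc",
                        names_transform = as.integer) |>
    mutate(detected = !is.na(.data$nspc)) |>
    arrange(.data$day, .data$entity)
}

#' Write an abundance matrix as delimited text
#'
#' Mirrors the layout of the published genus-by-day table: rows are
#' entities, columns are days, not-detected cells are written as a
#' configurable token (an em-dash by default) and values are rounded to a
#' fixed number of decimals. Reading the file back with
#' [read_abundance_matrix()] recovers the matrix up to that rounding,
#' missingness included.
#'
#' @param m An `ms_abundance_matrix`.
#' @param path Output path.
#' @param na_token Token written for not-detected cells.
#' @param digits Decimals kept in the output.
#' @export
write_abundance_matrix <- function(m, path, na_token = "—", digits = 2) {
  stopifnot(inherits(m, "ms_abundance_matrix"))
  out <- as_tibble(m)
  out[-1] <- lapply(out[-1], function(v) {
    ifelse(is.na(v), na_token, formatC(round(v, digits), format = "f",
                                       digits = digits))
  })
  names(out) <- c("entity", paste0("day", names(m)[-1]))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an abundance matrix written by [write_abundance_matrix()]
#'
#' @param path Input path.
#' @param na_token Token meaning "not detected".
#' @return An `ms_abundance_matrix`.
#' @export
read_abundance_matrix <- function(path, na_token = "—") {
  df <- readr::read_tsv(path, na = c(na_token, "NA", ""), comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  names(df) <- sub("^day", "", names(df))
  names(df)[1] <- "entity"
  df[-1] <- lapply(df[-1], as.numeric)
  as_abundance_matrix(df)
}

#' Heatmap of an abundance matrix
#'
#' @param object An `ms_abundance_matrix`.
#' @param ... Unused.
#' @return A ggplot object; not-detected cells are blank.
#' @method autoplot ms_abundance_matrix
#' @export
autoplot.ms_abundance_matrix <- function(object, ...) {
  long <- tidy(object) |> filter(.data$detected)
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$day), .data$entity,
                                     fill = .data$nspc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "sqrt", name = "NSpC") +
    ggplot2::labs(x = "Incubation time (d)", y = NULL) +
    ggplot2::theme_minimal()
}
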