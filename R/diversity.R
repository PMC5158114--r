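#' Proportions from non-negative abundances
#'
#' @param x Non-negative numeric abundances with a positive total.
#' @return `x / sum(x)`.
#' @export
as_proportions <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    abort("abundances must be non-negative", class = "ms_domain_error")
  }
  x <- tidyr::replace_na(x, 0)
  total <- sum(x)
  if (total <= 0) {
    abort("total abundance is zero; proportions are undefined",
          class = "ms_domain_error")
  }
  x / total
}

#' Simpson's diversity index
#'
#' `1 - sum(p_i^2)`: the probability that two abundance units drawn at
#' random belong to different categories. Over genus proportions of NSpC it
#' is the taxonomic diversity Dt; over functional-group proportions, the
#' functional diversity Df. The value lies in `[0, 1 - 1/s]` for `s`
#' categories, reaching the upper bound exactly at the uniform
#' distribution and 0 when a single category holds everything.
#'
#' @param p Numeric proportion vector: non-negative, summing to 1 within
#'   `1e-9`. Use [as_proportions()] to normalize raw abundances.
#' @return The index, at full precision (round only for reporting).
#' @export
simpson_index <- function(p) {
  if (length(p) < 1) {
    abort("proportion vector must have at least one entry",
          class = "ms_domain_error")
  }
  if (any(p < 0)) {
    abort("proportions must be non-negative", class = "ms_domain_error")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    abort("proportions must sum to 1 (within 1e-9); see as_proportions()",
          class = "ms_domain_error")
  }
  1 - sum(p^2)
}

#' Per-day Simpson diversity from an abundance matrix
#'
#' Computes one index per day column. Not-detected cells contribute nothing
#' and do not create entities: the proportion vector at each day runs over
#' the entities detected that day. A day with no detected entity (or zero
#' total) yields a missing point rather than 0.
#'
#' @param m An [as_abundance_matrix()] whose cells are NSpC sums — a genus
#'   matrix for Dt, a functional-group matrix for Df.
#' @param kind `"Dt"` (taxonomic) or `"Df"` (functional); recorded as an
#'   attribute and in plots.
#' @return A tibble of class `ms_diversity_series` with columns `day`,
#'   `value`, `s` (number of detected entities) and `total_nspc`.
#' @export
diversity_series <- function(m, kind = c("Dt", "Df")) {
  kind <- match.arg(kind)
  stopifnot(inherits(m, "ms_abundance_matrix"))
  proto <- tibble(day = integer(), value = double(), s = integer(),
                  total_nspc = double())
  points <- purrr::map(matrix_days(m), function(d) {
    cells <- m[[as.character(d)]]
    x <- cells[!is.na(cells)]
    if (length(x) == 0 || sum(x) <= 0) {
      tibble(day = d, value = NA_real_, s = length(x), total_nspc = sum(x))
    } else {
      tibble(day = d, value = simpson_index(as_proportions(x)),
             s = length(x), total_nspc = sum(x))
    }
  })
  points <- bind_rows(proto, points)
  structure(points, kind = kind,
            class = c("ms_diversity_series", class(tibble())))
}

#' @export
print.ms_diversity_series <- function(x, ...) {
  cat("# Simpson diversity series (", attr(x, "kind"), ")\n", sep = "")
  NextMethod()
}

#' Line plot of a diversity series
#'
#' @param object An `ms_diversity_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ms_diversity_series
#' @export
autoplot.ms_diversity_series <- function(object, ...) {
  kind <- attr(object, "kind")
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$value)),
                  ggplot2::aes(.data$day, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Incubation time (d)",
                  y = paste0("Simpson ", kind)) +
    ggplot2::theme_minimal()
}
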